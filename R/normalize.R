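# template character matrix (n x T), column i = templating position i
template_matrix <- function(pairs, template_len) {
  n <- nrow(pairs)
  m <- matrix("", n, template_len)
  for (i in seq_len(template_len)) m[, i] <- substr(pairs$template, i, i)
  m
}

product_matrix <- function(pairs, template_len) {
  n <- nrow(pairs)
  m <- matrix("", n, template_len)
  L <- pairs$length
  for (i in seq_len(template_len)) {
    idx <- which(L >= i)
    m[idx, i] <- substr(pairs$product[idx], i, i)
  }
  m
}

infer_template_len <- function(pairs) {
  if (nrow(pairs) == 0L) {
    abort("cannot infer template length from an empty pair set",
          class = "nerpeseq_data_error")
  }
  tl <- unique(nchar(pairs$template))
  if (length(tl) != 1L) {
    abort("pairs carry templates of differing lengths",
          class = "nerpeseq_data_error")
  }
  tl
}

#' Composition-normalization factors from a no-extension control
#'
#' The synthesized random template region is not perfectly equimolar, so raw
#' product statistics confound incorporation preferences with template
#' composition. A control experiment with no activated nucleotides measures
#' the template composition alone; its per-position base fractions
#' `f(i, b)` yield reweighting factors `w(i, b) = 0.25 / f(i, b)` under which
#' statistics appear as they would if the template were perfectly random with
#' equal base ratios. An exactly uniform control gives all weights 1.
#'
#' @param control_pairs Pair tibble from the control experiment (only the
#'   `template` column is used).
#' @param template_len Template region length; inferred from the pairs when
#'   omitted.
#' @return A `nerpe_norm` object holding the `template_len x 4` weight matrix
#'   `w` and the control fractions `f`. Errors if any base is unobserved at
#'   any position (degenerate control).
#' @examples
#' ctrl <- tibble::tibble(template = c("ACG", "CGU", "GUA", "UAC"),
#'                        product = "", length = 0L)
#' compute_normalization(ctrl)$w
#' @export
compute_normalization <- function(control_pairs, template_len = NULL) {
  if (is.null(template_len)) template_len <- infer_template_len(control_pairs)
  if (nrow(control_pairs) == 0L) {
    abort("control pair set is empty", class = "nerpeseq_data_error")
  }
  tm <- template_matrix(control_pairs, template_len)
  f <- matrix(0, template_len, 4L, dimnames = list(NULL, rna_bases))
  for (i in seq_len(template_len)) {
    tab <- table(factor(tm[, i], levels = rna_bases))
    f[i, ] <- as.numeric(tab) / nrow(control_pairs)
  }
  if (any(f == 0)) {
    abort(
      "degenerate control: some template base is never observed at some position",
      class = "nerpeseq_data_error"
    )
  }
  structure(list(w = 0.25 / f, f = f, n_control = nrow(control_pairs)),
            class = "nerpe_norm")
}

#' Uniform (identity) normalization
#'
#' All weights 1: statistics computed under it equal unnormalized statistics
#' exactly.
#' @param template_len Template region length.
#' @return A `nerpe_norm` object.
#' @export
uniform_normalization <- function(template_len) {
  f <- matrix(0.25, template_len, 4L, dimnames = list(NULL, rna_bases))
  structure(list(w = 0.25 / f, f = f, n_control = NA_integer_),
            class = "nerpe_norm")
}

#' @export
print.nerpe_norm <- function(x, ...) {
  cat("<nerpe_norm> per-position, per-base weights over",
      nrow(x$w), "template positions\n")
  cat("  weight range: [", format(min(x$w), digits = 4), ", ",
      format(max(x$w), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nerpe_norm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(nrow(x$w)), 4L),
    base = rep(rna_bases, each = nrow(x$w)),
    f_control = as.vector(x$f),
    weight = as.vector(x$w)
  ) |> dplyr::arrange(.data$position, .data$base)
}

#' Per-pair composition weights
#'
#' The weight of a pair over a set of template positions is the product of
#' the normalization factors `w(i, t_i)` of its template bases at those
#' positions. Positional statistics use positions `1..L`; trimer statistics
#' use the three window positions.
#'
#' @param pairs Pair tibble.
#' @param norm A `nerpe_norm`, or `NULL` for uniform weights.
#' @param positions Integer positions entering the statistic; the default
#'   `NULL` means positions `1..L` of each pair (capped at its own product
#'   length).
#' @return Numeric vector of positive weights, one per pair.
#' @export
pair_weight <- function(pairs, norm = NULL, positions = NULL) {
  n <- nrow(pairs)
  if (is.null(norm)) return(rep(1, n))
  stopifnot(inherits(norm, "nerpe_norm"))
  w <- rep(1, n)
  tl <- nrow(norm$w)
  L <- pairs$length
  pos <- if (is.null(positions)) seq_len(tl) else as.integer(positions)
  if (any(pos < 1L | pos > tl)) {
    abort("positions outside the template region", class = "nerpeseq_data_error")
  }
  for (i in pos) {
    ti <- substr(pairs$template, i, i)
    wi <- norm$w[i, ][ti]
    if (is.null(positions)) {
      use <- L >= i
      w[use] <- w[use] * wi[use]
    } else {
      w <- w * wi
    }
  }
  unname(w)
}
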