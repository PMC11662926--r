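#' Compute the full statistics bundle for one experiment
#'
#' Runs every product statistic on a pair set: yield and length distribution,
#' cumulative incorporation, error frequency, product-class fractions,
#' composition-normalized positional base frequencies (complementary products
#' and all products), trimer tables for windows 1-2-3 and 4-5-6, and the
#' mismatch spectrum. When `control_pairs` is supplied, normalization factors
#' are computed from the control template composition and applied to the
#' frequency tables; error frequency and the mismatch spectrum stay
#' unweighted.
#'
#' @param pairs Pair tibble for the experiment.
#' @param control_pairs Pair tibble from the matched no-extension control, or
#'   `NULL` to skip composition normalization.
#' @param normalize Apply composition normalization (default: yes when a
#'   control is given).
#' @param template_len Template region length; inferred when omitted.
#' @return A `nerpe_stats` object (list). Methods: `print()`, `glance()`
#'   (one-row scalar summary), `tidy()` (long table of all frequency tables),
#'   [summary_json()], [write_stats()].
#' @examples
#' p <- simulate_pairs(simulation_params(n_reads = 2000, seed = 1))
#' st <- nerpe_statistics(p)
#' glance(st)
#' @export
nerpe_statistics <- function(pairs, control_pairs = NULL,
                             normalize = !is.null(control_pairs),
                             template_len = NULL) {
  if (is.null(template_len)) template_len <- infer_template_len(pairs)
  norm <- if (normalize) {
    if (is.null(control_pairs)) {
      abort("normalize = TRUE requires control pairs",
            class = "nerpeseq_config_error")
    }
    compute_normalization(control_pairs, template_len)
  } else {
    uniform_normalization(template_len)
  }
  yl <- yield_and_lengths(pairs, template_len)
  tri1 <- tryCatch(trimer_frequencies(pairs, norm, window = 1),
                   nerpeseq_data_error = function(e) NULL)
  tri4 <- tryCatch(trimer_frequencies(pairs, norm, window = 4),
                   nerpeseq_data_error = function(e) NULL)
  any_ext <- any(extended(pairs))
  structure(
    list(
      n_pairs = nrow(pairs),
      template_len = template_len,
      normalized = normalize,
      yield_fraction = yl$yield_fraction,
      length_distribution = yl$length_distribution,
      cumulative_incorporation = yl$cumulative_incorporation,
      error_frequency = if (any_ext) error_frequency(pairs) else NA_real_,
      class_fractions = if (any_ext) product_class_fractions(pairs) else NULL,
      positional_complementary =
        positional_frequencies(pairs, norm, "complementary", template_len),
      positional_all =
        positional_frequencies(pairs, norm, "all", template_len),
      trimer_123 = tri1,
      trimer_456 = tri4,
      mismatch_spectrum = mismatch_spectrum(pairs, NULL, template_len),
      normalization = norm
    ),
    class = "nerpe_stats"
  )
}

#' @export
print.nerpe_stats <- function(x, ...) {
  g <- glance(x)
  cat("<nerpe_stats> ", x$n_pairs, " template-product pairs",
      if (x$normalized) ", composition-normalized" else "", "\n", sep = "")
  cat(sprintf("  yield: %.3f   error frequency: %.3f   complementary: %.3f\n",
              g$yield_fraction, g$error_frequency, g$complementary_fraction))
  if (!is.na(g$trimer_123_median)) {
    cat(sprintf("  trimer 1-2-3: median %.3f, max/min %s\n",
                g$trimer_123_median,
                format(round(g$trimer_123_max_min_ratio))))
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row scalar summary of a statistics bundle
#'
#' @param x A `nerpe_stats` object.
#' @param ... Unused.
#' @return A one-row tibble of the scalar statistics: pair counts, yield,
#'   error frequency, product-class fractions, and trimer medians/extremes
#'   for both windows (NA where a window had no qualifying products).
#' @exportS3Method generics::glance
glance.nerpe_stats <- function(x, ...) {
  cf <- x$class_fractions
  if (is.null(cf)) {
    cf <- tibble::tibble(complementary_fraction = NA_real_,
                         multi_mismatch_fraction = NA_real_,
                         terminal_mismatch_fraction = NA_real_,
                         n_extended = 0L)
  }
  tri_cols <- function(tt, prefix) {
    if (is.null(tt)) {
      out <- tibble::tibble(a = NA_real_, b = NA_real_, c = NA_real_,
                            d = NA_real_)
    } else {
      s <- trimer_summary(tt)
      out <- tibble::tibble(a = s$median, b = s$min, c = s$max,
                            d = s$max_min_ratio)
    }
    stats::setNames(out, paste0(prefix, c("median", "min", "max",
                                          "max_min_ratio")))
  }
  dplyr::bind_cols(
    tibble::tibble(
      n_pairs = x$n_pairs,
      yield_fraction = x$yield_fraction,
      error_frequency = x$error_frequency
    ),
    cf,
    tri_cols(x$trimer_123, "trimer_123_"),
    tri_cols(x$trimer_456, "trimer_456_")
  )
}

#' Long-format view of all frequency tables in a bundle
#'
#' @param x A `nerpe_stats` object.
#' @param ... Unused.
#' @return A tibble with columns `table`, `term`, `position`, `value`
#'   stacking the positional, trimer, mismatch-spectrum, length and
#'   cumulative tables.
#' @exportS3Method generics::tidy
tidy.nerpe_stats <- function(x, ...) {
  pieces <- list(
    positional_complementary = dplyr::transmute(
      x$positional_complementary, term = .data$base,
      position = .data$position, value = .data$freq),
    positional_all = dplyr::transmute(
      x$positional_all, term = .data$base, position = .data$position,
      value = .data$freq),
    mismatch_spectrum = dplyr::transmute(
      x$mismatch_spectrum, term = .data$type, position = .data$position,
      value = .data$freq),
    length_distribution = dplyr::transmute(
      x$length_distribution, term = "L", position = .data$length,
      value = .data$freq),
    cumulative_incorporation = dplyr::transmute(
      x$cumulative_incorporation, term = "extended",
      position = .data$position, value = .data$fraction)
  )
  if (!is.null(x$trimer_123)) {
    pieces$trimer_123 <- dplyr::transmute(
      tibble::as_tibble(x$trimer_123), term = .data$trimer,
      position = NA_integer_, value = .data$freq)
  }
  if (!is.null(x$trimer_456)) {
    pieces$trimer_456 <- dplyr::transmute(
      tibble::as_tibble(x$trimer_456), term = .data$trimer,
      position = NA_integer_, value = .data$freq)
  }
  dplyr::bind_rows(pieces, .id = "table")
}

#' Canonical JSON summary of a statistics bundle
#'
#' Serializes the scalar summary plus every table at full precision with
#' stable ordering, so two bundles computed from identical pairs serialize to
#' byte-identical strings — the basis of the pipeline's determinism and
#' lossless round-trip checks.
#'
#' @param x A `nerpe_stats` object.
#' @return A JSON string (class `json`).
#' @export
summary_json <- function(x) {
  stopifnot(inherits(x, "nerpe_stats"))
  g <- glance(x)
  obj <- list(
    schema = "nerpeseq/summary/1",
    n_pairs = x$n_pairs,
    template_len = x$template_len,
    normalized = x$normalized,
    scalars = as.list(g),
    length_distribution = as.data.frame(x$length_distribution),
    cumulative_incorporation = as.data.frame(x$cumulative_incorporation),
    positional_complementary = as.data.frame(x$positional_complementary),
    positional_all = as.data.frame(x$positional_all),
    trimer_123 = if (!is.null(x$trimer_123)) as.data.frame(x$trimer_123),
    trimer_456 = if (!is.null(x$trimer_456)) as.data.frame(x$trimer_456),
    mismatch_spectrum = as.data.frame(x$mismatch_spectrum)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                   null = "null")
}

#' Write all bundle artifacts to a directory
#'
#' One TSV per table (positional complementary/all, trimer 1-2-3 and 4-5-6,
#' mismatch spectrum, length distribution, cumulative incorporation,
#' normalization factors) plus `summary.json`.
#'
#' @param x A `nerpe_stats` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stats <- function(x, dir) {
  stopifnot(inherits(x, "nerpe_stats"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(tbl, name) {
    if (!is.null(tbl)) {
      readr::write_tsv(as.data.frame(tbl), file.path(dir, name))
    }
  }
  tsv(x$positional_complementary, "positional_complementary.tsv")
  tsv(x$positional_all, "positional_all.tsv")
  tsv(x$trimer_123, "trimer_123.tsv")
  tsv(x$trimer_456, "trimer_456.tsv")
  tsv(x$mismatch_spectrum, "mismatch_spectrum.tsv")
  tsv(x$length_distribution, "length_distribution.tsv")
  tsv(x$cumulative_incorporation, "cumulative_incorporation.tsv")
  tsv(tidy(x$normalization), "normalization_factors.tsv")
  writeLines(summary_json(x), file.path(dir, "summary.json"))
  invisible(dir)
}
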