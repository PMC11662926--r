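# logical mismatch matrix (n x T): TRUE where product base i violates
# Watson-Crick pairing with template base i; FALSE where matched or absent
mismatch_matrix <- function(pairs, template_len) {
  n <- nrow(pairs)
  m <- matrix(FALSE, n, template_len)
  L <- pairs$length
  for (i in seq_len(template_len)) {
    idx <- which(L >= i)
    if (!length(idx)) next
    ti <- substr(pairs$template[idx], i, i)
    pi <- substr(pairs$product[idx], i, i)
    m[idx, i] <- pi != chartr("ACGU", "UGCA", ti)
  }
  m
}

extended <- function(pairs) pairs$length >= 1L

#' Position-normalized product base frequencies
#'
#' For each product position `+i`, the composition-weighted fraction of
#' selected products carrying each base at that position:
#' `F(i, b) = sum of weights of selected products with p_i = b` divided by
#' the summed weights of selected products covering position `i`. With
#' `products = "complementary"` (the default, matching how product
#' composition is usually reported) only zero-mismatch products are selected;
#' `"all"` uses every extended product.
#'
#' @param pairs Pair tibble.
#' @param norm A `nerpe_norm` from [compute_normalization()], or `NULL` for
#'   unnormalized frequencies.
#' @param products `"complementary"` or `"all"`.
#' @param template_len Template region length; inferred when omitted.
#' @return A tibble with columns `position`, `base`, `freq`, `n_eff` (summed
#'   weights at the position). Positions covered by no selected product have
#'   `freq = NA` and `n_eff = 0`. Defined rows sum to 1 over bases.
#' @export
positional_frequencies <- function(pairs, norm = NULL,
                                   products = c("complementary", "all"),
                                   template_len = NULL) {
  products <- match.arg(products)
  if (is.null(template_len)) template_len <- infer_template_len(pairs)
  sel <- extended(pairs)
  if (products == "complementary") sel <- sel & pairs$n_mismatch == 0L
  sub <- pairs[sel, , drop = FALSE]
  w <- pair_weight(sub, norm)
  out <- vector("list", template_len)
  for (i in seq_len(template_len)) {
    idx <- which(sub$length >= i)
    denom <- sum(w[idx])
    pi <- substr(sub$product[idx], i, i)
    num <- vapply(rna_bases, function(b) sum(w[idx][pi == b]), 0)
    out[[i]] <- tibble::tibble(
      position = i, base = rna_bases,
      freq = if (denom > 0) unname(num) / denom else rep(NA_real_, 4L),
      n_eff = denom
    )
  }
  dplyr::bind_rows(out)
}

#' Mean frequency of one base over a range of product positions
#'
#' @param freq_table Output of [positional_frequencies()].
#' @param base One of `"A", "C", "G", "U"`.
#' @param positions Product positions to average over (e.g. `1:4`).
#' @return The arithmetic mean of `F(i, base)` over the range.
#' @export
mean_base_frequency <- function(freq_table, base, positions) {
  stopifnot(base %in% rna_bases, length(positions) >= 1L)
  rows <- freq_table$base == base & freq_table$position %in% positions
  vals <- freq_table$freq[rows]
  if (length(vals) != length(positions) || anyNA(vals)) {
    abort("requested positions are not all populated",
          class = "nerpeseq_data_error")
  }
  mean(vals)
}

#' Trimer frequency table of complementary products
#'
#' Each fully complementary product at least `window + 2` nucleotides long
#' contributes its product-base trimer at positions `window..window+2`
#' (window 1 = positions +1+2+3, window 4 = positions +4+5+6), weighted by
#' the composition factors of the three window positions. Frequencies are
#' normalized to sum to 1 over all 64 trimers (zeros kept).
#'
#' @param pairs Pair tibble.
#' @param norm A `nerpe_norm` or `NULL`.
#' @param window First position of the trimer window, 1 or 4.
#' @return A `nerpe_trimers` tibble with columns `trimer` (all 64, sorted)
#'   and `freq`; summarize with [trimer_summary()].
#' @export
trimer_frequencies <- function(pairs, norm = NULL, window = 1) {
  window <- as.integer(window)
  if (!window %in% c(1L, 4L)) {
    abort("`window` must be 1 (positions 1-2-3) or 4 (positions 4-5-6)",
          class = "nerpeseq_config_error")
  }
  qual <- extended(pairs) & pairs$n_mismatch == 0L &
    pairs$length >= window + 2L
  if (!any(qual)) {
    abort("no fully complementary products long enough for this window",
          class = "nerpeseq_data_error")
  }
  sub <- pairs[qual, , drop = FALSE]
  w <- pair_weight(sub, norm, positions = window:(window + 2L))
  tri <- substr(sub$product, window, window + 2L)
  tot <- as.numeric(tapply(w, factor(tri, levels = all_trimers), sum,
                           default = 0))
  out <- tibble::tibble(trimer = all_trimers, freq = tot / sum(tot))
  structure(out, window = window, n_products = nrow(sub),
            class = c("nerpe_trimers", class(out)))
}

#' Summary statistics of a trimer frequency table
#'
#' The median is taken over all 64 trimers, zeros included (unobserved
#' trimers rank at the bottom of the distribution). The minimum, maximum and
#' max/min fold-difference are taken over *represented* (nonzero) trimers
#' only.
#'
#' @param trimer_table A table with columns `trimer` and `freq` covering all
#'   64 trimers (as produced by [trimer_frequencies()]).
#' @return One-row tibble: `median`, `min`, `max`, `min_trimer`,
#'   `max_trimer`, `max_min_ratio`, `n_represented`.
#' @export
trimer_summary <- function(trimer_table) {
  f <- trimer_table$freq
  if (length(f) != 64L) {
    abort("a trimer table must have 64 rows", class = "nerpeseq_data_error")
  }
  rep_idx <- which(f > 0)
  lo <- rep_idx[which.min(f[rep_idx])]
  hi <- rep_idx[which.max(f[rep_idx])]
  tibble::tibble(
    median = stats::median(f),
    min = f[lo], max = f[hi],
    min_trimer = trimer_table$trimer[lo],
    max_trimer = trimer_table$trimer[hi],
    max_min_ratio = f[hi] / f[lo],
    n_represented = length(rep_idx)
  )
}

#' Overall error frequency of incorporation
#'
#' The fraction of all incorporated product bases that violate Watson-Crick
#' complementarity to their templating base, over all extended products:
#' total mismatch calls divided by total product bases. Computed unweighted
#' by default — composition normalization reweights *which* templates are
#' counted, which is a statement about bias, not fidelity; pass a
#' `nerpe_norm` to get the composition-weighted variant.
#'
#' @param pairs Pair tibble.
#' @param norm `NULL` (default, unweighted) or a `nerpe_norm` for the
#'   weighted variant (per-pair weight over positions `1..L`).
#' @return A single frequency in `[0, 1]`.
#' @export
error_frequency <- function(pairs, norm = NULL) {
  ext <- pairs[extended(pairs), , drop = FALSE]
  if (nrow(ext) == 0L) {
    abort("no extended products", class = "nerpeseq_data_error")
  }
  w <- pair_weight(ext, norm)
  sum(w * ext$n_mismatch) / sum(w * ext$length)
}

#' Mismatch spectrum by product position
#'
#' Counts each of the 12 `template:product` mismatch types at each product
#' position and normalizes over all mismatches, so the full matrix sums to 1
#' whenever any mismatch exists. Unweighted by default (see
#' [error_frequency()] for the rationale).
#'
#' @param pairs Pair tibble.
#' @param norm `NULL` or a `nerpe_norm` (weighted variant).
#' @param template_len Template region length; inferred when omitted.
#' @return A tibble with columns `type` (12 levels), `position` (1..T) and
#'   `freq`. The position marginal is `dplyr::count(x, position, wt = freq)`.
#' @export
mismatch_spectrum <- function(pairs, norm = NULL, template_len = NULL) {
  if (is.null(template_len)) template_len <- infer_template_len(pairs)
  types <- mismatch_types()
  w <- pair_weight(pairs, norm)
  grid <- tidyr::expand_grid(type = types, position = seq_len(template_len))
  counts <- numeric(nrow(grid))
  L <- pairs$length
  for (i in seq_len(template_len)) {
    idx <- which(L >= i)
    if (!length(idx)) next
    ti <- substr(pairs$template[idx], i, i)
    pi <- substr(pairs$product[idx], i, i)
    bad <- pi != chartr("ACGU", "UGCA", ti)
    if (!any(bad)) next
    lab <- paste0(ti[bad], ":", pi[bad])
    agg <- tapply(w[idx][bad], factor(lab, levels = types), sum, default = 0)
    counts[grid$position == i] <- as.numeric(agg)
  }
  tot <- sum(counts)
  dplyr::mutate(grid, freq = if (tot > 0) counts / tot else counts)
}

#' Product classes: complementary, multi-mismatch, terminal-mismatch
#'
#' Over extended products: the fraction that are fully complementary; among
#' products with at least one mismatch, the fraction with more than one; and
#' among products with exactly one mismatch, the fraction whose mismatch sits
#' at the 3'-terminal (last-added) position. Conditional fractions with an
#' empty denominator are `NA` (undefined), never 0.
#'
#' @param pairs Pair tibble.
#' @return One-row tibble: `complementary_fraction`,
#'   `multi_mismatch_fraction`, `terminal_mismatch_fraction`, `n_extended`.
#' @export
product_class_fractions <- function(pairs) {
  ext <- pairs[extended(pairs), , drop = FALSE]
  if (nrow(ext) == 0L) {
    abort("no extended products", class = "nerpeseq_data_error")
  }
  nm <- ext$n_mismatch
  one <- ext[nm == 1L, , drop = FALSE]
  terminal <- if (nrow(one) > 0L) {
    # the single mismatch position is the leading integer of the label
    pos <- as.integer(sub(":.*$", "", one$mismatches))
    mean(pos == one$length)
  } else NA_real_
  tibble::tibble(
    complementary_fraction = mean(nm == 0L),
    multi_mismatch_fraction = if (any(nm >= 1L)) {
      mean(nm[nm >= 1L] > 1L)
    } else NA_real_,
    terminal_mismatch_fraction = terminal,
    n_extended = nrow(ext)
  )
}

#' Yield, product-length distribution and cumulative incorporation
#'
#' Yield is the fraction of all hairpin primers extended by at least one
#' nucleotide. The length distribution covers `L = 0..T`. The cumulative
#' incorporation at position `i` is the fraction of *all* pairs whose product
#' reaches position `i`, split by whether the call at position `i` itself is
#' correct or incorrect; it is non-increasing in `i` and its value at
#' position 1 equals the yield.
#'
#' @param pairs Pair tibble (must include unextended, `L = 0`, records for
#'   the yield to be meaningful).
#' @param template_len Template region length; inferred when omitted.
#' @return A list with `yield_fraction`, `length_distribution` (tibble
#'   `length`, `n`, `freq`) and `cumulative_incorporation` (tibble
#'   `position`, `fraction` = correct + incorrect, `correct`, `incorrect`).
#' @export
yield_and_lengths <- function(pairs, template_len = NULL) {
  if (is.null(template_len)) template_len <- infer_template_len(pairs)
  n <- nrow(pairs)
  if (n == 0L) abort("empty pair set", class = "nerpeseq_data_error")
  L <- pairs$length
  tabL <- table(factor(L, levels = 0:template_len))
  mm <- mismatch_matrix(pairs, template_len)
  cum <- lapply(seq_len(template_len), function(i) {
    covered <- L >= i
    tibble::tibble(
      position = i,
      fraction = mean(covered),
      correct = mean(covered & !mm[, i]),
      incorrect = mean(covered & mm[, i])
    )
  })
  list(
    yield_fraction = mean(L >= 1L),
    length_distribution = tibble::tibble(
      length = 0:template_len, n = as.integer(tabL),
      freq = as.integer(tabL) / nrow(pairs)
    ),
    cumulative_incorporation = dplyr::bind_rows(cum)
  )
}
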