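#' Read paired FASTQ files into a read-pair table
#'
#' Reads standard 4-line Phred+33 FASTQ (optionally gzipped) for the forward
#' and reverse mates and pairs records positionally. Sequences stay in the
#' DNA alphabet here; the T-to-U mapping happens when template-product pairs
#' are extracted.
#'
#' @param fwd_path,rev_path Paths to the forward (R1) and reverse (R2) FASTQ
#'   files.
#' @return A tibble with columns `id`, `fwd_seq`, `rev_seq`, `fwd_qual`,
#'   `rev_qual`.
#' @export
read_pairs_fastq <- function(fwd_path, rev_path) {
  for (p in c(fwd_path, rev_path)) {
    if (!file.exists(p)) {
      abort(paste0("FASTQ file not found: ", p),
            class = "nerpeseq_config_error")
    }
  }
  f <- Biostrings::readDNAStringSet(fwd_path, format = "fastq",
                                    with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(rev_path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(f) != length(r)) {
    abort("forward and reverse FASTQ files have different record counts",
          class = "nerpeseq_data_error")
  }
  ids <- sub("\\s.*$", "", names(f))
  tibble::tibble(
    id = ids,
    fwd_seq = as.character(f),
    rev_seq = as.character(r),
    fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
    rev_qual = as.character(S4Vectors::mcols(r)$qualities)
  )
}

#' Filter read pairs on mean base quality
#'
#' A pair passes when the mean Phred score of each mate is at least
#' `min_mean_q` (the boundary is inclusive). The companion per-base threshold
#' is enforced later, on the template and product windows of the merged
#' insert, where the bases actually enter statistics — see [extract_pairs()].
#'
#' @param read_pairs Tibble from [read_pairs_fastq()].
#' @param min_mean_q Minimum mean Phred score per mate (default 30).
#' @return The input tibble with a logical `pass_quality` column added.
#' @export
quality_filter <- function(read_pairs, min_mean_q = 30) {
  mq_f <- cpp_mean_qual(read_pairs$fwd_qual)
  mq_r <- cpp_mean_qual(read_pairs$rev_qual)
  if (anyNA(mq_f) || anyNA(mq_r)) {
    abort("malformed (empty) quality string", class = "nerpeseq_data_error")
  }
  dplyr::mutate(read_pairs, pass_quality = mq_f >= min_mean_q & mq_r >= min_mean_q)
}

#' Merge overlapping mates into a consensus insert
#'
#' The forward read covers the insert 5' end and the reverse read (reverse-
#' complemented) its 3' end. Candidate insert sizes compatible with the
#' construct (fixed regions plus 0 to `template_len` product bases) are
#' scanned and the size minimizing overlap disagreements is chosen. A pair is
#' rejected (`mates_disagree`) when no candidate overlaps by at least
#' `min_overlap` bases with at most `max_disagreements` conflicting
#' positions; at a retained disagreeing position the higher-quality base
#' wins.
#'
#' @param read_pairs Tibble with `fwd_seq`, `rev_seq`, `fwd_qual`, `rev_qual`
#'   (DNA alphabet).
#' @param spec A [construct_spec()]; bounds the candidate insert sizes.
#' @param max_disagreements Maximum tolerated conflicting overlap positions
#'   (default 0).
#' @param min_overlap Minimum usable overlap in bases (default 10).
#' @return The input tibble with columns `merged`, `merged_qual`,
#'   `insert_len` (NA where merging failed) added.
#' @export
merge_mates <- function(read_pairs, spec, max_disagreements = 0,
                        min_overlap = 10) {
  stopifnot(inherits(spec, "construct_spec"))
  revrc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(read_pairs$rev_seq))
  )
  res <- cpp_merge_pairs(
    read_pairs$fwd_seq, revrc, read_pairs$fwd_qual, read_pairs$rev_qual,
    min_n = fixed_insert_len(spec),
    max_n = fixed_insert_len(spec) + spec$template_len,
    min_overlap = as.integer(min_overlap),
    max_disagreements = as.integer(max_disagreements)
  )
  dplyr::mutate(read_pairs, merged = res$merged, merged_qual = res$qual,
                insert_len = res$insert_len)
}

#' Locate the construct's fixed regions in merged inserts
#'
#' Anchors each fixed region (`handle5`, `loop`, `primer`, `rt_handle`) by
#' substitution-only (Hamming) matching within `search_window` bases of its
#' architectural offset, tolerating up to `spec$max_region_mismatches`
#' substitutions per region. No indels are considered: the template window
#' between `handle5` and `loop` must have exactly `template_len` bases. All
#' coordinates are 0-based, half-open.
#'
#' @param merged Tibble with `merged` and `merged_qual` columns (from
#'   [merge_mates()]), or a character vector of merged inserts.
#' @param spec A [construct_spec()].
#' @param search_window Offset slack per region in bases (default 3).
#' @param min_base_q Minimum Phred score for every template/product-window
#'   base (default 20, inclusive).
#' @return A tibble with `status` (`"ok"`, `"fixed_region_mismatch"`,
#'   `"product_overrun"`, `"template_has_ambiguity"`, `"low_quality"`),
#'   `template_start`, `template_end`, `product_start`, `product_end`.
#' @export
locate_regions <- function(merged, spec, search_window = 3, min_base_q = 20) {
  stopifnot(inherits(spec, "construct_spec"))
  if (is.character(merged)) {
    merged <- tibble::tibble(
      merged = merged,
      merged_qual = strrep("~", nchar(merged))
    )
  }
  res <- locate_extract_cpp(merged, spec, search_window, min_base_q)
  tibble::tibble(
    status = status_labels()[res$status + 1L],
    template_start = res$template_start,
    template_end = res$template_start + spec$template_len,
    product_start = res$product_start,
    product_end = res$product_start + res$product_len
  )
}

status_labels <- function() {
  c("ok", "fixed_region_mismatch", "product_overrun",
    "template_has_ambiguity", "low_quality")
}

locate_extract_cpp <- function(merged, spec, search_window, min_base_q) {
  cpp_locate_extract(
    merged$merged, merged$merged_qual,
    h5 = chartr("U", "T", spec$handle5),
    loop = chartr("U", "T", spec$loop),
    primer = chartr("U", "T", spec$primer),
    rt = chartr("U", "T", spec$rt_handle),
    template_len = spec$template_len,
    window = as.integer(search_window),
    max_region_mm = spec$max_region_mismatches,
    min_base_q = as.integer(min_base_q)
  )
}

#' Extract one template-product pair from a merged insert
#'
#' Cuts the template and product windows at the given coordinates, maps T to
#' U, and re-indexes the template into templating order: the template base
#' adjacent to the primer 3' terminus (the 3'-most base of the template
#' window) becomes position 1, pairing with the first-added product base.
#'
#' @param merged_seq A single merged insert (character).
#' @param coords One row of [locate_regions()] output (list or data frame
#'   row) with `template_start`, `template_end`, `product_start`,
#'   `product_end`.
#' @param spec A [construct_spec()].
#' @return A one-row tibble with `template` (templating order), `product`
#'   (order of addition), `length`, `n_mismatch` and `mismatches` (compact
#'   `pos:template:product` labels, `;`-separated).
#' @export
extract_pair <- function(merged_seq, coords, spec) {
  stopifnot(length(merged_seq) == 1L)
  tpl <- substr(merged_seq, coords$template_start + 1L, coords$template_end)
  prd <- substr(merged_seq, coords$product_start + 1L, coords$product_end)
  tpl <- chartr("T", "U", tpl)
  prd <- chartr("T", "U", prd)
  if (grepl("[^ACGU]", tpl) || (nchar(prd) > 0L && grepl("[^ACGU]", prd))) {
    abort("template or product window contains an ambiguous base",
          class = "nerpeseq_data_error")
  }
  if (nchar(prd) > spec$template_len) {
    abort("product window longer than the template region",
          class = "nerpeseq_length_error")
  }
  finish_pairs(tibble::tibble(id = NA_character_, template = str_rev(tpl),
                              product = prd))
}

# vectorized mismatch annotation; template already in templating order (RNA)
finish_pairs <- function(pairs) {
  n <- nrow(pairs)
  L <- nchar(pairs$product)
  n_mm <- integer(n)
  mm_row <- integer(0)
  mm_lab <- character(0)
  for (i in seq_len(max(L, 0L))) {
    idx <- which(L >= i)
    ti <- substr(pairs$template[idx], i, i)
    pi <- substr(pairs$product[idx], i, i)
    bad <- pi != chartr("ACGU", "UGCA", ti)
    n_mm[idx] <- n_mm[idx] + bad
    if (any(bad)) {
      j <- idx[bad]
      mm_row <- c(mm_row, j)
      mm_lab <- c(mm_lab, paste0(i, ":", ti[bad], ":", pi[bad]))
    }
  }
  mmstr <- character(n)
  if (length(mm_row)) {
    agg <- vapply(split(mm_lab, mm_row), paste0, "", collapse = ";")
    mmstr[as.integer(names(agg))] <- agg
  }
  dplyr::mutate(pairs, length = as.integer(L), n_mismatch = n_mm,
                mismatches = mmstr)
}

#' Extract template-product pairs from paired reads
#'
#' The full read-processing stage: mean-quality filtering, mate merging,
#' fixed-region location (with an orientation retry on the reverse
#' complement, so mate-swapped inputs extract identically), per-base quality
#' and ambiguity screening of the template and product windows, and
#' template-product extraction. Every input pair is accounted for exactly
#' once, either as an accepted pair or under one rejection reason; the
#' accounting is returned by [filter_report()].
#'
#' @param read_pairs Tibble from [read_pairs_fastq()].
#' @param spec A [construct_spec()].
#' @param min_mean_q,min_base_q Quality thresholds (inclusive; defaults 30
#'   and 20). The per-base threshold applies to template and product window
#'   bases of the merged insert.
#' @param max_disagreements,min_overlap Mate-merging controls, see
#'   [merge_mates()].
#' @param search_window Fixed-region offset slack, see [locate_regions()].
#' @return A `nerpe_pairs` tibble of accepted pairs with columns `id`,
#'   `template` (templating order), `product` (order of addition), `length`,
#'   `n_mismatch`, `mismatches`, carrying the filter report as an attribute.
#' @examples
#' spec <- construct_spec()
#' sim <- simulate_experiment(simulation_params(n_reads = 50, seed = 1),
#'                            spec, dir = tempfile("sim"))
#' pairs <- extract_pairs(read_pairs_fastq(sim$experiment_r1, sim$experiment_r2), spec)
#' filter_report(pairs)
#' @export
extract_pairs <- function(read_pairs, spec, min_mean_q = 30, min_base_q = 20,
                          max_disagreements = 0, min_overlap = 10,
                          search_window = 3) {
  stopifnot(inherits(spec, "construct_spec"))
  n_total <- nrow(read_pairs)
  reasons <- c("low_quality", "mates_disagree", "fixed_region_mismatch",
               "template_has_ambiguity", "product_overrun")
  counts <- stats::setNames(integer(length(reasons)), reasons)

  rp <- quality_filter(read_pairs, min_mean_q = min_mean_q)
  counts["low_quality"] <- sum(!rp$pass_quality)
  rp <- dplyr::filter(rp, .data$pass_quality)

  if (nrow(rp) > 0L) {
    rp <- merge_mates(rp, spec, max_disagreements = max_disagreements,
                      min_overlap = min_overlap)
    counts["mates_disagree"] <- sum(is.na(rp$merged))
    rp <- dplyr::filter(rp, !is.na(.data$merged))
  }

  if (nrow(rp) > 0L) {
    res <- locate_extract_cpp(rp, spec, search_window, min_base_q)
    # orientation retry: a merged insert assembled from swapped mates is the
    # reverse complement of the construct; re-locate before rejecting
    retry <- which(res$status == 1L)
    if (length(retry)) {
      flipped <- tibble::tibble(
        merged = as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rp$merged[retry])
        )),
        merged_qual = str_rev(rp$merged_qual[retry])
      )
      res2 <- locate_extract_cpp(flipped, spec, search_window, min_base_q)
      fixed <- which(res2$status != 1L)
      for (nm in names(res)) res[[nm]][retry[fixed]] <- res2[[nm]][fixed]
    }
    st <- res$status
    counts["fixed_region_mismatch"] <- sum(st == 1L)
    counts["product_overrun"] <- sum(st == 2L)
    counts["template_has_ambiguity"] <- sum(st == 3L)
    counts["low_quality"] <- counts["low_quality"] + sum(st == 4L)
    keep <- st == 0L
    pairs <- tibble::tibble(
      id = rp$id[keep],
      template = str_rev(chartr("T", "U", res$template[keep])),
      product = chartr("T", "U", res$product[keep])
    )
  } else {
    pairs <- tibble::tibble(id = character(), template = character(),
                            product = character())
  }
  pairs <- finish_pairs(pairs)
  report <- tibble::tibble(
    reason = c("accepted", reasons),
    count = c(nrow(pairs), unname(counts))
  )
  attr(report, "total") <- n_total
  structure(pairs, filter_report = report,
            class = c("nerpe_pairs", class(pairs)))
}

#' @rdname extract_pairs
#' @param fwd_path,rev_path FASTQ paths, passed to [read_pairs_fastq()].
#' @param ... Passed on to `extract_pairs()`.
#' @export
extract_pairs_fastq <- function(fwd_path, rev_path, spec, ...) {
  extract_pairs(read_pairs_fastq(fwd_path, rev_path), spec, ...)
}

#' Filter accounting for an extraction run
#'
#' @param pairs A `nerpe_pairs` tibble from [extract_pairs()].
#' @return A tibble of `reason`/`count` rows (`accepted` plus the five
#'   rejection reasons); counts sum to the number of input read pairs,
#'   available as `attr(, "total")`.
#' @export
filter_report <- function(pairs) {
  rep <- attr(pairs, "filter_report")
  if (is.null(rep)) {
    abort("no filter report attached; was this produced by extract_pairs()?",
          class = "nerpeseq_data_error")
  }
  rep
}

#' Write or read a template-product pair table
#'
#' Plain TSV with columns `id`, `template` (templating order), `product`,
#' `length`, `n_mismatch`, `mismatches`.
#'
#' @param pairs Pair tibble.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(as.data.frame(pairs), path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_character(), template = readr::col_character(),
      product = readr::col_character(), length = readr::col_integer(),
      n_mismatch = readr::col_integer(), mismatches = readr::col_character()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(
      product = dplyr::coalesce(.data$product, ""),
      mismatches = dplyr::coalesce(.data$mismatches, "")
    )
}
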