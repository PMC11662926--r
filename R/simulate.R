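#' Parameters of the synthetic read generator
#'
#' Defines the full generative model for a primer-extension sequencing
#' experiment on the hairpin construct. Defaults reflect the headline
#' conditions of the mixed mononucleotide + random-oligo copying chemistry
#' this package analyses: 23% of primers extended, a per-incorporated-base
#' substitution probability of 0.063 spread uniformly over the three wrong
#' bases, a truncated-geometric product-length distribution with mean 3, a
#' uniform random template, and occasional ligation of an oligonucleotide
#' block at the product 3' end producing the characteristic multi-mismatch
#' tail of longer products.
#'
#' @param n_reads Number of molecules (read pairs) to simulate.
#' @param seed Integer seed recorded with the parameters; used by
#'   [simulate_experiment()].
#' @param template_len Random-template length (default 18).
#' @param template_composition `template_len x 4` stochastic matrix of base
#'   probabilities per templating position (columns A, C, G, U), or a single
#'   length-4 vector recycled over positions. Default uniform 0.25.
#' @param extension_prob Fraction of primers extended by at least one
#'   nucleotide (default 0.23).
#' @param length_mean,length_min Product-length model for extended primers:
#'   `L = length_min + Geometric`, with mean `length_mean`, capped at
#'   `template_len`. Defaults 3 and 1.
#' @param base_bias 4x4 stochastic matrix `B[t, p]`: probability that
#'   template base `t` (rows) directs product base `p` (columns). Rows encode
#'   both fidelity and bias; the Watson-Crick complement entry is the correct
#'   incorporation. Default: 1 - 0.063 on the complement, 0.063/3 elsewhere.
#' @param ligation_prob Probability that an extended product additionally
#'   receives a contiguous ligated oligo block at its 3' end (default 0.02).
#' @param ligation_len Length of the ligated block (default 6).
#' @param ligation_error_rate Per-base mismatch rate inside a ligated block
#'   (default 0.25).
#' @param seq_error_rate Per-read-base sequencing substitution probability
#'   applied independently to each mate (default 0.001).
#' @param read_len Read length of each mate; reads are truncated at the
#'   insert end (default 75).
#' @param quality_q Constant Phred score written for every base (default 37).
#' @return A `simulation_params` object (validated list).
#' @export
simulation_params <- function(n_reads = 10000,
                              seed = NULL,
                              template_len = 18L,
                              template_composition = NULL,
                              extension_prob = 0.23,
                              length_mean = 3,
                              length_min = 1L,
                              base_bias = NULL,
                              ligation_prob = 0.02,
                              ligation_len = 6L,
                              ligation_error_rate = 0.25,
                              seq_error_rate = 0.001,
                              read_len = 75L,
                              quality_q = 37L) {
  template_len <- as.integer(template_len)
  if (is.null(template_composition)) {
    template_composition <- matrix(0.25, template_len, 4L)
  } else if (is.vector(template_composition)) {
    template_composition <- matrix(template_composition, template_len, 4L,
                                   byrow = TRUE)
  }
  colnames(template_composition) <- rna_bases
  if (is.null(base_bias)) base_bias <- base_bias_matrix(0.063)
  check_stochastic <- function(m, what) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      abort(paste0("`", what, "` rows must be probabilities summing to 1"),
            class = "nerpeseq_config_error")
    }
  }
  check_stochastic(template_composition, "template_composition")
  check_stochastic(base_bias, "base_bias")
  if (nrow(template_composition) != template_len) {
    abort("`template_composition` must have template_len rows",
          class = "nerpeseq_config_error")
  }
  stopifnot(
    extension_prob >= 0, extension_prob <= 1,
    ligation_prob >= 0, ligation_prob <= 1,
    ligation_error_rate >= 0, ligation_error_rate <= 1,
    seq_error_rate >= 0, seq_error_rate <= 1,
    length_min >= 1, length_mean >= length_min,
    ligation_len >= 1, ligation_len <= template_len
  )
  structure(
    list(
      n_reads = as.integer(n_reads), seed = seed,
      template_len = template_len,
      template_composition = template_composition,
      extension_prob = extension_prob,
      length_mean = length_mean, length_min = as.integer(length_min),
      base_bias = base_bias,
      ligation_prob = ligation_prob, ligation_len = as.integer(ligation_len),
      ligation_error_rate = ligation_error_rate,
      seq_error_rate = seq_error_rate,
      read_len = as.integer(read_len), quality_q = as.integer(quality_q)
    ),
    class = "simulation_params"
  )
}

#' Build a base-bias matrix from a flat substitution probability
#'
#' Rows are template bases, columns product bases: the Watson-Crick
#' complement gets `1 - error`, every wrong base `error / 3`.
#'
#' @param error Per-incorporated-base substitution probability.
#' @return A 4x4 stochastic matrix with dimnames over `A, C, G, U`.
#' @export
base_bias_matrix <- function(error = 0) {
  stopifnot(error >= 0, error <= 1)
  B <- matrix(error / 3, 4L, 4L, dimnames = list(rna_bases, rna_bases))
  for (t in rna_bases) B[t, complement(t)] <- 1 - error
  B
}

draw_lengths <- function(n, params) {
  p <- 1 / (params$length_mean - params$length_min + 1)
  pmin(params$length_min + stats::rgeom(n, p), params$template_len)
}

#' Simulate ground-truth template-product pairs
#'
#' Draws, for each molecule: a template from the per-position composition;
#' with probability `extension_prob` a product length from the truncated-
#' geometric model and each product base from the base-bias matrix row of its
#' templating base; and, with probability `ligation_prob`, a contiguous
#' ligated block of `ligation_len` further bases whose per-base mismatch rate
#' is `ligation_error_rate` (mismatching bases uniform over the three wrong
#' bases), truncated at the template end.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional seed set before drawing (defaults to `params$seed`
#'   when that is non-NULL; pass `NA` to leave the RNG state alone).
#' @return A truth pair tibble: `id`, `template` (templating order),
#'   `product`, `length`, `n_mismatch`, `mismatches`, `ligated`.
#' @export
simulate_pairs <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- params$n_reads
  T <- params$template_len
  tm <- matrix("", n, T)
  for (i in seq_len(T)) {
    tm[, i] <- sample(rna_bases, n, replace = TRUE,
                      prob = params$template_composition[i, ])
  }
  L <- integer(n)
  ext <- stats::runif(n) < params$extension_prob
  L[ext] <- draw_lengths(sum(ext), params)
  pm <- matrix("", n, T)
  for (i in seq_len(T)) {
    idx <- which(L >= i)
    if (!length(idx)) next
    ti <- tm[idx, i]
    for (b in rna_bases) {
      j <- idx[ti == b]
      if (!length(j)) next
      pm[j, i] <- sample(rna_bases, length(j), replace = TRUE,
                         prob = params$base_bias[b, ])
    }
  }
  lig <- ext & stats::runif(n) < params$ligation_prob
  if (any(lig)) {
    L2 <- pmin(L + params$ligation_len, T)
    for (i in seq_len(T)) {
      idx <- which(lig & L < i & L2 >= i)
      if (!length(idx)) next
      comp <- chartr("ACGU", "UGCA", tm[idx, i])
      wrong <- stats::runif(length(idx)) < params$ligation_error_rate
      pm[idx, i] <- comp
      if (any(wrong)) {
        j <- which(wrong)
        pm[idx[j], i] <- vapply(
          comp[j], function(b) sample(setdiff(rna_bases, b), 1L), ""
        )
      }
    }
    L[lig] <- L2[lig]
  }
  template <- do.call(paste0, lapply(seq_len(T), function(i) tm[, i]))
  product <- do.call(paste0, lapply(seq_len(T), function(i) pm[, i]))
  pairs <- tibble::tibble(
    id = sprintf("sim%07d", seq_len(n)),
    template = template,
    product = product
  )
  dplyr::mutate(finish_pairs(pairs), ligated = lig)
}

# per-base substitution noise on a character vector of reads
apply_seq_error <- function(reads, rate) {
  if (rate <= 0) return(reads)
  len <- nchar(reads)
  for (p in seq_len(max(len))) {
    hit <- which(len >= p & stats::runif(length(reads)) < rate)
    if (!length(hit)) next
    cur <- substr(reads[hit], p, p)
    for (b in c("A", "C", "G", "T")) {
      j <- hit[cur == b]
      if (!length(j)) next
      substr(reads[j], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b),
                                       length(j), replace = TRUE)
    }
  }
  reads
}

#' Render truth pairs as paired FASTQ reads
#'
#' Assembles each sequenced insert as `handle5 + template (molecule
#' orientation) + loop + primer + product + rt_handle`, converts to the DNA
#' alphabet, applies independent per-base sequencing substitutions to each
#' mate, and writes the forward read (first `read_len` insert bases) and
#' reverse read (reverse complement of the last `read_len` bases), both
#' truncated at the insert ends, with constant Phred+33 qualities.
#'
#' @param truth Truth pair tibble from [simulate_pairs()] (`template` in
#'   templating order).
#' @param spec A [construct_spec()].
#' @param params A [simulation_params()] (read length, error rate, quality).
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
render_fastq <- function(truth, spec, params, r1_path, r2_path) {
  stopifnot(inherits(spec, "construct_spec"),
            inherits(params, "simulation_params"))
  if (2L * params$read_len <
      fixed_insert_len(spec) + spec$template_len + 10L) {
    abort("read_len too short to cover the insert with overlap",
          class = "nerpeseq_config_error")
  }
  insert <- paste0(spec$handle5, str_rev(truth$template), spec$loop,
                   spec$primer, truth$product, spec$rt_handle)
  insert <- chartr("U", "T", insert)
  n <- nchar(insert)
  fwd <- substr(insert, 1L, pmin(params$read_len, n))
  rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(insert))
  )
  rev <- substr(rev, 1L, pmin(params$read_len, n))
  fwd <- apply_seq_error(fwd, params$seq_error_rate)
  rev <- apply_seq_error(rev, params$seq_error_rate)
  qc <- rawToChar(as.raw(params$quality_q + 33L))
  write_fastq <- function(seqs, path) {
    rec <- rbind(paste0("@", truth$id), seqs, "+",
                 strrep(qc, nchar(seqs)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.vector(rec), con)
  }
  write_fastq(fwd, r1_path)
  write_fastq(rev, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Simulate a full experiment: reads, matched control, truth and parameters
#'
#' Seeds the RNG once from `params$seed`, simulates the experiment molecules
#' and a matched no-extension control (`extension_prob = 0`, everything else
#' identical), renders both as paired FASTQ, and writes the ground truth
#' (TSV) and a parameter echo (JSON) alongside.
#'
#' @param params A [simulation_params()]; `params$seed` should be set for
#'   reproducible output.
#' @param spec A [construct_spec()].
#' @param dir Output directory (created).
#' @param n_control Number of control molecules (default: same as
#'   `params$n_reads`).
#' @return A list of file paths (`experiment_r1/2`, `control_r1/2`,
#'   `truth`, `control_truth`, `params`) plus the truth tibbles
#'   (`truth_pairs`, `control_pairs`).
#' @export
simulate_experiment <- function(params, spec = construct_spec(),
                                dir, n_control = params$n_reads) {
  stopifnot(inherits(params, "simulation_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  truth <- simulate_pairs(params, seed = NA)
  ctrl_params <- params
  ctrl_params$extension_prob <- 0
  ctrl_params$n_reads <- as.integer(n_control)
  ctrl <- simulate_pairs(ctrl_params, seed = NA)
  ctrl$id <- sub("^sim", "ctl", ctrl$id)
  paths <- list(
    experiment_r1 = file.path(dir, "experiment_R1.fastq"),
    experiment_r2 = file.path(dir, "experiment_R2.fastq"),
    control_r1 = file.path(dir, "control_R1.fastq"),
    control_r2 = file.path(dir, "control_R2.fastq"),
    truth = file.path(dir, "truth_pairs.tsv"),
    control_truth = file.path(dir, "control_truth_pairs.tsv"),
    params = file.path(dir, "params.json")
  )
  render_fastq(truth, spec, params, paths$experiment_r1, paths$experiment_r2)
  render_fastq(ctrl, spec, ctrl_params, paths$control_r1, paths$control_r2)
  write_pairs(truth, paths$truth)
  write_pairs(ctrl, paths$control_truth)
  echo <- params
  echo$template_composition <- as.data.frame(params$template_composition)
  echo$base_bias <- as.data.frame(params$base_bias)
  writeLines(
    jsonlite::toJSON(unclass(echo), auto_unbox = TRUE, digits = NA,
                     null = "null"),
    paths$params
  )
  c(paths, list(truth_pairs = truth, control_pairs = ctrl))
}
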