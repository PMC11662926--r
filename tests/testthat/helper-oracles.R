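# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: everything is per-molecule loops
# over split characters with an explicit pairing table.

wc_pair <- c(A = "U", C = "G", G = "C", U = "A")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revstr <- function(s) {
  vapply(s, function(x) paste(rev(chars(x)), collapse = ""), "",
         USE.NAMES = FALSE)
}

dna_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(chars(chartr("ACGT", "TGCA", x))), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# build a pair tibble row-by-row from template (templating order) + product
make_pairs <- function(template, product) {
  stopifnot(length(template) == length(product))
  rows <- lapply(seq_along(template), function(k) {
    tb <- chars(template[k])
    pb <- if (nchar(product[k])) chars(product[k]) else character(0)
    mm <- which(pb != unname(wc_pair[tb[seq_along(pb)]]))
    tibble::tibble(
      id = paste0("p", k),
      template = template[k],
      product = product[k],
      length = length(pb),
      n_mismatch = length(mm),
      mismatches = paste(
        vapply(mm, function(i) paste(i, tb[i], pb[i], sep = ":"), ""),
        collapse = ";"
      )
    )
  })
  dplyr::bind_rows(rows)
}

# assemble the sequenced insert (DNA alphabet) for a template given in
# templating order plus a product in order of addition
build_insert <- function(spec, template, product) {
  chartr(
    "U", "T",
    paste0(spec$handle5, revstr(template), spec$loop, spec$primer, product,
           spec$rt_handle)
  )
}

# paired reads from an insert, constant quality
insert_reads <- function(insert, read_len = 75, q = "F") {
  n <- nchar(insert)
  fwd <- substr(insert, 1, pmin(read_len, n))
  rev <- substr(dna_revcomp(insert), 1, pmin(read_len, n))
  tibble::tibble(
    id = paste0("r", seq_along(insert)),
    fwd_seq = fwd, rev_seq = rev,
    fwd_qual = strrep(q, nchar(fwd)), rev_qual = strrep(q, nchar(rev))
  )
}

# brute-force trimer frequencies: explicit loop over molecules
naive_trimer <- function(pairs, w = NULL, window = 1) {
  counts <- stats::setNames(numeric(64), nerpeseq::all_trimers)
  for (k in seq_len(nrow(pairs))) {
    pb <- if (nchar(pairs$product[k])) chars(pairs$product[k]) else character(0)
    tb <- chars(pairs$template[k])
    L <- length(pb)
    if (L < window + 2) next
    if (any(pb != unname(wc_pair[tb[seq_len(L)]]))) next
    wt <- 1
    if (!is.null(w)) {
      for (i in window:(window + 2)) wt <- wt * w[i, tb[i]]
    }
    tri <- paste(pb[window:(window + 2)], collapse = "")
    counts[tri] <- counts[tri] + wt
  }
  if (sum(counts) == 0) stop("no qualifying products")
  counts / sum(counts)
}

# brute-force mismatch spectrum: counts of template:product types by position
naive_spectrum <- function(pairs, template_len) {
  types <- nerpeseq::mismatch_types()
  M <- matrix(0, length(types), template_len,
              dimnames = list(types, NULL))
  for (k in seq_len(nrow(pairs))) {
    if (!nchar(pairs$product[k])) next
    pb <- chars(pairs$product[k])
    tb <- chars(pairs$template[k])
    for (i in seq_along(pb)) {
      if (pb[i] != unname(wc_pair[tb[i]])) {
        M[paste0(tb[i], ":", pb[i]), i] <- M[paste0(tb[i], ":", pb[i]), i] + 1
      }
    }
  }
  if (sum(M) > 0) M <- M / sum(M)
  M
}
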