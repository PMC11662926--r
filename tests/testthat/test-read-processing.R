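spec <- construct_spec()

test_that("quality_filter thresholds mean Phred per mate, boundary inclusive", {
  # Phred+33: "I" = Q40, "+" = Q10, "?" = Q30
  rp <- tibble::tibble(
    id = c("a", "b", "c"),
    fwd_seq = "ACGT", rev_seq = "ACGT",
    fwd_qual = c(strrep("I", 4), strrep("+", 4), strrep("?", 4)),
    rev_qual = c(strrep("I", 4), strrep("+", 4), strrep("?", 4))
  )
  out <- quality_filter(rp, min_mean_q = 30)
  expect_identical(out$pass_quality, c(TRUE, FALSE, TRUE))
})

test_that("merge_mates reconstructs the insert and applies the quality rule", {
  tpl <- strrep("A", 18)
  insert <- build_insert(spec, tpl, "UUUU")
  rp <- insert_reads(insert)
  m <- merge_mates(rp, spec)
  expect_identical(m$merged, insert)
  expect_identical(m$insert_len, nchar(insert))

  # one overlap disagreement, max 0 -> reject
  rp2 <- rp
  mid <- 40L # inside the overlap of 75nt reads over a ~79nt insert
  substr(rp2$fwd_seq, mid, mid) <- "C"
  expect_true(is.na(merge_mates(rp2, spec, max_disagreements = 0)$merged))

  # tolerated disagreement: the higher-quality base wins
  rp3 <- rp2
  substr(rp3$rev_qual, nchar(insert) - mid + 1L, nchar(insert) - mid + 1L) <- "+"
  m3 <- merge_mates(rp3, spec, max_disagreements = 1)
  expect_identical(substr(m3$merged, mid, mid), "C") # fwd (Q40) beats rev (Q10)
})

test_that("locate_regions anchors fixed regions and windows", {
  tpl <- paste(rep(c("A", "C", "G"), 6), collapse = "")
  insert <- build_insert(spec, tpl, "CGUA")
  loc <- locate_regions(insert, spec)
  expect_identical(loc$status, "ok")
  expect_identical(loc$template_end - loc$template_start, 18L)
  expect_identical(loc$product_end - loc$product_start, 4L)

  # one substitution in the loop is within the default tolerance of 1
  ins2 <- insert
  loop_at <- nchar(spec$handle5) + 18L + 3L
  substr(ins2, loop_at, loop_at) <- setdiff(c("A", "C", "G", "T"),
                                            substr(ins2, loop_at, loop_at))[1]
  expect_identical(locate_regions(ins2, spec)$status, "ok")

  # missing rt_handle -> reject
  ins3 <- substr(insert, 1, nchar(insert) - nchar(spec$rt_handle))
  expect_identical(locate_regions(ins3, spec)$status, "fixed_region_mismatch")

  # product longer than the template region -> overrun, counted separately
  ins4 <- build_insert(spec, tpl, strrep("A", 19))
  expect_identical(locate_regions(ins4, spec)$status, "product_overrun")

  # ambiguity in the template window
  ins5 <- insert
  substr(ins5, nchar(spec$handle5) + 2L, nchar(spec$handle5) + 2L) <- "N"
  expect_identical(locate_regions(ins5, spec)$status, "template_has_ambiguity")
})

test_that("extract_pair re-indexes into templating order and calls matches", {
  tpl <- "ACGUACGUACGUACGUAC" # templating order
  prd <- complement(substr(tpl, 1, 4))
  insert <- build_insert(spec, tpl, prd)
  loc <- locate_regions(insert, spec)
  pair <- extract_pair(insert, loc, spec)
  expect_identical(pair$template, tpl)
  expect_identical(pair$product, prd)
  expect_identical(pair$n_mismatch, 0L)

  # empty product window -> unextended primer
  ins0 <- build_insert(spec, tpl, "")
  pair0 <- extract_pair(ins0, locate_regions(ins0, spec), spec)
  expect_identical(pair0$length, 0L)

  # single terminal mismatch at the 3'-most product position
  prd_t <- prd
  substr(prd_t, 4, 4) <- setdiff(rna_bases, substr(prd, 4, 4))[1]
  ins_t <- build_insert(spec, tpl, prd_t)
  pair_t <- extract_pair(ins_t, locate_regions(ins_t, spec), spec)
  expect_identical(pair_t$n_mismatch, 1L)
  expect_match(pair_t$mismatches, "^4:")
})

test_that("filter report counts are conserved on noisy synthetic data", {
  params <- simulation_params(n_reads = 3000, seed = 21, seq_error_rate = 0.002)
  sim <- simulate_experiment(params, spec, dir = withr::local_tempdir())
  pairs <- extract_pairs_fastq(sim$experiment_r1, sim$experiment_r2, spec)
  rep <- filter_report(pairs)
  expect_identical(sum(rep$count), attr(rep, "total"))
  expect_identical(attr(rep, "total"), 3000L)
  expect_identical(rep$count[rep$reason == "accepted"], nrow(pairs))
})

test_that("zero sequencing error extraction recovers every truth pair", {
  params <- simulation_params(n_reads = 2000, seed = 5, seq_error_rate = 0)
  sim <- simulate_experiment(params, spec, dir = withr::local_tempdir())
  pairs <- extract_pairs_fastq(sim$experiment_r1, sim$experiment_r2, spec)
  expect_identical(nrow(pairs), 2000L)
  got <- as.data.frame(pairs)[c("template", "product", "length", "n_mismatch")]
  want <- as.data.frame(sim$truth_pairs)[c("template", "product", "length",
                                           "n_mismatch")]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("extraction is invariant to swapping the mates", {
  params <- simulation_params(n_reads = 300, seed = 3, seq_error_rate = 0)
  sim <- simulate_experiment(params, spec, dir = withr::local_tempdir())
  a <- extract_pairs_fastq(sim$experiment_r1, sim$experiment_r2, spec)
  b <- extract_pairs_fastq(sim$experiment_r2, sim$experiment_r1, spec)
  cols <- c("template", "product", "length", "n_mismatch", "mismatches")
  expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols],
               ignore_attr = TRUE)
})

test_that("pair tables round-trip through TSV", {
  pairs <- make_pairs(c("ACGUA", "GGGGG"), c("UGC", ""))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, path)
  back <- read_pairs(path)
  expect_equal(as.data.frame(back), as.data.frame(pairs), ignore_attr = TRUE)
})
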