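spec <- construct_spec()

test_that("simulation parameters are validated", {
  expect_error(simulation_params(base_bias = matrix(1, 4, 4)),
               class = "nerpeseq_config_error")
  expect_error(simulation_params(template_composition = c(0.5, 0.5, 0.5, 0.5)),
               class = "nerpeseq_config_error")
  expect_error(simulation_params(extension_prob = 1.2))
  p <- simulation_params(template_composition = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(dim(p$template_composition), c(18L, 4L))
})

test_that("extension probability zero leaves every primer unextended", {
  pairs <- simulate_pairs(simulation_params(n_reads = 500, seed = 1,
                                            extension_prob = 0))
  expect_true(all(pairs$length == 0L))
  expect_true(all(pairs$product == ""))
})

test_that("a perfect-complement bias with no ligation gives only matches", {
  pairs <- simulate_pairs(simulation_params(
    n_reads = 2000, seed = 2, extension_prob = 1,
    base_bias = base_bias_matrix(0), ligation_prob = 0
  ))
  expect_true(all(pairs$n_mismatch == 0L))
  expect_true(all(pairs$length >= 1L))
  expect_identical(pairs$product,
                   complement(substr(pairs$template, 1, pairs$length)))
})

test_that("ligation blocks lengthen products and carry extra mismatches", {
  base <- simulation_params(n_reads = 4000, seed = 4, extension_prob = 1,
                            length_mean = 2, base_bias = base_bias_matrix(0),
                            ligation_prob = 0)
  lig <- base
  lig$ligation_prob <- 1
  p0 <- simulate_pairs(base)
  p1 <- simulate_pairs(lig, seed = 4)
  expect_true(all(p1$ligated))
  expect_false(any(p0$ligated))
  expect_gt(mean(p1$length), mean(p0$length))
  # elevated block error rate produces multi-mismatch products
  expect_gt(mean(p1$n_mismatch > 1), mean(p0$n_mismatch > 1))
})

test_that("rendering is deterministic under a fixed seed", {
  params <- simulation_params(n_reads = 300, seed = 12,
                              seq_error_rate = 0.002)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_experiment(params, spec, dir = d1)
  s2 <- simulate_experiment(params, spec, dir = d2)
  for (f in c("experiment_r1", "experiment_r2", "control_r1", "control_r2")) {
    expect_identical(readLines(s1[[f]]), readLines(s2[[f]]))
  }
  expect_identical(readLines(s1$truth), readLines(s2$truth))
})

test_that("rendered inserts follow the construct layout", {
  params <- simulation_params(n_reads = 50, seed = 6, seq_error_rate = 0)
  d <- withr::local_tempdir()
  sim <- simulate_experiment(params, spec, dir = d)
  r1 <- readLines(sim$experiment_r1)
  seqs <- r1[seq(2, length(r1), by = 4)]
  expect_length(seqs, 50L)
  expect_true(all(startsWith(seqs, chartr("U", "T", spec$handle5))))
  # control reads carry no product: fixed insert length throughout
  c1 <- readLines(sim$control_r1)
  cseq <- c1[seq(2, length(c1), by = 4)]
  expect_true(all(grepl(chartr("U", "T", paste0(spec$primer, spec$rt_handle)),
                        cseq, fixed = TRUE)))
})

test_that("a too-short read length is a configuration error", {
  params <- simulation_params(n_reads = 10, seed = 1, read_len = 30)
  truth <- simulate_pairs(params)
  expect_error(
    render_fastq(truth, spec, params, tempfile(), tempfile()),
    class = "nerpeseq_config_error"
  )
})
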