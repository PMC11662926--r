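test_that("positional frequencies follow the weighted definition", {
  # one complementary product "GC": template starts C, G in templating order
  p1 <- make_pairs("CGAAU", "GC")
  f1 <- positional_frequencies(p1)
  expect_equal(f1$freq[f1$position == 1 & f1$base == "G"], 1)
  expect_equal(f1$freq[f1$position == 2 & f1$base == "C"], 1)
  expect_true(all(is.na(f1$freq[f1$position == 3])))

  # two products "A" and "G" with equal weight
  p2 <- make_pairs(c("UAC", "CAC"), c("A", "G"))
  f2 <- positional_frequencies(p2)
  expect_equal(f2$freq[f2$position == 1 & f2$base %in% c("A", "G")],
               c(0.5, 0.5))
})

test_that("rows of a positional table sum to one where defined", {
  pairs <- simulate_pairs(simulation_params(n_reads = 3000, seed = 13))
  f <- positional_frequencies(pairs, products = "all")
  sums <- tapply(f$freq, f$position, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  expect_true(all(f$freq >= 0, na.rm = TRUE))
})

test_that("mean_base_frequency averages over a position range", {
  p <- make_pairs(c("AGC", "AAA", "AAC"), c("UC", "UU", "UUG"))
  f <- positional_frequencies(p, products = "all")
  expect_equal(mean_base_frequency(f, "U", 1:2),
               mean(c(f$freq[f$position == 1 & f$base == "U"],
                      f$freq[f$position == 2 & f$base == "U"])))
  expect_error(mean_base_frequency(f, "U", 1:9),
               class = "nerpeseq_data_error")
})

test_that("uniform trimer usage gives 1/64 everywhere and median 0.016", {
  # template in templating order = complement of the product, per position
  pairs <- make_pairs(complement(all_trimers), all_trimers)
  tt <- trimer_frequencies(pairs)
  expect_equal(tt$freq, rep(1 / 64, 64))
  s <- trimer_summary(tt)
  expect_equal(round(s$median, 3), 0.016)
  expect_equal(s$max_min_ratio, 1)
})

test_that("a single product trimer concentrates all mass", {
  pairs <- make_pairs("CCCAA", "GGG")
  tt <- trimer_frequencies(pairs)
  expect_equal(tt$freq[tt$trimer == "GGG"], 1)
  expect_equal(trimer_summary(tt)$median, 0)
  expect_error(trimer_frequencies(pairs, window = 4),
               class = "nerpeseq_data_error")
  expect_error(trimer_frequencies(pairs, window = 2),
               class = "nerpeseq_config_error")
})

test_that("trimer windows select by product length and window positions", {
  # L = 6 complementary product contributes to both windows
  tpl <- "ACGUACGUA"
  prd <- complement(substr(tpl, 1, 6))
  pairs <- make_pairs(tpl, prd)
  t123 <- trimer_frequencies(pairs, window = 1)
  t456 <- trimer_frequencies(pairs, window = 4)
  expect_equal(t123$freq[t123$trimer == substr(prd, 1, 3)], 1)
  expect_equal(t456$freq[t456$trimer == substr(prd, 4, 6)], 1)
})

test_that("error frequency is mismatch calls over product bases", {
  p <- make_pairs(c("ACGUA", "ACGUAC", "GGGG"),
                  c("UGCG", complement("ACGUAC"), ""))
  # one mismatch in 4 + 6 incorporated bases
  expect_equal(error_frequency(p), 1 / 10)
  expect_equal(error_frequency(make_pairs("AAA", "UUU")), 0)
  expect_error(error_frequency(make_pairs("AAA", "")),
               class = "nerpeseq_data_error")
})

test_that("mismatch spectrum normalizes over all mismatches", {
  m1 <- mismatch_spectrum(make_pairs("AUG", "G"))
  expect_equal(m1$freq[m1$type == "A:G" & m1$position == 1], 1)
  expect_equal(sum(m1$freq), 1)

  m2 <- mismatch_spectrum(make_pairs(c("AGA", "AAU"), c("UU", "UUG")))
  expect_equal(m2$freq[m2$type == "G:U" & m2$position == 2], 0.5)
  expect_equal(m2$freq[m2$type == "U:G" & m2$position == 3], 0.5)
  expect_equal(sum(m2$freq), 1)

  # all-zero spectrum allowed
  m0 <- mismatch_spectrum(make_pairs("ACG", "UG"))
  expect_equal(sum(m0$freq), 0)
})

test_that("product class fractions handle terminal and undefined cases", {
  # terminal mismatch only
  p <- make_pairs(c("ACGU", "ACGU"), c("UGA", "UGA"))
  cf <- product_class_fractions(p)
  expect_equal(cf$terminal_mismatch_fraction, 1)

  # 10 mismatch-containing products, 4 with >= 2 mismatches
  tpl <- strrep("A", 6)
  prods <- c(rep("UUG", 6), rep("UGG", 4))
  cf2 <- product_class_fractions(make_pairs(rep(tpl, 10), prods))
  expect_equal(cf2$multi_mismatch_fraction, 0.4)

  # no mismatches anywhere: conditionals undefined, not zero
  cf3 <- product_class_fractions(make_pairs("ACG", "UG"))
  expect_equal(cf3$complementary_fraction, 1)
  expect_true(is.na(cf3$multi_mismatch_fraction))
  expect_true(is.na(cf3$terminal_mismatch_fraction))
})

test_that("yield and cumulative incorporation follow the definitions", {
  tpl <- strrep("A", 4)
  p <- make_pairs(rep(tpl, 4), c("", "", "U", "UUU"))
  yl <- yield_and_lengths(p)
  expect_equal(yl$yield_fraction, 0.5)
  cum <- yl$cumulative_incorporation
  expect_equal(cum$fraction[cum$position == 1], 0.5)
  expect_equal(cum$fraction[cum$position == 2], 0.25)
  expect_equal(cum$fraction, cum$correct + cum$incorrect)
  expect_equal(sum(yl$length_distribution$freq), 1)

  # all unextended
  y0 <- yield_and_lengths(make_pairs(tpl, ""))
  expect_equal(y0$yield_fraction, 0)
  expect_true(all(y0$cumulative_incorporation$fraction == 0))
})

test_that("cumulative incorporation is monotone and anchored at the yield", {
  pairs <- simulate_pairs(simulation_params(n_reads = 5000, seed = 17))
  yl <- yield_and_lengths(pairs)
  frac <- yl$cumulative_incorporation$fraction
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], yl$yield_fraction)
})

test_that("positional estimator recovers a known generative distribution", {
  # every template base directs the same product distribution, so the
  # position-wise product composition is the bias row itself
  B <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 4), 4, 4,
              dimnames = list(rna_bases, rna_bases))
  params <- simulation_params(n_reads = 50000, seed = 31, extension_prob = 1,
                              base_bias = B, ligation_prob = 0)
  pairs <- simulate_pairs(params)
  f <- positional_frequencies(pairs, products = "all")
  got <- f$freq[f$position == 1]
  expect_lt(max(abs(got - c(0.4, 0.3, 0.2, 0.1))), 0.01)
})

test_that("normalization makes a biased template look equimolar", {
  comp <- c(0.4, 0.3, 0.2, 0.1)
  params <- simulation_params(
    n_reads = 40000, seed = 33, template_composition = comp,
    extension_prob = 0.5, base_bias = base_bias_matrix(0),
    ligation_prob = 0
  )
  pairs <- simulate_pairs(params)
  ctrl_params <- params
  ctrl_params$extension_prob <- 0
  ctrl <- simulate_pairs(ctrl_params, seed = 34)
  norm <- compute_normalization(ctrl)
  f <- positional_frequencies(pairs, norm)
  got <- f$freq[f$position %in% 1:3]
  expect_lt(max(abs(got - 0.25)), 0.02)
  # unnormalized, the same data show the template bias (complement of comp)
  f0 <- positional_frequencies(pairs)
  expect_gt(f0$freq[f0$position == 1 & f0$base == "U"], 0.35)
})

test_that("glance and tidy summarize a bundle coherently", {
  pairs <- simulate_pairs(simulation_params(n_reads = 4000, seed = 19))
  st <- nerpe_statistics(pairs)
  g <- glance(st)
  expect_identical(g$n_pairs, 4000L)
  expect_equal(g$yield_fraction, mean(pairs$length >= 1))
  expect_equal(g$error_frequency, error_frequency(pairs))
  td <- tidy(st)
  expect_true(all(c("positional_complementary", "mismatch_spectrum",
                    "trimer_123") %in% td$table))
  expect_s3_class(summary_json(st), "json")
})
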