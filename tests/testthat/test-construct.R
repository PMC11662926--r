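test_that("complement and reverse_complement follow Watson-Crick pairing", {
  expect_identical(complement("A"), "U")
  expect_identical(complement("G"), "C")
  expect_identical(complement(c("A", "C", "G", "U")), c("U", "G", "C", "A"))
  expect_identical(reverse_complement("AAC"), "GUU")
  expect_identical(reverse_complement("GAUC"), "GAUC") # palindrome fixed point
  expect_identical(reverse_complement(""), "")
  expect_error(complement("N"), class = "nerpeseq_alphabet_error")
  expect_error(reverse_complement("ACGT"), class = "nerpeseq_alphabet_error")
})

test_that("reverse_complement is an involution on random sequences", {
  set.seed(42)
  seqs <- vapply(1:50, function(i) {
    paste(sample(rna_bases, sample(1:30, 1), replace = TRUE), collapse = "")
  }, "")
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("call_matches classifies positions and labels template:product", {
  expect_identical(call_matches("AAA", "UUU"), c("M", "M", "M"))
  expect_identical(call_matches("A", "G"), "A:G")
  expect_identical(call_matches("GC", "UG"), c("G:U", "M"))
  expect_identical(call_matches("ACGU", ""), character(0))
  expect_error(call_matches("AC", "UUU"), class = "nerpeseq_length_error")
})

test_that("all-match happens exactly when the product complements the template", {
  set.seed(7)
  for (k in 1:25) {
    tpl <- paste(sample(rna_bases, 10, replace = TRUE), collapse = "")
    L <- sample(0:10, 1)
    good <- complement(substr(tpl, 1, L))
    expect_true(all(call_matches(tpl, good) == "M"))
    if (L > 0) {
      bad <- good
      i <- sample(L, 1)
      substr(bad, i, i) <- setdiff(rna_bases, substr(good, i, i))[1]
      expect_false(all(call_matches(tpl, bad) == "M"))
    }
  }
})

test_that("there are exactly 12 mismatch types", {
  mt <- mismatch_types()
  expect_length(mt, 12L)
  expect_length(unique(mt), 12L)
  # no label pairs a base with its complement
  for (lab in mt) {
    expect_false(substr(lab, 3, 3) == complement(substr(lab, 1, 1)))
  }
})

test_that("construct_spec validates its regions", {
  expect_error(construct_spec(template_len = 2), class = "nerpeseq_config_error")
  expect_error(construct_spec(handle5 = "ACGT"), class = "nerpeseq_alphabet_error")
  expect_error(construct_spec(loop = ""), class = "nerpeseq_config_error")
  spec <- construct_spec(template_len = 12)
  expect_s3_class(spec, "construct_spec")
  expect_identical(spec$template_len, 12L)
})

test_that("construct definitions round-trip through YAML", {
  spec <- construct_spec(template_len = 9, max_region_mismatches = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_construct(spec, path)
  expect_identical(read_construct(path), spec)
  expect_error(read_construct(tempfile()), class = "nerpeseq_config_error")
  # unknown keys are refused
  yaml::write_yaml(list(handle5 = "ACGU", bogus = 1), path)
  expect_error(read_construct(path), class = "nerpeseq_config_error")
})
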