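Package: nerpeseq
Title: Analysis and Simulation of Nonenzymatic RNA Primer Extension Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequencing-based characterization of nonenzymatic RNA
    primer extension on a self-priming hairpin construct with a random-sequence
    template. Turns raw paired-end FASTQ reads into matched template-product
    pairs by quality filtering, mate merging and fixed-region matching, and
    computes composition-normalized product statistics: positional base
    frequencies, trimer frequency tables, mismatch spectra, error frequencies,
    yields and product-length distributions. Includes a fully parameterized
    synthetic read generator with ground truth, so every estimator can be
    validated by parameter recovery without external data, plus an end-to-end
    pipeline runner and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
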