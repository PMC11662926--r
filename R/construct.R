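#' @useDynLib nerpeseq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import rlang
NULL

#' RNA alphabet used throughout
#'
#' All internal sequence handling uses the RNA alphabet `A, C, G, U`; FASTQ
#' `T`s are mapped to `U` on input.
#' @export
rna_bases <- c("A", "C", "G", "U")

#' The 64 possible product trimers
#'
#' All trinucleotides over `A, C, G, U`, in lexicographic order. Trimer
#' frequency tables always carry all 64 rows, with zeros where a trimer was
#' not observed.
#' @export
all_trimers <- sort(paste0(
  rep(rna_bases, each = 16), rep(rep(rna_bases, each = 4), 4), rna_bases
))

assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(
      paste0(what, " contains non-RNA symbols (allowed: A, C, G, U): ",
             paste(utils::head(x[bad], 3L), collapse = ", ")),
      class = "nerpeseq_alphabet_error"
    )
  }
  invisible(x)
}

#' Watson-Crick complement of RNA bases or sequences
#'
#' `complement()` complements each base in place (A<->U, G<->C);
#' `reverse_complement()` additionally reverses the sequence, giving the
#' antiparallel partner strand. Both are vectorized over character vectors
#' and reject any symbol outside `A, C, G, U` (ambiguity codes are handled —
#' rejected — upstream, during read processing).
#'
#' @param x Character vector of RNA sequences (single bases are length-1
#'   sequences).
#' @return Character vector of the same length.
#' @examples
#' complement("A")
#' reverse_complement("AAC")
#' @export
complement <- function(x) {
  assert_rna(x)
  chartr("ACGU", "UGCA", x)
}

#' @rdname complement
#' @export
reverse_complement <- function(x) {
  assert_rna(x)
  out <- chartr("ACGU", "UGCA", x)
  as.character(Biostrings::reverse(Biostrings::BStringSet(out)))
}

# reverse (no complement) of a character vector of sequences
str_rev <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Define the self-priming hairpin construct
#'
#' The construct is a single RNA molecule laid out 5' to 3' as
#' `handle5 - template (random, template_len nt) - loop - primer`, whose 3'
#' primer folds back and anneals so that extension of the primer copies the
#' random template in cis. After the reaction an `rt_handle` is ligated to the
#' product 3' end, so the sequenced insert reads
#' `handle5 + template + loop + primer + product + rt_handle`.
#'
#' Only the *architecture* matters for analysis: the default fixed-region
#' sequences shipped here are arbitrary placeholders with the documented
#' roles, and any real construct is supplied via [read_construct()] or by
#' calling this constructor with the actual sequences.
#'
#' @param handle5 Fixed region at the molecule 5' end.
#' @param template_len Length of the random-sequence template region
#'   (default 18; must be at least 3 so trimer statistics are defined).
#' @param loop Fixed hairpin loop between template and primer.
#' @param primer Fixed self-priming 3' segment; the product is added
#'   immediately 3' of it.
#' @param rt_handle Fixed handle ligated 3' of the product before reverse
#'   transcription.
#' @param max_region_mismatches Substitutions tolerated when matching each
#'   fixed region in a read (default 1).
#' @return A `construct_spec` object (a validated list).
#' @examples
#' spec <- construct_spec()
#' spec$template_len
#' @export
construct_spec <- function(handle5 = "ACUGUCAGGUACC",
                           template_len = 18L,
                           loop = "GAAACUUCGGUUUC",
                           primer = "GGUACGAUCG",
                           rt_handle = "UAGCAACCGUGA",
                           max_region_mismatches = 1L) {
  for (nm in c("handle5", "loop", "primer", "rt_handle")) {
    val <- get(nm)
    if (!is.character(val) || length(val) != 1L || nchar(val) == 0L) {
      abort(paste0("`", nm, "` must be a single nonempty RNA string"),
            class = "nerpeseq_config_error")
    }
    assert_rna(val, nm)
  }
  template_len <- as.integer(template_len)
  if (is.na(template_len) || template_len < 3L) {
    abort("`template_len` must be an integer >= 3 (trimer statistics require it)",
          class = "nerpeseq_config_error")
  }
  max_region_mismatches <- as.integer(max_region_mismatches)
  if (is.na(max_region_mismatches) || max_region_mismatches < 0L) {
    abort("`max_region_mismatches` must be a non-negative integer",
          class = "nerpeseq_config_error")
  }
  structure(
    list(
      handle5 = handle5, template_len = template_len, loop = loop,
      primer = primer, rt_handle = rt_handle,
      max_region_mismatches = max_region_mismatches
    ),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("<construct_spec>\n")
  cat("  5'-", x$handle5, "-[N", x$template_len, "]-", x$loop, "-",
      x$primer, "-3'  (+ product + ", x$rt_handle, " after ligation)\n",
      sep = "")
  cat("  fixed-region mismatch tolerance:", x$max_region_mismatches, "\n")
  invisible(x)
}

# total fixed (non-product) insert length
fixed_insert_len <- function(spec) {
  nchar(spec$handle5) + spec$template_len + nchar(spec$loop) +
    nchar(spec$primer) + nchar(spec$rt_handle)
}

#' Read or write a construct definition file
#'
#' Construct definitions are stored as YAML with keys `handle5`,
#' `template_len`, `loop`, `primer`, `rt_handle` and (optionally)
#' `max_region_mismatches`.
#'
#' @param path Path to a YAML file.
#' @return `read_construct()` returns a `construct_spec`;
#'   `write_construct()` returns `path` invisibly.
#' @export
read_construct <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("construct file not found: ", path),
          class = "nerpeseq_config_error")
  }
  y <- yaml::read_yaml(path)
  allowed <- c("handle5", "template_len", "loop", "primer", "rt_handle",
               "max_region_mismatches")
  extra <- setdiff(names(y), allowed)
  if (length(extra)) {
    abort(paste0("unknown construct fields: ", paste(extra, collapse = ", ")),
          class = "nerpeseq_config_error")
  }
  do.call(construct_spec, y)
}

#' @rdname read_construct
#' @param spec A `construct_spec`.
#' @export
write_construct <- function(spec, path) {
  stopifnot(inherits(spec, "construct_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Classify product positions as matches or mismatches
#'
#' Compares a product to its template in templating order: position `i` of
#' the product pairs with template base `t_i` (the template base adjacent to
#' the primer 3' terminus is `t_1`). A position is a match when the product
#' base is the Watson-Crick complement of its templating base; otherwise it
#' is a mismatch, labelled `template:product` (so `"G:U"` means template G
#' directed product U).
#'
#' @param template RNA string in templating order, at least as long as
#'   `product`.
#' @param product RNA string in order of addition (first-added base first).
#' @return Character vector of length `nchar(product)`: `"M"` for a match,
#'   otherwise the `template:product` mismatch label. Zero-length for an
#'   unextended primer.
#' @examples
#' call_matches("AAA", "UUU")
#' call_matches("A", "G")    # the template:product label "A:G"
#' @export
call_matches <- function(template, product) {
  stopifnot(length(template) == 1L, length(product) == 1L)
  assert_rna(template, "template")
  if (nchar(product) > 0L) assert_rna(product, "product")
  L <- nchar(product)
  if (L > nchar(template)) {
    abort("product is longer than the template region",
          class = "nerpeseq_length_error")
  }
  if (L == 0L) return(character(0))
  tb <- strsplit(substr(template, 1L, L), "", fixed = TRUE)[[1L]]
  pb <- strsplit(product, "", fixed = TRUE)[[1L]]
  ifelse(pb == chartr("ACGU", "UGCA", tb), "M", paste0(tb, ":", pb))
}

#' The 12 possible mismatch labels
#'
#' Every mismatch is labelled `template:product`; with 4 template bases and
#' 3 possible wrong product bases each there are exactly 12 labels.
#' @return Character vector of length 12.
#' @export
mismatch_types <- function() {
  out <- c(outer(rna_bases, rna_bases, function(t, p) paste0(t, ":", p)))
  keep <- substr(out, 3L, 3L) != chartr("ACGU", "UGCA", substr(out, 1L, 1L))
  sort(out[keep])
}
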