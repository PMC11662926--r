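---
title: "Methods: template-product analysis for nonenzymatic primer extension sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-product analysis for nonenzymatic primer extension sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerpeseq)
```

## The measurement

Nonenzymatic template-directed RNA polymerization is studied by deep
sequencing of a self-priming hairpin: a single RNA molecule whose 3' primer
folds back and anneals adjacent to an internal random-sequence template
(18 nt by default), so that chemistry extends the primer by copying the
template *in cis*. After the reaction, a fixed handle is ligated 3' of the
product, and each sequenced insert reads

```
handle5 + template + loop + primer + product + rt_handle
```

Because template and product travel on the same molecule, every read yields
a matched template-product pair, and millions of pairs characterize the
copying chemistry: which sequences get copied (bias), how faithfully
(error frequency, mismatch spectrum), and how far (yield, length
distribution).

`nerpeseq` implements the full analysis path from raw paired FASTQ to those
statistics, plus a generative simulator with ground truth so that every
estimator can be validated by parameter recovery without any external data.

## Coordinate conventions

All statistics are indexed in *templating order*: template base `t_1` is the
base adjacent to the primer 3' terminus (the 3'-most base of the template
region in molecule orientation), and it directs product position `+1`. A
product of length `L` has bases `p_1..p_L` in order of addition; position
`i` is a match when `p_i` is the Watson-Crick complement of `t_i`, otherwise
a mismatch labelled `template:product` (`"G:U"` means template G directed
product U; there are exactly 12 such labels). Internally all coordinates are
0-based half-open, and the single point of conversion to templating order is
pair extraction. FASTQ input is cDNA-derived and uses T; the package maps T
to U on extraction and reports RNA bases everywhere.

## Read processing

1. **Mean-quality filter.** A pair passes when each mate's mean Phred score
   is at least `min_mean_q` (default 30, inclusive). The companion per-base
   threshold (`min_base_q`, default 20) is applied later, only to the bases
   that enter statistics — the template and product windows of the merged
   insert. These defaults are conventional Illumina practice; they are
   configurable and deliberately not load-bearing for any estimator.
2. **Mate merging.** The mates overlap by construction. Candidate insert
   sizes run from the fixed-region total to that plus the template length;
   the size minimizing overlap disagreements wins, requiring at least
   `min_overlap` (10) overlapping bases and at most `max_disagreements` (0)
   conflicts. At a retained conflicting position the higher-quality base is
   used. With the default `read_len = 75` and the default construct, the
   overlap is at least ~70 nt, so the insert size — and hence the product
   length — is identified essentially unambiguously.
3. **Fixed-region matching.** Each fixed region is anchored by
   substitution-only (Hamming) matching within ±3 nt of its architectural
   offset, tolerating `max_region_mismatches` (1) substitutions per region.
   Indel-tolerant alignment is deliberately not used: the construct has a
   rigid architecture and merged inserts can only carry substitutions, so
   the template window between `handle5` and `loop` must be exactly
   `template_len` nt — anything else is a `fixed_region_mismatch`. If the
   fixed regions are not found, the reverse complement of the merged insert
   is tried before rejecting, which makes extraction invariant to swapping
   the two mates.
4. **Window screening and extraction.** Ambiguity codes (N) are tolerated in
   fixed regions (they consume mismatch budget) but any non-ACGU symbol in
   the template or product window rejects the read
   (`template_has_ambiguity`): degenerate bases must not enter statistics. A
   product window longer than the template region would mean extension ran
   into the 5' handle; whether such molecules occur in real libraries is not
   established, so they are rejected and counted separately
   (`product_overrun`) rather than truncated or guessed at.

Every input pair is accounted for exactly once — accepted or under one
rejection reason — and the suite asserts this conservation on every
synthetic run.

## Composition normalization

Synthesized "random" templates are not perfectly equimolar, so raw product
statistics confound chemistry with template composition. A matched control
experiment with no activated nucleotides measures composition alone: with
`f(i, b)` the fraction of control templates carrying base `b` at templating
position `i`, the package uses weights

```
w(i, b) = 0.25 / f(i, b)
```

and weights each observation by the product of `w(i, t_i)` over exactly the
positions entering the statistic: positions `1..L` for positional frequency
tables, the three window positions for trimer tables. This is the minimal
multiplicative scheme that makes a biased template look equimolar: it
reduces to the identity under a perfectly uniform control (all weights 1,
asserted exactly in the tests) and recovers 0.25-per-base positional
frequencies on simulated data with a skewed template (asserted to ±0.02 at
n = 40,000). A control in which some base is never seen at some position is
reported as a degenerate-control error rather than patched.

Two fidelity statistics are deliberately *unweighted* by default: the error
frequency and the mismatch spectrum. Reweighting by template composition is
a statement about which templates are counted, i.e. about bias; folding it
into a fidelity estimate would conflate the two. Both functions accept a
normalization object for the weighted variant when that is wanted.

## The statistics

- **Positional frequencies** `F(i, b)`: weighted fraction of selected
  products with base `b` at `+i`, over products covering `+i`. The default
  selection is fully complementary products (zero mismatches over the full
  length), the standard way product composition is reported; `products =
  "all"` uses every extended product. Defined rows sum to 1 within 1e-9.
- **Trimer tables**: each fully complementary product of length ≥ 3 (window
  1-2-3) or ≥ 6 (window 4-5-6) contributes its product trimer, weighted over
  the window positions; all 64 trimers are always present, zeros kept, and
  frequencies sum to 1. The ideal uniform value is 1/64 ≈ 0.016. The summary
  median is taken over all 64 trimers *including* zeros, so unobserved
  trimers rank at the bottom of the distribution; the min, max and max/min
  fold-difference are taken over represented (nonzero) trimers only, and the
  fold-difference is conventionally read to the nearest integer.
- **Error frequency**: total mismatch calls over total incorporated bases,
  across all extended products.
- **Mismatch spectrum**: counts of the 12 `template:product` types by
  position, normalized over all mismatches.
- **Product classes**: the complementary fraction among extended products;
  among mismatch-containing products, the fraction with more than one
  mismatch; among single-mismatch products, the fraction whose mismatch is
  terminal (at position `L`, the last-added base). Conditional fractions
  with empty denominators are reported as undefined (`NA`), never as 0.
- **Yield and lengths**: yield is the fraction of all primers extended by at
  least one base; the cumulative incorporation at `+i` is the fraction of
  all molecules whose product reaches `+i`, split by whether the call *at
  position i itself* is correct. The split classifies each position by its
  own call, not by "any mismatch up to i" — the alternative reading — since
  the per-position convention is the one under which the correct/incorrect
  bands at each position sum exactly to the coverage at that position. The
  curve is non-increasing and its value at `+1` equals the yield; both are
  asserted as invariants.

## The simulator

`simulation_params()` exposes one lever per estimated quantity:

| lever | default | what it emulates |
|---|---|---|
| `template_composition` | uniform 0.25 | synthesis bias of the random region |
| `extension_prob` | 0.23 | fraction of primers extended (the oligo-mix yield) |
| `length_mean`, `length_min` | 3, 1 | truncated-geometric product lengths, capped at 18 |
| `base_bias` | 0.063 off-complement, uniform | incorporation fidelity and bias per template base |
| `ligation_prob`, `ligation_len`, `ligation_error_rate` | 0.02, 6, 0.25 | oligo ligation: a contiguous 3' block with elevated errors |
| `seq_error_rate` | 0.001 | per-read-base sequencing substitutions |
| `read_len`, `quality_q` | 75, Q37 | paired-end 150-cycle-style reads, constant quality |

The defaults are the headline conditions of the mixed
mononucleotide/random-oligo chemistry: 23% extension and a 0.063
per-incorporated-base substitution probability. The geometric length model
is a stand-in — the empirical length distribution is dominated by short
products but is not tabulated analytically — and the mean of 3 gives enough
mass at L ≥ 3 and L ≥ 6 for both trimer windows to populate. Ligation is
modelled as the simplest mechanism that reproduces the observed enrichment
of multi-mismatch products among longer ones: an appended contiguous block
with independent per-base errors at an elevated rate (0.25), occurring for
2% of extended products. This is a generative convenience chosen for
testability, not a kinetic claim; real ligation errors are junction-enriched
in a way this model does not attempt to capture. The constant-Q quality
model reflects that quality filtering is not an estimation target.

Rendering assembles the insert in molecule orientation (the template region
is written reversed relative to templating order — the renderer owns the
orientation flip), truncates both mates at the insert ends, and applies
sequencing noise independently per mate. With `seq_error_rate = 0`
extraction is lossless: the suite asserts that the statistics bundle
computed from extracted pairs serializes to a byte-identical JSON summary as
the bundle computed from simulator truth. All output is deterministic under
a fixed seed, byte for byte.

What passing these tests shows — and what it does not: recovery on
simulated reads validates the estimators and the extraction logic under the
generative model's assumptions (rigid construct architecture,
substitution-only noise, constant quality). It does not validate behavior
under adapter read-through, indels, position-dependent quality decay, or
chimeric library artifacts, none of which the simulator emulates.

## Numerical and design choices

- Frequencies are reported at full precision in TSV/JSON; printed summaries
  round to 3 decimals, matching how such tables are conventionally quoted.
- Ties in fixed-region anchoring resolve to the architectural offset
  (the search expands outward from the expected position).
- Mate-merge ties resolve to the smallest insert compatible with a perfect
  overlap; with ≥ 70 nt overlaps, competing candidates are effectively
  impossible unless the read is degenerate.
- `quality_filter` boundaries are inclusive (a mate at exactly the mean
  threshold passes).
- Thresholds mirror common practice for the upstream instrument-side filter;
  the original analysis code documents its exact values elsewhere, and no
  claim of bit-for-bit agreement with it is made.
- Problem sizes used by the checks: parameter-recovery assertions run at
  n = 100,000 molecules (error frequency, yield), 50,000 (trimer median,
  positional recovery), 10,000 (lossless round trip), with brute-force
  oracle comparisons at ≤ 1,000 pairs — sizes at which binomial noise sits
  well inside the stated tolerances (e.g. se ≈ 0.0004 for the error
  frequency at 100,000 pairs against a ±0.005 band).

## Known limitations

- Products longer than the template region are counted but not analyzed.
- The simulator's ligation and length models are intentionally minimal (see
  above); estimates of ligation-specific quantities from real data should
  not be benchmarked against them.
- Fixed-region matching is substitution-only; a library with real indels in
  the fixed regions would lose those reads to `fixed_region_mismatch`
  (visibly, in the filter report) rather than rescue them.
- The shipped default construct sequences are documented placeholders with
  the correct architecture; analyses of real libraries must supply the
  actual construct via `construct_spec()` or a YAML definition.

## A worked pass, end to end

```{r example, eval = FALSE}
spec <- construct_spec()
params <- simulation_params(n_reads = 20000, seed = 42)
sim <- simulate_experiment(params, spec, dir = tempfile("sim"))

pairs <- extract_pairs_fastq(sim$experiment_r1, sim$experiment_r2, spec)
ctrl <- extract_pairs_fastq(sim$control_r1, sim$control_r2, spec)
filter_report(pairs)

st <- nerpe_statistics(pairs, control_pairs = ctrl)
glance(st)
plot_trimer_frequencies(st$trimer_123)
plot_cumulative_incorporation(st$cumulative_incorporation)
```
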