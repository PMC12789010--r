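---
title: "Methods: integrative analysis of TF binding, accessibility and expression"
author: "peakcooccur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of TF binding, accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcooccur)
```

This vignette documents the statistical procedures implemented in
`peakcooccur`, the conventions and defaults behind them, and what the
synthetic-data generators do and do not emulate. The package operates
entirely downstream of peak calling: its inputs are interval sets
(ChIP-seq peaks, ATAC-seq peaks, TF footprints), PWMs, DEG tables and
normalized proteomics counts.

## Coordinate conventions

All file I/O follows the BED convention (0-based, half-open); in memory,
intervals are `GRanges` (1-based, closed). Two consequences worth spelling
out:

* *Book-ended* intervals — `[100,200)` followed by `[200,300)` — share no
  base, so they do **not** overlap, but they **do** fuse under
  `merge_intervals(gr, max_gap = 0)`.
* "Overlap" means sharing at least `min_bp` bases with at least one
  interval of the other set; the default `min_bp = 1` matches common
  bedtools usage. The threshold is exposed because published analyses
  rarely state it.

Chromosome names are compared as exact strings; no `chr`/Ensembl aliasing
is attempted.

## Consensus peaks

A consensus peak is a maximal run of positions covered by at least
`min_support` distinct replicates, computed on per-base coverage after
collapsing each replicate (so a replicate contributes at most one unit of
support per base). Base resolution was chosen because "present in at least
k samples" is ambiguous at peak level (which replicate's boundaries win?);
the base-level definition is order-independent and reproducible. A
peak-level alternative (`method = "peak"`: keep replicate peaks overlapping
at least `min_support − 1` other replicates, then merge) is provided for
comparison with tools that work that way. The reported `support` is the
maximum replicate support inside the run.

`min_support` larger than the number of replicates yields an empty set with
a warning rather than an error: in scripted sweeps over support thresholds
this is a legitimate boundary case.

## Annotation

The promoter window is `[TSS − hw, TSS + hw)` with `hw = 1000` bp,
strand-agnostic, reflecting the common "±1 kb of TSS" definition.
Precedence is promoter > genic > intergenic, so region classes partition
the peaks. Peak-to-gene assignment takes the gene with the nearest TSS
(distance 0 if the TSS falls inside the peak) within `max_distance`
(default 100 kb — a deliberate, configurable convention; annotation tools
differ here and published gene counts generally cannot be regenerated
without knowing the original tool's rule). Exact distance ties assign all
tied genes.

## PWM scanning and co-occurrence

PWMs are built from count matrices (JASPAR raw-count and MEME
minimal-motif dialects are parsed; MEME probabilities are rescaled by
`nsites` so the pseudocount acts on effective counts). A pseudocount of
0.01 is added before normalization, and scores are log2 odds (bits)
against a user-supplied background (default uniform). Scanning evaluates
every offset on both strands inside each container; reverse-strand hits
are reported on forward coordinates. Ambiguous bases score `-Inf`, so
windows containing them never pass a finite threshold.

Co-occurrence classification is per container: presence of at least one A
hit and at least one B hit yields the classes A-only / B-only / both /
neither, which always sum to the container count. Condition comparisons
use Pearson's chi-squared on the 2 × 4 condition-by-class table (df 3),
with an explicit error when any expected cell is zero (pooling sparse
classes is the user's decision, not something done silently).

### Spacing

For each container holding both motifs, the spacing is the **minimum over
all A × B pairs** of the center-to-center distance, with centers at
`floor((start0 + end0)/2)`. Nearest-pair center-to-center was chosen for
robustness to motif width; an edge-gap convention (`convention = "edge"`,
overlapping hits clamped to 0) is exposed because the field does not agree
on one definition, and no claim is made that either reproduces any
particular published figure. Distances are summarized by the median and by
the most populated 5-bp histogram bin. The bins are *centered on multiples
of 5* (`[5k − 2, 5k + 3)`): with edge-aligned bins, a true mode sitting on
a bin boundary (e.g. 25 bp with edges at 20/25/30) splits its mass almost
exactly in half between two bins, and the modal bin becomes a coin flip no
matter how large the sample; centered bins keep the estimator identifiable.

### Kolmogorov–Smirnov test

`ks_two_sample()` computes `D = sup_t |F̂_x(t) − F̂_y(t)|` over all observed
points (well defined under ties). The p-value uses the exact conditional
null distribution when the effective sample size `mn/(m+n)` is below 35
and the pooled sample is tie-free, and the asymptotic Kolmogorov series
`Q(λ) = 2 Σ (−1)^{k−1} e^{−2k²λ²}` at `λ = √(mn/(m+n))·D` otherwise.
Integer-valued spacing data always carry ties, so they take the asymptotic
route; the resulting p is mildly conservative, which is acceptable for the
strongly separated distributions this test is used on.

## Permutation overlap null

The observed statistic is the number of query intervals overlapping the
target set. Under the null, each query interval is re-placed independently
and uniformly among its valid start positions — by default on its own
chromosome (the analogue of `bedtools shuffle -chrom`), because
cross-chromosome placement inflates significance whenever chromosome
composition is non-uniform. Cross-chromosome placement (probability
proportional to chromosome length) and exclusion regions (rejection
sampling with a 1000-redraw budget per interval) are available; shuffled
intervals may overlap one another, as in bedtools, with an opt-in
no-self-overlap mode. Only the query set is shuffled; swap the arguments
to shuffle the other set. Which set the original analyses shuffled is
generally unstated in publications, so this is exposed rather than fixed.

The empirical p-value is `(r + 1)/(N + 1)` with `r` the number of null
counts at least as extreme as the observed count. This estimator is never
zero — with `N = 1000` shuffles the smallest attainable p is
`1/1001 ≈ 9.99 × 10⁻⁴` — and is the standard unbiased choice for
permutation tests. Shuffle `i` uses seed `seed + i`, making runs
reproducible and parallelizable by index.

When `min_bp = 1`, no exclusion regions apply and placement is
per-chromosome, the null loop runs on a vectorized fast path (uniform
start draws plus a stabbing query against the merged target) that is
RNG-identical to the generic shuffle-and-count route; the test suite
asserts this equivalence.

## Accessibility and expression integration

A bound site overlapping at least one ATAC peak is *accessible*; otherwise
it is a closed chromatin region (CCR). Class-conditional proportions are
compared with Pearson's chi-squared without continuity correction (none of
the analyses this mirrors report using one); Yates' correction is a flag
for 2 × 2 tables. Differential-accessibility calls ("more accessible in
condition X") are consumed as precomputed interval sets with a direction,
not recomputed — the thresholds behind such calls vary by pipeline and are
treated as an input contract.

DEG direction uses fold change > 1.5 with adjusted p < 0.05, applied
symmetrically (up: fold > 1.5; down: fold < 1/1.5); missing adjusted p
means not significant. The symmetric reading of "fold change > 1.5" is a
choice — publications rarely state the down-regulation bound. Genes bound
by peaks of several motif classes are classified by the union of their
peaks' motif content (both > A-only > B-only > neither) and logged, since
the per-gene class is otherwise ill-defined. The class-by-direction test
uses only up/down columns; `ns` rows are reported but not tested, and
empty classes are dropped with a warning.

The proteomics filter keeps proteins whose
`(tagged + c)/(control + c)` ratio strictly exceeds 2 ("more than
two-fold"), with pseudocount `c = 0.5` to define behavior at zero
controls; `c = 0` recovers raw ratios (zero controls then yield infinite
enrichment and are kept).

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with planted
structure recorded in truth tables:

* `simulate_genome()` — uniform-base sequences plus a layout. No GC
  structure, repeats or gaps.
* `simulate_peaks_with_motifs()` — fixed-width, non-overlapping containers
  (a 1-bp minimum spacer prevents book-ended artifacts), exact per-class
  motif counts, and for dual-motif peaks a center distance drawn from
  `Normal(25, 2)` rounded to integers (half away from zero) and truncated
  to the feasible range. Motif instances are the PWM consensus string
  written into the sequence, guaranteeing rediscovery at the
  consensus-score threshold; they are not sampled from the PWM, so scanner
  sensitivity at sub-consensus thresholds is *not* exercised.
* `simulate_replicates()` — per-peak Bernoulli detection and rounded
  Gaussian boundary jitter. No signal-strength model.
* `simulate_accessibility()` — class-conditional Bernoulli accessibility
  (or exact counts), one flanking ATAC peak per accessible container,
  clipped at neighboring containers so truth labels stay exact.
* `simulate_deg()` — class-conditional direction with
  `log2FC = ±1.5 + Normal(0, 0.1)` and `padj ~ U(0, 0.05)` for calls,
  `Normal(0, 0.1)` / `U(0.05, 1)` for non-calls. No count-level noise
  model.
* `simulate_set_pair()` — id sets with exact cardinalities and overlap.

Counts mode exists because printed worked examples are exact ratios;
probability mode exists because calibration tests need sampling noise.
Passing tests on this synthetic layer certifies the *bookkeeping and
statistics* of the pipeline — classification, counting, null calibration,
recovery within binomial error — not robustness to the biological
messiness of real data (irregular peak shapes, motif degeneracy,
GC-dependent background, correlated replicates).

## Problem sizes and numerical choices

The test suite runs at deliberately modest scale, chosen so the whole
suite stays fast while keeping every statistical check well-powered:
oracle-equivalence suites use ≥200 random instances per operation on
multi-kb toy genomes; null calibration uses 200 independent runs of a
200-shuffle test on a 2 × 1 Mb genome (the add-one estimator's
discreteness makes the rejection fraction at 0.05 land near 0.05 but not
exactly; the accepted band is [0.02, 0.10]); parameter-recovery suites use
500 sites per class (accessibility), 400 genes per class (expression), and
a 3-standard-error tolerance. All jitters and roundings are
round-half-away-from-zero, stated explicitly for cross-language
reproducibility. Seeds are mandatory everywhere randomness occurs; no
generator falls back to clock seeding.

## Known limitations

* The shuffle null models placement uniformity only — no GC matching, no
  gap-awareness beyond explicit exclusion regions, no local (regioneR-style)
  shuffling.
* The scanner is a plain PWM scanner: no dinucleotide background, no
  E-values, no de novo discovery.
* Region annotation uses TSS and gene-body intervals only; enhancer calls
  must come from outside.
* `padj` values are consumed as given; no multiple-testing recomputation.
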