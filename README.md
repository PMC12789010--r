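# peakcooccur

Integrative analysis of a transcription factor's binding landscape from
post-peak-calling data. The package was built around the kind of question
asked when profiling a repressor such as PRDM1 (Blimp-1) in primary human
NK cells: where does the factor bind reproducibly across ChIP-seq
replicates, which binding sites also carry a partner motif (e.g. RUNX or
AP-1) and at what spacing, is the overlap between two interval sets (ChIP
peaks vs ATAC peaks, footprints vs differential regions) larger than chance,
which bound sites sit in closed chromatin, and how does binding class relate
to differential gene expression.

It is aimed at computational biologists who already have peak calls,
footprint calls, DEG tables and normalized proteomics counts, and want the
downstream integration to be reproducible and testable without touching the
raw reads.

## What it computes

* **Consensus peaks** — maximal genomic runs supported by at least *k* of
  *n* replicate peak sets, at base resolution (a peak-level variant is
  available). `consensus_peaks()`
* **Region annotation** — promoter (TSS ± 1 kb by default) > genic >
  intergenic, plus nearest-TSS gene assignment with exact-tie retention.
  `annotate_region()`, `assign_to_genes()`
* **Motif scanning and co-occurrence** — log2-odds PWM scanning (JASPAR and
  MEME minimal formats) inside container intervals; containers are
  classified A-only / B-only / both / neither and two conditions are
  compared by a df-3 chi-squared test. Nearest-pair motif spacing per
  container, with a two-sample Kolmogorov–Smirnov test
  (`D = sup_t |F̂_x(t) − F̂_y(t)|`, exact null for small tie-free samples).
  `scan_pwm()`, `classify_cooccurrence()`, `pair_distance_distribution()`,
  `ks_two_sample()`
* **Permutation overlap null** — each query interval is re-placed uniformly
  on its chromosome (lengths preserved, optional exclusion regions), and
  the overlap count against a fixed target set is recomputed over *N*
  shuffles; the empirical p-value uses add-one smoothing,
  `p = (1 + #{null ≥ obs}) / (1 + N)`. `permutation_overlap_test()`
* **Accessibility partition** — bound sites split into accessible vs closed
  chromatin regions (CCRs) by ATAC-peak overlap; class-conditional
  proportions compared by chi-squared. `classify_accessibility()`,
  `crosstab_chi2()`
* **Expression crosstabs** — DEG direction (fold change > 1.5,
  adjusted p < 0.05 by default) tabulated against binding/footprint
  classes. `deg_filter()`, `direction_by_class()`
* **Set and proteomics summaries** — exact id-set overlaps and the
  more-than-two-fold normalized-peptide-count enrichment filter.
  `set_overlap_summary()`, `protein_enrichment_filter()`
* **Synthetic data** — deterministic generators that plant class counts,
  motif instances with controlled spacing, replicate detection/jitter,
  class-conditional accessibility and expression, and fixed set overlaps,
  together with truth tables, so every stage's recovery is verifiable.
  `simulate_*()`

Intervals are `GenomicRanges::GRanges`; BED/narrowPeak I/O uses the 0-based
half-open convention at the file boundary. `run_pipeline()` chains the
stages from a validated `run_config()` and writes a versioned JSON report.

## Worked example

```r
library(peakcooccur)

genome <- simulate_genome(c(chr1 = 3e5, chr2 = 2e5), seed = 11)
sim <- simulate_peaks_with_motifs(
  genome, c(a_only = 120, b_only = 30, both = 40, neither = 10), seed = 12)
reps <- simulate_replicates(sim$containers, genome$layout,
                            n_replicates = 3, detection_prob = 0.85,
                            jitter_sd = 8, seed = 13)
peaks <- consensus_peaks(reps, min_support = 2)
length(peaks)
#> [1] 187

pwms <- example_pwms()
hits_a <- scan_pwm(peaks, sim$sequences, pwms$prdm1_like,
                   threshold = 0.9 * max_score(pwms$prdm1_like))
hits_b <- scan_pwm(peaks, sim$sequences, pwms$runx_like,
                   threshold = 0.9 * max_score(pwms$runx_like))
classify_cooccurrence(peaks, hits_a, hits_b)
#> co-occurrence over 187 containers: A-only 113 (60.4%), B-only 28 (15.0%),
#>   both 36 (19.3%), neither 10 (5.3%)
pair_distance_distribution(peaks, hits_a, hits_b)
#> spacing distribution: 36 pair(s), median 25.0 bp, modal 5-bp bin [23, 28)

acc <- simulate_accessibility(sim$containers,
                              c(a_only = 0.6, b_only = 0.95, both = 0.9,
                                neither = 0.8), seed = 14)
permutation_overlap_test(peaks, acc$atac, genome$layout,
                         n_shuffles = 1000, seed = 15)
#> permutation overlap test: observed 136, null mean 26.0 (n = 1000
#>   shuffles), p = 0.000999 (greater), seed 15
classify_accessibility(peaks, acc$atac)$ccr_percent
#> [1] 27.3
```

Reading the output: of 190 planted peaks, 187 survive the two-of-three
consensus requirement; the scanner recovers the planted motif classes
(60.4% A-only against 120/190 = 63% planted, with the shortfall coming from
peaks lost at the consensus stage and chance background matches); the
spacing mode sits at the planted 25 bp; the consensus peaks overlap the
ATAC set far above the shuffle null (136 observed vs 26 expected,
p = 1/1001, the smallest value 1000 shuffles can certify); and 27.3% of
bound sites are in closed chromatin.

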