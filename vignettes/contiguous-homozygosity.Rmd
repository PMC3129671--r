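---
title: "Quantifying contiguous homozygosity with hzkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contiguous homozygosity with hzkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hzkit detects runs of contiguous homozygosity (homozygous segments / runs of
homozygosity, ROH) in dense diploid SNP panels and quantifies their
population-level structure. This vignette explains the models and procedures
the package implements, the parameters that matter, the numerical choices
made where a published description left the details open, and what the
synthetic-data generator does and does not emulate.

```{r setup, message = FALSE}
library(hzkit)
library(dplyr)
```

## The data model

A `genotype_matrix` holds diploid calls coded 0 (homozygous reference), 1
(heterozygous), 2 (homozygous alternate) and 3 (missing), with loci strictly
ordered by chromosome and base-pair position. Standard quality control is
applied before detection: a pooled minor-allele-frequency filter
(`filter_maf()`, default keep MAF > 0.05), an exact test of Hardy–Weinberg
equilibrium per locus (`hwe_exact_test()`, the conditional enumeration over
heterozygote counts; the removal threshold, default p < 1e-6, is
configuration — published analyses state that the test is applied but not
its cutoff), and removal of loci in immunoglobulin-variable regions or in
copy-number-variable intervals at or above 5% population frequency
(`apply_region_mask()`). Coordinates are 1-based inclusive throughout; BED
input is converted on read. On chromosome X only female genotypes are used
for segment detection.

## Segment detection

`detect_segments()` runs a four-stage heuristic per sample and chromosome:

1. **Run detection.** Maximal runs of homozygous calls. Missing calls never
   break a run (they are counted per segment); heterozygous calls do.
2. **Gap handling.** Runs are split at inter-SNP gaps above a
   chromosome-specific boundary, then rejoined when the joining rule for the
   gap's size range allows it. The boundary is derived from the data:
   inter-SNP gaps are log-transformed, a standard boxplot summary computed,
   and the boundary set to `exp(upper hinge + 1.5 × inter-hinge spread)`
   (`compute_gap_thresholds()`). Each row of the gap table
   (`gap_min_bp`, `gap_max_bp`, `min_density_snp_per_kb`,
   `min_flank_proportion`) demands that both flanking runs be at least a
   proportion of the gap size and that the joined span keep a minimum SNP
   density — so only very long (autozygous-scale) segments span
   centromere-scale gaps while short segments are truncated at gap edges.
   The shipped default ranges (up to 50 kb: flanks ≥ 2% of the gap; 50–500
   kb: ≥ 10%; above 500 kb: ≥ 50%) are explicit configuration, not a claim
   about any other implementation's internal values.
3. **Heterozygote 'error' absorption.** Two runs separated by a single
   isolated heterozygote merge when one heterozygote over the flanking run
   pair's called SNPs is within the maximum heterozygote proportion
   (default 1%), and the accumulated segment still satisfies the same bound.
   The pairwise form matches the worked boundary cases: 300 + 1 het + 300
   merges (1/601 ≈ 0.17%), 40 + 1 het + 40 does not (1/81 ≈ 1.23%).
4. **Scan-ahead.** Each segment is greedily extended rightward across
   heterogeneous gap/heterozygosity structure. A candidate end (a run
   boundary) is admissible when the whole extended segment keeps
   heterozygosity ≤ 1%, every crossed large gap passes the scan gap table,
   and two *local* screens pass. The scan never retracts previous joins.

### The local heterozygosity screens

A proportion threshold of a few percent needs a real denominator, so the 2%
scan threshold is evaluated over the **trailing window** of the last
`min_scan_window` (default 100) called SNPs of the candidate segment:
sustained local heterozygosity above 2% stops extension, while an isolated
error heterozygote inside a long clean tract (1 in 100 = 1%) does not.
Separately, an extension may never cross a **dense burst** — a stretch
exceeding `max_dense_het` (default 20%) heterozygosity within a
`dense_window` (default 25) called-SNP window. Bursts mark genuinely
heterozygous sequence at a segment's edge; crossing one is always possible
arithmetically when a long clean region follows (the global 1% budget
dilutes), but doing so spends the error budget on real heterozygosity and
truncates the far end of true autozygous tracts. Sparse pockets of clustered
genotyping error (say 3 heterozygotes spread over 100 SNPs) fall below the
dense cap and are bridged. The scan terminates once the frontier is locally
heterozygous, the global budget is exhausted, and the scan has ranged past
twice the established segment's SNP count — a point after which no
admissible stop arises in practice.

These window semantics are this package's own design (a published
description fixes only the 1% and 2% thresholds); they were chosen so that
(i) with both local screens disabled the detector reduces exactly to the
left-greedy maximal extension under the 1% rule, which an exhaustive
enumerator can verify, (ii) extension halts at a sustained 3% neighbourhood
and proceeds through 1%, and (iii) a multi-megabase autozygous tract with
0.5% genotyping error is recovered as one segment.

Emitted segments carry ≥ 2 homozygous calls and flags: `high_missing`
(no-call rate > 5%), `low_density` (≤ 0.2 SNP/kb, one SNP per 5 kb), and
`masked_cnv` (> 50% of loci inside CNV/abnormality intervals).

## Segment scores

**HPS.** The homozygosity probability score of a segment is the product of
its loci's observed homozygosity frequencies (`Freq_HOM`, the fraction of
non-missing calls that are homozygous), computed in log space so
multi-thousand-SNP segments do not underflow. With pooled (cross-population)
frequencies this is `HPS_ex`; with the sample's own population's
frequencies, `HPS_in`. Segments with `HPS_ex ≤ 0.01` form the analysis set:
smaller scores mean the run is unlikely to be chance homozygosity. Because
the pooled frequencies encode all populations, a region fixed in one
population but polymorphic in another remains informative — which is what
lets the fixed-region analysis below work; in a single-population panel a
fixed region has `Freq_HOM ≈ 1`, `HPS_ex ≈ 1`, and its segments are
(correctly) discarded as uninformative.

**MISL.** The minimum inclusive segment length is, per chromosome, the
smallest over samples of each sample's longest segment; filtering at MISL
guarantees every sample contributes at a threshold. The genome-wide MISL is
the minimum over chromosomes.

**MAD score.** To identify putative autozygous segments, the
intersecting-segment-length vectors under a segment are extracted, duplicate
columns collapsed, and for each representative the median m and raw median
absolute deviation d of the non-zero values computed; the per-vector score
is `(length − m) / (1.4826 · d)` — a robust z-score under the normal
consistency constant — and the segment's score is the median over vectors.
The exact standardisation is this package's documented assumption (the
published account gives the threshold but not the equation). Segments with
score > 10 are flagged for masking; those whose founder-haplotype frequency
is also zero form the autozygosity call set.

**Founder haplotype frequency.** A segment's founder haplotype is its
homozygous allele string (absorbed heterozygous and missing loci excluded).
Against a phased panel restricted to the segment's loci and population —
excluding the carrier's own two haplotypes, so that a private haplotype
scores zero — the frequency is the proportion of panel haplotypes within
`max(0.01 · L, 1)` mismatches, L the segment's SNP count; missing panel
alleles are excluded from the comparison.

## Locus-level extent: ISLM, PE_mat and ext_AUC

The intersecting segment length matrix (`build_islm()`) holds, per sample
and locus, the length (bp or cM) of the sample's segment covering that
locus, zero when none does, `NA` under CNV-masked segments. Centimorgan
lengths use chromosome-arm-average recombination rates, with arm-spanning
segments split proportionally. Cells fed by putative autozygous segments
(MAD > 10) are capped at the highest non-autozygous length in their column
(`mask_islm_autozygous()`), removing rare very long segments' leverage
without discarding the carriers.

`pe_mat()` summarises one population's column distributions as 101
percentiles (type-7, linear interpolation). `ext_auc()` reverses the sign of
each locus's combined values — orienting the rare long segments at the start
of the distribution — takes integration bounds from that combined vector
(lower: the most negative value; upper: the value closest to zero from
below, the empty interval next to zero being noise), forms the population's
ECDF (zeros included, masked cells dropped) and integrates it exactly as a
step function over the bounds. Exact step integration replaces generic
quadrature: it is deterministic, and the tests keep piecewise adaptive
quadrature as an independent oracle. When the combined vector has a single
distinct negative value the bounds collapse and ext_AUC is 0. Ranks
(`ext_auc_rank()`) are the empirical cumulative probabilities of ext_AUC
within a chromosome–population.

## Peaks, outlier regions, fixed areas

A cubic smoothing spline with knots at 3% of the loci (the controlled
parameter; the penalty itself is left to generalized cross-validation)
smooths each population's ext_AUC track; apexes and valleys are sign changes
of the analytic first derivative, with chromosome ends counting as valleys.
Adjacent peaks merge when their heights and the intervening valley differ by
less than 10% (differences taken relative to the taller peak — the published
rule does not name the denominator; it is configurable); merging iterates to
a fixpoint. Outlier peaks exceed the boxplot upper whisker of their
chromosome's merged-peak heights; adjoining outlier peaks that are not well
separated (intervening valley above half the smaller height) merge into
outlier peak regions.

For each peak, the percentile-extent matrix supplies pairs (Extent,
Pr = 1 − percentile/100); the pair maximising Extent × Pr gives the optimal
length threshold `extent_min` and exceedance probability `p_max` (ties
resolve toward the larger extent — the longer-haplotype hypothesis). If a
single haplotype explains the peak, homozygous carriers arise at its squared
frequency, so `freq_hap_exp = sqrt(p_max)`; `freq_hap_max` is the largest
founder-haplotype frequency among peak-intersecting segments longer than
`extent_min`.

Candidate fixed areas are maximal runs of loci whose 0th-percentile extent
is positive — every sample of the population carries a covering segment —
filtered to runs whose SNP count and extent exceed the first quartiles
computed over all populations' runs pooled (a per-population variant is
available via the quartile arguments; the pooled form is the default).

`peak_recombination()` computes the rate over a window centred on the
midpoint of the peak's upper-quartile ext_AUC loci, with width a
configurable fraction of the peak width (default 0.5 — a literal
full-width reading of "central half-width ± half the width" would make the
window the whole peak, so the fraction is exposed), and places it among
reference rates from same-sized windows tiled along the chromosome, since
the rate distribution depends on window size.

## Population differentiation and the two-group test

`fst_theta()` is the two-population Weir–Cockerham-style moment estimator
computed from genotype frequencies (observed heterozygosity enters directly,
so within-population Hardy–Weinberg equilibrium is not assumed), with the
sample-size corrections for unequal n. Negative estimates are reported as
computed. `differentiated_peaks()` selects peaks with maximum ext_AUC rank
≥ 0.90 in both populations and mean theta above a chromosome-type threshold
(defaults 0.0360 autosomes / 0.0538 for X — plain configuration values),
then estimates each population's haplotype frequency as the mean
pooled-minor-allele frequency across the peak's extreme-theta loci.

The agglomerative haplotype analysis scan (`cvm_scan()`) compares two
groups' segment-length distributions at each locus with a discrete
two-sample Cramér–von Mises statistic: both ECDFs are evaluated at every
unique combined value and ω² is the sum of squared differences. This
unweighted discrete form (rather than the classical nm/(n+m)²-weighted
statistic) is deliberate: only the relative ranking matters because
significance comes from a label-permutation test, whose achieved
significance level is the proportion of permuted statistics at least as
large as the observed one (denominator `n_perm`; a `plus_one` flag gives the
strictly positive convention). Zero lengths are retained in the ECDFs by
default, consistent with ext_AUC's treatment; `drop_zeros` is available.
A screening threshold allows permuting only loci whose ω² is large.

## The synthetic-data generator

`simulate_panel()` draws from a windowed founder-pool model: the chromosome
is cut into windows (50 kb scale by default, the scale of haplotype blocks),
each carrying a pool of 8 founder haplotypes with a geometric frequency
profile whose skew varies by window within `skew_range = c(0.1, 0.35)` —
so background homozygosity varies along the chromosome the way local LD
strength does, and the most frequent background haplotype stays below ~0.29.
Each individual draws two founders per window; identical draws make the
window homozygous. Planted features force known truth: an autozygous tract
copies one private haplotype onto both chromosomes of a sample; an extended
haplotype forces one founder to an exact carrier count, with the same
carrier chromosomes across all the feature's windows; a fixed region makes
one founder universal in one population, flanked by short forced-
heterozygous "diversity walls" so the planted boundary has a sharp truth
coordinate (real swept regions are bounded by recombination-restored
diversity, though not this sharply). Homozygote→heterozygote error flips
and missingness are layered on genotypes only; the phased panel is
error-free. Everything is reproducible byte-for-byte from the seed.

The model deliberately omits recombination-driven LD decay, realistic
demography, and selection: it controls directly the quantities the methods
measure (haplotype frequency, extent, fixation) and keeps the tests
analytic. Passing the planted-truth tests therefore shows the estimators
recover frequencies and extents under block-haplotype structure with
array-scale noise; it does not certify behaviour under fine-scale
recombination gradients or cryptic relatedness.

### Validation experiment sizes

The seeded recovery experiments use: a 3.5 Mb tract in a 5 Mb / 40-sample
panel at 0.5% heterozygote error (the error level at which the absorption
rules are exercised hard); extended haplotypes of 0.8 Mb at frequency 0.6
(30 samples) and 0.55 Mb at 0.3 (100 samples — at 9% expected homozygote
frequency the carrier count needs a larger panel, and a longer haplotype at
that frequency would start tripping the MAD autozygosity mask, which is the
method working as designed); and a 0.4 Mb fixed region in a two-population
30 + 30 panel without noise, since a ±1-SNP boundary comparison is only
meaningful against a sharply defined truth. Statistical calibrations use
5,000 simulated loci (theta, against the island-model expectation
Fst = 0.1) and 1,000 null loci at 999 permutations (type-I error of the
ω² test).

## A small worked run

```{r example, fig.width = 7, fig.height = 3.5}
cfg <- sim_config(
  n_samples = c(popA = 25, popB = 25), n_loci = 4000, n_windows = 80,
  extended_haplotypes = list(list(start_locus = 1801, end_locus = 2400,
                                  frequency = c(popA = 0.6, popB = 0.2))),
  seed = 11
)
sim <- simulate_panel(cfg)
gmap <- simulate_genetic_map(sim$gm$loci$position_bp)
res <- run_pipeline(sim$gm, panel = sim$panel, arm_rates = gmap$arm_rates)
glance(res)
res$peaks |>
  filter(outlier) |>
  select(population, apex_bp, height, extent_min, p_max, freq_hap_max)
plot_ext_auc(res$tracks, res$peaks)
```

## Known limitations

* Detection is greedy left-to-right and never retracts a join; a different
  scan order could in principle emit different boundaries in pathological
  heterozygosity patterns.
* Centimorgan lengths use arm-average recombination rates only; fine-scale
  maps enter solely through peak-level rate annotation.
* The MAD autozygosity mask cannot distinguish a rare private haplotype
  from a low-frequency (few-percent-homozygote) extended haplotype class;
  segments of the latter may be capped when the background length spread is
  tight.
* The two-group ω² scan does not correct for population stratification or
  provide genome-wide significance thresholds; its achieved significance
  levels are per-locus.
* Phasing is not performed; the founder-haplotype frequency requires an
  external (or simulated) phased panel.
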