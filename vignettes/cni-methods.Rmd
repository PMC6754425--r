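---
title: "Quantifying chromosomal instability in plasma cfDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability in plasma cfDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Advanced solid tumors, gastric cancer prominently among them, are often
driven by chromosomal instability: recurrent arm-level and focal somatic
copy number alterations (SCNAs). A fraction of circulating cell-free DNA
(cfDNA) in a patient's plasma derives from tumor cells, so shallow
whole-genome sequencing of plasma — a few million reads, far below 1x
coverage — carries a faint, genome-wide imprint of the tumor's copy-number
landscape. `cnipipe` turns that imprint into a single per-sample number, the
copy number instability (CNI) score, and into a binary call — CIN
(chromosomally instable) versus CNS (stable) — that can be compared across
patients and tracked across treatment timepoints.

The package implements the full chain: binned read counts, GC and
healthy-reference normalization, circular binary segmentation (CBS), the
per-bin z transform, the percentile-window score, healthy-cohort cutoff
estimation, and cohort-level statistics for response association and
longitudinal monitoring. A synthetic-data generator reproduces the
statistical structure the analysis assumes, so every stage is tested
without access to sequencing data.

## From reads to relative copy number

Reads are counted into fixed, non-overlapping windows of 1000 kb over the
22 autosomes (`build_bins()`, `count_reads_in_bins()`); sex chromosomes are
rejected at input so no sex-specific ploidy handling is needed. Counting is
by read start position into half-open intervals; internal coordinates are
0-based half-open, SEG output is 1-based inclusive, BED input 0-based.

Raw counts carry a smooth bias with GC content. `gc_correct()` fits a
locally weighted regression (tricube weights, two robustness iterations,
span 0.3 of the data per window) of count on GC fraction and divides it
out, rescaled to preserve the mean count. Bins with GC outside [0.28,
0.68] or zero count are masked from everything downstream. On grids with
fewer than 100 usable bins the fit falls back to medians within 2%-wide GC
strata, which keeps very small test genomes well defined; at least 30
usable bins are required at all.

The healthy reference (`build_reference()`) is the per-bin median across a
donor cohort of GC-corrected count fractions. Bins that are zero in more
than half the cohort, have non-positive median level, or whose
cross-sample MAD exceeds five times the cohort-typical MAD are masked. A
sample is then normalized (`normalize_to_reference()`) as

$$x_i = 2\,\frac{f_i}{r_i},$$

where $f_i$ is the sample's corrected count fraction in bin $i$ and $r_i$
the reference level: a healthy-like bin sits at $x_i = 2$ by construction.
We deliberately do not re-center by the sample's median ploidy: at
low-coverage depth with a substantial tumor fraction, genome-median
recentring is unstable, and the diploid anchor is what the downstream
formula assumes. Values are clamped below at $x = 0.01$ so the log
transform stays defined; the clamp bounds any single bin's z value at
$\sqrt{|\log_2 0.005|} \approx 2.77$.

Whether to normalize by sample total before or after GC correction is
arbitrary under scale invariance (multiplying all counts by a constant
leaves $x$ unchanged, which the tests assert); we correct first, then take
fractions.

## Segmentation

SCNAs are segmental, so per-bin signals are smoothed by circular binary
segmentation before scoring. `segment_profile()` works per chromosome on
$\log_2(x/2)$ of the unmasked bins. Each current segment is treated as a
circle; the arc $(i, j]$ maximizing the pooled two-sample t statistic
between arc and complement is found by exhaustive $O(n^2)$ scan (the scan
is compiled code; on signals of up to 50 bins the tests check it against a
brute-force R oracle). The split is accepted when its permutation p-value —
label permutations of the bins within the segment — falls below `alpha`,
and the pieces are segmented recursively.

Numerical and algorithmic choices that matter:

* **Defaults** `alpha = 0.01`, `n_perm = 1000`, `min_width = 3`, all
  exposed in the configuration. Segments shorter than `min_width` are
  merged into the neighbour with the closer mean. Chromosomes are never
  merged with each other.
* **Canonical arcs.** An arc ending at the segment's last position
  duplicates the partition of a prefix arc (the complement of a suffix is
  a prefix); only one representative is enumerated, so the smallest-
  $(i,j)$ tie-break is well defined even under floating-point noise.
* **Centering.** The signal is centered before the scan; the statistic is
  location-invariant, and centering avoids catastrophic cancellation on
  (near-)constant segments. A segment with zero pooled variance but a
  nonzero mean difference is scored with a large sentinel so noise-free
  steps always split.
* **Sequential early stopping.** The permutation scan stops as soon as the
  exceedance count alone forces $p \ge$ `alpha`; this changes no
  accept/reject decision but makes flat (healthy) chromosomes roughly
  fifty times cheaper, which is what makes cohort-scale Monte-Carlo
  feasible on one CPU.
* **Determinism.** All permutations run under a seeded RNG; identical
  inputs and seed give identical segment sets.

## The instability score

With segments applied (every unmasked bin replaced by its segment's copy
number — the default; `z_source = "raw"` scores unsegmented bins instead),
each bin gets

$$z_i = \sqrt{\left|\log_2\frac{x_i}{2}\right|},$$

zero for diploid bins and 1 for a bin one doubling away in either
direction. The CNI score sums the upper tail of the z distribution while
excluding its extreme:

$$\mathrm{CNI} = \sum_{i = m_b}^{p_b} |z_i|,$$

where $m_b$ and $p_b$ are the bins ranked at the $m$-th and $p$-th
percentile of z ($m = 95$, $p = 99$ by default). The window takes the
strongest 4% of genomic deviations — large enough to capture arm-level
events, robust to the top 1% of bins where isolated artifacts concentrate
(the tests assert the score is exactly invariant to magnifying the single
largest z). Ranks are defined as $m_b = \lceil mN/100 \rceil$ and
$p_b = \lfloor pN/100 \rfloor$, 1-based inclusive on an ascending stable
sort (ties broken by bin index), over the $N$ unmasked bins; the window
must be non-empty, which requires roughly $N \ge 100/(p - m)$.

A sample is called CIN when its score strictly exceeds the cutoff; a score
exactly at the cutoff is CNS. The cutoff is the mean plus one sample
standard deviation (n−1 denominator) of a healthy cohort's CNI scores. The
package ships 56.60 as the default constant — the published value from a
100-donor plasma panel. That constant is data-dependent: it reflects the
original study's sequencing depth, bin grid and cohort, and is **not**
recomputable from synthetic data, which is why the simulated analyses
always calibrate their own cutoff.

Two calibration decisions were genuinely open and are resolved as follows:

* **Leave-one-out calibration.** The cutoff is applied to unseen patient
  samples, so scoring each donor against a reference its own noise helped
  define would bias the cutoff low. `build_reference()` therefore scores
  donor $j$ against the per-bin median of the other $n-1$ donors. For a
  100-donor median reference the numerical effect is small; the choice is
  on principle.
* **Decoupled RNG streams.** Simulation consumers derive child seeds
  through an integer hash (`mix_seed`) rather than using consecutive seed
  values directly. Streams seeded with nearby integers can be measurably
  correlated; in an early version this coupled the GC track with cohort
  sample noise and damped cohort score dispersion by ~15%, visibly biasing
  the cutoff. Hash-mixing restores exchangeability between cohort members
  and fresh samples while keeping the documented seed-plus-index API.

Note a structural property of a mean-plus-SD cutoff: for a roughly
Gaussian score distribution about 16% of healthy samples exceed it by
construction. The observed exceedance in our simulations is 8–16%
depending on the cohort realization (the score distribution is mildly
right-skewed). Any application of such a cutoff should expect
healthy-sample "CIN" calls at about that rate.

## Cohort statistics

`build_table()` dichotomizes best response as responder (PR) versus
non-responder (SD or PD) — no complete responses occur in the cohort this
mirrors, and only this dichotomy reproduces the published association —
and `pearson_chi2()` applies the Pearson chi-square without continuity
correction (the correction is available behind a flag; with it the
published table would no longer be significant). `trajectory_summary()`
reports, over patient timelines: the fraction of patients whose score at
PR falls below the cutoff; the fraction whose score at PD exceeds the
immediately preceding timepoint ("elevated again" is operationalized as a
strict increase over the previous measurement, the study having left it
undefined); and the fraction whose PD score stays under baseline.
`pattern_concordance()` is the Pearson correlation of two segmented
$\log_2(x/2)$ profiles over shared unmasked bins — amplitude-free evidence
that a progression sample carries the same alteration pattern as its
baseline.

## The synthetic generator

`simulate_*` emulates the data-generating process the analysis assumes:

* a fixed GC track per genome (normal, mean 0.45, SD 0.05, clamped to
  [0.30, 0.65]);
* a smooth unimodal GC bias multiplying expected depth,
  $(1-a) + a\exp(-(g-0.45)^2/2\cdot0.12^2)$ with amplitude $a = 0.3$ —
  the canonical low-coverage WGS bias shape;
* negative-binomial counts with variance $\mu + \phi\mu^2$,
  overdispersion $\phi = 0.01$ by default (Poisson at $\phi = 0$), with
  about 5 million reads per sample — the depth regime the score is
  designed for (at ~17,000 reads per 1000-kb bin the 10% overdispersion
  noise dominates Poisson noise);
* segmental SCNA truths: non-overlapping events painted on a diploid
  genome, copy states {1, 3, 4} — pronounced single-copy losses and one-
  to two-copy gains, the amplitude scale of large chromosomal events in
  instable tumors; shallower states would be invisible at this depth and
  would not produce the designed identity between baseline and
  progression patterns;
* tumor-fraction mixing, $\mathrm{mix}_i = (1-\mathrm{tf})\cdot 2 +
  \mathrm{tf}\cdot\mathrm{truth}_i$; longitudinal scenarios share one
  truth per patient and vary only the tumor fraction, so progression
  recapitulates the baseline pattern at its own amplitude.

It does **not** model fragment-size (fragmentomics) signal, mappability
variation, batch effects across sequencing runs, or subclonal mixtures of
distinct truths. Passing tests therefore demonstrate correctness of the
analysis chain under this generative model, not performance on real
plasma.

## Problem sizes

Two genome scales are used, chosen once:

* the **desk-scale default** (`sim_config()`): four pseudo-autosomes
  totalling 300 Mb — 300 bins — with four events of 15–40 bins; the whole
  pipeline runs in seconds, which is what unit tests and cohort-scale
  Monte-Carlo use;
* the **full scale** (`sim_config_fullscale()`): the hg19 autosome grid
  (~2,897 bins) with eight arm-scale events of 40–120 Mb, mirroring
  large-scale gain/loss patterns on about eight chromosomes.

The scales matter for detection power. A single-copy event at tumor
fraction 0.2 shifts $\log_2(x/2)$ by ~0.14 against per-bin noise of ~0.14;
on a 60–90-bin chromosome the CBS max-statistic for such an event sits
near its permutation threshold, so on the desk-scale genome events at
moderate tumor fraction are detected unreliably and baseline/progression
concordance is correspondingly noisy. On the full grid chromosomes are
2–4x longer and the same events are detected consistently; the
baseline-versus-progression concordance analysis is therefore run at full
scale, which is also the scale the method is designed for.

## Known limitations

* The published population constants (the 56.60 cutoff; cohort score means
  such as 67.62 ± 15.99 and 49.88 ± 2.47) depend on the original cohort's
  raw data, which is not deposited; they are treated as inputs, not as
  reproduction targets, and synthetic cohorts calibrate their own cutoff
  on a different numerical scale.
* The score has no attached uncertainty; no confidence interval is
  provided, and tumor-fraction estimation is out of scope.
* The mean-plus-SD cutoff rule guarantees a nontrivial healthy
  false-positive rate (see above); a percentile- or FDR-based rule would
  behave differently but would no longer match the published definition.
* BAM handling is intentionally out of core scope: any (chromosome,
  position) stream can be adapted through `read_positions()`, and binned
  counts enter directly through the TSV reader.
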