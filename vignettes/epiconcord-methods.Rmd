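---
title: "Methods: differential calling and cross-tissue concordance in epiconcord"
author: "epiconcord authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential calling and cross-tissue concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Environmental-exposure studies in mice often profile an easily sampled
surrogate tissue (blood) next to a disease-relevant target tissue
(liver), in both sexes, across several exposures, with a handful of
biological replicates per group (n = 6 here throughout). Three layers
of molecular response are measured: gene expression (RNA-seq counts),
chromatin accessibility (ATAC-seq counts over consensus open-chromatin
regions) and DNA methylation (WGBS per-CpG methylated/unmethylated
read counts). The scientific questions are comparative: how many
differential features does each exposure induce, how much do the
responses of the two sexes agree, and — the surrogate-tissue question —
how often is a feature altered in blood also altered in liver, in the
same direction, and more often than chance would allow?

`epiconcord` implements this analysis end to end as a tested R
package: the differential callers, the comparison statistics, and
seeded simulators that emulate the study design with planted ground
truth so that every stage can be scored for sensitivity and false
discovery rate without any external data.

# The DMR caller

Methylation differences are called on 2x2 contingency tables of pooled
read counts. The genome is tiled into windows of `window_size` = 200 bp
(`window_step` defaults to the window size, so tiles are disjoint and
the multiple-testing units do not overlap; a smaller step is supported
and the merge stage resolves the resulting overlaps). Within each
window, methylated and unmethylated read counts are summed over
replicates and over retained CpGs separately for the control and
exposed groups, and the uncorrected Pearson chi-squared test (1 df)
is applied to the resulting table. Windows with no retained CpG or a
degenerate margin are untestable and excluded from the
Benjamini-Hochberg adjustment, which runs genome-wide per contrast.

A window is significant when all of the following hold:

* BH q strictly below `max_q` = 0.1;
* absolute pooled methylation difference `|delta|` of at least
  `min_delta` = 0.1, where `delta` is computed from pooled counts
  (methylated / total per group), not as a mean of per-replicate
  levels — consistent with the pooled test;
* at least `region_min_cpgs` = 2 retained CpG sites;
* pooled average coverage of at least `region_min_avg_coverage` = 20
  reads per CpG per group.

Sites enter windows only if their pooled per-group coverage reaches
`site_min_coverage` = 20 reads in *both* groups. The pooled (rather
than per-replicate) reading of the coverage rule is deliberate: with
n = 6 replicates at ~10x each, a per-sample 20x rule would discard
nearly everything, while pooled coverage matches the group-level
pooling of the test itself.

Significant windows that overlap or are bookended (gap at most
`merge_max_gap` = 0 bp) and share a direction are merged by transitive
closure, and the merged region's methylation levels, `delta` and CpG
count are recomputed from pooled counts over the whole span. Because
pooling reweights the constituent windows, a merged span can in
principle fall below `min_delta`; such records are dropped so that
every emitted region satisfies all thresholds by construction.
Direction labels: *hyper* means exposed above control.

Two behaviours are intentionally configurable because the procedure
admits more than one reading: the Yates continuity correction (off by
default — the plain chi-squared statistic is the conventional choice
in this caller family) and strand collapsing of CpG dyads at the
reader (off by default; the simulator emits strand-combined records).

# The differential count test

Published DEG/DAR tables for studies of this kind come from the
dedicated count-model packages run on consortium-normalised matrices.
`epiconcord` accepts such tables directly
(`load_external_differential()`), re-applying the significance
thresholds so semantics stay uniform. To make the pipeline runnable
and scoreable with no external inputs it also ships a fully specified
stand-in test (`nb_wald_test()`):

* median-of-ratios size factors (`size_factors()`);
* per feature, normalised group means `m0`, `m1` and
  `log2FC = log2((m1 + c) / (m0 + c))` with pseudocount `c` = 0.5;
* a negative-binomial overdispersion `alpha` estimated by method of
  moments, `(v - m) / m^2`, from the pooled within-group variance and
  grand mean. By default one **common** `alpha` (the mean of the
  per-feature estimates over adequately expressed features) is used
  for all features. At n = 6 + 6 the per-feature estimate is so noisy
  that a normal-reference Wald test built on it rejects ~7% of true
  nulls at the 5% level; pooling the dispersion restores calibration
  (measured type-I 0.050, Kolmogorov-Smirnov distance from uniform
  0.012 on 20,000 null features) while staying far simpler than
  empirical-Bayes shrinkage, which is out of scope. The per-feature
  variant remains available via `diff_params(dispersion_method =
  "per_feature")`;
* delta-method variance of each group's log2 mean,
  `Vg = (1/(mg + c) + alpha) / (ng ln^2 2)`, a two-sided normal Wald
  p-value, and BH adjustment over all tested features. Features with
  zero counts throughout are reported untested.

Thresholds follow the study conventions and are strict on both sides:
expression requires adjusted p < 0.001 and |log2FC| > log2(1.5);
accessibility requires FDR < 0.01 with the same fold-change cutoff.
Boundary values (padj exactly 0.001, |log2FC| exactly log2(1.5)) are
not significant.

# The concordance layer

All comparisons operate on one tidy feature collection — one row per
(exposure, sex, tissue, kind, feature) with its effect size and
significance flag. Matching rules are kind-specific: genes match by
id; accessibility regions by identical coordinates (an overlap mode is
available); methylation regions by at least 1 bp of genomic
intersection, with one pair emitted per intersecting partner.

* **Cross-exposure sharing**: for each significant feature, the number
  of exposures in which it is significant (any direction, and same
  direction in parallel), summarised as fractions at 1, 2, 3, > 3
  exposures.
* **Female-male concordance**: shared features between the sexes, the
  fraction with agreeing signs, and the Pearson correlation of effect
  sizes over shared pairs (Spearman available); the correlation is
  reported missing below 3 shared pairs rather than as a number.
* **Blood-liver concordance**: shared features, direction concordance
  (pairs with a zero effect are excluded and counted separately), the
  effect correlation, and a hypergeometric upper-tail test of whether
  the observed sharing exceeds chance.

The universe N of the hypergeometric test is genuinely underdetermined
in studies of this kind, so it is an explicit policy: the default is
the intersection of the *tested* (not merely significant) feature
universes of the two sides — only features testable in both tissues
can be shared — with a union policy and a user-supplied N available,
and N always reported next to p. Swapping the two sides permutes the
side-specific counts and leaves the shared count and p unchanged.

# The simulators

Every generator is fully determined by one integer seed.

**WGBS.** CpGs are placed as dense island blocks (default: islands
cover 20% of the genome at 10x the background density, mean length
1 kb) on a sparse background, with the overall density matching the
mammalian genome-wide rate of ~1 CpG per 100 bp. Islands carry a low
methylation baseline (mean 0.08) and the background a high one (mean
0.82) — the spatially coherent two-state structure of real
methylomes. The block structure matters for honesty: with
independently drawn per-CpG states, windows mixing low and high CpGs
produce pooled-level artifacts (coverage fluctuations shift the
pooled methylation level between groups) that real, spatially
coherent methylomes do not show. Planted DMRs (default width 600 bp,
|delta| 0.3) are laid alternately aligned to and straddling the
200-bp window grid, so merging across window boundaries is exercised;
hyper-DMRs are seeded on low baselines and hypo-DMRs on high ones so
the full shift has headroom before clipping to [0.02, 0.98]. Coverage
is Poisson (mean 10 reads per CpG per sample) and methylated counts
are beta-binomial with a single overdispersion rho = 0.01 across
replicates — modest biological variability between inbred littermates.

**Counts.** Feature baselines are lognormal (meanlog 4, sdlog 1.5 — a
heavy-tailed mix in which a substantial minority of features is weakly
expressed), counts are negative-binomial with dispersion 0.05, and a
planted fraction (default 5%) of features has its exposed mean
multiplied by `2^log2fc`. Per-sample depth factors (uniform on
[0.7, 1.4]) exercise the normalisation.

**Cross-structure.** Per (exposure, sex), the planted union of
features is assigned to blood-only / liver-only / both at the
configured `tissue_sharing` rate (default 0.05), with sign agreement
between tissues at `same_direction` (default 0.62). An
exposure-shared pool (fraction `exposure_sharing` = 0.4 of each
union, with one fixed assignment) is planted identically in every
exposure and sex; of the remaining features, males inherit a fraction
`sex_sharing` = 0.3 of the female draw *with* the female assignment,
so shared female-male effects correlate as in a paired design. These
semantics make the realised rates match the parameters in
expectation; the realisation of a given seed is recorded in the
ground truth and is the reference the recovery checks compare
against.

The concordance-recovery scenario (`scenario_config()`) combines the
default cross-structure with strong planted count effects (|log2FC| =
2 on high lognormal baselines, meanlog 5, sdlog 1) so the calling
layer runs near saturation and the concordance estimates measure the
comparison layer rather than caller power; its WGBS cells use a
compact 0.5-Mb chromosome with 20 planted DMRs.

# What the tests do and do not show

The simulation is deliberately idealised: no batch effects beyond
per-sample depth, no spatial correlation of replicate noise, no
mapping or conversion artifacts, exchangeable replicates, and a
feature universe identical across tissues. Passing recovery checks
therefore demonstrates the correctness and internal calibration of the
implementation under its own model, not performance on real data.

Two honest findings from the recovery analyses are worth stating
because they reflect the methods, not bugs, and the acceptance script
recomputes both:

* **Interval-level DMR FDR under overdispersion.** With replicate
  overdispersion present (rho = 0.01), the pooled chi-squared test is
  mildly anticonservative — it models binomial noise only — and at
  ~10x per-sample coverage a 2-CpG background window that crosses the
  BH threshold automatically has |delta| > 0.1, so the effect-size
  filter cannot remove it. Merging compounds this at the region
  level: true regions collapse ~3 windows into one record while false
  windows stay singletons. Measured interval-level FDR at the default
  recovery scenario (100 planted DMRs, 6 vs 6, coverage 10) is
  ~0.12-0.17 against a window-level FDR within the BH guarantee, and
  ~0.06 with rho = 0. This anticonservativeness under biological
  replicate variance is precisely the motivation for beta-binomial
  DMR models, which are out of scope here. Sensitivity is 1.0
  throughout.
* **DEG sensitivity under a weakly expressed baseline.** At the DEG
  thresholds (padj < 0.001) with n = 6 and dispersion 0.05, the Wald
  statistic of a 2-fold change asymptotes at z ~ 5.4 even for
  infinitely expressed features, against a BH-realised cutoff of
  z ~ 4.2; power is ~0.88 at best and falls quickly below a
  normalised mean of ~40. Under the default baseline distribution
  (~40% of planted features below mean 40) aggregate sensitivity is
  ~0.55 with observed FDR < 0.01. Detection at these stringent
  thresholds is expression-limited — a caution that transfers
  directly to real designs of this size.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (BED
  convention); 1-based cytosine-report positions are converted at the
  I/O boundary only. Chromosome names are compared as exact strings;
  disjoint name sets raise a warning rather than silent emptiness.
* Interval intersection and merging are backed by `IRanges` /
  `GenomicRanges` (with an all-pairs brute force as the test oracle);
  BH is `stats::p.adjust`, the hypergeometric tail is `stats::phyper`
  computed in log space, correlations are `stats::cor`. The
  window-level chi-squared statistic is computed vectorised in the
  `|ad - bc|` form, algebraically identical to the textbook
  sum((O-E)^2/E).
* Degenerate inputs yield explicit missing values, not zeros: an
  undefined chi-squared table (zero margin) is untestable; a
  correlation over fewer than 3 pairs, or with zero variance, is
  missing; direction concordance of an empty pair set is missing.
* Ties in BH need no special handling (the step-up minimum resolves
  them); significance comparisons are strict (`q < max_q`,
  `padj < max_padj`, `|log2FC| > min_abs_log2fc`) except the
  effect-size floor of the DMR caller, which is inclusive
  (`|delta| >= min_delta`).
* Problem sizes are desk-scale by choice: 1-4 Mb genomes (~10-40k
  CpGs), 10-20k count features, 8 study cells. Every generator scales
  upward through its configuration.

# Limitations

Beyond the simulation idealisations above: the stand-in count test is
not a replacement for the established count-model packages on real
data (no shrinkage, no GLM covariates, no independent filtering); the
DMR caller implements exactly the windowed chi-squared procedure and
none of the smoothing or beta-binomial alternatives; consensus-region
construction, annotation joins, enrichment analysis and plotting are
out of scope. The hypergeometric sharing test inherits whatever
universe policy is chosen — reported p-values should always be read
next to their N.
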