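# epiconcord

Cross-tissue concordance of exposure-induced molecular changes:
differential-feature calling and comparison statistics for multi-omics
toxicant-exposure studies in which an easily sampled surrogate tissue
(blood) is profiled next to a target tissue (liver), in both sexes,
across several exposures, with n = 6 biological replicates per group.

The package implements three layers:

1. **Differential calling.**
   - A sliding-window chi-squared caller for differentially methylated
     regions (DMRs) from Bismark-style per-CpG counts: 200-bp windows,
     pooled per-group 2x2 tables (methylated/unmethylated x
     control/exposed), uncorrected Pearson chi-squared, genome-wide
     Benjamini-Hochberg adjustment, then region filters (q < 0.1,
     |Δβ| ≥ 0.1, ≥ 2 CpGs, ≥ 20x pooled average coverage per group)
     and same-direction merging of neighbouring significant windows.
   - A self-contained negative-binomial Wald test for differential
     expression (DEG: BH-adjusted p < 0.001 and |log2FC| > log2(1.5))
     and accessibility (DAR: FDR < 0.01, same fold-change cutoff) on
     median-of-ratios-normalised counts, plus a pass-through for
     externally computed differential tables.
2. **Concordance statistics.** Cross-exposure sharing profiles,
   female-male concordance (shared features, sign agreement, effect
   correlation), and blood-liver concordance with a hypergeometric
   upper-tail test of sharing, `P(X ≥ s)` for
   `X ~ Hypergeom(N, K, n)`, over an explicit, reported universe N.
   Matching is by gene id (DEG), identical coordinates (DAR) or ≥ 1-bp
   genomic intersection (DMR).
3. **Seeded simulators with ground truth.** WGBS with CpG-island
   block structure and beta-binomial replicate noise, negative-binomial
   count matrices, and a full two-tissue x two-sex x multi-exposure
   scenario whose planted cross-tissue sharing, direction concordance,
   cross-sex and cross-exposure sharing rates are configurable — so
   every caller and every comparison statistic can be scored for
   sensitivity and false discovery rate.

See `vignettes/epiconcord-methods.Rmd` for the full model description,
parameter rationale and known limitations.

## Worked example

Simulate a WGBS contrast with 25 planted DMRs (|Δβ| = 0.3, width
600 bp, 6 vs 6 samples at ~10x) and call DMRs at the default
thresholds:

```r
library(epiconcord)

cfg <- sim_config(seed = 7, chrom_sizes = c(chr1 = 1e6),
                  dmr = list(n = 25L, width = 600L, delta = 0.3,
                             hyper_fraction = 0.5))
w   <- simulate_wgbs(cfg)
res <- call_dmrs(w$cpgs, w$sample_sheet, cfg$chrom_sizes)
res$dmrs[1:3, .(chrom, start, end, direction, n_cpgs,
                delta = round(delta, 3), min_q = signif(min_q, 2))]
#>     chrom start   end direction n_cpgs  delta   min_q
#> 1:   chr1  1000  1800     hyper     42  0.248 6.7e-35
#> 2:   chr1  3800  4200      hypo     20 -0.300 1.7e-34
#> 3:   chr1  6200  7000     hyper     24  0.307 1.1e-35
```

Each row is a merged region: `direction` is the sign of the change in
the exposed group, `n_cpgs` the retained CpGs in the span, `delta` the
pooled methylation difference (exposed − control) and `min_q` the best
BH q among its windows. Scoring against the planted truth
(direction-matched ≥ 1-bp recovery):

```r
unlist(score_dmr_calls(res$dmrs, w$truth))
#> sensitivity         fdr    n_called     n_truth
#>    1.000000    0.137931   29.000000   25.000000
```

All 25 planted DMRs are recovered; 4 of 29 called regions are noise
windows — the measured interval-level FDR of the pooled chi-squared
caller under replicate overdispersion (discussed in the methods
vignette).

The numbered scripts under `analysis/` run the whole study in order —
`01_simulate.R`, `02_call_dmrs.R`, `03_differential.R`,
`04_concordance.R`, `05_report.R` — writing tables under `results/`.
Stage 4 prints, for the default seeded scenario:

```
blood-liver DEG sharing: 3.99% of the union; direction concordance 0.54;
4/4 groups with hypergeometric p <= 0.05
female-male DEG fold-change correlation: 0.98 (weighted over 601 shared pairs)
```

i.e. the pipeline recovers this realisation's planted sharing (4.0%
of the union planted in both tissues) and its planted direction
concordance, flags the sharing as far beyond chance, and reproduces
the paired-design female-male correlation.

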