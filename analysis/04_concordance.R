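#!/usr/bin/env Rscript
# Stage 4 — the comparison layer: cross-exposure sharing, female-male
# concordance and blood-liver (surrogate vs target tissue) concordance,
# with the hypergeometric sharing test over the jointly tested
# universe.

source("analysis/00_config.R")

cfg <- analysis_config()
rep <- run_pipeline(cfg, include_wgbs = TRUE)

fwrite(rep$feature_counts, file.path(RESULTS_DIR, "feature_counts.tsv"),
       sep = "\t")
fwrite(rep$exposure_sharing, file.path(RESULTS_DIR,
                                       "exposure_sharing.tsv"), sep = "\t")
fwrite(rep$sex_concordance, file.path(RESULTS_DIR, "sex_concordance.tsv"),
       sep = "\t")
fwrite(rep$tissue_concordance,
       file.path(RESULTS_DIR, "tissue_concordance.tsv"), sep = "\t")

tc <- rep$tissue_concordance[kind == "DEG"]
sharing <- sum(tc$shared_a) / sum(tc$n_sig_a + tc$n_sig_b - tc$shared_a)
message(sprintf("blood-liver DEG sharing: %.2f%% of the union; direction concordance %.2f; %d/%d groups with hypergeometric p <= 0.05",
                100 * sharing,
                weighted.mean(tc$direction_concordance, tc$n_pairs),
                sum(tc$hyper_p <= 0.05), nrow(tc)))
sx <- rep$sex_concordance[kind == "DEG"]
message(sprintf("female-male DEG fold-change correlation: %.2f (weighted over %d shared pairs)",
                weighted.mean(sx$effect_cor, sx$n_pairs, na.rm = TRUE),
                sum(sx$n_pairs)))
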