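Package: epiconcord
Title: Cross-Tissue Concordance of Exposure-Induced Molecular Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-feature calling and cross-tissue concordance
    analysis for multi-omics toxicant-exposure studies in which an easily
    sampled surrogate tissue (blood) is compared with a target tissue
    (liver). Implements a sliding-window chi-squared caller for
    differentially methylated regions (DMRs) from per-CpG bisulfite
    counts, a self-contained negative-binomial Wald test for differential
    expression and chromatin accessibility, and the cross-exposure,
    cross-sex and cross-tissue sharing, direction-concordance, correlation
    and hypergeometric-enrichment statistics that compare them. Seeded
    generators simulate the full study design (two tissues, two sexes,
    multiple exposures, n = 6 replicates per group) with planted effects
    and ground truth so every stage can be scored for sensitivity and
    false discovery rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
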