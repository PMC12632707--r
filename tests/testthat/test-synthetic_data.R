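test_that("config validation enforces fraction and consistency rules", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, cross = list(exposures = "E1",
                                                 tissue_sharing = 0,
                                                 same_direction = 0.6,
                                                 sex_sharing = 0.3,
                                                 exposure_sharing = 0.4)),
               "inconsistent")
  expect_error(sim_config(seed = 1, rho = 1.2))
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_replicates, 6L)
})

test_that("CpG placement is deterministic and hits the target density", {
  cfg <- sim_config(seed = 33, chrom_sizes = c(chr1 = 1e6),
                    dmr = list(n = 0L, width = 600L, delta = 0.3,
                               hyper_fraction = 0.5))
  cpg1 <- simulate_genome_cpgs(cfg)
  cpg2 <- simulate_genome_cpgs(cfg)
  expect_identical(cpg1, cpg2)
  expect_true(all(diff(cpg1$start) > 0))
  # overall density 1/100 bp on 1 Mb: ~10,000 CpGs within 5%
  expect_lt(abs(nrow(cpg1) - 10000) / 10000, 0.05)
  # islands are denser than background
  expect_gt(mean(cpg1$island), 0.3)
  cfg0 <- cfg; cfg0$cpg_density <- 0
  expect_error(simulate_genome_cpgs(cfg0), "positive")
  cfg_sparse <- sim_config(seed = 33, cpg_density = 1e-4,
                           dmr = list(n = 5L, width = 600L, delta = 0.3,
                                      hyper_fraction = 0.5))
  expect_error(simulate_genome_cpgs(cfg_sparse), "< 2 CpGs")
})

test_that("WGBS simulation matches its configured coverage and shift", {
  cfg <- sim_config(seed = 44, chrom_sizes = c(chr1 = 5e5),
                    dmr = list(n = 12L, width = 600L, delta = 0.3,
                               hyper_fraction = 0.5))
  w <- simulate_wgbs(cfg)
  expect_equal(nrow(w$truth), 12)
  expect_setequal(unique(w$sample_sheet$group), c("control", "exposed"))
  # empirical mean coverage within 2% of the Poisson mean
  cov <- w$cpgs$meth + w$cpgs$unmeth
  expect_lt(abs(mean(cov) - cfg$coverage_mean) / cfg$coverage_mean, 0.02)
  # inside planted hyper-DMRs the pooled beta difference sits near +0.3
  pooled <- filter_sites(w$cpgs, w$sample_sheet,
                         dmr_params(site_min_coverage = 0))
  hits <- intersect_regions(pooled[, .(chrom, start, end = start + 1L)],
                            w$truth[direction == "hyper"])
  ins <- pooled[unique(hits$query)]
  delta <- sum(ins$meth_exposed) / sum(ins$cov_exposed) -
    sum(ins$meth_control) / sum(ins$cov_control)
  expect_lt(abs(delta - 0.3), 0.05)
  # no planted effect leaves an empty truth table
  cfg0 <- sim_config(seed = 44, dmr = list(n = 0L, width = 600L,
                                           delta = 0.3,
                                           hyper_fraction = 0.5))
  expect_equal(nrow(simulate_wgbs(cfg0)$truth), 0)
})

test_that("written cytosine reports are valid reader input", {
  cfg <- sim_config(seed = 55, chrom_sizes = c(chr1 = 5e4),
                    dmr = list(n = 2L, width = 600L, delta = 0.3,
                               hyper_fraction = 0.5))
  dir <- withr::local_tempdir()
  w <- simulate_wgbs(cfg, write_dir = dir)
  files <- list.files(dir, pattern = "cytosine_report", full.names = TRUE)
  expect_equal(length(files), 12)
  back <- read_cytosine_report(files[1], sample = w$sample_sheet$sample[1])
  orig <- w$cpgs[sample == w$sample_sheet$sample[1],
                 .(chrom, start, strand, meth, unmeth)]
  expect_equal(as.data.frame(back[, .(chrom, start, meth, unmeth)]),
               as.data.frame(orig[, .(chrom, start, meth, unmeth)]))
  truth_bed <- read_bed(file.path(dir, "truth_dmrs.bed"))
  expect_equal(nrow(truth_bed), 2)
})

test_that("count simulation is deterministic with calibrated fold changes", {
  cfg <- sim_config(seed = 66)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_equal(nrow(s1$truth), 500)

  # planted 2-fold changes: empirical mean ratio for well-expressed
  # features within [1.8, 2.2]
  y <- sweep(s1$matrix, 2, s1$sf_true, "/")
  m0 <- rowMeans(y[, s1$groups == "control"])
  m1 <- rowMeans(y[, s1$groups == "exposed"])
  up <- s1$truth[log2fc > 0]$feature
  up <- up[m0[up] >= 50]
  expect_gt(length(up), 20)
  ratios <- m1[up] / m0[up]
  expect_true(mean(ratios) > 1.8 && mean(ratios) < 2.2)

  cfg0 <- sim_config(seed = 66)
  cfg0$counts$planted_fraction <- 0
  expect_equal(nrow(simulate_counts(cfg0)$truth), 0)
})

test_that("cross-tissue scenarios honour their sharing structure", {
  cfg <- scenario_config(9)
  sc <- simulate_cross_tissue_scenario(cfg, include_wgbs = FALSE)
  a <- sc$assignment$DEG
  # planted union per (exposure, sex) cell pair is the configured count
  expect_equal(unname(unlist(a[, .N, by = .(exposure, sex)][, "N"])),
               rep(round(cfg$counts$n_features *
                           cfg$counts$planted_fraction), 4))
  # realised tissue sharing within 2 binomial SE of the configured rate
  p <- cfg$cross$tissue_sharing
  se <- sqrt(p * (1 - p) / nrow(a))
  expect_lt(abs(mean(a$tissues == "both") - p), 2 * se)

  # zero sharing plants nothing in both tissues (and needs no
  # direction-concordance parameter)
  cfg0 <- scenario_config(9)
  cfg0$cross$tissue_sharing <- 0
  cfg0$cross$same_direction <- NA
  sc0 <- simulate_cross_tissue_scenario(cfg0, include_wgbs = FALSE)
  expect_equal(sum(sc0$assignment$DEG$tissues == "both"), 0)

  # full direction agreement when same_direction = 1
  cfg1 <- scenario_config(9)
  cfg1$cross$same_direction <- 1
  sc1 <- simulate_cross_tissue_scenario(cfg1, include_wgbs = FALSE)
  a1 <- sc1$assignment$DEG
  expect_true(all(sign(a1$effect_liver) == sign(a1$effect_blood)))
})

test_that("ground truth keys join losslessly to generated features", {
  cfg <- scenario_config(12)
  sc <- simulate_cross_tissue_scenario(cfg, include_wgbs = TRUE)
  cell <- sc$cells[["blood.F.E1"]]
  # count truth features exist in the matrix
  expect_true(all(cell$deg$truth$feature %in% rownames(cell$deg$matrix)))
  expect_true(all(cell$dar$truth$feature %in% rownames(cell$dar$matrix)))
  # planted DMRs contain retained CpGs
  pooled <- filter_sites(cell$wgbs$cpgs, cell$wgbs$sample_sheet,
                         dmr_params())
  hits <- intersect_regions(cell$wgbs$truth,
                            pooled[, .(chrom, start, end = start + 1L)])
  expect_setequal(unique(hits$query), seq_len(nrow(cell$wgbs$truth)))
})
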