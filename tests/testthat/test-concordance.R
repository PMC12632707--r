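test_that("cross-tissue matching follows the kind-specific rules", {
  blood <- toy_diff_table(c("A", "B", "C"), c(1, -2, 0.5))
  liver <- toy_diff_table(c("B", "C", "D"), c(1, 2, -1), tissue = "liver")
  pairs <- cross_tissue_match(blood, liver, "DEG")
  expect_equal(pairs$feature_a, c("B", "C"))

  # DMRs: 1-bp intersection suffices
  bd <- toy_diff_table("chr1:100-300", 0.2, kind = "DMR")
  ld <- toy_diff_table(c("chr1:299-400", "chr1:300-400"), c(0.2, 0.2),
                       kind = "DMR", tissue = "liver")
  pd <- cross_tissue_match(bd, ld, "DMR")
  expect_equal(pd$feature_b, "chr1:299-400")

  # DARs: exact coordinates by default, overlap mode optional
  ba <- toy_diff_table("chr1:0-200", 1, kind = "DAR")
  la <- toy_diff_table("chr1:0-201", 1, kind = "DAR", tissue = "liver")
  expect_equal(nrow(cross_tissue_match(ba, la, "DAR")), 0)
  expect_equal(nrow(cross_tissue_match(ba, la, "DAR",
                                       dar_mode = "overlap")), 1)

  # non-significant rows never match
  liver$significant[1] <- FALSE
  expect_equal(cross_tissue_match(blood, liver, "DEG")$feature_a, "C")

  # a DMR intersecting two partners yields two pairs
  ld2 <- toy_diff_table(c("chr1:50-150", "chr1:200-250"), c(0.3, -0.3),
                        kind = "DMR", tissue = "liver")
  expect_equal(nrow(cross_tissue_match(bd, ld2, "DMR")), 2)
})

test_that("direction concordance handles zeros and empty input", {
  pairs <- data.frame(effect_a = c(1, 2, -3), effect_b = c(2, -1, -4))
  dc <- direction_concordance(pairs)
  expect_equal(dc$concordance, 2 / 3)
  expect_equal(direction_concordance(
    data.frame(effect_a = c(1, 1), effect_b = c(2, 3)))$concordance, 1)
  empty <- direction_concordance(pairs[0, ])
  expect_true(is.na(empty$concordance))
  withz <- direction_concordance(
    data.frame(effect_a = c(0, 1), effect_b = c(1, 1)))
  expect_equal(withz$n_zero, 1L)
  expect_equal(withz$concordance, 1)
})

test_that("hypergeometric sharing test resolves universes", {
  a <- toy_diff_table(paste0("g", 1:10), 1, significant = c(rep(TRUE, 5),
                                                            rep(FALSE, 5)))
  b <- toy_diff_table(paste0("g", 1:10), 1, tissue = "liver",
                      significant = c(rep(FALSE, 5), rep(TRUE, 5)))
  res <- cross_tissue_sharing_test(a, b)
  expect_equal(res$N, 10)
  expect_equal(res$s, 0)
  expect_equal(res$p, 1)

  b2 <- toy_diff_table(paste0("g", 1:10), 1, tissue = "liver",
                       significant = c(rep(TRUE, 5), rep(FALSE, 5)))
  res2 <- cross_tissue_sharing_test(a, b2)
  expect_equal(res2$s, 5)
  expect_equal(res2$p, 1 / 252)

  # K = N forces containment
  ball <- toy_diff_table(paste0("g", 1:10), 1, tissue = "liver")
  resf <- cross_tissue_sharing_test(a, ball)
  expect_equal(resf$p, 1)

  # numeric universe and containment errors
  resn <- cross_tissue_sharing_test(a, b2, universe = 40)
  expect_equal(resn$N, 40)
  expect_error(cross_tissue_sharing_test(a, b2, universe = paste0("g", 6:10)),
               "universe")
})

test_that("sex concordance reports sharing, correlation and missingness", {
  f <- toy_diff_table(c("A", "B"), c(1, 2), sex = "F")
  m <- toy_diff_table(c("B", "C"), c(3, 1), sex = "M")
  rep1 <- sex_concordance(rbind(f, m), "E1", "blood", "DEG")
  expect_equal(rep1$shared_a, 1)
  expect_true(is.na(rep1$effect_cor))  # < 3 shared pairs

  f3 <- toy_diff_table(c("A", "B", "C"), c(1, 2, 3), sex = "F")
  m3 <- toy_diff_table(c("A", "B", "C"), c(2, 4, 6), sex = "M")
  rep2 <- sex_concordance(rbind(f3, m3), "E1", "blood", "DEG")
  expect_equal(rep2$effect_cor, 1)
  expect_equal(rep2$direction_concordance, 1)
  m3$effect <- -m3$effect
  rep3 <- sex_concordance(rbind(f3, m3), "E1", "blood", "DEG")
  expect_equal(rep3$effect_cor, -1)
  expect_equal(rep3$direction_concordance, 0)
})

test_that("exposure sharing profiles count any- and same-direction sharing", {
  tabs <- rbind(
    toy_diff_table(c("A", "B"), c(1, 1), exposure = "BPA"),
    toy_diff_table(c("B", "C"), c(-1, 1), exposure = "TBT"),
    toy_diff_table("D", 1, exposure = "PM"))
  prof <- exposure_sharing_profile(tabs, "F", "blood", "DEG")
  per <- prof$per_feature
  expect_equal(per[per$feature == "B", ]$n_exposures_any, c(2L, 2L))
  expect_equal(per[per$feature == "B", ]$n_exposures_same_dir, c(1L, 1L))
  expect_equal(per[per$feature == "A", ]$n_exposures_any, 1L)
  expect_equal(prof$summary$fraction_shared, 2 / 5)
  expect_true(all(per$n_exposures_same_dir <= per$n_exposures_any))

  # disjoint sets across exposures share nothing
  dis <- rbind(toy_diff_table("A", 1, exposure = "E1"),
               toy_diff_table("B", 1, exposure = "E2"),
               toy_diff_table("C", 1, exposure = "E3"))
  expect_equal(exposure_sharing_profile(dis, "F", "blood",
                                        "DEG")$summary$fraction_shared, 0)

  expect_error(exposure_sharing_profile(toy_diff_table("A", 1), "F",
                                        "blood", "DEG"),
               "at least 2 exposures")
})

test_that("exposure sharing of DMRs uses interval intersection", {
  tabs <- rbind(
    toy_diff_table("chr1:100-300", 0.3, exposure = "E1", kind = "DMR"),
    toy_diff_table("chr1:250-400", 0.3, exposure = "E2", kind = "DMR"),
    toy_diff_table("chr2:0-200", -0.3, exposure = "E2", kind = "DMR"))
  prof <- exposure_sharing_profile(tabs, "F", "blood", "DMR")
  per <- prof$per_feature
  expect_equal(per[per$feature == "chr1:100-300", ]$n_exposures_any, 2L)
  expect_equal(per[per$feature == "chr2:0-200", ]$n_exposures_any, 1L)
  expect_equal(prof$summary$fraction_shared, 2 / 3)
})

test_that("tissue concordance is symmetric under side swapping", {
  set.seed(3)
  cl <- rbind(
    toy_diff_table(paste0("g", 1:50), rnorm(50), tissue = "blood",
                   significant = c(rep(TRUE, 20), rep(FALSE, 30))),
    toy_diff_table(paste0("g", 1:50), rnorm(50), tissue = "liver",
                   significant = c(rep(FALSE, 10), rep(TRUE, 20),
                                   rep(FALSE, 20))))
  ab <- tissue_concordance(cl, "E1", "F", "DEG")
  ba <- tissue_concordance(cl, "E1", "F", "DEG",
                           tissue_a = "liver", tissue_b = "blood")
  expect_equal(ab$shared_a, ba$shared_b)
  expect_equal(ab$n_sig_a, ba$n_sig_b)
  expect_equal(ab$a_only, ba$b_only)
  expect_equal(ab$hyper_p, ba$hyper_p)
  expect_equal(ab$universe_N, ba$universe_N)
  expect_equal(ab$direction_concordance, ba$direction_concordance)
})

test_that("region-set annotation counts each feature once", {
  feats <- data.frame(feature = c("chr1:0-100", "chr1:500-700",
                                  "chr2:0-50"))
  regions <- data.frame(chrom = c("chr1", "chr1"),
                        start = c(50L, 600L), end = c(80L, 650L))
  ann <- region_set_annotation(feats, regions)
  expect_equal(ann$flags, c(TRUE, TRUE, FALSE))
  expect_equal(ann$n_overlapping, 2)
  # overlapping two regions still counts once
  feat2 <- data.frame(chrom = "chr1", start = 0L, end = 700L)
  expect_equal(region_set_annotation(feat2, regions)$n_overlapping, 1)
  expect_equal(region_set_annotation(feats, regions[0, ])$n_overlapping, 0)
})

test_that("feature collections validate keys and kinds", {
  good <- toy_diff_table(c("A", "B"), c(1, 2))
  expect_silent(feature_collection(good))
  expect_error(feature_collection(rbind(good, good)), "duplicate")
  bad <- good; bad$kind <- "XXX"
  expect_error(feature_collection(bad), "kind")
  badiv <- toy_diff_table("not-an-interval", 1, kind = "DMR")
  expect_error(feature_collection(badiv), "malformed")
})
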