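test_that("genome tiling clips terminal windows and supports overlap", {
  p <- dmr_params(window_size = 200, window_step = 200)
  w <- tile_genome(c(chr1 = 500), p)
  expect_equal(w$start, c(0L, 200L, 400L))
  expect_equal(w$end, c(200L, 400L, 500L))

  p2 <- dmr_params(window_size = 200, window_step = 100)
  w2 <- tile_genome(c(chr1 = 500), p2)
  expect_equal(w2$start, c(0L, 100L, 200L, 300L, 400L))
  expect_equal(w2$end, c(200L, 300L, 400L, 500L, 500L))

  expect_warning(w3 <- tile_genome(c(chr1 = 500, chr0 = 0), p),
                 "non-positive")
  expect_equal(nrow(w3), 3)
  expect_error(dmr_params(window_step = 300))  # step > size
})

test_that("site filter applies the pooled per-group coverage rule", {
  sites <- data.frame(chrom = "chr1", start = c(10L, 20L, 30L),
                      meth_control = c(10L, 10L, 5L),
                      unmeth_control = c(15L, 15L, 5L),
                      meth_exposed = c(12L, 9L, 40L),
                      unmeth_exposed = c(10L, 10L, 40L))
  cpgs <- toy_cpgs(sites, n_rep = 2)
  kept <- filter_sites(cpgs, toy_sample_sheet(2), dmr_params())
  # site 1: 25/22 kept; site 2: 25/19 dropped; site 3: 10/80 dropped
  expect_equal(kept$start, 10L)
  kept0 <- filter_sites(cpgs, toy_sample_sheet(2),
                        dmr_params(site_min_coverage = 0))
  expect_equal(nrow(kept0), 3)
  expect_error(filter_sites(cpgs, data.frame(sample = unique(cpgs$sample),
                                             group = "control")),
               "exposed")
})

test_that("window scoring pools counts into the 2x2 test", {
  # one window holding the worked 2x2 example: control 60/140,
  # exposed 120/80 split over two CpGs
  sites <- data.frame(chrom = "chr1", start = c(50L, 150L),
                      meth_control = c(30L, 30L),
                      unmeth_control = c(70L, 70L),
                      meth_exposed = c(60L, 60L),
                      unmeth_exposed = c(40L, 40L))
  cpgs <- toy_cpgs(sites)
  pooled <- filter_sites(cpgs, toy_sample_sheet(), dmr_params())
  stat <- score_windows(pooled, tile_genome(c(chr1 = 200), dmr_params()))
  expect_equal(stat$n_cpgs, 2L)
  expect_equal(stat$beta_control, 0.3)
  expect_equal(stat$beta_exposed, 0.6)
  expect_equal(stat$delta, 0.3)
  expect_equal(stat$chi2, 36.3636, tolerance = 1e-4)
  expect_equal(stat$avg_cov_control, 100)

  # identical pooled counts: delta 0, chi2 0, p 1
  sites$meth_exposed <- sites$meth_control
  sites$unmeth_exposed <- sites$unmeth_control
  pooled2 <- filter_sites(toy_cpgs(sites), toy_sample_sheet(),
                          dmr_params())
  stat2 <- score_windows(pooled2, tile_genome(c(chr1 = 200), dmr_params()))
  expect_equal(stat2$delta, 0)
  expect_equal(stat2$chi2, 0)
  expect_equal(stat2$p, 1)

  # a window with no retained CpGs is untestable
  stat3 <- score_windows(pooled, tile_genome(c(chr1 = 400), dmr_params()))
  expect_true(is.na(stat3$p[2]))
  expect_equal(stat3$n_cpgs[2], 0L)
})

test_that("adjacent significant windows merge by direction", {
  base <- data.frame(chrom = "chr1",
                     start = c(50L, 150L, 250L, 350L),
                     meth_control = 60L, unmeth_control = 140L,
                     meth_exposed = 120L, unmeth_exposed = 80L)
  res <- call_dmrs(toy_cpgs(base), toy_sample_sheet(), c(chr1 = 400))
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(c(res$dmrs$start, res$dmrs$end), c(0L, 400L))
  expect_equal(res$dmrs$direction, "hyper")
  expect_equal(res$dmrs$n_cpgs, 4L)
  expect_equal(res$dmrs$delta, 0.3)
  expect_equal(res$dmrs$n_windows, 2L)

  # second window flipped to hypo: two separate records
  flip <- base
  flip[3:4, c("meth_control", "meth_exposed")] <-
    flip[3:4, c("meth_exposed", "meth_control")]
  flip[3:4, c("unmeth_control", "unmeth_exposed")] <-
    flip[3:4, c("unmeth_exposed", "unmeth_control")]
  res2 <- call_dmrs(toy_cpgs(flip), toy_sample_sheet(), c(chr1 = 400))
  expect_equal(nrow(res2$dmrs), 2)
  expect_equal(res2$dmrs$direction, c("hyper", "hypo"))
})

test_that("called DMRs satisfy every region threshold by construction", {
  cfg <- sim_config(seed = 77, chrom_sizes = c(chr1 = 4e5),
                    dmr = list(n = 10L, width = 600L, delta = 0.25,
                               hyper_fraction = 0.5))
  w <- simulate_wgbs(cfg)
  par <- dmr_params()
  res <- call_dmrs(w$cpgs, w$sample_sheet, cfg$chrom_sizes, par)
  expect_gt(nrow(res$dmrs), 0)
  expect_true(all(abs(res$dmrs$delta) >= par$min_delta))
  expect_true(all(res$dmrs$n_cpgs >= par$region_min_cpgs))
  expect_true(all(res$dmrs$min_q < par$max_q))
  expect_true(all((res$dmrs$delta > 0) == (res$dmrs$direction == "hyper")))
  # sorted and pairwise non-overlapping
  d <- res$dmrs
  expect_true(all(d$start[-1] >= d$end[-nrow(d)] | d$chrom[-1] !=
                    d$chrom[-nrow(d)]))
  # significant windows all pass the per-window predicate
  sig <- res$windows[significant == TRUE]
  expect_true(all(sig$q < par$max_q & abs(sig$delta) >= par$min_delta &
                    sig$n_cpgs >= par$region_min_cpgs &
                    sig$avg_cov_control >= par$region_min_avg_coverage &
                    sig$avg_cov_exposed >= par$region_min_avg_coverage))
})

test_that("calls are invariant to record and replicate order", {
  cfg <- sim_config(seed = 123, chrom_sizes = c(chr1 = 3e5),
                    dmr = list(n = 5L, width = 600L, delta = 0.3,
                               hyper_fraction = 0.5))
  w <- simulate_wgbs(cfg)
  res1 <- call_dmrs(w$cpgs, w$sample_sheet, cfg$chrom_sizes)
  set.seed(1)
  shuffled <- w$cpgs[sample(.N)]
  sheet <- w$sample_sheet[sample(nrow(w$sample_sheet))]
  res2 <- call_dmrs(shuffled, sheet, cfg$chrom_sizes)
  expect_equal(res1$dmrs, res2$dmrs)
  expect_equal(res1$windows, res2$windows)
})

test_that("threshold comparisons are strict for q and inclusive for delta", {
  # single-window contrast whose q equals its p; rerunning with max_q
  # set to the realised q must exclude it (strict <), while min_delta
  # set to the realised |delta| must keep it (inclusive >=)
  sites <- data.frame(chrom = "chr1", start = c(50L, 150L),
                      meth_control = c(30L, 30L),
                      unmeth_control = c(70L, 70L),
                      meth_exposed = c(60L, 60L),
                      unmeth_exposed = c(40L, 40L))
  cpgs <- toy_cpgs(sites)
  res <- call_dmrs(cpgs, toy_sample_sheet(), c(chr1 = 200))
  q <- res$windows$q[1]
  delta <- res$windows$delta[1]
  expect_equal(nrow(res$dmrs), 1)
  at_q <- call_dmrs(cpgs, toy_sample_sheet(), c(chr1 = 200),
                    dmr_params(max_q = q))
  expect_equal(nrow(at_q$dmrs), 0)
  at_delta <- call_dmrs(cpgs, toy_sample_sheet(), c(chr1 = 200),
                        dmr_params(min_delta = abs(delta)))
  expect_equal(nrow(at_delta$dmrs), 1)
})

test_that("a contrast with no testable windows warns and returns empty", {
  sites <- data.frame(chrom = "chr1", start = 50L,
                      meth_control = 2L, unmeth_control = 3L,
                      meth_exposed = 2L, unmeth_exposed = 3L)
  expect_warning(
    res <- call_dmrs(toy_cpgs(sites), toy_sample_sheet(), c(chr1 = 200)),
    "no testable")
  expect_equal(nrow(res$dmrs), 0)
})

test_that("DMR BED export writes direction, score and betas", {
  base <- data.frame(chrom = "chr1", start = c(50L, 150L),
                     meth_control = 60L, unmeth_control = 140L,
                     meth_exposed = 120L, unmeth_exposed = 80L)
  res <- call_dmrs(toy_cpgs(base), toy_sample_sheet(), c(chr1 = 200))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(res$dmrs, f, params = list(max_q = 0.1))
  line <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(line[1:4], c("chr1", "0", "200", "hyper"))
  expect_equal(as.numeric(line[10]), 0.3)
})
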