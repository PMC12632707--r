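#' Simulation configuration
#'
#' One structured object drives every generator. Defaults emulate the
#' design of a multi-tissue toxicant-exposure study in inbred mice:
#' n = 6 biological replicates per group, two sexes, two tissues,
#' two or more exposures; WGBS-style per-CpG counts with beta-binomial
#' replicate noise and planted differentially methylated regions; and
#' negative-binomial count matrices (expression and accessibility) with
#' planted fold changes shared across tissues, sexes and exposures at
#' configurable rates.
#'
#' @param seed Integer seed; mandatory, and every realisation is fully
#'   determined by it.
#' @param n_replicates Biological replicates per group (default 6).
#' @param chrom_sizes Named vector of chromosome lengths for the WGBS
#'   simulation (default one 1-Mb chromosome; desk scale).
#' @param cpg_density Overall expected CpGs per bp (default 0.01, one
#'   CpG per 100 bp, the mammalian genome-wide rate). CpGs are placed
#'   non-uniformly: dense island blocks on a sparse background, see
#'   `islands`.
#' @param islands CpG-island structure: `fraction` of the genome
#'   covered by islands, `density_ratio` (island CpG density relative
#'   to background) and `mean_len` (island length, bp). The background
#'   density is derived so the overall density matches `cpg_density`.
#'   Islands carry the low-methylation baseline, the background the
#'   high one, giving the spatially coherent methylation state of real
#'   methylomes.
#' @param coverage_mean Mean reads per CpG per sample (Poisson;
#'   default 10, so pooled group coverage ~60 at n = 6).
#' @param meth_baseline Baseline methylation levels: island CpGs sit at
#'   `low_mean`, background CpGs at `high_mean`, with per-CpG Gaussian
#'   `spread`.
#' @param rho Beta-binomial overdispersion of methylation across
#'   replicates (default 0.01, modest biological variability between
#'   inbred littermates).
#' @param dmr Planted-DMR spec: `n`, `width` (bp), `delta` (absolute
#'   methylation shift), `hyper_fraction`.
#' @param counts Count-matrix spec: `n_features`, lognormal baseline
#'   mean parameters `meanlog`/`sdlog`, NB `dispersion`,
#'   `planted_fraction`, `log2fc` (absolute), `up_fraction`, and
#'   `depth_range` for per-sample depth factors (set to `c(1, 1)` to
#'   disable).
#' @param cross Cross-structure spec: `exposures` (labels),
#'   `tissue_sharing` (fraction of planted features present in both
#'   tissues), `same_direction` (fraction of tissue-shared features
#'   with equal sign), `sex_sharing`, `exposure_sharing` (fraction of a
#'   cell's planted features drawn from an exposure-shared pool).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_replicates = 6L,
                       chrom_sizes = c(chr1 = 1e6),
                       cpg_density = 0.01,
                       islands = list(fraction = 0.2, density_ratio = 10,
                                      mean_len = 1000),
                       coverage_mean = 10,
                       meth_baseline = list(low_mean = 0.08,
                                            high_mean = 0.82,
                                            spread = 0.03),
                       rho = 0.01,
                       dmr = list(n = 50L, width = 600L, delta = 0.3,
                                  hyper_fraction = 0.5),
                       counts = list(n_features = 10000L, meanlog = 4,
                                     sdlog = 1.5, dispersion = 0.05,
                                     planted_fraction = 0.05, log2fc = 1,
                                     up_fraction = 0.5,
                                     depth_range = c(0.7, 1.4)),
                       cross = list(exposures = c("E1", "E2"),
                                    tissue_sharing = 0.05,
                                    same_direction = 0.62,
                                    sex_sharing = 0.3,
                                    exposure_sharing = 0.4)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(seed == round(seed), seed >= 0, seed < 2^30,
            n_replicates >= 2, all(chrom_sizes > 0), cpg_density >= 0,
            islands$fraction >= 0, islands$fraction < 1,
            islands$density_ratio >= 1, islands$mean_len > 0,
            coverage_mean > 0, rho >= 0, rho < 1,
            dmr$n >= 0, dmr$width > 0, dmr$delta > 0, dmr$delta <= 1,
            dmr$hyper_fraction >= 0, dmr$hyper_fraction <= 1,
            counts$n_features > 0, counts$dispersion > 0,
                counts$planted_fraction >= 0, counts$planted_fraction <= 1,
            counts$up_fraction >= 0, counts$up_fraction <= 1,
            length(cross$exposures) >= 1,
            cross$tissue_sharing >= 0, cross$tissue_sharing <= 1,
            cross$sex_sharing >= 0, cross$sex_sharing <= 1,
            cross$exposure_sharing >= 0, cross$exposure_sharing <= 1)
  if (!is.na(cross$same_direction)) {
    stopifnot(cross$same_direction >= 0, cross$same_direction <= 1)
    if (cross$tissue_sharing == 0 && cross$same_direction > 0) {
      stop("same_direction specified with zero tissue sharing is ",
           "inconsistent")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 chrom_sizes = chrom_sizes, cpg_density = cpg_density,
                 islands = islands, coverage_mean = coverage_mean,
                 meth_baseline = meth_baseline, rho = rho, dmr = dmr,
                 counts = counts, cross = cross),
            class = "sim_config")
}

# island intervals + CpG positions without touching the RNG seed
# (callers manage seeding); `dense` intervals (planted DMRs) get
# island-level CpG density regardless of island status
.sim_cpg_positions <- function(config, dense = NULL) {
  if (config$cpg_density <= 0) stop("cpg_density must be positive")
  isl <- config$islands
  # overall = bg * (1 - f + f * ratio)
  bg_density <- config$cpg_density / (1 - isl$fraction +
                                        isl$fraction * isl$density_ratio)
  isl_density <- bg_density * isl$density_ratio
  if (config$dmr$n > 0 && isl_density * config$dmr$width < 2) {
    stop("CpG density too low: a planted DMR of width ", config$dmr$width,
         " bp would contain < 2 CpGs in expectation")
  }
  draw <- function(ch, from, to, density) {
    n <- stats::rbinom(1, max(0L, to - from), density)
    if (n == 0) return(NULL)
    data.table::data.table(
      chrom = ch, start = from + sort(sample.int(to - from, n)) - 1L)
  }
  islands <- list(); cpgs <- list()
  for (ch in names(config$chrom_sizes)) {
    len <- as.integer(config$chrom_sizes[[ch]])
    n_isl <- round(len * isl$fraction / isl$mean_len)
    if (n_isl > 0) {
      ist <- sort(sample.int(max(1L, len - as.integer(isl$mean_len)),
                             n_isl))
      iw <- pmax(200L, as.integer(round(stats::rexp(n_isl,
                                                    1 / isl$mean_len))))
      it <- data.table::data.table(chrom = ch, start = ist - 1L,
                                   end = pmin(ist - 1L + iw, len))
      it <- merge_regions(it, require_same_direction = FALSE)[
        , .(chrom, start, end)]
      islands[[ch]] <- it
    } else {
      it <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
    }
    cpgs[[paste0(ch, ".bg")]] <- draw(ch, 0L, len, bg_density)
    for (j in seq_len(nrow(it))) {
      cpgs[[paste0(ch, ".isl", j)]] <-
        draw(ch, it$start[j], it$end[j], isl_density - bg_density)
    }
  }
  islands <- data.table::rbindlist(islands)
  if (!is.null(dense) && nrow(dense)) {
    for (j in seq_len(nrow(dense))) {
      cpgs[[paste0("dense", j)]] <-
        draw(dense$chrom[j], dense$start[j], dense$end[j],
             isl_density - bg_density)
    }
  }
  out <- unique(data.table::rbindlist(cpgs))
  data.table::setkey(out, chrom, start)
  in_isl <- rep(FALSE, nrow(out))
  if (nrow(islands)) {
    hits <- intersect_regions(out[, .(chrom, start, end = start + 1L)],
                              islands)
    in_isl[unique(hits$query)] <- TRUE
  }
  out[, island := in_isl]
  out[]
}

#' Simulate CpG positions
#'
#' Clustered CpG placement: dense island blocks (low-methylation
#' baseline) on a sparse high-methylation background, with the overall
#' density matching `cpg_density`. Positions are strictly increasing
#' within each chromosome.
#'
#' @param config A [sim_config()].
#' @return `data.table` with `chrom`, 0-based `start` and an `island`
#'   flag.
#' @export
simulate_genome_cpgs <- function(config) {
  set.seed(config$seed)
  .sim_cpg_positions(config)
}

# non-overlapping planted DMR intervals, alternately aligned to the
# 200-bp window grid and straddling it, so merging across window
# boundaries is exercised
.plant_dmr_intervals <- function(config, window = 200L, buffer = 2000L) {
  n <- config$dmr$n
  if (n == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), direction = character(),
                                  delta = numeric()))
  }
  w <- as.integer(config$dmr$width)
  slot <- w + buffer
  chroms <- names(config$chrom_sizes)
  avail <- floor((unlist(config$chrom_sizes) - buffer) / slot)
  if (sum(avail) < n) {
    stop("genome too small for ", n, " planted DMRs of width ", w)
  }
  per <- pmin(avail, ceiling(n * avail / sum(avail)))
  while (sum(per) > n) per[which.max(per)] <- per[which.max(per)] - 1L
  res <- list()
  k <- 0L
  for (i in seq_along(chroms)) {
    if (per[i] == 0) next
    starts <- buffer %/% 2L + slot * (seq_len(per[i]) - 1L)
    aligned <- (k + seq_len(per[i])) %% 2L == 0L
    starts <- as.integer((starts %/% window) * window +
                           ifelse(aligned, 0L, window %/% 2L))
    res[[i]] <- data.table::data.table(chrom = chroms[i], start = starts,
                                       end = starts + w)
    k <- k + per[i]
  }
  out <- data.table::rbindlist(res)
  nh <- round(nrow(out) * config$dmr$hyper_fraction)
  dir <- sample(rep(c("hyper", "hypo"),
                    c(nh, nrow(out) - nh)))
  out[, direction := dir]
  out[, delta := data.table::fifelse(direction == "hyper",
                                     config$dmr$delta, -config$dmr$delta)]
  out[]
}

#' Simulate a WGBS experiment with planted DMRs
#'
#' Per CpG per sample, coverage is Poisson around the configured mean
#' and the methylated count is beta-binomial around the site's
#' group-level methylation: a low/high baseline mixture, shifted by the
#' planted delta inside DMR intervals (hyper-DMRs are seeded on
#' low-methylation baselines and hypo-DMRs on high ones, so the full
#' shift has headroom) and clipped to [0.02, 0.98].
#'
#' @param config A [sim_config()].
#' @param write_dir If non-`NULL`, cytosine reports (one per sample)
#'   and a sample sheet are written there.
#' @param truth Optional pre-drawn planted-DMR table (`chrom`, `start`,
#'   `end`, `direction`, `delta`); by default intervals are placed by
#'   the internal planter.
#' @return A list: `cpgs` (long per-sample table: `sample`, `chrom`,
#'   `start`, `strand`, `meth`, `unmeth`), `sample_sheet` (`sample`,
#'   `group`), `truth` (planted DMR intervals with `direction` and
#'   `delta`), `site_beta` (per-CpG control/exposed means).
#' @export
simulate_wgbs <- function(config, write_dir = NULL, truth = NULL) {
  set.seed(config$seed)
  .sim_wgbs(config, write_dir, truth)
}

.sim_wgbs <- function(config, write_dir = NULL, truth = NULL) {
  if (is.null(truth)) truth <- .plant_dmr_intervals(config)
  cpg <- .sim_cpg_positions(config, dense = truth)
  mb <- config$meth_baseline
  nc <- nrow(cpg)
  # islands are low-methylated, background high; inside planted DMRs
  # the baseline is overridden so the shift has headroom (hyper-DMRs
  # start low, hypo-DMRs start high)
  base <- ifelse(cpg$island,
                 stats::rnorm(nc, mb$low_mean, mb$spread),
                 stats::rnorm(nc, mb$high_mean, mb$spread))
  shift <- rep(0, nc)
  if (nrow(truth)) {
    hits <- intersect_regions(cpg[, .(chrom, start, end = start + 1L)],
                              truth)
    dirs <- truth$direction[hits$subject]
    base[hits$query] <- ifelse(
      dirs == "hyper",
      stats::rnorm(length(hits$query), mb$low_mean, mb$spread),
      stats::rnorm(length(hits$query), mb$high_mean, mb$spread))
    shift[hits$query] <- truth$delta[hits$subject]
  }
  clip <- function(x) pmin(0.98, pmax(0.02, x))
  beta_control <- clip(base)
  beta_exposed <- clip(base + shift)
  nrep <- config$n_replicates
  samples <- c(sprintf("ctrl_%02d", seq_len(nrep)),
               sprintf("expo_%02d", seq_len(nrep)))
  groups <- rep(c("control", "exposed"), each = nrep)
  ns <- length(samples)
  cov <- stats::rpois(nc * ns, config$coverage_mean)
  beta_site <- rep(ifelse(groups == "exposed", 1, 0), each = nc)
  mu <- ifelse(beta_site == 1, rep(beta_exposed, ns), rep(beta_control, ns))
  if (config$rho > 0) {
    a <- mu * (1 - config$rho) / config$rho
    b <- (1 - mu) * (1 - config$rho) / config$rho
    psamp <- stats::rbeta(nc * ns, a, b)
  } else {
    psamp <- mu
  }
  meth <- stats::rbinom(nc * ns, cov, psamp)
  cpgs <- data.table::data.table(
    sample = rep(samples, each = nc),
    chrom = rep(cpg$chrom, ns),
    start = rep(cpg$start, ns),
    strand = "+",
    meth = meth,
    unmeth = cov - meth)
  sample_sheet <- data.table::data.table(sample = samples, group = groups)
  out <- list(cpgs = cpgs, sample_sheet = sample_sheet, truth = truth,
              site_beta = data.table::data.table(
                chrom = cpg$chrom, start = cpg$start,
                beta_control = beta_control, beta_exposed = beta_exposed))
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples) {
      f <- file.path(write_dir, paste0(s, ".cytosine_report.tsv"))
      sub <- cpgs[sample == s,
                  .(chrom, pos = start + 1L, strand, meth, unmeth)]
      data.table::fwrite(sub, f, sep = "\t", col.names = FALSE)
    }
    data.table::fwrite(sample_sheet,
                       file.path(write_dir, "sample_sheet.tsv"), sep = "\t")
    if (nrow(truth)) {
      write_bed(truth[, .(chrom, start, end, name = direction,
                          score = abs(delta), strand = ".")],
                file.path(write_dir, "truth_dmrs.bed"))
    }
  }
  out
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Feature baseline means are lognormal (heavy-tailed); counts are
#' negative-binomial at the configured dispersion; a planted fraction
#' of features has its exposed-group mean multiplied by `2^log2fc`.
#' Per-sample depth factors (uniform over `counts$depth_range`)
#' exercise the normalisation step.
#'
#' @param config A [sim_config()].
#' @param feature_prefix Prefix for feature ids (default `"gene"`).
#' @return A list: `matrix` (features x samples), `groups`, `sf_true`
#'   (the depth factors used), `truth` (`feature`, `log2fc` of planted
#'   features).
#' @export
simulate_counts <- function(config, feature_prefix = "gene") {
  set.seed(config$seed)
  .sim_counts(config, feature_prefix = feature_prefix)
}

.sim_counts <- function(config, feature_prefix = "gene",
                        features = NULL, planted = NULL) {
  cs <- config$counts
  nf <- cs$n_features
  if (is.null(features)) {
    features <- sprintf("%s%05d", feature_prefix, seq_len(nf))
  }
  nf <- length(features)
  mu0 <- stats::rlnorm(nf, cs$meanlog, cs$sdlog)
  if (is.null(planted)) {
    npl <- round(nf * cs$planted_fraction)
    idx <- sort(sample.int(nf, npl))
    sgn <- ifelse(stats::runif(npl) < cs$up_fraction, 1, -1)
    planted <- data.table::data.table(feature = features[idx],
                                      log2fc = sgn * cs$log2fc)
  }
  lfc <- rep(0, nf)
  lfc[match(planted$feature, features)] <- planted$log2fc
  nrep <- config$n_replicates
  samples <- c(sprintf("ctrl_%02d", seq_len(nrep)),
               sprintf("expo_%02d", seq_len(nrep)))
  groups <- rep(c("control", "exposed"), each = nrep)
  depth <- stats::runif(length(samples), cs$depth_range[1],
                        cs$depth_range[2])
  mu <- outer(mu0, depth)
  exposed <- groups == "exposed"
  mu[, exposed] <- mu[, exposed] * 2^lfc
  m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cs$dispersion),
              nrow = nf, dimnames = list(features, samples))
  storage.mode(m) <- "integer"
  list(matrix = m, groups = groups,
       sf_true = stats::setNames(depth, samples),
       truth = planted[order(feature)])
}

# draw the planted-feature assignment for a full scenario. Per
# (exposure, sex) the planted union is n_cell features; each feature
# carries a tissue assignment (both / liver-only / blood-only at the
# configured tissue-sharing rate) and signed effects whose cross-tissue
# sign agreement follows same_direction. An exposure-shared pool
# (fraction exposure_sharing of every union, with one fixed assignment)
# is planted identically in every exposure and sex; of the remaining
# features, males inherit a fraction sex_sharing from the same
# exposure's female draw with the female assignment, so female-male
# effects of shared features correlate as in a paired design.
.plant_cross_assignment <- function(config, features,
                                    n_cell = NULL, effect = NULL,
                                    up_fraction = NULL) {
  cr <- config$cross
  cs <- config$counts
  nf <- length(features)
  # planted union per (exposure, sex) pair of tissue cells
  if (is.null(n_cell)) n_cell <- round(nf * cs$planted_fraction)
  if (is.null(effect)) effect <- cs$log2fc
  if (is.null(up_fraction)) up_fraction <- cs$up_fraction
  assign_block <- function(feats) {
    n <- length(feats)
    u <- stats::runif(n)
    tis <- ifelse(u < cr$tissue_sharing, "both",
                  ifelse(u < cr$tissue_sharing +
                           (1 - cr$tissue_sharing) / 2,
                         "liver", "blood"))
    sgn_l <- ifelse(stats::runif(n) < up_fraction, 1, -1)
    same <- stats::runif(n) <
      (if (is.na(cr$same_direction)) 1 else cr$same_direction)
    data.table::data.table(feature = feats, tissues = tis,
                           effect_liver = sgn_l * effect,
                           effect_blood = ifelse(same, sgn_l, -sgn_l) *
                             effect)
  }
  n_pool <- round(n_cell * cr$exposure_sharing)
  pool_block <- assign_block(sample(features, n_pool))
  n_fresh <- n_cell - n_pool
  rows <- list()
  for (exposure in cr$exposures) {
    female_fresh <- NULL
    for (sex in c("F", "M")) {
      if (sex == "M" && nrow(female_fresh) > 0) {
        n_inherit <- min(round(n_fresh * cr$sex_sharing),
                         nrow(female_fresh))
        inherited <- female_fresh[sample(nrow(female_fresh), n_inherit)]
      } else {
        inherited <- pool_block[0]
      }
      taken <- c(pool_block$feature, inherited$feature)
      fresh <- assign_block(sample(setdiff(features, taken),
                                   max(0, n_fresh - nrow(inherited))))
      if (sex == "F") female_fresh <- fresh
      block <- data.table::rbindlist(list(pool_block, inherited, fresh))
      rows[[length(rows) + 1]] <- cbind(
        data.table::data.table(exposure = exposure, sex = sex), block)
    }
  }
  data.table::rbindlist(rows)
}

#' Simulate a full cross-tissue study
#'
#' Generates, for every (tissue, sex, exposure) cell, an expression
#' count matrix, an accessibility count matrix over consensus-like
#' intervals and (optionally) a WGBS experiment, with planted
#' differential features drawn so that the configured cross-tissue
#' sharing fraction, same-direction fraction, cross-sex sharing and
#' exposure sharing hold in expectation. Every assignment is recorded
#' in the ground truth.
#'
#' @param config A [sim_config()].
#' @param include_wgbs Also simulate WGBS per cell (default `TRUE`).
#' @param n_dar Number of accessibility intervals (default 2000).
#' @return A list: `cells` (named `tissue.sex.exposure`, each with
#'   `deg` and `dar` outputs of the count simulator and optionally
#'   `wgbs`), `truth` (tidy table: `exposure`, `sex`, `tissue`, `kind`,
#'   `feature`, `log2fc`), `assignment` (the raw cross-structure draw),
#'   `config`.
#' @export
simulate_cross_tissue_scenario <- function(config, include_wgbs = TRUE,
                                           n_dar = 2000L) {
  set.seed(config$seed)
  cs <- config$counts
  genes <- sprintf("gene%05d", seq_len(cs$n_features))
  # consensus-like accessibility intervals on a virtual chromosome
  dar_starts <- sort(sample.int(5e7, n_dar)) * 10L
  dar_iv <- data.table::data.table(chrom = "chrA", start = dar_starts,
                                   end = dar_starts + 500L)
  dars <- interval_key(dar_iv$chrom, dar_iv$start, dar_iv$end)
  assign_deg <- .plant_cross_assignment(config, genes)
  assign_dar <- .plant_cross_assignment(config, dars)
  assign_dmr <- NULL
  if (include_wgbs && config$dmr$n > 0) {
    # candidate DMR slots on the WGBS genome; the cross-structure draw
    # selects which slots are planted in which tissue and with which
    # direction
    slot_cfg <- config
    slot_cfg$dmr$n <- .n_dmr_slots(config)
    slots <- .plant_dmr_intervals(slot_cfg)
    slot_keys <- interval_key(slots$chrom, slots$start, slots$end)
    assign_dmr <- .plant_cross_assignment(config, slot_keys,
                                          n_cell = config$dmr$n,
                                          effect = config$dmr$delta,
                                          up_fraction =
                                            config$dmr$hyper_fraction)
  }
  cells <- list()
  truth <- list()
  i <- 0L
  for (exposure in config$cross$exposures) {
    for (sex in c("F", "M")) {
      for (tissue in c("blood", "liver")) {
        i <- i + 1L
        cell_cfg <- config
        cell_cfg$seed <- config$seed + i * 1009L
        set.seed(cell_cfg$seed)
        key <- paste(tissue, sex, exposure, sep = ".")
        cell <- list()
        for (kind in c("DEG", "DAR")) {
          asn <- if (kind == "DEG") assign_deg else assign_dar
          feats <- if (kind == "DEG") genes else dars
          sel <- asn$exposure == exposure & asn$sex == sex &
            (asn$tissues == "both" | asn$tissues == tissue)
          sub <- asn[which(sel)]
          lfc <- if (tissue == "liver") sub$effect_liver else
            sub$effect_blood
          planted <- data.table::data.table(feature = sub$feature,
                                            log2fc = lfc)
          sim <- .sim_counts(cell_cfg, features = feats, planted = planted)
          cell[[tolower(kind)]] <- sim
          truth[[length(truth) + 1]] <- data.table::data.table(
            exposure = exposure, sex = sex, tissue = tissue, kind = kind,
            feature = planted$feature, log2fc = planted$log2fc)
        }
        if (include_wgbs) {
          cell_truth <- NULL
          if (!is.null(assign_dmr)) {
            sel <- assign_dmr$exposure == exposure &
              assign_dmr$sex == sex &
              (assign_dmr$tissues == "both" |
                 assign_dmr$tissues == tissue)
            sub <- assign_dmr[which(sel)]
            d <- if (tissue == "liver") sub$effect_liver else
              sub$effect_blood
            iv <- parse_interval_key(sub$feature)
            cell_truth <- cbind(iv, data.table::data.table(
              direction = ifelse(d > 0, "hyper", "hypo"), delta = d))
            data.table::setorder(cell_truth, chrom, start)
          }
          cell$wgbs <- .sim_wgbs(cell_cfg, truth = cell_truth)
          tw <- cell$wgbs$truth
          if (!is.null(tw) && nrow(tw)) {
            truth[[length(truth) + 1]] <- data.table::data.table(
              exposure = exposure, sex = sex, tissue = tissue,
              kind = "DMR",
              feature = interval_key(tw$chrom, tw$start, tw$end),
              log2fc = tw$delta)
          }
        }
        cells[[key]] <- cell
      }
    }
  }
  list(cells = cells, truth = data.table::rbindlist(truth),
       assignment = list(DEG = assign_deg, DAR = assign_dar,
                         DMR = assign_dmr),
       config = config)
}

# how many non-overlapping DMR slots the genome can hold (same layout
# as the planter)
.n_dmr_slots <- function(config, buffer = 2000L) {
  slot <- as.integer(config$dmr$width) + buffer
  sum(pmax(0L, floor((unlist(config$chrom_sizes) - buffer) / slot)))
}
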