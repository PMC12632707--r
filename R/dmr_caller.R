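#' Parameters of the sliding-window DMR caller
#'
#' Houses every constant of the window chi-squared procedure. Defaults
#' follow the usual practice for this caller family: non-overlapping
#' 200-bp windows, a pooled 20-read site coverage floor per group, at
#' least 2 CpG sites and a 20-read average coverage per region, an
#' absolute methylation difference of at least 0.1 and a BH q-value
#' below 0.1, with bookended same-direction regions merged.
#'
#' @param window_size Window width in bp.
#' @param window_step Distance between window starts in bp; must satisfy
#'   `0 < window_step <= window_size`. The default equals `window_size`
#'   (disjoint tiling), which keeps the BH units non-overlapping;
#'   overlapping windows are supported and resolved by the merge stage.
#' @param site_min_coverage Minimum pooled (summed over replicates) read
#'   coverage per CpG required in *both* groups for the site to enter any
#'   window.
#' @param region_min_cpgs Minimum number of retained CpG sites per
#'   region.
#' @param region_min_avg_coverage Minimum average pooled coverage per
#'   retained CpG per group over the region.
#' @param min_delta Minimum absolute pooled methylation difference
#'   (exposed - control).
#' @param max_q Regions must have BH q strictly below this.
#' @param merge_max_gap Maximum gap in bp between significant windows
#'   merged into one DMR (0 = overlapping or bookended).
#' @param require_same_direction Merge only windows whose methylation
#'   change has the same sign.
#' @param yates Continuity correction for the window chi-squared test;
#'   off by default.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(window_size = 200L, window_step = window_size,
                       site_min_coverage = 20L, region_min_cpgs = 2L,
                       region_min_avg_coverage = 20, min_delta = 0.1,
                       max_q = 0.1, merge_max_gap = 0L,
                       require_same_direction = TRUE, yates = FALSE) {
  stopifnot(window_size > 0, window_step > 0, window_step <= window_size,
            site_min_coverage >= 0, region_min_cpgs >= 1,
            region_min_avg_coverage >= 0,
            min_delta > 0, min_delta <= 1, max_q > 0, max_q <= 1,
            merge_max_gap >= 0)
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 site_min_coverage = site_min_coverage,
                 region_min_cpgs = as.integer(region_min_cpgs),
                 region_min_avg_coverage = region_min_avg_coverage,
                 min_delta = min_delta, max_q = max_q,
                 merge_max_gap = as.integer(merge_max_gap),
                 require_same_direction = require_same_direction,
                 yates = yates),
            class = "dmr_params")
}

#' Tile chromosomes into sliding windows
#'
#' Windows are `[k * step, k * step + size)` clipped at the chromosome
#' end; a non-empty terminal partial window is kept.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param params A [dmr_params()] object.
#' @return `data.table` with `chrom`, `start`, `end`, ordered by
#'   position.
#' @export
tile_genome <- function(chrom_sizes, params = dmr_params()) {
  stopifnot(length(chrom_sizes) > 0, !is.null(names(chrom_sizes)))
  size <- params$window_size; step <- params$window_step
  res <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    if (len <= 0) {
      warning("chromosome ", ch, " has non-positive length; no windows")
      return(NULL)
    }
    starts <- seq.int(0L, len - 1L, by = step)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + size, len))
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  }
  out[]
}

# pool per-replicate CpG counts into per-group counts
.pool_cpgs <- function(cpgs, sample_sheet) {
  cpgs <- data.table::as.data.table(cpgs)
  ss <- data.table::as.data.table(sample_sheet)
  stopifnot(all(c("sample", "group") %in% names(ss)),
            all(c("sample", "chrom", "start", "meth", "unmeth") %in%
                  names(cpgs)))
  if (!all(ss$group %in% c("control", "exposed"))) {
    stop("sample sheet groups must be 'control' or 'exposed'")
  }
  for (g in c("control", "exposed")) {
    if (!any(ss$group == g)) stop("no samples in group '", g, "'")
  }
  missing <- setdiff(unique(cpgs$sample), ss$sample)
  if (length(missing)) stop("samples absent from sample sheet: ",
                            paste(missing, collapse = ", "))
  x <- merge(cpgs, ss[, .(sample, group)], by = "sample")
  pooled <- data.table::dcast(
    x, chrom + start ~ group,
    value.var = c("meth", "unmeth"),
    fun.aggregate = sum, fill = 0L
  )
  for (col in c("meth_control", "meth_exposed",
                "unmeth_control", "unmeth_exposed")) {
    if (!col %in% names(pooled)) pooled[, (col) := 0L]
  }
  pooled[, `:=`(cov_control = meth_control + unmeth_control,
                cov_exposed = meth_exposed + unmeth_exposed)]
  data.table::setkey(pooled, chrom, start)
  pooled[]
}

#' Site coverage filter
#'
#' Retains CpGs whose pooled coverage (summed over replicates) reaches
#' `site_min_coverage` in *both* groups; all other sites are excluded
#' from windows and from region average-coverage computations.
#'
#' @param cpgs Long per-sample CpG table with columns `sample`, `chrom`,
#'   `start`, `meth`, `unmeth` (as produced by
#'   [read_cytosine_report()] with `sample =` set, row-bound over
#'   samples).
#' @param sample_sheet Data frame with columns `sample` and `group`
#'   (`"control"` / `"exposed"`).
#' @param params A [dmr_params()] object.
#' @return Pooled per-CpG `data.table` (`chrom`, `start`,
#'   `meth_control`, `unmeth_control`, `meth_exposed`, `unmeth_exposed`,
#'   `cov_control`, `cov_exposed`) restricted to retained sites.
#' @export
filter_sites <- function(cpgs, sample_sheet, params = dmr_params()) {
  pooled <- .pool_cpgs(cpgs, sample_sheet)
  pooled[cov_control >= params$site_min_coverage &
           cov_exposed >= params$site_min_coverage &
           cov_control + cov_exposed > 0]
}

#' Score windows with the pooled chi-squared test
#'
#' Sums retained CpG counts per window into a 2x2 table (group x
#' meth/unmeth), computes pooled methylation levels, their difference,
#' and the uncorrected Pearson chi-squared p-value. Windows with no
#' retained CpG, or with a zero marginal, are untestable (`NA` p) and
#' excluded from multiple-testing adjustment downstream.
#'
#' @param pooled Output of [filter_sites()].
#' @param windows Output of [tile_genome()].
#' @param params A [dmr_params()] object.
#' @return `data.table` of per-window statistics: interval, `n_cpgs`,
#'   pooled counts, `avg_cov_control`, `avg_cov_exposed`,
#'   `beta_control`, `beta_exposed`, `delta`, `chi2`, `p`.
#' @export
score_windows <- function(pooled, windows, params = dmr_params()) {
  windows <- data.table::as.data.table(windows)
  pooled <- data.table::as.data.table(pooled)
  win <- data.table::copy(windows)
  win[, window_id := .I]
  if (nrow(pooled)) {
    size <- params$window_size; step <- params$window_step
    # window index range covering position p: k in
    # [floor((p - size)/step) + 1, floor(p/step)]
    klo <- pmax(0L, as.integer((pooled$start - size) %/% step) + 1L)
    khi <- as.integer(pooled$start %/% step)
    reps <- khi - klo + 1L
    idx <- rep(seq_len(nrow(pooled)), reps)
    k <- unlist(lapply(seq_len(nrow(pooled)),
                       function(i) seq.int(klo[i], khi[i])), use.names = FALSE)
    assign_dt <- pooled[idx]
    assign_dt[, win_start := k * step]
    agg <- assign_dt[, .(
      n_cpgs = .N,
      meth_control = sum(meth_control), unmeth_control = sum(unmeth_control),
      meth_exposed = sum(meth_exposed), unmeth_exposed = sum(unmeth_exposed)
    ), by = .(chrom, win_start)]
    stat <- merge(win, agg,
                  by.x = c("chrom", "start"), by.y = c("chrom", "win_start"),
                  all.x = TRUE)
  } else {
    stat <- win
    stat[, `:=`(n_cpgs = NA_integer_, meth_control = NA_integer_,
                unmeth_control = NA_integer_, meth_exposed = NA_integer_,
                unmeth_exposed = NA_integer_)]
  }
  stat[is.na(n_cpgs), n_cpgs := 0L]
  for (col in c("meth_control", "unmeth_control",
                "meth_exposed", "unmeth_exposed")) {
    stat[is.na(get(col)), (col) := 0L]
  }
  stat[, `:=`(
    cov_control = meth_control + unmeth_control,
    cov_exposed = meth_exposed + unmeth_exposed
  )]
  stat[, `:=`(
    avg_cov_control = ifelse(n_cpgs > 0, cov_control / n_cpgs, NA_real_),
    avg_cov_exposed = ifelse(n_cpgs > 0, cov_exposed / n_cpgs, NA_real_),
    beta_control = ifelse(cov_control > 0,
                          meth_control / cov_control, NA_real_),
    beta_exposed = ifelse(cov_exposed > 0,
                          meth_exposed / cov_exposed, NA_real_)
  )]
  stat[, delta := beta_exposed - beta_control]
  test <- chi2_2x2(stat$meth_control, stat$unmeth_control,
                   stat$meth_exposed, stat$unmeth_exposed,
                   correct = params$yates)
  stat[, `:=`(chi2 = test$statistic, p = test$p)]
  data.table::setorder(stat, window_id)
  stat[, window_id := NULL]
  stat[]
}

#' Call differentially methylated regions
#'
#' The full window procedure for one control-vs-exposed contrast:
#' pool and filter CpGs, score windows, BH-adjust over all testable
#' windows, keep windows passing every threshold (q, |delta|, CpG count,
#' average coverage), merge neighbouring significant windows, and
#' recompute region-level methylation from pooled counts over each
#' merged span.
#'
#' @inheritParams filter_sites
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param params A [dmr_params()] object.
#' @return A list with `windows` (all per-window statistics, with `q`
#'   and `significant` columns) and `dmrs` (one row per merged region:
#'   interval, `direction` ("hyper" = exposed above control), `n_cpgs`,
#'   per-group betas over the span, `delta`, `min_q`, `n_windows`).
#' @export
call_dmrs <- function(cpgs, sample_sheet, chrom_sizes,
                      params = dmr_params()) {
  pooled <- filter_sites(cpgs, sample_sheet, params)
  windows <- tile_genome(chrom_sizes, params)
  stat <- score_windows(pooled, windows, params)
  testable <- !is.na(stat$p)
  stat[, q := NA_real_]
  if (!any(testable)) {
    warning("no testable windows")
  } else {
    stat$q[testable] <- bh_adjust(stat$p[testable])
  }
  stat[, significant :=
         !is.na(q) & q < params$max_q &
         abs(delta) >= params$min_delta &
         n_cpgs >= params$region_min_cpgs &
         avg_cov_control >= params$region_min_avg_coverage &
         avg_cov_exposed >= params$region_min_avg_coverage]
  sig <- stat[significant == TRUE]
  dmrs <- .empty_dmr_table()
  if (nrow(sig)) {
    sig[, direction := ifelse(delta > 0, "hyper", "hypo")]
    merged <- merge_regions(sig[, .(chrom, start, end, direction)],
                            max_gap = params$merge_max_gap,
                            require_same_direction =
                              params$require_same_direction)
    dmrs <- .summarise_dmrs(merged, sig, pooled, params)
  }
  list(windows = stat[], dmrs = dmrs)
}

.empty_dmr_table <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    direction = character(), n_cpgs = integer(),
    beta_control = numeric(), beta_exposed = numeric(),
    delta = numeric(), min_q = numeric(), n_windows = integer())
}

.summarise_dmrs <- function(merged, sig_windows, pooled, params) {
  if (nrow(merged) == 0) return(.empty_dmr_table())
  hits <- intersect_regions(merged[, .(chrom, start, end)],
                            pooled[, .(chrom, start, end = start + 1L)])
  span <- data.table::data.table(region = hits$query, site = hits$subject)
  sums <- cbind(span,
                pooled[span$site,
                       .(meth_control, unmeth_control,
                         meth_exposed, unmeth_exposed)])
  agg <- sums[, .(n_cpgs = .N,
                  mc = sum(meth_control), uc = sum(unmeth_control),
                  me = sum(meth_exposed), ue = sum(unmeth_exposed)),
              by = region]
  out <- data.table::copy(merged)
  out[, region := .I]
  out <- merge(out, agg, by = "region", all.x = TRUE)
  out[, `:=`(beta_control = mc / (mc + uc),
             beta_exposed = me / (me + ue))]
  out[, delta := beta_exposed - beta_control]
  out[, min_q := vapply(members, function(i) min(sig_windows$q[i]),
                        numeric(1))]
  out[, n_windows := n_members]
  # pooling over the span reweights windows; enforce the region
  # thresholds on the recomputed quantities so every emitted record
  # satisfies them
  keep <- abs(out$delta) >= params$min_delta &
    ((out$delta > 0) == (out$direction == "hyper") |
       !params$require_same_direction) &
    out$n_cpgs >= params$region_min_cpgs
  out <- out[keep]
  out[, direction := ifelse(delta > 0, "hyper", "hypo")]
  out <- out[, .(chrom, start, end, direction, n_cpgs,
                 beta_control, beta_exposed, delta, min_q, n_windows)]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Write called DMRs as BED6+
#'
#' Name column carries the direction, score `-log10(q)` (capped at 1000),
#' extra columns `n_cpgs`, `beta_control`, `beta_exposed`, `delta`.
#'
#' @param dmrs The `dmrs` table from [call_dmrs()].
#' @param path Output path.
#' @param params Parameters echoed into the header comment.
#' @export
write_dmr_bed <- function(dmrs, path, params = NULL) {
  dt <- data.table::as.data.table(dmrs)
  bed <- dt[, .(chrom, start, end, name = direction,
                score = round(pmin(1000, -log10(pmax(min_q, 1e-300))), 3),
                strand = ".", n_cpgs, beta_control = round(beta_control, 4),
                beta_exposed = round(beta_exposed, 4),
                delta = round(delta, 4))]
  write_bed(bed, path, params = params)
}
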