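#' Significance thresholds for differential expression / accessibility
#'
#' The gene-expression defaults require BH-adjusted p strictly below
#' 0.001 and |log2 fold change| strictly above log2(1.5); accessibility
#' uses FDR < 0.01 with the same fold-change cutoff. Use
#' [deg_params()] / [dar_params()] for the two presets.
#'
#' @param max_padj Adjusted-p cutoff (strict `<`).
#' @param min_abs_log2fc Absolute log2 fold-change cutoff (strict `>`).
#' @param pseudocount Added to group means before the fold-change log to
#'   avoid log of zero.
#' @param dispersion_floor Lower bound on the overdispersion estimate.
#' @param dispersion_method `"global"` (default): one common
#'   overdispersion for all features, the mean of the per-feature
#'   method-of-moments estimates — the small-sample-stable choice, as in
#'   common-dispersion count models; or `"per_feature"`: each feature
#'   uses its own estimate (noisy at n = 6 per group, inflating the
#'   type-I error of the normal reference).
#' @return A list of class `diff_params`.
#' @export
diff_params <- function(max_padj = 0.001, min_abs_log2fc = log2(1.5),
                        pseudocount = 0.5, dispersion_floor = 1e-8,
                        dispersion_method = c("global", "per_feature")) {
  stopifnot(max_padj > 0, min_abs_log2fc > 0, pseudocount >= 0,
            dispersion_floor > 0)
  dispersion_method <- match.arg(dispersion_method)
  structure(list(max_padj = max_padj, min_abs_log2fc = min_abs_log2fc,
                 pseudocount = pseudocount,
                 dispersion_floor = dispersion_floor,
                 dispersion_method = dispersion_method),
            class = "diff_params")
}

#' @rdname diff_params
#' @export
deg_params <- function() diff_params(max_padj = 0.001)

#' @rdname diff_params
#' @export
dar_params <- function() diff_params(max_padj = 0.01)

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors for sequencing depth: each sample's factor
#' is the median over all-positive features of the ratio of its count to
#' the feature's geometric mean across samples.
#'
#' @param m Integer count matrix, features x samples.
#' @return Named numeric vector of positive size factors, one per
#'   sample.
#' @export
size_factors <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 1)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no feature has positive counts in every sample; size factors ",
         "undefined (consider a pseudocount on the matrix)")
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  stats::setNames(sf, colnames(m))
}

#' Negative-binomial Wald test for two-group count comparisons
#'
#' A self-contained differential test over normalised counts, declared
#' as a stand-in: published DEG/DAR tables typically come from the
#' dedicated count-model packages, and [load_external_differential()]
#' accepts those directly. This test makes the pipeline runnable and
#' scoreable end-to-end with no external inputs.
#'
#' Per feature, with normalised counts `y = k / s`: group means `m0`
#' (control) and `m1` (exposed); `log2fc = log2((m1 + c)/(m0 + c))` with
#' pseudocount `c`; a method-of-moments overdispersion
#' `(v - m)/m^2` from the pooled within-group variance `v` and grand
#' mean `m` of `y`, floored and by default pooled into one common
#' `alpha` across features (see [diff_params()]); delta-method variance
#' of each group's log2 mean `Vg = (1/(mg + c) + alpha) / (ng *
#' ln(2)^2)`; Wald `z = log2fc / sqrt(V0 + V1)` against a two-sided
#' normal, BH-adjusted over all tested features. Features with all-zero
#' counts in both groups are reported untested (`NA` p).
#'
#' @param m Count matrix, features x samples.
#' @param groups Character/factor vector over columns of `m` with
#'   levels `"control"` and `"exposed"`, each of size >= 2.
#' @param sf Size factors (default computed by [size_factors()]).
#' @param params A [diff_params()] object.
#' @return A `data.table` differential table: `feature`, `baseMean`,
#'   `log2fc`, `p`, `padj`, `significant`, `direction` (`"up"`/`"down"`
#'   for significant rows, `NA` otherwise).
#' @export
nb_wald_test <- function(m, groups, sf = size_factors(m),
                         params = diff_params()) {
  stopifnot(is.matrix(m), length(groups) == ncol(m), length(sf) == ncol(m),
            all(sf > 0))
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "exposed"))) {
    stop("groups must be 'control' or 'exposed'")
  }
  n0 <- sum(groups == "control"); n1 <- sum(groups == "exposed")
  if (n0 < 2 || n1 < 2) stop("each group needs at least 2 samples")
  y <- sweep(m, 2, sf, "/")
  y0 <- y[, groups == "control", drop = FALSE]
  y1 <- y[, groups == "exposed", drop = FALSE]
  m0 <- rowMeans(y0); m1 <- rowMeans(y1)
  cc <- params$pseudocount
  log2fc <- log2((m1 + cc) / (m0 + cc))
  v0 <- apply(y0, 1, stats::var); v1 <- apply(y1, 1, stats::var)
  vpool <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  mpool <- (n0 * m0 + n1 * m1) / (n0 + n1)
  mom <- rep(NA_real_, nrow(m))
  nz <- mpool > 0
  mom[nz] <- (vpool[nz] - mpool[nz]) / mpool[nz]^2
  if (params$dispersion_method == "global") {
    # mean of the per-feature method-of-moments estimates over
    # adequately expressed features; unbiased for a common dispersion
    use <- nz & mpool > 1
    g <- if (any(use)) mean(mom[use]) else params$dispersion_floor
    alpha <- rep(max(params$dispersion_floor, g), nrow(m))
  } else {
    alpha <- pmax(params$dispersion_floor, mom)
    alpha[!nz] <- params$dispersion_floor
  }
  ln2sq <- log(2)^2
  V0 <- (1 / (m0 + cc) + alpha) / (n0 * ln2sq)
  V1 <- (1 / (m1 + cc) + alpha) / (n1 * ln2sq)
  z <- log2fc / sqrt(V0 + V1)
  p <- 2 * stats::pnorm(-abs(z))
  untested <- m0 == 0 & m1 == 0
  p[untested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  if (any(!is.na(p))) padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  tab <- data.table::data.table(
    feature = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
              else rownames(m),
    baseMean = mpool, log2fc = log2fc, p = p, padj = padj)
  apply_thresholds(tab, params)
}

#' Apply significance thresholds to a differential table
#'
#' A feature is significant iff `padj < max_padj` (strict) and
#' `|log2fc| > min_abs_log2fc` (strict). Direction is the sign of the
#' fold change.
#'
#' @param tab Data frame with at least `log2fc` and `padj`.
#' @param params A [diff_params()] object.
#' @return The table with `significant` and `direction` columns
#'   (re)computed.
#' @export
apply_thresholds <- function(tab, params = diff_params()) {
  tab <- data.table::as.data.table(tab)
  stopifnot(all(c("log2fc", "padj") %in% names(tab)))
  tab[, significant := !is.na(padj) & padj < params$max_padj &
        abs(log2fc) > params$min_abs_log2fc]
  tab[, direction := data.table::fifelse(
    significant, data.table::fifelse(log2fc > 0, "up", "down"),
    NA_character_)]
  tab[]
}

#' Load an externally computed differential table
#'
#' Pass-through for tables produced by dedicated count-model packages.
#' Expected TSV columns: `feature`, `log2fc`, `p`, `padj` (extra columns
#' kept). Thresholds are re-applied so significance semantics are
#' uniform with [nb_wald_test()].
#'
#' @param path TSV path.
#' @param params A [diff_params()] object.
#' @return A validated differential `data.table`.
#' @export
load_external_differential <- function(path, params = diff_params()) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  required <- c("feature", "log2fc", "p", "padj")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("differential table '", path, "' missing columns: ",
         paste(miss, collapse = ", "))
  }
  badp <- !is.na(dt$p) & (dt$p < 0 | dt$p > 1)
  if (any(badp)) stop("p outside [0,1] in '", path, "'")
  inconsistent <- !is.na(dt$p) & !is.na(dt$padj) & dt$padj < dt$p
  if (any(inconsistent)) {
    warning(sum(inconsistent), " rows with padj < p in '", path,
            "'; kept as given")
  }
  apply_thresholds(dt, params)
}
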