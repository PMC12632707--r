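#' Validate a feature-set collection
#'
#' The concordance layer works on one tidy table holding every
#' differential result of a study: one row per (exposure, sex, tissue,
#' kind, feature). `kind` is `"DEG"`, `"DAR"` or `"DMR"`; DEG features
#' are gene ids, DAR/DMR features are `chrom:start-end` interval keys.
#' `effect` is the log2 fold change (DEG/DAR) or the methylation
#' difference delta (DMR). Non-significant rows may be included; they
#' define the tested universe used by the hypergeometric sharing test.
#'
#' @param tab Data frame with columns `exposure`, `sex`, `tissue`,
#'   `kind`, `feature`, `effect`, `significant`.
#' @return The validated table as a `data.table`.
#' @export
feature_collection <- function(tab) {
  tab <- data.table::as.data.table(tab)
  required <- c("exposure", "sex", "tissue", "kind", "feature", "effect",
                "significant")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("collection missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$kind %in% c("DEG", "DAR", "DMR"))) {
    stop("kind must be DEG, DAR or DMR")
  }
  dup <- duplicated(tab[, .(exposure, sex, tissue, kind, feature)])
  if (any(dup)) stop("duplicate (exposure, sex, tissue, kind, feature) keys")
  iv <- tab$kind %in% c("DAR", "DMR")
  if (any(iv)) parse_interval_key(tab$feature[iv])  # validates format
  tab[]
}

.sig <- function(tab) tab[significant == TRUE]

# pairs of matching significant features between two tables of one kind
.match_features <- function(a, b, kind, dar_mode = "exact",
                            min_overlap = 1L) {
  a <- .sig(data.table::as.data.table(a))
  b <- .sig(data.table::as.data.table(b))
  empty <- data.table::data.table(
    feature_a = character(), feature_b = character(),
    effect_a = numeric(), effect_b = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  by_key <- kind == "DEG" || (kind == "DAR" && dar_mode == "exact")
  if (by_key) {
    pairs <- merge(a[, .(feature, effect)], b[, .(feature, effect)],
                   by = "feature", suffixes = c("_a", "_b"))
    pairs <- pairs[, .(feature_a = feature, feature_b = feature,
                       effect_a, effect_b)]
  } else {
    ia <- parse_interval_key(a$feature)
    ib <- parse_interval_key(b$feature)
    hits <- suppressWarnings(
      intersect_regions(ia, ib, min_overlap = min_overlap))
    pairs <- data.table::data.table(
      feature_a = a$feature[hits$query], feature_b = b$feature[hits$subject],
      effect_a = a$effect[hits$query], effect_b = b$effect[hits$subject])
  }
  data.table::setorder(pairs, feature_a, feature_b)
  pairs[]
}

#' Match significant features across two tissues
#'
#' Genes match by id; accessibility regions by identical coordinates
#' (default) or, in `"overlap"` mode, by at least `min_overlap` bp of
#' intersection; methylation regions always by >= 1 bp intersection. A
#' region intersecting several partners yields one pair per partner.
#'
#' @param blood,liver Differential tables (rows of a
#'   [feature_collection()]) for the two tissues, same `kind`.
#' @param kind `"DEG"`, `"DAR"` or `"DMR"`.
#' @param dar_mode `"exact"` (identical coordinates) or `"overlap"`.
#' @param min_overlap Minimum overlap in bp for interval matching.
#' @return `data.table` of pairs: `feature_a`/`feature_b` (blood/liver)
#'   with their `effect_a`/`effect_b`.
#' @export
cross_tissue_match <- function(blood, liver, kind = c("DEG", "DAR", "DMR"),
                               dar_mode = c("exact", "overlap"),
                               min_overlap = 1L) {
  kind <- match.arg(kind)
  dar_mode <- match.arg(dar_mode)
  .match_features(blood, liver, kind, dar_mode, min_overlap)
}

#' Fraction of matched pairs with concordant effect direction
#'
#' @param pairs Pair table from [cross_tissue_match()] (or any frame
#'   with `effect_a`, `effect_b`).
#' @return A list: `concordance` (fraction of sign-agreeing pairs among
#'   pairs with two nonzero effects; `NA` when none), `n_used`, and
#'   `n_zero` (pairs excluded for a zero effect, counted separately).
#' @export
direction_concordance <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0) {
    return(list(concordance = NA_real_, n_used = 0L, n_zero = 0L))
  }
  zero <- pairs$effect_a == 0 | pairs$effect_b == 0
  use <- pairs[!zero]
  list(
    concordance = if (nrow(use) == 0) NA_real_ else
      mean(sign(use$effect_a) == sign(use$effect_b)),
    n_used = nrow(use),
    n_zero = sum(zero)
  )
}

#' Hypergeometric test of cross-set sharing
#'
#' Probability of observing at least the observed number of shared
#' significant features, given the two significant-set sizes and a
#' universe of features testable in both sets.
#'
#' @param a,b Differential tables with `feature`, `significant` (key
#'   matched kinds: DEG, or DAR in exact mode).
#' @param universe Universe policy: `"intersection"` (default; features
#'   present in both tables), `"union"`, or a user-supplied character
#'   vector / single number N.
#' @return A list: `p`, `N`, `K` (significant in `b` within universe),
#'   `n` (significant in `a` within universe), `s` (shared).
#' @export
cross_tissue_sharing_test <- function(a, b, universe = "intersection") {
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  siga <- unique(.sig(a)$feature)
  sigb <- unique(.sig(b)$feature)
  shared <- intersect(siga, sigb)
  if (is.character(universe) && length(universe) == 1 &&
      universe %in% c("intersection", "union")) {
    U <- if (universe == "intersection") {
      intersect(unique(a$feature), unique(b$feature))
    } else {
      union(unique(a$feature), unique(b$feature))
    }
  } else if (is.numeric(universe) && length(universe) == 1) {
    N <- as.integer(universe)
    K <- length(sigb); n <- length(siga); s <- length(shared)
    if (K > N || n > N) stop("universe smaller than a significant set")
    return(list(p = hypergeom_tail(N, K, n, s), N = N, K = K, n = n, s = s))
  } else {
    U <- as.character(universe)
  }
  if (length(setdiff(shared, U))) {
    stop("shared features fall outside the universe; the universe must ",
         "contain both significant sets")
  }
  K <- length(intersect(sigb, U))
  n <- length(intersect(siga, U))
  s <- length(shared)
  if (K > length(U) || n > length(U)) {
    stop("significant sets not contained in the universe")
  }
  list(p = hypergeom_tail(length(U), K, n, s),
       N = length(U), K = K, n = n, s = s)
}

# full two-set concordance report used for both the sex and the tissue
# comparisons
.concordance_report <- function(a, b, kind, universe = "intersection",
                                cor_method = "pearson",
                                dar_mode = "exact") {
  pairs <- .match_features(a, b, kind, dar_mode = dar_mode)
  na <- length(unique(.sig(data.table::as.data.table(a))$feature))
  nb <- length(unique(.sig(data.table::as.data.table(b))$feature))
  shared_a <- length(unique(pairs$feature_a))
  shared_b <- length(unique(pairs$feature_b))
  dc <- direction_concordance(pairs)
  r <- pearson_r(pairs$effect_a, pairs$effect_b, method = cor_method)
  hg <- if (kind == "DEG" || (kind == "DAR" && dar_mode == "exact")) {
    cross_tissue_sharing_test(a, b, universe = universe)
  } else {
    list(p = NA_real_, N = NA_integer_, K = nb, n = na,
         s = min(shared_a, shared_b))
  }
  data.table::data.table(
    n_sig_a = na, n_sig_b = nb,
    a_only = na - shared_a, b_only = nb - shared_b,
    shared_a = shared_a, shared_b = shared_b,
    n_pairs = nrow(pairs),
    direction_concordance = dc$concordance,
    n_zero_effect = dc$n_zero,
    effect_cor = r,
    hyper_p = hg$p, universe_N = hg$N)
}

#' Female-male concordance for one exposure, tissue and feature kind
#'
#' Shared features between the sexes (key match for DEG/DAR, >= 1 bp
#' intersection for DMR), the direction-concordant fraction, the
#' correlation of effect sizes over shared features (reported missing
#' below 3 shared pairs), and for key-matched kinds the hypergeometric
#' sharing p with the universe used.
#'
#' @param collection A [feature_collection()].
#' @param exposure,tissue,kind Cell selectors.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return One-row `data.table` (a concordance report) with the two
#'   sexes as sides A = female, B = male.
#' @export
sex_concordance <- function(collection, exposure, tissue, kind,
                            cor_method = "pearson") {
  cl <- data.table::as.data.table(collection)
  sel <- cl$exposure == exposure & cl$tissue == tissue & cl$kind == kind
  f <- cl[which(sel & cl$sex == "F")]
  m <- cl[which(sel & cl$sex == "M")]
  if (nrow(f) == 0 && nrow(m) == 0) {
    stop("no rows for the requested cell")
  }
  out <- .concordance_report(f, m, kind, cor_method = cor_method)
  cbind(data.table::data.table(exposure = exposure, tissue = tissue,
                               kind = kind, side_a = "F", side_b = "M"),
        out)
}

#' Cross-tissue concordance for one exposure, sex and feature kind
#'
#' @inheritParams sex_concordance
#' @param sex Cell selector.
#' @param tissue_a,tissue_b The two tissues compared (e.g. blood and
#'   liver).
#' @param universe Universe policy for the hypergeometric test, see
#'   [cross_tissue_sharing_test()].
#' @param dar_mode DAR matching mode, see [cross_tissue_match()].
#' @return One-row `data.table` concordance report.
#' @export
tissue_concordance <- function(collection, exposure, sex, kind,
                               tissue_a = "blood", tissue_b = "liver",
                               universe = "intersection",
                               cor_method = "pearson",
                               dar_mode = "exact") {
  cl <- data.table::as.data.table(collection)
  sel <- cl$exposure == exposure & cl$sex == sex & cl$kind == kind
  a <- cl[which(sel & cl$tissue == tissue_a)]
  b <- cl[which(sel & cl$tissue == tissue_b)]
  if (nrow(a) == 0 && nrow(b) == 0) stop("no rows for the requested cell")
  out <- .concordance_report(a, b, kind, universe = universe,
                             cor_method = cor_method, dar_mode = dar_mode)
  cbind(data.table::data.table(exposure = exposure, sex = sex, kind = kind,
                               side_a = tissue_a, side_b = tissue_b),
        out)
}

#' Sharing of significant features across exposures
#'
#' For one (sex, tissue, kind) cell: in how many exposures is each
#' significant feature significant (any direction and same direction),
#' and what fraction of features is exposure-specific vs shared. Genes
#' and accessibility regions are matched across exposures by feature
#' key; methylation regions by >= 1 bp intersection.
#'
#' @param collection A [feature_collection()].
#' @param sex,tissue,kind Cell selectors.
#' @return A list: `per_feature` (`exposure`, `feature`, `effect`,
#'   `n_exposures_any`, `n_exposures_same_dir`) and `summary` (fractions
#'   of features with exposure counts 1, 2, 3, > 3 and
#'   `fraction_shared` = fraction in >= 2 exposures).
#' @export
exposure_sharing_profile <- function(collection, sex, tissue, kind) {
  cl <- data.table::as.data.table(collection)
  sel <- cl$sex == sex & cl$tissue == tissue & cl$kind == kind
  cell <- .sig(cl[which(sel)])
  exposures <- unique(cell$exposure)
  if (length(exposures) < 2) {
    stop("exposure sharing needs at least 2 exposures; found ",
         length(exposures))
  }
  if (nrow(cell) == 0) stop("no significant features in the cell")
  if (kind %in% c("DEG", "DAR")) {
    per <- cell[, .(exposure, feature, effect)]
    counts <- cell[, .(n_exposures_any = data.table::uniqueN(exposure)),
                   by = feature]
    samedir <- cell[, .(n_up = data.table::uniqueN(exposure[effect > 0]),
                        n_dn = data.table::uniqueN(exposure[effect < 0])),
                    by = feature]
    samedir[, n_exposures_same_dir := pmax(n_up, n_dn)]
    per <- merge(per, counts, by = "feature")
    per <- merge(per, samedir[, .(feature, n_exposures_same_dir)],
                 by = "feature")
  } else {
    iv <- parse_interval_key(cell$feature)
    hits <- suppressWarnings(intersect_regions(iv, iv))
    hdt <- data.table::data.table(
      q = hits$query, s = hits$subject,
      exp_s = cell$exposure[hits$subject],
      same = sign(cell$effect[hits$query]) ==
        sign(cell$effect[hits$subject]))
    agg <- hdt[, .(n_exposures_any = data.table::uniqueN(exp_s),
                   n_exposures_same_dir =
                     data.table::uniqueN(exp_s[same])), by = q]
    per <- cell[, .(exposure, feature, effect)]
    per[agg$q, `:=`(n_exposures_any = agg$n_exposures_any,
                    n_exposures_same_dir = agg$n_exposures_same_dir)]
  }
  stopifnot(all(per$n_exposures_same_dir <= per$n_exposures_any))
  n <- per$n_exposures_any
  summary <- data.table::data.table(
    sex = sex, tissue = tissue, kind = kind,
    n_features = nrow(per),
    frac_1 = mean(n == 1), frac_2 = mean(n == 2),
    frac_3 = mean(n == 3), frac_gt3 = mean(n > 3),
    fraction_shared = mean(n >= 2))
  data.table::setorder(per, exposure, feature)
  list(per_feature = per[], summary = summary)
}

#' Overlap of interval features with an annotation region set
#'
#' Flags each interval-keyed feature that intersects (>= 1 bp) any
#' region of a user-supplied annotation BED (for example imprint
#' control regions). A feature overlapping several regions counts once.
#'
#' @param features Data frame with interval keys in `feature`, or
#'   columns `chrom`, `start`, `end`.
#' @param regions Region set (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()].
#' @return A list: `flags` (logical per feature) and `n_overlapping`
#'   (number of features overlapping at least one region).
#' @export
region_set_annotation <- function(features, regions) {
  features <- data.table::as.data.table(features)
  iv <- if (all(c("chrom", "start", "end") %in% names(features))) {
    features[, .(chrom, start, end)]
  } else {
    parse_interval_key(features$feature)
  }
  regions <- data.table::as.data.table(regions)
  flags <- rep(FALSE, nrow(iv))
  if (nrow(regions) && nrow(iv)) {
    hits <- suppressWarnings(intersect_regions(iv, regions))
    flags[unique(hits$query)] <- TRUE
  }
  list(flags = flags, n_overlapping = sum(flags))
}
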