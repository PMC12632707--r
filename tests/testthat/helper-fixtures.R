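# Tiny hand-built fixtures for the DMR caller and concordance layer.

# a long-format per-sample CpG table from a compact spec:
# sites = data.frame(chrom, start, meth_control, unmeth_control,
#                    meth_exposed, unmeth_exposed) given as POOLED counts;
# split evenly over n replicates per group (remainder on the first)
toy_cpgs <- function(sites, n_rep = 1L) {
  split_counts <- function(total, n) {
    base <- total %/% n
    counts <- rep(base, n)
    counts[1] <- counts[1] + total - base * n
    counts
  }
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (grp in c("control", "exposed")) {
      meth <- split_counts(sites[[paste0("meth_", grp)]][i], n_rep)
      unmeth <- split_counts(sites[[paste0("unmeth_", grp)]][i], n_rep)
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1]] <- data.table::data.table(
          sample = sprintf("%s_%d", grp, r),
          chrom = sites$chrom[i], start = sites$start[i],
          meth = meth[r], unmeth = unmeth[r])
      }
    }
  }
  data.table::rbindlist(rows)
}

toy_sample_sheet <- function(n_rep = 1L) {
  data.table::data.table(
    sample = c(sprintf("control_%d", seq_len(n_rep)),
               sprintf("exposed_%d", seq_len(n_rep))),
    group = rep(c("control", "exposed"), each = n_rep))
}

# a minimal differential-table row set for concordance tests
toy_diff_table <- function(features, effects, significant = TRUE,
                           exposure = "E1", sex = "F", tissue = "blood",
                           kind = "DEG") {
  data.table::data.table(
    exposure = exposure, sex = sex, tissue = tissue, kind = kind,
    feature = features, effect = effects,
    significant = rep_len(significant, length(features)))
}
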