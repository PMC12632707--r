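#' @import data.table
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#' @importFrom IRanges IRanges width pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All intervals inside the package are 0-based half-open [start, end),
# the BED convention. Conversion to/from 1-based formats (cytosine
# reports, GRanges) happens only at these boundaries.

.as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a Bismark-style per-CpG cytosine report
#'
#' Tab-separated columns: chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count; any further columns
#' (trinucleotide context etc.) are ignored. Positions are converted to
#' the package-internal 0-based convention.
#'
#' @param path Path to the report file.
#' @param sample Optional sample id attached to every record.
#' @param collapse_strands If `TRUE`, counts at adjacent positions `p`
#'   (+ strand) and `p + 1` (- strand) are summed into one record at `p`,
#'   treating the CpG dyad as a single unit. Default `FALSE`.
#' @return A `data.table` with columns `chrom`, `start` (0-based),
#'   `strand`, `meth`, `unmeth` and, when given, `sample`. An empty file
#'   yields an empty table with a warning.
#' @export
read_cytosine_report <- function(path, sample = NULL, collapse_strands = FALSE) {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        colClasses = list(character = 1), fill = TRUE)),
    error = function(e) stop("cannot read cytosine report '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0) {
    warning("empty cytosine report: ", path)
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  strand = character(), meth = integer(),
                                  unmeth = integer())
    if (!is.null(sample)) out[, sample := character()]
    return(out[])
  }
  if (ncol(dt) < 5) stop("cytosine report '", path, "' has ", ncol(dt),
                         " columns; at least 5 required")
  out <- dt[, 1:5]
  data.table::setnames(out, c("chrom", "pos", "strand", "meth", "unmeth"))
  for (col in c("pos", "meth", "unmeth")) {
    v <- suppressWarnings(as.integer(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad)) stop("cytosine report '", path, "': non-integer ", col,
                          " at line ", bad[1])
    data.table::set(out, j = col, value = v)
  }
  if (any(out$pos <= 0L)) {
    stop("cytosine report '", path, "': position <= 0 at line ",
         which(out$pos <= 0L)[1])
  }
  if (any(out$meth < 0L) || any(out$unmeth < 0L)) {
    stop("cytosine report '", path, "': negative count")
  }
  badstr <- which(!out$strand %in% c("+", "-", "."))
  if (length(badstr)) stop("cytosine report '", path,
                           "': unknown strand symbol at line ", badstr[1])
  out[, start := pos - 1L][, pos := NULL]
  data.table::setcolorder(out, c("chrom", "start", "strand", "meth", "unmeth"))
  if (collapse_strands) {
    # fold a '-' record at p+1 onto a '+' record at p
    out[strand == "-", start := start - 1L]
    out <- out[, .(strand = "+", meth = sum(meth), unmeth = sum(unmeth)),
               by = .(chrom, start)]
    data.table::setcolorder(out, c("chrom", "start", "strand", "meth", "unmeth"))
  }
  if (!is.null(sample)) out[, sample := sample]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Read a BED3+ interval file
#'
#' @param path Path to a BED file (0-based half-open, matching the
#'   internal convention). Lines starting with `#`, `track` or `browser`
#'   are skipped.
#' @return A `data.table` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` plus any extra columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  bed_cols <- c("chrom", "start", "end", "name", "score", "strand")
  nc <- ncol(dt)
  data.table::setnames(dt, seq_len(min(nc, 6)), bed_cols[seq_len(min(nc, 6))])
  dt[, start := as.integer(start)][, end := as.integer(end)]
  if (any(dt$start < 0L)) stop("BED '", path, "': negative start")
  if (any(dt$start >= dt$end)) {
    stop("BED '", path, "': start >= end at line ",
         which(dt$start >= dt$end)[1])
  }
  data.table::setkey(dt, chrom, start, end)
  dt[]
}

#' Write intervals as BED
#'
#' Output is sorted by (chrom, start, end). A comment header records the
#' package version and any parameters supplied.
#'
#' @param intervals A data.frame with at least `chrom`, `start`, `end`;
#'   `name`, `score`, `strand` and further columns are written in BED6+
#'   order when present.
#' @param path Output path.
#' @param params Optional named list echoed into the header comment.
#' @export
write_bed <- function(intervals, path, params = NULL) {
  dt <- data.table::as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  if (nrow(dt) && any(dt$start >= dt$end)) stop("start >= end in intervals")
  bed_cols <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- c(bed_cols[bed_cols %in% names(dt)],
            setdiff(names(dt), bed_cols))
  dt <- dt[, keep, with = FALSE]
  data.table::setorder(dt, chrom, start, end)
  hdr <- sprintf("#epiconcord %s%s",
                 as.character(utils::packageVersion("epiconcord")),
                 if (is.null(params)) "" else
                   paste0(" ", paste(names(params), unlist(params),
                                     sep = "=", collapse = " ")))
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' All pairs of overlapping intervals between two region sets
#'
#' Finds every pair `(i in a, j in b)` whose intervals overlap by at
#' least `min_overlap` base pairs. Half-open semantics: `[100,200)` and
#' `[200,300)` do not overlap.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_overlap Minimum overlap width in bp (default 1).
#' @return A `data.table` with columns `query` (row index in `a`),
#'   `subject` (row index in `b`) and `overlap` (width in bp).
#' @export
intersect_regions <- function(a, b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  empty <- data.table::data.table(query = integer(), subject = integer(),
                                  overlap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ca <- unique(a$chrom); cb <- unique(b$chrom)
  if (length(intersect(ca, cb)) == 0) {
    warning("region sets share no chromosome names (",
            paste(utils::head(ca, 3), collapse = ","), " vs ",
            paste(utils::head(cb, 3), collapse = ","), ")")
    return(empty)
  }
  ga <- .as_granges0(a)
  gb <- .as_granges0(b)
  hits <- GenomicRanges::findOverlaps(ga, gb,
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0) return(empty)
  ov <- IRanges::width(IRanges::pintersect(
    ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]))
  out <- data.table::data.table(query = S4Vectors::queryHits(hits),
                                subject = S4Vectors::subjectHits(hits),
                                overlap = as.integer(ov))
  data.table::setorder(out, query, subject)
  out[]
}

#' Merge neighbouring intervals
#'
#' Transitive closure of "same chromosome, gap at most `max_gap` bp (and
#' same direction when required)", collapsed into single spans. Bookended
#' intervals (`[0,200)` + `[200,400)`) have gap 0 and merge at the
#' default.
#'
#' @param x Data frame with `chrom`, `start`, `end` and, when
#'   `require_same_direction` is `TRUE`, a `direction` column.
#' @param max_gap Maximum gap in bp between members of one merged span
#'   (default 0: overlapping or bookended only).
#' @param require_same_direction Only merge intervals with equal
#'   `direction` (default `TRUE`).
#' @return A `data.table` with `chrom`, `start`, `end`, `direction` (when
#'   used), `n_members` and `members` (list column of row indices of `x`
#'   in each merged span), sorted by position.
#' @export
merge_regions <- function(x, max_gap = 0L, require_same_direction = TRUE) {
  x <- data.table::as.data.table(x)
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_members = integer(),
                                  members = list()))
  }
  if (require_same_direction && !"direction" %in% names(x)) {
    stop("require_same_direction = TRUE needs a 'direction' column")
  }
  grp <- if (require_same_direction) as.character(x$direction)
         else rep("*", nrow(x))
  res <- lapply(split(seq_len(nrow(x)), grp), function(idx) {
    g <- .as_granges0(x[idx])
    red <- GenomicRanges::reduce(g, min.gapwidth = max_gap + 1L,
                                 with.revmap = TRUE)
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      direction = if (require_same_direction)
        as.character(x$direction[idx][1]) else NA_character_,
      n_members = lengths(red$revmap),
      members = lapply(red$revmap, function(i) idx[i])
    )
  })
  out <- data.table::rbindlist(res)
  if (!require_same_direction) out[, direction := NULL]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Read a feature-by-sample count matrix from TSV
#'
#' First column holds feature ids (gene ids or `chrom:start-end` interval
#' keys), remaining columns one sample each, header row of sample ids.
#'
#' @param path Path to the TSV.
#' @return An integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("count matrix '", path, "' has no sample columns")
  ids <- dt[[1]]
  if (anyDuplicated(ids)) stop("duplicate feature ids in '", path, "'")
  m <- as.matrix(dt[, -1])
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in '", path, "'")
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0)) stop("non-integer or negative counts in '",
                                   path, "'")
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample count matrix as TSV
#' @param m Integer matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table::data.table(feature = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Interval key helpers
#'
#' DAR-style features are keyed as `"chrom:start-end"` (0-based
#' half-open). `interval_key()` builds keys; `parse_interval_key()`
#' recovers a table of intervals.
#' @param chrom,start,end Interval fields.
#' @return `interval_key`: character vector of keys.
#' @export
interval_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @rdname interval_key
#' @param key Character vector of `chrom:start-end` keys.
#' @export
parse_interval_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):([0-9]+)-([0-9]+)$", key))
  bad <- which(lengths(m) != 4)
  if (length(bad)) stop("malformed interval key: ", key[bad[1]])
  data.table::data.table(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4))
  )
}
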