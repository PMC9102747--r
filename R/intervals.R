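#' @importFrom data.table data.table as.data.table := setorder setorderv rbindlist setnames fread fwrite setDT copy
NULL

# Internal: coerce to a validated interval table (chrom, start, end[, id]).
# Coordinates are 0-based half-open throughout the package (BED convention).
as_intervals <- function(x, validate = TRUE) {
  x <- as.data.table(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("interval table requires columns: ", paste(need, collapse = ", "))
  }
  if (!"id" %in% names(x)) x[, id := NA_character_]
  x <- x[, c("chrom", "start", "end", "id"), with = FALSE]
  if (validate) validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    stop("interval coordinates must be finite")
  }
  if (any(x$start < 0)) stop("interval start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(sprintf("interval end must exceed start (first offending row %d: [%s, %s))",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Construct a genomic interval table
#'
#' Intervals are stored as a `data.table` with columns `chrom`, `start`,
#' `end`, `id`, using 0-based half-open coordinates. All interval algebra in
#' the package operates on this representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param id optional interval identifiers.
#' @return A sorted interval `data.table`.
#' @export
gintervals <- function(chrom, start, end, id = NULL) {
  x <- data.table(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  id = if (is.null(id)) NA_character_ else as.character(id))
  validate_intervals(x)
  sort_intervals(x)
}

#' Sort intervals by (chrom, start, end, id)
#'
#' Lexicographic tie-break on id keeps sorting deterministic.
#' @param x interval table.
#' @return sorted copy.
#' @export
sort_intervals <- function(x) {
  x <- as_intervals(x, validate = FALSE)
  setorderv(copy(x), c("chrom", "start", "end", "id"), na.last = TRUE)
}

#' Total covered base pairs of an interval set
#'
#' Sums interval widths; equals covered bp only after [merge_intervals()].
#' @param x interval table.
#' @return numeric scalar (bp).
#' @export
total_bp <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Joins intervals on the same chromosome whose gap is at most `max_gap` bp
#' (gap 0 joins book-ended intervals). Output is disjoint and sorted, so
#' `total_bp()` of the result is the covered-bp of the input.
#'
#' @param x interval table.
#' @param max_gap maximum gap (bp) to bridge; must be >= 0.
#' @return merged interval table (ids dropped).
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be non-negative")
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(x[, .(chrom, start, end)])
  x <- sort_intervals(x)
  # new run when start exceeds the running max end by more than max_gap
  x[, run_end := cummax(end), by = chrom]
  grp <- x[, {
    brk <- if (.N == 1L) TRUE else c(TRUE, start[-1] > run_end[-.N] + max_gap)
    .(start = start, end = end, g = cumsum(brk))
  }, by = chrom]
  out <- grp[, .(start = min(start), end = max(end)), by = .(chrom, g)]
  out[, g := NULL]
  x[, run_end := NULL]
  setorderv(out, c("chrom", "start", "end"))
  out[]
}

# Internal: overlap pairs between two interval tables (indices + overlap bp).
# Uses data.table foverlaps on closed integer intervals.
overlap_pairs <- function(x, y) {
  x <- as_intervals(x); y <- as_intervals(y)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(data.table(xid = integer(), yid = integer(), overlap = numeric()))
  }
  a <- data.table(chrom = x$chrom, s = x$start, e = x$end - 1, xid = seq_len(nrow(x)))
  b <- data.table(chrom = y$chrom, s = y$start, e = y$end - 1, yid = seq_len(nrow(y)))
  data.table::setkey(b, chrom, s, e)
  ov <- data.table::foverlaps(a, b, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) {
    return(data.table(xid = integer(), yid = integer(), overlap = numeric()))
  }
  ov[, overlap := pmin(e, i.e) - pmax(s, i.s) + 1]
  ov[, .(xid, yid, overlap)]
}

#' Base pairs of each interval overlapped by a set
#'
#' @param targets interval table (need not be merged).
#' @param set interval table; merged internally so overlapping set members are
#'   not double counted.
#' @return numeric vector of overlap bp, one per target row.
#' @export
overlap_bp <- function(targets, set) {
  targets <- as_intervals(targets)
  set <- merge_intervals(set)
  out <- numeric(nrow(targets))
  ov <- overlap_pairs(targets, set)
  if (nrow(ov)) {
    agg <- ov[, .(bp = sum(overlap)), by = xid]
    out[agg$xid] <- agg$bp
  }
  out
}

#' Fraction of a target interval covered by a set
#'
#' Used e.g. for the gene-body H3K27me3 mark rule (fraction > 0.20 flags a
#' gene as marked).
#'
#' @param targets one or more intervals.
#' @param set covering interval set.
#' @return numeric vector in \[0, 1\].
#' @export
coverage_fraction <- function(targets, set) {
  targets <- as_intervals(targets)
  overlap_bp(targets, set) / (targets$end - targets$start)
}

#' Intersect two interval sets
#'
#' Both sets are merged first; returns the disjoint bp-wise intersection.
#' @param x,y interval tables.
#' @return merged interval table of the intersection.
#' @export
intersect_intervals <- function(x, y) {
  x <- merge_intervals(x); y <- merge_intervals(y)
  ov <- overlap_pairs(x, y)
  if (nrow(ov) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- data.table(chrom = x$chrom[ov$xid],
                    start = pmax(x$start[ov$xid], y$start[ov$yid]),
                    end = pmin(x$end[ov$xid], y$end[ov$yid]))
  setorderv(out, c("chrom", "start", "end"))
  out[]
}

#' Does each interval overlap a set by at least one bp?
#' @param targets interval table.
#' @param set interval table.
#' @return logical vector.
#' @export
overlaps_any <- function(targets, set) {
  overlap_bp(targets, set) > 0
}

#' Best reciprocal overlap of each interval against a set
#'
#' For each target the maximum over set members of
#' `min(overlap/width_target, overlap/width_member)`. Reciprocal overlap is
#' the identity criterion for matching domains across cell types.
#'
#' @param targets,set interval tables (assumed internally disjoint each).
#' @return numeric vector in \[0, 1\].
#' @export
reciprocal_overlap <- function(targets, set) {
  targets <- as_intervals(targets); set <- as_intervals(set)
  out <- numeric(nrow(targets))
  ov <- overlap_pairs(targets, set)
  if (nrow(ov)) {
    ov[, ro := pmin(overlap / (targets$end[xid] - targets$start[xid]),
                    overlap / (set$end[yid] - set$start[yid]))]
    agg <- ov[, .(ro = max(ro)), by = xid]
    out[agg$xid] <- agg$ro
  }
  out
}

#' Fraction of the genome covered by a region set
#' @param regions interval table.
#' @param genome_size total genome size in bp.
#' @return fraction in \[0, 1\].
#' @export
marked_genome_fraction <- function(regions, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  total_bp(merge_intervals(regions)) / genome_size
}

#' Count regions at least a given width
#'
#' The broad-domain census: how many enriched regions exceed 100 Kb.
#' @param regions interval table.
#' @param min_width minimum width in bp (default 100 Kb).
#' @return integer count.
#' @export
large_region_count <- function(regions, min_width = 100000) {
  regions <- as_intervals(regions)
  sum(regions$end - regions$start >= min_width)
}
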