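# Chromosome name dialects ("1" vs "chr1") are normalized to "chr*" on read.
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; track/browser lines are skipped. Intervals are
#' validated (end > start, start >= 0) with the offending line number
#' reported, chromosome names normalized to the "chr*" dialect, and the
#' result sorted.
#'
#' @param path file path.
#' @return sorted interval table; BED6 name/score/strand kept as
#'   `id`/`score`/`strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      id = character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", lineno[which(nf < 3)[1]]))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed BED line %d: non-numeric coordinates", lineno[bad[1]]))
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: end <= start or negative start", lineno[bad[1]]))
  }
  x <- data.table(chrom = normalize_chrom(vapply(fields, `[`, "", 1L)),
                  start = start, end = end,
                  id = if (all(nf >= 4)) vapply(fields, `[`, "", 4L) else NA_character_)
  if (all(nf >= 5)) x[, score := suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))]
  if (all(nf >= 6)) x[, strand := vapply(fields, `[`, "", 6L)]
  setorderv(x, c("chrom", "start", "end", "id"), na.last = TRUE)
  x[]
}

#' Write intervals as BED
#'
#' Writes BED3 (or BED6 when `id`/`score`/`strand` are present) after sorting.
#' @param x interval table.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  setorderv(x <- copy(x), intersect(c("chrom", "start", "end", "id"), names(x)), na.last = TRUE)
  cols <- c("chrom", "start", "end")
  if ("id" %in% names(x) && !all(is.na(x$id))) {
    x[, id := ifelse(is.na(id), ".", id)]
    cols <- c(cols, "id")
    if ("score" %in% names(x)) {
      cols <- c(cols, "score")
      if ("strand" %in% names(x)) cols <- c(cols, "strand")
    }
  }
  x[, start := format(start, scientific = FALSE, trim = TRUE)]
  x[, end := format(end, scientific = FALSE, trim = TRUE)]
  fwrite(x[, cols, with = FALSE], path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path file path.
#' @return data.table with chrom, start, end, value (chrom normalized,
#'   sorted).
#' @export
read_bedgraph <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t",
             col.names = c("chrom", "start", "end", "value")[1:4])
  x[, chrom := normalize_chrom(chrom)]
  validate_intervals(x[, .(chrom, start, end)])
  setorderv(x, c("chrom", "start", "end"))
  x[]
}

#' Write a bedGraph file
#' @param x data.table with chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  x <- copy(as.data.table(x))
  x[, start := format(start, scientific = FALSE, trim = TRUE)]
  x[, end := format(end, scientific = FALSE, trim = TRUE)]
  fwrite(x[, .(chrom, start, end, value)], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wiggle file (fixedStep / variableStep)
#'
#' Wiggle coordinates are 1-based; they are converted to 0-based half-open
#' on read. Read-only support, `span` honoured.
#'
#' @param path file path.
#' @return data.table with chrom, start, end, value.
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  out <- list()
  mode <- NULL; chrom <- NULL; pos <- NULL; step <- NULL; span <- 1
  grab <- function(l, key, default = NULL) {
    m <- regmatches(l, regexec(paste0(key, "=(\\S+)"), l))[[1]]
    if (length(m) == 2) m[2] else default
  }
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(l) || grepl("^(track|#)", l)) next
    if (grepl("^fixedStep", l)) {
      mode <- "fixed"
      chrom <- normalize_chrom(grab(l, "chrom"))
      pos <- as.numeric(grab(l, "start")) - 1   # to 0-based
      step <- as.numeric(grab(l, "step"))
      span <- as.numeric(grab(l, "span", "1"))
    } else if (grepl("^variableStep", l)) {
      mode <- "variable"
      chrom <- normalize_chrom(grab(l, "chrom"))
      span <- as.numeric(grab(l, "span", "1"))
    } else if (is.null(mode)) {
      stop(sprintf("wiggle parse error at line %d: data before a step header", i))
    } else if (mode == "fixed") {
      out[[length(out) + 1]] <- data.table(chrom = chrom, start = pos,
                                           end = pos + span, value = as.numeric(l))
      pos <- pos + step
    } else {
      f <- strsplit(l, "\\s+")[[1]]
      if (length(f) != 2) stop(sprintf("wiggle parse error at line %d", i))
      s <- as.numeric(f[1]) - 1
      out[[length(out) + 1]] <- data.table(chrom = chrom, start = s,
                                           end = s + span, value = as.numeric(f[2]))
    }
  }
  x <- rbindlist(out)
  if (nrow(x)) setorderv(x, c("chrom", "start", "end"))
  x[]
}

#' Convert interval-valued signal (bedGraph-like) to a binned track
#'
#' @param bg data.table with chrom, start, end, value (tags per interval).
#' @param bin_width bin width bp.
#' @param chrom_sizes named chromosome sizes.
#' @param depth library depth; defaults to the total value.
#' @return a [signal_track()].
#' @export
bedgraph_to_track <- function(bg, bin_width, chrom_sizes, depth = NULL) {
  bg <- as.data.table(bg)
  bins <- lapply(chrom_sizes, function(sz) numeric(ceiling(sz / bin_width)))
  for (k in seq_len(nrow(bg))) {
    ch <- bg$chrom[k]
    if (is.null(bins[[ch]])) next
    s <- bg$start[k]; e <- min(bg$end[k], chrom_sizes[[ch]])
    if (e <= s) next
    i0 <- floor(s / bin_width); i1 <- ceiling(e / bin_width) - 1
    w <- pmin(e, (i0:i1 + 1) * bin_width) - pmax(s, (i0:i1) * bin_width)
    bins[[ch]][(i0:i1) + 1] <- bins[[ch]][(i0:i1) + 1] + bg$value[k] * w / (e - s)
  }
  signal_track(bins, bin_width, chrom_sizes, depth = depth)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns gene_id, chrom, strand, tss, start, end,
#' gc_fraction, biotype. TSS must sit at the strand-appropriate end of the
#' gene body; gc_fraction in \[0, 1\].
#'
#' @param path file path.
#' @return gene annotation data.table.
#' @export
read_gene_annotation <- function(path) {
  g <- fread(path, header = TRUE, sep = "\t")
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end", "gc_fraction", "biotype")
  if (!all(need %in% names(g))) {
    stop("gene annotation requires columns: ", paste(need, collapse = ", "))
  }
  g[, chrom := normalize_chrom(chrom)]
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(g$gc_fraction < 0 | g$gc_fraction > 1)) stop("gc_fraction must be in [0,1]")
  validate_intervals(g[, .(chrom, start, end)])
  bad <- g[(strand == "+" & tss != start) | (strand == "-" & tss != end)]
  if (nrow(bad)) stop("TSS inconsistent with strand for gene ", bad$gene_id[1])
  setorderv(g, c("chrom", "start", "end", "gene_id"))
  g[]
}

#' Write a gene annotation table
#' @param genes gene annotation data.table.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  fwrite(genes, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a CpG methylation bedGraph
#'
#' Columns chrom, start, end, fraction\[, coverage\]; fraction in \[0, 1\].
#' Each record is taken as one CpG at `start`.
#'
#' @param path file path.
#' @return data.table with chrom, pos, fraction, coverage.
#' @export
read_methyl_bedgraph <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < 4) stop("methylation bedGraph requires >= 4 columns")
  setnames(x, 1:4, c("chrom", "start", "end", "fraction"))
  x[, coverage := if (ncol(x) >= 5) as.integer(x[[5]]) else NA_integer_]
  if (any(x$fraction < 0 | x$fraction > 1)) stop("methylation fraction outside [0,1]")
  out <- x[, .(chrom = normalize_chrom(chrom), pos = start, fraction, coverage)]
  setorderv(out, c("chrom", "pos"))
  out <- unique(out, by = c("chrom", "pos"))
  out[]
}

#' Write a CpG methylation bedGraph
#' @param methyl data.table with chrom, pos, fraction, coverage.
#' @param path output path.
#' @export
write_methyl_bedgraph <- function(methyl, path) {
  m <- as.data.table(methyl)
  out <- m[, .(chrom, start = as.integer(pos), end = as.integer(pos + 1), fraction)]
  if ("coverage" %in% names(m) && !all(is.na(m$coverage))) out[, coverage := m$coverage]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
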