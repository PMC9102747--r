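#' Binned ChIP-seq signal track
#'
#' A per-chromosome vector of non-negative tag counts in fixed-width bins,
#' together with the library depth. Tag counts in arbitrary regions are
#' obtained by pro-rating boundary bins by their overlap fraction, which
#' makes region counts exact linear functionals of the bin vector.
#'
#' @param bins named list, one non-negative numeric vector per chromosome.
#' @param bin_width bin width in bp (> 0).
#' @param chrom_sizes named numeric vector of chromosome sizes in bp.
#' @param depth library depth (total tags); must be >= sum of bin counts.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(bins, bin_width, chrom_sizes, depth = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!is.list(bins) || is.null(names(bins))) stop("bins must be a named list")
  chrom_sizes <- chrom_sizes[names(bins)]
  if (any(is.na(chrom_sizes))) stop("chrom_sizes must cover every track chromosome")
  for (ch in names(bins)) {
    v <- bins[[ch]]
    if (any(v < 0)) stop("bin counts must be non-negative (", ch, ")")
    n_expect <- ceiling(chrom_sizes[[ch]] / bin_width)
    if (length(v) != n_expect) {
      stop(sprintf("chromosome %s: expected %d bins, got %d", ch, n_expect, length(v)))
    }
  }
  tot <- sum(vapply(bins, sum, numeric(1)))
  if (is.null(depth)) depth <- tot
  if (depth < tot - 1e-6) stop("library depth smaller than total binned tags")
  structure(list(bins = bins, bin_width = bin_width,
                 chrom_sizes = chrom_sizes, depth = depth),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin width %g bp, %.3g tags (depth %.3g)\n",
              length(x$bins), x$bin_width,
              sum(vapply(x$bins, sum, numeric(1))), x$depth))
  invisible(x)
}

# Internal: cumulative tag function per chromosome. C(pos) = tags in [0, pos)
# with linear interpolation inside bins, so C(end) - C(start) is exactly the
# pro-rated tag count of [start, end).
track_cum <- function(track, chrom, pos) {
  v <- track$bins[[chrom]]
  if (is.null(v)) stop("region off-chromosome: unknown chromosome ", chrom)
  bw <- track$bin_width
  size <- track$chrom_sizes[[chrom]]
  if (any(pos < 0 | pos > size)) stop("region off-chromosome bounds on ", chrom)
  cs <- c(0, cumsum(v))
  i <- pmin(floor(pos / bw), length(v) - 1)        # bin index, 0-based
  cs[i + 1] + v[i + 1] * (pos - i * bw) / bw
}

#' Tag count within regions
#'
#' Sums bin counts over each region, pro-rating bins that straddle a region
#' boundary by their overlap fraction.
#'
#' @param track a [signal_track()].
#' @param regions interval table.
#' @return numeric vector of tag counts, one per region.
#' @export
region_tag_count <- function(track, regions) {
  regions <- as_intervals(regions)
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    out[idx] <- track_cum(track, ch, regions$end[idx]) -
      track_cum(track, ch, regions$start[idx])
  }
  out
}

#' Normalized tag density of regions
#'
#' ChIP-seq signal is normalized to the total number of tags falling within
#' enriched regions, not to raw library depth. Density unit: tags per Kb per
#' `scale` enriched tags (default per 10 million).
#'
#' @param track a [signal_track()].
#' @param regions interval table.
#' @param within_enriched_total total tags inside the cell type's enriched
#'   regions (see [enriched_tag_total()]).
#' @param scale normalization scale (default 1e7).
#' @param per_kb divide by region width in Kb (default TRUE).
#' @return numeric vector of densities.
#' @export
normalized_density <- function(track, regions, within_enriched_total,
                               scale = 1e7, per_kb = TRUE) {
  if (within_enriched_total <= 0) stop("within_enriched_total must be positive")
  regions <- as_intervals(regions)
  cnt <- region_tag_count(track, regions)
  if (per_kb) cnt <- cnt / ((regions$end - regions$start) / 1000)
  cnt / within_enriched_total * scale
}

#' Total tags inside enriched regions
#'
#' The normalization denominator for ChIP-seq densities.
#' @param track a [signal_track()].
#' @param enriched_regions interval table of the library's enriched regions.
#' @return numeric scalar.
#' @export
enriched_tag_total <- function(track, enriched_regions) {
  sum(region_tag_count(track, merge_intervals(enriched_regions)))
}

#' Rasterize weighted regions onto a binned track
#'
#' Deterministically spreads `density` (tags per Kb) over the bins each
#' region overlaps, pro-rated by overlap fraction; used by the simulator
#' before Poisson sampling.
#'
#' @param regions interval table.
#' @param density tags per Kb per region (recycled).
#' @param bin_width bin width bp.
#' @param chrom_sizes named chromosome sizes.
#' @return named list of per-chromosome expected-count vectors.
#' @keywords internal
regions_to_bin_means <- function(regions, density, bin_width, chrom_sizes) {
  regions <- as_intervals(regions)
  density <- rep_len(density, nrow(regions))
  out <- lapply(chrom_sizes, function(sz) numeric(ceiling(sz / bin_width)))
  for (k in seq_len(nrow(regions))) {
    ch <- regions$chrom[k]
    if (is.null(out[[ch]])) next
    s <- regions$start[k]; e <- min(regions$end[k], chrom_sizes[[ch]])
    if (e <= s) next
    i0 <- floor(s / bin_width); i1 <- ceiling(e / bin_width) - 1
    w <- pmin(e, (i0:i1 + 1) * bin_width) - pmax(s, (i0:i1) * bin_width)
    out[[ch]][(i0:i1) + 1] <- out[[ch]][(i0:i1) + 1] + density[k] * w / 1000
  }
  out
}
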