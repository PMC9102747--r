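# Brute-force per-base oracles for the interval algebra, used to verify the
# production implementations on random instances.

# covered bp of an interval set on one chromosome, by boolean array
oracle_covered_bp <- function(starts, ends, max_pos) {
  hit <- logical(max_pos)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(hit)
}

# covered bp after merging with a gap allowance: internal FALSE runs of
# length <= max_gap between covered bases are filled before counting
oracle_covered_bp_gap <- function(starts, ends, max_pos, max_gap) {
  hit <- logical(max_pos)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(hit)
  n <- length(r$values)
  for (k in seq_len(n)) {
    if (!r$values[k] && k > 1 && k < n && r$lengths[k] <= max_gap) {
      r$values[k] <- TRUE
    }
  }
  sum(inverse.rle(r))
}

# overlap bp of target [s, e) with a set, by boolean array
oracle_overlap_bp <- function(s, e, set_s, set_e, max_pos) {
  hit <- logical(max_pos)
  for (i in seq_along(set_s)) {
    if (set_e[i] > set_s[i]) hit[(set_s[i] + 1):set_e[i]] <- TRUE
  }
  sum(hit[(s + 1):e])
}

# pro-rated tag count of [s, e) on a binned track, by per-base accumulation
oracle_tag_count <- function(bins, bin_width, s, e) {
  per_base <- rep(bins / bin_width, each = bin_width)
  sum(per_base[(s + 1):e])
}

random_intervals <- function(n, max_pos, max_width = 50, chrom = "chr1") {
  s <- sample.int(max_pos - max_width, n, replace = TRUE) - 1
  w <- sample.int(max_width, n, replace = TRUE)
  data.table::data.table(chrom = chrom, start = s, end = pmin(s + w, max_pos))
}
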