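# The default synthetic cohort and its catalogue are expensive enough to
# build once and share across test files.
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_cohort(cohort_spec(seed = 7))
  }
  .fixture_cache$cohort
}

default_catalogue <- function() {
  if (is.null(.fixture_cache$catalogue)) {
    co <- default_cohort()
    .fixture_cache$catalogue <- build_catalogue(
      lapply(co$marks, function(m) m$H3K27ac$regions),
      lapply(co$marks, function(m) m$H3K27ac$track),
      co$genes,
      k4me1_tracks = lapply(co$marks, function(m) m$H3K4me1$track),
      seed = 1)
  }
  .fixture_cache$catalogue
}

# planted_id -> catalogue region_id (regions are placed disjoint, so
# coordinates identify them)
planted_to_catalogue <- function(cohort, catalogue) {
  key <- paste(cohort$truth$enh$regions$chrom, cohort$truth$enh$regions$start)
  ckey <- paste(catalogue$regions$chrom, catalogue$regions$start)
  stats::setNames(catalogue$regions$region_id,
                  cohort$truth$enh$regions$planted_id[match(ckey, key)])
}

# planted truth states aligned to catalogue region order
planted_states_for_catalogue <- function(cohort, catalogue) {
  key <- paste(cohort$truth$enh$regions$chrom, cohort$truth$enh$regions$start)
  ckey <- paste(catalogue$regions$chrom, catalogue$regions$start)
  cohort$truth$enh$states[match(ckey, key), , drop = FALSE]
}
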