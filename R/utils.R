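# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Named sub-seeds derived from a master seed: one pseudo-random stream per
# output family, so one family's parameters can change without perturbing
# the draws of another. Kept below 2^31 - 1.
sub_seed <- function(master, name) {
  offsets <- c(locks = 101L, segments = 211L, k9 = 307L, lads = 401L,
               genes = 503L, counts = 601L, methyl = 701L, enhancers = 809L,
               tracks = 907L, motifs = 1009L, thinning = 1103L, misc = 1201L,
               decoys = 1301L)
  if (!name %in% names(offsets)) stop("unknown seed family: ", name)
  (as.integer(master) * 1000L + offsets[[name]]) %% 2147483647L
}
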