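#' Specification of a synthetic hematopoietic cohort
#'
#' Defines the stated world of the simulator: 8 cell types (4 progenitor,
#' 2 mature myeloid, 2 mature lymphoid) on a small 3 x 30 Mb genome, with
#' progenitor-shared broad H3K27me3 domains that contract to a punctate
#' profile in the myeloid types, H3K9me3 co-occupancy and LAD enrichment
#' inside domains, GC-biased expression with planted differential genes, an
#' enhancer catalogue with primed/active structure, super-enhancer clusters,
#' CpG methylation depressed inside myeloid-retained domains and at
#' mature-active enhancers, and motif occupancy with planted cell-type bias.
#'
#' @param seed master seed; one named sub-stream per output family.
#' @param chrom_sizes named chromosome sizes (default 3 x 30 Mb).
#' @param n_locks number of true domains (default 40).
#' @param lock_meanlog,lock_sdlog log-normal LOCK width (median 300 Kb).
#' @param myeloid_loss fraction of domains lost in the myeloid types (0.7).
#' @param shrink within-retained-domain segment width shrink factor (0.2).
#' @param n_genes number of genes (default 8000).
#' @param n_de planted DE genes per cell type vs the reference (default 300).
#' @param gc_bias_amplitude GC log-bias half-spread across samples (1).
#' @param lock_depression methylation depression inside myeloid-retained
#'   domain footprints in the myeloid cell types (default 0.2).
#' @param enhancer_depression methylation depression at progenitor-primed /
#'   mature-active enhancers in the mature cell types (default 0.3).
#' @param n_motifs total motifs in the occurrence map (default 40).
#' @param bin_width signal-track bin width bp (default 200).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1,
                        chrom_sizes = c(chr1 = 3e7, chr2 = 3e7, chr3 = 3e7),
                        n_locks = 40, lock_meanlog = log(3e5), lock_sdlog = 0.35,
                        myeloid_loss = 0.7, shrink = 0.2,
                        n_genes = 8000, n_de = 300, gc_bias_amplitude = 1,
                        lock_depression = 0.2, enhancer_depression = 0.3,
                        n_motifs = 40, bin_width = 200) {
  stopifnot(myeloid_loss >= 0, myeloid_loss <= 1, shrink > 0, shrink <= 1,
            lock_depression >= 0, lock_depression <= 1,
            enhancer_depression >= 0, enhancer_depression <= 1)
  structure(list(
    seed = seed, chrom_sizes = chrom_sizes,
    cell_types = data.table(
      name = c("CD34_38neg", "CMP", "GMP", "MEP",
               "Monocyte", "Erythroblast", "Bcell", "Tcell"),
      class = c(rep("progenitor", 4), rep("myeloid", 2), rep("lymphoid", 2))),
    n_locks = n_locks, lock_meanlog = lock_meanlog, lock_sdlog = lock_sdlog,
    myeloid_loss = myeloid_loss, shrink = shrink,
    # broad-domain internal geometry: enriched segments ~U(20,30) Kb with
    # ~U(5,10) Kb gaps in broad cell types; shrunken (left-anchored) in the
    # myeloid retained domains so stitching gaps stay below the log-gap
    # threshold while background gaps stay far above it
    seg_width = c(20e3, 30e3), seg_gap = c(5e3, 10e3),
    n_punctate = 12, n_tiny = 24, n_background_k27 = 45,
    k9_seg = c(25e3, 35e3), k9_gap = c(8e3, 15e3), n_background_k9 = 30,
    lad_seg = c(30e3, 50e3), lad_gap = c(15e3, 25e3),
    n_background_lads = 25, lad_bg_width = c(1e5, 4e5),
    n_genes = n_genes, n_de = n_de, gc_bias_amplitude = gc_bias_amplitude,
    dispersion = 100, de_lfc_range = c(1, 3),
    # enhancer composition (counts per class; see methods vignette)
    enh = list(n_core = 99, n_prog_shared = 36, n_spec_active = 45,
               n_prog_active = 180, n_constitutive = 20,
               n_ineligible = 30, n_borderline = 80,
               n_decoy = 50, n_se_clusters = 6, se_cluster_size = 6,
               n_se_prog = 2,
               width = c(1200, 2500), width_borderline = c(3500, 4500),
               min_sep = 15e3, se_member_gap = c(5e3, 10e3),
               d_active = c(90, 180), d_se = c(250, 450),
               d_borderline = c(18, 32), d_low = c(0, 4), d_primed_k27 = c(2, 8),
               d_k4_high = c(80, 160), d_k4_low = c(0, 10)),
    n_cpg = 30000, cpg_per_enhancer = 6, meth_base = c(mean = 0.75, conc = 30),
    meth_noise_sd = 0.03, lock_depression = lock_depression,
    enhancer_depression = enhancer_depression,
    n_motifs = n_motifs, n_biased_per_mature = 2, n_silent_tfs = 5,
    motif_rate = 0.08,
    bin_width = bin_width, track_background = 0.005,
    d_k27_track = c(20, 50), d_k4me3 = c(30, 80), d_k9_track = c(15, 35),
    d_k36 = c(10, 25)
  ), class = "cohort_spec")
}

# Internal: rbind possibly-empty region tables to (chrom, start, end).
bind_regions <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(as.data.table(p)) > 0, list(...))
  if (!length(parts)) {
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  }
  rbindlist(lapply(parts, function(p) as.data.table(p)[, .(chrom, start, end)]))
}

# Internal: rejection-sample n regions of given widths, keeping min_sep bp
# from previously placed/occupied intervals. occupied is a merged interval
# table (may be empty). Returns the placed intervals.
place_regions <- function(n, widths, chrom_sizes, occupied, min_sep,
                          max_tries = 400) {
  widths <- rep_len(widths, n)
  occ <- lapply(names(chrom_sizes), function(ch) {
    o <- occupied[occupied$chrom == ch]
    list(s = o$start, e = o$end)
  })
  names(occ) <- names(chrom_sizes)
  probs <- chrom_sizes / sum(chrom_sizes)
  out_ch <- character(n); out_s <- numeric(n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(names(chrom_sizes), 1, prob = probs)
      s <- floor(stats::runif(1, 1e5, chrom_sizes[[ch]] - widths[k] - 1e5))
      a <- s - min_sep; b <- s + widths[k] + min_sep
      hit <- any(occ[[ch]]$s < b & occ[[ch]]$e > a)
      if (!hit) {
        occ[[ch]]$s <- c(occ[[ch]]$s, s)
        occ[[ch]]$e <- c(occ[[ch]]$e, s + widths[k])
        out_ch[k] <- ch; out_s[k] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible spec: could not place region ", k,
                      " (genome too crowded)")
  }
  data.table(chrom = out_ch, start = out_s, end = out_s + widths)
}

# Internal: tile [start, end) with segments of width ~U(w), gaps ~U(g);
# first segment starts at start, last is truncated at end. If shrink < 1 the
# segment occupies only the left shrink fraction of its slot.
tile_segments <- function(chrom, start, end, w, g, shrink = 1) {
  s <- numeric(0); e <- numeric(0)
  pos <- start
  while (pos < end) {
    full_w <- stats::runif(1, w[1], w[2])
    seg_end <- min(pos + shrink * full_w, end)
    s <- c(s, pos); e <- c(e, seg_end)
    pos <- pos + full_w + stats::runif(1, g[1], g[2])
  }
  data.table(chrom = chrom, start = s, end = e)[end - start >= 200]
}

#' Generate the synthetic cohort
#'
#' Emits, per cell type, enriched-region sets and binned tag tracks for the
#' six histone marks, an expression table, CpG methylation tracks, a gene
#' annotation, a LAD set, a motif occurrence map, and a ground-truth ledger
#' sufficient for parameter-recovery tests of the downstream modules.
#' The same spec and seed give byte-identical output.
#'
#' Enhancer regions are laid out before genes; genes are then placed so that
#' no TSS +/- 2 Kb window overlaps an enhancer region (emulating intergenic
#' regulatory space). A set of decoy regions deliberately straddling TSS
#' exercises the catalogue's promoter-exclusion filter.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  sizes <- spec$chrom_sizes
  genome <- sum(sizes)
  cts <- spec$cell_types$name
  prog <- spec$cell_types[class == "progenitor", name]
  myel <- spec$cell_types[class == "myeloid", name]
  lymph <- spec$cell_types[class == "lymphoid", name]
  broad_cts <- c(prog, lymph)
  mature <- c(myel, lymph)
  reference <- prog[1]

  ## --- true LOCK footprints -------------------------------------------------
  locks <- with_seed(sub_seed(spec$seed, "locks"), {
    if (spec$n_locks == 0) {
      data.table(chrom = character(), start = numeric(), end = numeric(),
                 lock_id = character(), retained_myeloid = logical())
    } else {
      w <- pmin(pmax(exp(stats::rnorm(spec$n_locks, spec$lock_meanlog,
                                      spec$lock_sdlog)), 1.5e5), 8e5)
      if (sum(w) > 0.5 * genome) stop("infeasible spec: LOCK bp exceeds genome capacity")
      lk <- place_regions(spec$n_locks, round(w), sizes,
                          occupied = data.table(chrom = character(),
                                                start = numeric(), end = numeric()),
                          min_sep = 4e5)
      lk <- sort_intervals(lk)[, .(chrom, start, end)]
      lk[, lock_id := sprintf("true_lock_%03d", seq_len(.N))]
      n_ret <- round((1 - spec$myeloid_loss) * spec$n_locks)
      ret <- sample(seq_len(nrow(lk)), n_ret)
      lk[, retained_myeloid := seq_len(.N) %in% ret]
      lk
    }
  })

  ## --- per-cell-type H3K27me3 enriched regions ------------------------------
  k27 <- with_seed(sub_seed(spec$seed, "segments"), {
    bg_pos <- if (spec$n_background_k27 > 0) {
      place_regions(spec$n_background_k27,
                    round(stats::runif(spec$n_background_k27, 2e3, 8e3)),
                    sizes, occupied = locks[, .(chrom, start, end)],
                    min_sep = 1.5e5)
    } else data.table(chrom = character(), start = numeric(), end = numeric())
    # Punctate myeloid remnants are emitted as pairs ~25 Kb apart on the
    # chromosomes that retain at least one domain: pairwise gaps then fall in
    # the intra-domain range (keeping the chromosome-wise log-gap statistic
    # anchored there) while a pair's <=100 Kb span can never be called a
    # domain. Sub-MinLength fragments are sprinkled anywhere.
    punct <- if (nrow(locks) && spec$n_punctate + spec$n_tiny > 0) {
      ret_chroms <- unique(locks[retained_myeloid == TRUE, chrom])
      occ <- merge_intervals(bind_regions(
        locks[retained_myeloid == TRUE, .(chrom, start, end)], bg_pos))
      duos <- if (length(ret_chroms) && spec$n_punctate >= 2) {
        n_duo <- floor(spec$n_punctate / 2)
        blocks <- place_regions(n_duo, 6e4, sizes[ret_chroms],
                                occupied = occ, min_sep = 1.2e5)
        w1 <- round(stats::runif(n_duo, 1.5e3, 8e3))
        w2 <- round(stats::runif(n_duo, 1.5e3, 8e3))
        gap <- round(stats::runif(n_duo, 2e4, 3e4))
        rbind(data.table(chrom = blocks$chrom, start = blocks$start,
                         end = blocks$start + w1),
              data.table(chrom = blocks$chrom, start = blocks$start + w1 + gap,
                         end = blocks$start + w1 + gap + w2))
      } else data.table(chrom = character(), start = numeric(), end = numeric())
      tiny <- if (spec$n_tiny > 0) {
        place_regions(spec$n_tiny, round(stats::runif(spec$n_tiny, 300, 900)),
                      sizes, occupied = merge_intervals(bind_regions(occ, duos)),
                      min_sep = 5e4)
      } else NULL
      bind_regions(duos, tiny)
    } else data.table(chrom = character(), start = numeric(), end = numeric())
    out <- list()
    for (ct in cts) {
      segs <- list()
      if (nrow(locks)) {
        if (ct %in% broad_cts) {
          for (i in seq_len(nrow(locks))) {
            segs[[i]] <- tile_segments(locks$chrom[i], locks$start[i],
                                       locks$end[i], spec$seg_width, spec$seg_gap)
          }
        } else {
          for (i in which(locks$retained_myeloid)) {
            segs[[length(segs) + 1]] <-
              tile_segments(locks$chrom[i], locks$start[i], locks$end[i],
                            spec$seg_width, spec$seg_gap, shrink = spec$shrink)
          }
        }
      }
      segs <- rbindlist(segs)
      extra <- if (ct %in% broad_cts) {
        if (nrow(bg_pos)) {
          j <- round(stats::runif(nrow(bg_pos), -1500, 1500))
          data.table(chrom = bg_pos$chrom, start = pmax(bg_pos$start + j, 0),
                     end = bg_pos$end + j)
        } else NULL
      } else punct
      out[[ct]] <- sort_intervals(bind_regions(segs, extra))
    }
    out
  })

  ## --- H3K9me3 regions ------------------------------------------------------
  k9 <- with_seed(sub_seed(spec$seed, "k9"), {
    bg <- if (spec$n_background_k9 > 0) {
      place_regions(spec$n_background_k9,
                    round(stats::runif(spec$n_background_k9, 5e3, 2e4)),
                    sizes, occupied = locks[, .(chrom, start, end)], min_sep = 5e4)
    } else data.table(chrom = character(), start = numeric(), end = numeric())
    out <- list()
    for (ct in cts) {
      segs <- list()
      idx <- if (ct %in% broad_cts) seq_len(nrow(locks)) else which(locks$retained_myeloid)
      for (i in idx) {
        segs[[length(segs) + 1]] <-
          tile_segments(locks$chrom[i], locks$start[i], locks$end[i],
                        spec$k9_seg, spec$k9_gap,
                        shrink = if (ct %in% broad_cts) 1 else 0.5)
      }
      out[[ct]] <- sort_intervals(bind_regions(rbindlist(segs), bg))
    }
    out
  })

  ## --- LAD annotation -------------------------------------------------------
  lads <- with_seed(sub_seed(spec$seed, "lads"), {
    inlock <- rbindlist(lapply(seq_len(nrow(locks)), function(i) {
      tile_segments(locks$chrom[i], locks$start[i], locks$end[i],
                    spec$lad_seg, spec$lad_gap)
    }))
    bg <- if (spec$n_background_lads > 0) {
      place_regions(spec$n_background_lads,
                    round(stats::runif(spec$n_background_lads,
                                       spec$lad_bg_width[1], spec$lad_bg_width[2])),
                    sizes, occupied = locks[, .(chrom, start, end)], min_sep = 5e4)
    } else NULL
    sort_intervals(bind_regions(inlock, bg))
  })

  ## --- enhancer layout (before genes; genes will avoid these) ---------------
  enh <- with_seed(sub_seed(spec$seed, "enhancers"), {
    E <- spec$enh
    base_occ <- merge_intervals(locks[, .(chrom, start, end)])
    classes <- c(rep("core", E$n_core), rep("prog_shared", E$n_prog_shared),
                 unlist(lapply(mature, function(m)
                   rep(paste0("spec_", m), E$n_spec_active))),
                 rep("prog_active", E$n_prog_active),
                 rep("constitutive", E$n_constitutive),
                 rep("ineligible", E$n_ineligible),
                 rep("borderline", E$n_borderline))
    widths <- ifelse(classes == "borderline",
                     round(stats::runif(length(classes), E$width_borderline[1],
                                        E$width_borderline[2])),
                     round(stats::runif(length(classes), E$width[1], E$width[2])))
    # super-enhancer clusters: per mature cell type, move se_cluster_size *
    # n_se_clusters of its specific-active regions into contiguous blocks;
    # progenitors share n_se_prog clusters from the prog_active class
    regions <- data.table(class = classes, width = widths,
                          se_cluster = NA_character_)
    cluster_plan <- list()
    for (m in mature) {
      idx <- which(regions$class == paste0("spec_", m))
      take <- idx[seq_len(E$n_se_clusters * E$se_cluster_size)]
      for (cl in seq_len(E$n_se_clusters)) {
        mem <- take[((cl - 1) * E$se_cluster_size + 1):(cl * E$se_cluster_size)]
        cid <- sprintf("se_%s_%02d", m, cl)
        regions$se_cluster[mem] <- cid
        cluster_plan[[cid]] <- mem
      }
    }
    pidx <- which(regions$class == "prog_active")
    for (cl in seq_len(E$n_se_prog)) {
      mem <- pidx[((cl - 1) * E$se_cluster_size + 1):(cl * E$se_cluster_size)]
      cid <- sprintf("se_prog_%02d", cl)
      regions$se_cluster[mem] <- cid
      cluster_plan[[cid]] <- mem
    }
    # place cluster blocks, then singles
    occupied <- copy(base_occ)
    placed <- data.table(chrom = rep(NA_character_, nrow(regions)),
                         start = NA_real_, end = NA_real_)
    for (cid in names(cluster_plan)) {
      mem <- cluster_plan[[cid]]
      gaps <- round(stats::runif(length(mem) - 1, E$se_member_gap[1],
                                 E$se_member_gap[2]))
      span <- sum(regions$width[mem]) + sum(gaps)
      blk <- place_regions(1, span, sizes, occupied, min_sep = E$min_sep + 5e3)
      occupied <- merge_intervals(rbind(occupied, blk[, .(chrom, start, end)]))
      pos <- blk$start
      for (j in seq_along(mem)) {
        placed$chrom[mem[j]] <- blk$chrom
        placed$start[mem[j]] <- pos
        placed$end[mem[j]] <- pos + regions$width[mem[j]]
        pos <- pos + regions$width[mem[j]] + if (j < length(mem)) gaps[j] else 0
      }
    }
    singles <- which(is.na(regions$se_cluster))
    sp <- place_regions(length(singles), regions$width[singles], sizes,
                        occupied, min_sep = E$min_sep)
    placed$chrom[singles] <- sp$chrom
    placed$start[singles] <- sp$start
    placed$end[singles] <- sp$end
    regions <- cbind(regions, placed)
    regions[, planted_id := sprintf("planted_%04d", seq_len(.N))]
    # planted state truth: active/primed/none per region per cell type
    st <- matrix("none", nrow(regions), length(cts),
                 dimnames = list(regions$planted_id, cts))
    cls <- regions$class
    st[cls == "core", prog] <- "primed"
    st[cls == "core", mature] <- "active"
    st[cls == "prog_shared", setdiff(prog, reference)] <- "primed"
    st[cls == "prog_shared", mature] <- "active"
    for (m in mature) st[cls == paste0("spec_", m), m] <- "active"
    st[cls == "prog_active", prog] <- "active"
    st[cls == "constitutive", cts] <- "active"
    st[cls == "borderline", prog] <- "borderline"
    # K27ac density per kb (pre-thinning targets) and K4me1 density
    n <- nrow(regions)
    d27 <- matrix(0, n, length(cts), dimnames = dimnames(st))
    d4 <- matrix(0, n, length(cts), dimnames = dimnames(st))
    for (ct in cts) {
      is_se <- !is.na(regions$se_cluster) & st[, ct] == "active" &
        (grepl(paste0("se_", ct), regions$se_cluster, fixed = TRUE) |
           (ct %in% prog & grepl("se_prog", regions$se_cluster, fixed = TRUE)))
      d27[, ct] <- stats::runif(n, E$d_low[1], E$d_low[2])
      d27[st[, ct] == "primed", ct] <-
        stats::runif(sum(st[, ct] == "primed"), E$d_primed_k27[1], E$d_primed_k27[2])
      d27[st[, ct] == "borderline", ct] <-
        stats::runif(sum(st[, ct] == "borderline"), E$d_borderline[1], E$d_borderline[2])
      d27[st[, ct] == "active", ct] <-
        stats::runif(sum(st[, ct] == "active"), E$d_active[1], E$d_active[2])
      d27[is_se, ct] <- stats::runif(sum(is_se), E$d_se[1], E$d_se[2])
      pr <- st[, ct] %in% c("active", "primed")
      d4[, ct] <- stats::runif(n, E$d_k4_low[1], E$d_k4_low[2])
      d4[pr, ct] <- stats::runif(sum(pr), E$d_k4_high[1], E$d_k4_high[2])
    }
    list(regions = regions, states = st, d27 = d27, d4 = d4)
  })

  ## --- gene annotation (TSS windows avoid enhancer regions) -----------------
  genes <- with_seed(sub_seed(spec$seed, "genes"), {
    n <- spec$n_genes
    enh_regions <- as.data.table(enh$regions)[, .(chrom, start, end)]
    len <- pmin(pmax(round(exp(stats::rnorm(n, log(4000), 0.6))), 1000), 30000)
    draw <- function(idx) {
      ch <- sample(names(sizes), length(idx), replace = TRUE,
                   prob = sizes / sum(sizes))
      s <- floor(stats::runif(length(idx), 1e4, sizes[ch] - len[idx] - 1e4))
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      data.table(chrom = ch, start = s, end = s + len[idx], strand = strand,
                 tss = ifelse(strand == "+", s, s + len[idx]))
    }
    g <- draw(seq_len(n))
    for (it in 1:100) {
      tw <- data.table(chrom = g$chrom, start = pmax(g$tss - 2000, 0),
                       end = g$tss + 2000)
      bad <- which(overlaps_any(tw, enh_regions))
      if (!length(bad)) break
      rep_g <- draw(bad)
      for (col in names(rep_g)) data.table::set(g, bad, col, rep_g[[col]])
    }
    if (length(bad)) stop("could not place genes clear of enhancer space")
    g[, gene_id := sprintf("gene_%05d", seq_len(.N))]
    g[, gc_fraction := 0.3 + 0.45 * stats::rbeta(n, 6, 6)]
    g[, biotype := sample(c("protein_coding", "lincRNA"), n,
                          replace = TRUE, prob = c(0.9, 0.1))]
    setorderv(g, c("chrom", "start", "end", "gene_id"))
    g[, .(gene_id, chrom, strand, tss, start, end, gc_fraction, biotype)]
  })

  ## --- decoy enhancer regions straddling TSS --------------------------------
  enh <- local({
    E <- spec$enh
    dec <- with_seed(sub_seed(spec$seed, "decoys"), {
      pc <- genes[biotype == "protein_coding"]
      dg <- pc[sample(.N, E$n_decoy)]
      decoys <- data.table(class = "decoy", width = 2000,
                           se_cluster = NA_character_,
                           chrom = dg$chrom, start = pmax(dg$tss - 500, 0),
                           end = pmax(dg$tss - 500, 0) + 2000,
                           planted_id = sprintf("decoy_%03d", seq_len(nrow(dg))))
      d27d <- matrix(stats::runif(nrow(decoys) * length(cts),
                                  E$d_active[1], E$d_active[2]),
                     nrow(decoys), length(cts),
                     dimnames = list(decoys$planted_id, cts))
      d4d <- matrix(stats::runif(nrow(decoys) * length(cts),
                                 E$d_k4_high[1], E$d_k4_high[2]),
                    nrow(decoys), length(cts),
                    dimnames = list(decoys$planted_id, cts))
      list(decoys = decoys, d27 = d27d, d4 = d4d)
    })
    std <- matrix("active", nrow(dec$decoys), length(cts),
                  dimnames = list(dec$decoys$planted_id, cts))
    list(regions = rbind(enh$regions, dec$decoys),
         states = rbind(enh$states, std),
         d27 = rbind(enh$d27, dec$d27), d4 = rbind(enh$d4, dec$d4))
  })

  ## --- expression with planted DE, coupled to mark loss ---------------------
  ref_marked <- genes$gene_id[coverage_fraction(
    genes[, .(chrom, start, end)], k27[[reference]]) > 0.20]
  lost_pool <- setdiff(ref_marked, genes$gene_id[coverage_fraction(
    genes[, .(chrom, start, end)],
    locks[retained_myeloid == TRUE, .(chrom, start, end)]) > 0.20])
  expr_sim <- with_seed(sub_seed(spec$seed, "counts"), {
    n <- nrow(genes)
    silent <- sample(genes[biotype == "protein_coding", gene_id], spec$n_silent_tfs)
    de_table <- rbindlist(lapply(setdiff(cts, reference), function(ct) {
      n_up_lost <- if (ct %in% myel) round(0.4 * spec$n_de) else 0
      pool_idx <- which(genes$gene_id %in% lost_pool)
      up_lost <- if (n_up_lost > 0) sample(pool_idx, min(n_up_lost, length(pool_idx)))
                 else integer(0)
      others <- sample(setdiff(seq_len(n), c(up_lost, which(genes$gene_id %in% silent))),
                       spec$n_de - length(up_lost))
      lfc <- stats::runif(spec$n_de, spec$de_lfc_range[1], spec$de_lfc_range[2])
      sgn <- c(rep(1, length(up_lost)),
               rep_len(c(1, -1), spec$n_de - length(up_lost)))
      data.table(sample = ct, gene = c(up_lost, others), lfc = sgn * lfc)
    }))
    sim <- simulate_counts(sample_names = cts, de_table = de_table,
                           gc_bias_amplitude = spec$gc_bias_amplitude,
                           dispersion = spec$dispersion, genes = genes,
                           silent_genes = silent,
                           seed = sub_seed(spec$seed, "misc"))
    sim$silent <- silent
    sim
  })

  ## --- tracks for all marks -------------------------------------------------
  tracks <- with_seed(sub_seed(spec$seed, "tracks"), {
    bw <- spec$bin_width
    mk_track <- function(means_list, depth_slack = 1.25) {
      bins <- lapply(names(sizes), function(ch) {
        mu <- means_list[[ch]] + spec$track_background
        stats::rpois(length(mu), mu)
      })
      names(bins) <- names(sizes)
      tot <- sum(vapply(bins, sum, numeric(1)))
      signal_track(bins, bw, sizes, depth = round(tot * depth_slack))
    }
    k4me3_regions <- list(); k36_regions <- list()
    out <- list()
    for (ct in cts) {
      rpkm <- expr_sim$table$rpkm[, ct]
      expressed <- genes[rpkm > 1]
      k4me3_regions[[ct]] <- sort_intervals(data.table(
        chrom = expressed$chrom, start = pmax(expressed$tss - 1000, 0),
        end = pmin(expressed$tss + 1000, sizes[expressed$chrom])))
      k36_regions[[ct]] <- sort_intervals(expressed[, .(chrom, start, end)])
      enh_present <- enh$states[, ct] != "none"
      er <- as.data.table(enh$regions)[enh_present]
      m <- list(
        H3K27me3 = regions_to_bin_means(
          k27[[ct]], stats::runif(nrow(k27[[ct]]), spec$d_k27_track[1],
                                  spec$d_k27_track[2]), bw, sizes),
        H3K9me3 = regions_to_bin_means(
          k9[[ct]], stats::runif(nrow(k9[[ct]]), spec$d_k9_track[1],
                                 spec$d_k9_track[2]), bw, sizes),
        H3K4me3 = regions_to_bin_means(
          k4me3_regions[[ct]], stats::runif(nrow(k4me3_regions[[ct]]),
                                            spec$d_k4me3[1], spec$d_k4me3[2]),
          bw, sizes),
        H3K36me3 = regions_to_bin_means(
          k36_regions[[ct]], stats::runif(nrow(k36_regions[[ct]]),
                                          spec$d_k36[1], spec$d_k36[2]),
          bw, sizes),
        H3K27ac = regions_to_bin_means(
          er[, .(chrom, start, end)], enh$d27[enh_present, ct], bw, sizes),
        H3K4me1 = regions_to_bin_means(
          er[, .(chrom, start, end)], enh$d4[enh_present, ct], bw, sizes))
      out[[ct]] <- lapply(m, mk_track)
    }
    list(tracks = out, k4me3_regions = k4me3_regions, k36_regions = k36_regions)
  })

  ## --- marks container ------------------------------------------------------
  marks <- list()
  for (ct in cts) {
    enh_present <- enh$states[, ct] != "none"
    er <- as.data.table(enh$regions)[enh_present]
    marks[[ct]] <- list(
      H3K27me3 = list(regions = k27[[ct]], track = tracks$tracks[[ct]]$H3K27me3),
      H3K9me3 = list(regions = k9[[ct]], track = tracks$tracks[[ct]]$H3K9me3),
      H3K4me3 = list(regions = tracks$k4me3_regions[[ct]],
                     track = tracks$tracks[[ct]]$H3K4me3),
      H3K36me3 = list(regions = tracks$k36_regions[[ct]],
                      track = tracks$tracks[[ct]]$H3K36me3),
      H3K27ac = list(regions = sort_intervals(er[, .(chrom, start, end)]),
                     track = tracks$tracks[[ct]]$H3K27ac),
      H3K4me1 = list(regions = sort_intervals(er[, .(chrom, start, end)]),
                     track = tracks$tracks[[ct]]$H3K4me1))
  }

  ## --- methylation ----------------------------------------------------------
  methyl <- with_seed(sub_seed(spec$seed, "methyl"), {
    pos_bg <- data.table(
      chrom = sample(names(sizes), spec$n_cpg, replace = TRUE,
                     prob = sizes / sum(sizes)))
    pos_bg[, pos := floor(stats::runif(.N, 0, sizes[chrom]))]
    er <- as.data.table(enh$regions)
    pos_enh <- er[rep(seq_len(.N), each = spec$cpg_per_enhancer)]
    pos_enh <- data.table(chrom = pos_enh$chrom,
                          pos = floor(stats::runif(nrow(pos_enh), pos_enh$start,
                                                   pos_enh$end)))
    cpg <- unique(rbind(pos_bg, pos_enh))
    setorderv(cpg, c("chrom", "pos"))
    mb <- spec$meth_base
    m0 <- pmin(pmax(stats::rbeta(nrow(cpg), mb[["mean"]] * mb[["conc"]],
                                 (1 - mb[["mean"]]) * mb[["conc"]]), 0.25), 0.95)
    retained <- locks[retained_myeloid == TRUE, .(chrom, start, end)]
    in_retained <- if (nrow(retained)) overlaps_any(
      data.table(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 1), retained)
      else rep(FALSE, nrow(cpg))
    hypo_enh <- er[class %in% c("core", "prog_shared")]
    in_hypo_enh <- if (nrow(hypo_enh)) overlaps_any(
      data.table(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 1),
      hypo_enh[, .(chrom, start, end)]) else rep(FALSE, nrow(cpg))
    out <- list()
    for (ct in cts) {
      m <- m0
      if (ct %in% myel) m[in_retained] <- m[in_retained] - spec$lock_depression
      if (ct %in% mature) {
        m[in_hypo_enh] <- m[in_hypo_enh] - spec$enhancer_depression
      }
      m <- pmin(pmax(m + stats::rnorm(length(m), 0, spec$meth_noise_sd), 0.01), 0.99)
      out[[ct]] <- data.table(chrom = cpg$chrom, pos = cpg$pos, fraction = m,
                              coverage = 10L + stats::rpois(length(m), 20))
    }
    out
  })

  ## --- motif occurrence map -------------------------------------------------
  motifs <- with_seed(sub_seed(spec$seed, "motifs"), {
    er <- as.data.table(enh$regions)
    eligible <- er[!(class %in% c("ineligible", "decoy")), planted_id]
    pcg <- genes[biotype == "protein_coding", gene_id]
    tf_pool <- setdiff(pcg, expr_sim$silent)
    map <- list(); truth <- list()
    k <- 0
    for (m in mature) {
      for (b in seq_len(spec$n_biased_per_mature)) {
        k <- k + 1
        mid <- sprintf("motif_%02d", k)
        spec_ids <- er[class == paste0("spec_", m), planted_id]
        rid <- c(sample(spec_ids, round(0.8 * length(spec_ids))),
                 sample(setdiff(eligible, spec_ids), 3))
        tf <- sample(tf_pool, 1)
        map[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf, region_id = rid)
        truth[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf,
                                   biased_cell = m, silent = FALSE)
      }
    }
    for (s in seq_len(spec$n_silent_tfs)) {
      k <- k + 1
      mid <- sprintf("motif_%02d", k)
      rid <- sample(eligible, max(3, round(spec$motif_rate * length(eligible))))
      tf <- expr_sim$silent[s]
      map[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf, region_id = rid)
      truth[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf,
                                 biased_cell = NA_character_, silent = TRUE)
    }
    while (k < spec$n_motifs) {
      k <- k + 1
      mid <- sprintf("motif_%02d", k)
      rid <- eligible[stats::runif(length(eligible)) < spec$motif_rate]
      if (!length(rid)) rid <- sample(eligible, 3)
      tf <- sample(tf_pool, 1)
      map[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf, region_id = rid)
      truth[[mid]] <- data.table(motif_id = mid, tf_gene_id = tf,
                                 biased_cell = NA_character_, silent = FALSE)
    }
    list(map = rbindlist(map), truth = rbindlist(truth))
  })

  ## --- ground-truth ledger --------------------------------------------------
  er <- as.data.table(enh$regions)
  truth <- list(
    locks = locks,
    lock_carriers = c(stats::setNames(rep(list(locks$lock_id), length(broad_cts)),
                                      broad_cts),
                      stats::setNames(rep(list(locks[retained_myeloid == TRUE, lock_id]),
                                          length(myel)), myel)),
    de = expr_sim$truth,
    silent_tfs = expr_sim$silent,
    marked_reference = ref_marked,
    lost_pool = lost_pool,
    enh = list(regions = er, states = enh$states,
               eligible = !(er$class %in% c("ineligible", "decoy")),
               borderline = er$class == "borderline",
               se_clusters = er[!is.na(se_cluster),
                                .(planted_id, se_cluster, chrom, start, end, class)],
               spec_in_se_fraction = spec$enh$n_se_clusters *
                 spec$enh$se_cluster_size / spec$enh$n_spec_active),
    methyl = list(lock_depression = spec$lock_depression,
                  enhancer_depression = spec$enhancer_depression,
                  depressed_lock_regions = locks[retained_myeloid == TRUE,
                                                 .(chrom, start, end)],
                  hypo_enhancer_ids = er[class %in% c("core", "prog_shared"),
                                         planted_id]),
    motifs = motifs$truth)

  structure(list(spec = spec, chrom_sizes = sizes,
                 cell_types = spec$cell_types, reference = reference,
                 marks = marks, expression = expr_sim$table,
                 methyl = methyl, genes = genes, lads = lads,
                 motif_map = motifs$map, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d cell types, %d genes, %d true LOCKs, ",
                     "%d enhancer regions, genome %.0f Mb\n"),
              nrow(x$cell_types), nrow(x$genes), nrow(x$truth$locks),
              nrow(x$truth$enh$regions), sum(x$chrom_sizes) / 1e6))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the formats the readers accept: BED per cell type and mark,
#' bedGraph tracks (non-zero bins), methylation bedGraph, gene annotation
#' TSV, expression TSV, LAD BED, motif map TSV, plus a manifest JSON listing
#' every file and the ground-truth ledger path.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (ct in names(cohort$marks)) {
    for (mk in names(cohort$marks[[ct]])) {
      f <- file.path(dir, sprintf("%s.%s.regions.bed", ct, mk))
      write_bed(cohort$marks[[ct]][[mk]]$regions, f)
      files[[sprintf("regions.%s.%s", ct, mk)]] <- basename(f)
      tr <- cohort$marks[[ct]][[mk]]$track
      bg <- rbindlist(lapply(names(tr$bins), function(ch) {
        v <- tr$bins[[ch]]
        nz <- which(v > 0)
        data.table(chrom = ch, start = (nz - 1) * tr$bin_width,
                   end = nz * tr$bin_width, value = v[nz])
      }))
      f <- file.path(dir, sprintf("%s.%s.track.bedgraph", ct, mk))
      write_bedgraph(bg, f)
      files[[sprintf("track.%s.%s", ct, mk)]] <- basename(f)
    }
    f <- file.path(dir, sprintf("%s.methyl.bedgraph", ct))
    write_methyl_bedgraph(cohort$methyl[[ct]], f)
    files[[paste0("methyl.", ct)]] <- basename(f)
  }
  write_gene_annotation(cohort$genes, file.path(dir, "genes.tsv"))
  write_expression_table(cohort$expression, file.path(dir, "expression.tsv"))
  write_bed(cohort$lads, file.path(dir, "lads.bed"))
  write_motif_map(cohort$motif_map, file.path(dir, "motif_map.tsv"))
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_file, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  files$genes <- "genes.tsv"; files$expression <- "expression.tsv"
  files$lads <- "lads.bed"; files$motif_map <- "motif_map.tsv"
  files$truth <- "truth.json"
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(chrom_sizes = as.list(cohort$chrom_sizes),
                            bin_width = cohort$spec$bin_width,
                            seed = cohort$spec$seed, files = files),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
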