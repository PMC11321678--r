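#' Default copy-number simulation scenario
#'
#' The standard conditions used to exercise the CNV module: a 3 x 60 Mb
#' genome, 200 diploid reference cells (the immune-cell stand-in) and 400
#' tumour cells from one clone carrying a copy-4 segment (chr2:10-30 Mb) and
#' a copy-1 segment (chr3:20-40 Mb), each spanning several 10-Mb windows,
#' with GC coverage bias switched on and a mean depth of 8,000 fragments per
#' cell.
#'
#' @param seed Integer seed.
#' @param n_reference,n_tumor Cells per group.
#' @param depth_mean Mean fragments per cell.
#' @param gc_bias_strength GC bias strength (see [expected_tile_rates()]).
#' @return List with genome, groups_spec, cnv_segments, fragments, truth.
#' @export
default_cnv_scenario <- function(seed = 1, n_reference = 200, n_tumor = 400,
                                 depth_mean = 8000, gc_bias_strength = 1) {
  genome <- generate_genome(n_chrom = 3, chrom_length_bp = 60e6,
                            tile_size = 500, gc_smoothness = 2000,
                            seed = derive_seed(seed, "genome"))
  groups_spec <- data.frame(
    group = c("reference", "tumor"),
    reference = c(TRUE, FALSE),
    clone = c(NA, "clone1"),
    stringsAsFactors = FALSE
  )
  cnv_segments <- data.frame(
    clone = "clone1",
    chrom = c("chr2", "chr3"),
    start = c(10e6, 20e6),
    end = c(30e6, 40e6),
    copy_number = c(4, 1),
    stringsAsFactors = FALSE
  )
  sim <- simulate_fragments(
    genome, groups_spec = groups_spec,
    n_cells_per_group = c(reference = n_reference, tumor = n_tumor),
    depth_mean = depth_mean, cnv_segments = cnv_segments,
    gc_bias_strength = gc_bias_strength,
    seed = derive_seed(seed, "fragments")
  )
  list(genome = genome, groups_spec = groups_spec, cnv_segments = cnv_segments,
       fragments = sim$fragments, truth = sim$truth)
}

#' Default regulatory-circuit simulation scenario
#'
#' The standard conditions used to exercise the motif-deviation, marker,
#' co-accessibility and network modules: a compact 3 x 12 Mb genome with 94
#' genes, of which 4 are programme TFs (each with its own motif), 40 are
#' decoy TFs (motifs with sites only in background peaks, no programme) and
#' each programme drives 5 target genes (2 of them neurotransmitter-receptor
#' genes) through their promoter peaks plus 8 distal peaks. Each programme
#' is active in two tumour cell groups at graded strength (`effect_size` and
#' `(1 + effect_size) / 2`), mirroring the several-clusters-per-subgroup
#' structure of real data and giving the cluster-level correlations enough
#' points; one diploid reference group completes the design.
#'
#' @param seed Integer seed.
#' @param n_reference Cells in the reference group.
#' @param n_cells_per_group Cells per tumour group (8 groups).
#' @param depth_mean Mean fragments per cell.
#' @param effect_size Accessibility multiplier of an active programme.
#' @param gc_bias_strength GC bias strength.
#' @return List with genome, genes, peaks, motif_sites, motifs, programs,
#'   groups_spec, fragments, truth.
#' @export
default_regulatory_scenario <- function(seed = 1, n_reference = 150,
                                        n_cells_per_group = 75,
                                        depth_mean = 2500, effect_size = 3,
                                        gc_bias_strength = 0.5) {
  genome <- generate_genome(n_chrom = 3, chrom_length_bp = 12e6,
                            tile_size = 500, gc_smoothness = 500,
                            n_blacklist = 0,
                            seed = derive_seed(seed, "genome"))
  reg <- build_regulatory_truth(genome, seed = derive_seed(seed, "truth"),
                                effect_size = effect_size)

  groups <- c("reference", as.vector(t(outer(paste0("g", 1:4), c("hi", "lo"), paste0))))
  groups_spec <- data.frame(
    group = groups,
    reference = groups == "reference",
    clone = NA_character_,
    stringsAsFactors = FALSE
  )
  n_cells <- setNames(c(n_reference, rep(n_cells_per_group, 8)), groups)

  # housekeeping accessibility structure shared by every group: peaks are
  # open (x20 over background) and promoters more so (a further x4), which
  # reproduces the TSS enrichment and reads-in-peaks features real QC
  # relies on
  genes <- reg$genes
  housekeeping <- list(
    list(program_id = "open_peaks", planted = FALSE,
         intervals = reg$peaks[, c("chrom", "start", "end")],
         effects = setNames(rep(20, length(groups)), groups)),
    list(program_id = "open_promoters", planted = FALSE,
         intervals = data.frame(chrom = genes$chrom,
                                start = pmax(0, genes$tss - 500),
                                end = genes$tss + 500),
         effects = setNames(rep(4, length(groups)), groups))
  )

  sim <- simulate_fragments(
    genome, genes = reg$genes, groups_spec = groups_spec,
    n_cells_per_group = n_cells, depth_mean = depth_mean,
    tf_programs = c(reg$programs, housekeeping),
    gc_bias_strength = gc_bias_strength,
    seed = derive_seed(seed, "fragments")
  )

  c(list(genome = genome, groups_spec = groups_spec,
         fragments = sim$fragments, truth = sim$truth),
    reg)
}

# genes, peaks, motif sites and TF programmes for the regulatory scenario
build_regulatory_truth <- function(genome, seed = 1, effect_size = 3,
                                   n_programs = 4, targets_per_program = 5,
                                   ntr_per_program = 2, n_decoy_tfs = 40,
                                   distal_per_program = 8,
                                   n_background_peaks = 150,
                                   sites_per_decoy = 10) {
  n_targets <- n_programs * targets_per_program
  n_genes <- n_programs + n_decoy_tfs + n_targets + 30
  genes <- generate_gene_models(genome, n_genes = n_genes,
                                length_range = c(5e3, 15e3),
                                margin_bp = 3e5,
                                seed = derive_seed(seed, "genes"))

  withr::with_seed(derive_seed(seed, "roles"), {
    ord <- sample.int(n_genes)
    tf_idx <- ord[seq_len(n_programs)]
    decoy_tf_idx <- ord[n_programs + seq_len(n_decoy_tfs)]
    target_idx <- ord[n_programs + n_decoy_tfs + seq_len(n_targets)]
  })
  genes$is_tf[c(tf_idx, decoy_tf_idx)] <- TRUE
  genes$motif_id[tf_idx] <- sprintf("MOTIF_P%d", seq_len(n_programs))
  genes$motif_id[decoy_tf_idx] <- sprintf("MOTIF_D%02d", seq_len(n_decoy_tfs))
  target_sets <- split(target_idx, rep(seq_len(n_programs), each = targets_per_program))
  for (p in seq_len(n_programs)) {
    genes$is_ntr[target_sets[[p]][seq_len(ntr_per_program)]] <- TRUE
  }

  # promoter peaks for every gene
  prom <- data.frame(chrom = genes$chrom, start = pmax(0, genes$tss - 250),
                     end = genes$tss + 250, stringsAsFactors = FALSE)
  prom$peak_id <- sprintf("prom_%s", genes$gene_id)
  prom$kind <- "promoter"

  # distal programme peaks near the targets, offsets well inside the 100-kb
  # gene window but outside the +/-5 kb promoter flank
  offsets <- c(-80e3, -55e3, -30e3, -15e3, 15e3, 30e3, 55e3, 80e3)
  distal <- do.call(rbind, lapply(seq_len(n_programs), function(p) {
    tgt <- target_sets[[p]]
    anchor_gene <- rep(tgt, length.out = distal_per_program)
    off <- offsets[seq_len(distal_per_program)]
    pos <- genes$tss[anchor_gene] + off
    pos <- pmax(500, pmin(pos, chrom_length(genome, genes$chrom[anchor_gene]) - 1000))
    data.frame(chrom = genes$chrom[anchor_gene], start = pos, end = pos + 500,
               peak_id = sprintf("distal_p%d_%02d", p, seq_len(distal_per_program)),
               kind = sprintf("distal_p%d", p), stringsAsFactors = FALSE)
  }))

  # background peaks, kept >= 20 kb away from every TSS
  withr::with_seed(derive_seed(seed, "background"), {
    bg_list <- list()
    tries <- 0L
    while (length(bg_list) < n_background_peaks && tries < 50L) {
      tries <- tries + 1L
      ci <- sample.int(nrow(genome$chromosomes), 1)
      len <- genome$chromosomes$length[ci]
      s <- sample.int(len - 1000, 1)
      same <- genes$chrom == genome$chromosomes$chrom[ci]
      if (any(abs(genes$tss[same] - s) < 20e3)) next
      bg_list[[length(bg_list) + 1L]] <- data.frame(
        chrom = genome$chromosomes$chrom[ci], start = s, end = s + 500,
        stringsAsFactors = FALSE)
      tries <- 0L
    }
    bg <- do.call(rbind, bg_list)
  })
  bg$peak_id <- sprintf("bg_%03d", seq_len(nrow(bg)))
  bg$kind <- "background"

  peaks <- rbind(prom, distal, bg)
  # drop later peaks that overlap an earlier one (keeps the matrix columns
  # disjoint, which downstream counting assumes)
  gr <- as_granges0(peaks)
  keep <- rep(TRUE, nrow(peaks))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep[unique(qi[qi > si])] <- FALSE
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL

  # motif sites: programme motifs in their target promoters + distal peaks,
  # decoy motifs in random background peaks
  site_in_peak <- function(pk, motif) {
    mid <- floor((pk$start + pk$end) / 2)
    data.frame(chrom = pk$chrom, start = mid - 5, end = mid + 5,
               motif_id = motif, stringsAsFactors = FALSE)
  }
  sites <- list()
  for (p in seq_len(n_programs)) {
    tgt_prom <- peaks[peaks$peak_id %in% sprintf("prom_%s", genes$gene_id[target_sets[[p]]]), ]
    dst <- peaks[peaks$kind == sprintf("distal_p%d", p), ]
    sites[[length(sites) + 1L]] <- site_in_peak(rbind(tgt_prom, dst),
                                                sprintf("MOTIF_P%d", p))
  }
  withr::with_seed(derive_seed(seed, "decoysites"), {
    bg_kept <- peaks[peaks$kind == "background", ]
    for (d in seq_len(n_decoy_tfs)) {
      pick <- bg_kept[sample.int(nrow(bg_kept), min(sites_per_decoy, nrow(bg_kept))), ]
      sites[[length(sites) + 1L]] <- site_in_peak(pick, sprintf("MOTIF_D%02d", d))
    }
  })
  motif_sites <- do.call(rbind, sites)
  motif_sites <- motif_sites[order(motif_sites$chrom, motif_sites$start), ]
  rownames(motif_sites) <- NULL

  # programmes: boosted intervals are the programme peaks plus the target
  # and TF gene bodies (so gene scores and motif deviations co-vary)
  programs <- lapply(seq_len(n_programs), function(p) {
    tgt <- target_sets[[p]]
    tf <- tf_idx[p]
    pk <- peaks[peaks$kind == sprintf("distal_p%d", p) |
                  peaks$peak_id %in% sprintf("prom_%s", genes$gene_id[tgt]), ]
    iv <- rbind(
      pk[, c("chrom", "start", "end")],
      data.frame(chrom = genes$chrom[c(tgt, tf)],
                 start = pmax(0, genes$start[c(tgt, tf)] - 2000),
                 end = genes$end[c(tgt, tf)] + 2000)
    )
    list(
      program_id = sprintf("P%d", p),
      planted = TRUE,
      motif_id = sprintf("MOTIF_P%d", p),
      tf_gene = genes$gene_id[tf],
      targets = genes$gene_id[tgt],
      ntr_targets = genes$gene_id[intersect(tgt, which(genes$is_ntr))],
      peak_ids = pk$peak_id,
      intervals = iv,
      effects = setNames(c(effect_size, (1 + effect_size) / 2),
                         paste0("g", p, c("hi", "lo")))
    )
  })

  list(genes = genes, peaks = peaks[, c("peak_id", "chrom", "start", "end", "kind")],
       motif_sites = motif_sites,
       motifs = sort(unique(motif_sites$motif_id)),
       programs = programs)
}

#' Simulate a bulk expression cohort with planted subgroups
#'
#' Emulates a large tumour cohort profiled over a fixed catalogue of
#' neurotransmitter-receptor genes. Each group elevates a disjoint block of
#' marker genes by `effect_size` over standard Gaussian noise; the last two
#' groups additionally share an elevated block (and carry smaller private
#' blocks), so that forcing one cluster fewer merges exactly that pair --
#' the Group3/Group4 analogue.
#'
#' @param n_samples Number of samples (default 763).
#' @param n_ntr_genes Number of genes (default 94).
#' @param k_groups Number of planted groups (>= 2, default 4).
#' @param effect_size Mean shift of a group's marker block (>= 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List with `expression` (samples x genes matrix), `labels`
#'   (integer planted group per sample) and `marker_blocks` (list of marker
#'   gene names per group, plus the shared block).
#' @export
simulate_cohort <- function(n_samples = 763, n_ntr_genes = 94, k_groups = 4,
                            effect_size = 5, noise_sd = 1, seed = 1) {
  if (k_groups < 2) stopf("'k_groups' must be >= 2")
  if (n_ntr_genes < k_groups) stopf("'n_ntr_genes' must be >= k_groups")
  if (effect_size < 0) stopf("'effect_size' must be >= 0")
  genes <- sprintf("NTR%03d", seq_len(n_ntr_genes))

  # disjoint private blocks; the last two groups get somewhat smaller
  # private blocks plus one shared block. The shared block is kept smaller
  # than the pair's private blocks so the pair is the closest two groups
  # (they merge first when one cluster fewer is forced) while all four
  # groups remain individually separable.
  base <- max(3L, n_ntr_genes %/% (k_groups + 1L))
  sizes <- rep(base, k_groups)
  shared_size <- 0L
  if (k_groups >= 2) {
    sizes[(k_groups - 1):k_groups] <- max(2L, (2L * base) %/% 3L)
    shared_size <- max(2L, base %/% 3L)
  }
  idx <- 1L
  blocks <- vector("list", k_groups)
  for (g in seq_len(k_groups)) {
    blocks[[g]] <- genes[idx:(idx + sizes[g] - 1L)]
    idx <- idx + sizes[g]
  }
  shared <- if (shared_size > 0 && idx + shared_size - 1L <= n_ntr_genes) {
    genes[idx:(idx + shared_size - 1L)]
  } else character(0)

  withr::with_seed(seed, {
    labels <- sort(rep_len(seq_len(k_groups), n_samples))
    labels <- sample(labels)
    x <- matrix(rnorm(n_samples * n_ntr_genes, sd = noise_sd),
                nrow = n_samples, dimnames = list(sprintf("S%04d", seq_len(n_samples)), genes))
  })
  for (g in seq_len(k_groups)) {
    x[labels == g, blocks[[g]]] <- x[labels == g, blocks[[g]]] + effect_size
  }
  if (length(shared)) {
    pair <- labels %in% c(k_groups - 1L, k_groups)
    x[pair, shared] <- x[pair, shared] + effect_size
  }
  list(expression = x, labels = labels,
       marker_blocks = c(setNames(blocks, paste0("group", seq_len(k_groups))),
                         list(shared = shared)))
}
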