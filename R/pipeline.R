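#' Default pipeline configuration
#'
#' Returns the full configuration template for [run_pipeline()]: global
#' seed, output directory, per-stage enable flags, and stage parameters
#' (all defaults match the package's documented conventions). Unknown keys
#' in a user-supplied configuration are rejected by [run_pipeline()].
#'
#' @param outdir Run directory.
#' @param seed Global seed; every stochastic stage derives its own sub-seed
#'   from it and the stage name.
#' @return Nested named list.
#' @export
pipeline_config <- function(outdir = "mbcircuits_run", seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    stages = list(simulate = TRUE, qc = TRUE, matrices = TRUE, cnv = TRUE,
                  motifs = TRUE, circuits = TRUE, classify = TRUE),
    simulate = list(n_reference = 100, n_cells_per_group = 50,
                    depth_mean = 2500, effect_size = 3, gc_bias_strength = 0.5),
    qc = list(min_fragments = 1000, min_tss = 4, top_n_by_tss = 12000),
    matrices = list(tile_size = 500, window_bp = 1e5, decay_bp = 5000,
                    n_dims = 15, n_clusters = 9, n_features = 10000),
    cnv = list(width = 10e6, step = 2e6, k = 4, pseudocount = 1,
               threshold = 1, min_consecutive = 2),
    motifs = list(n_background = 50, n_neighbors = 50),
    circuits = list(max_dist = 250000, cor_cut = 0.5, k_agg = 20,
                    r_cut = 0.5, padj_cut = 0.01, delta_quantile = 0.75,
                    promoter_flank = 5000),
    classify = list(n_samples = 763, n_ntr_genes = 94, k_groups = 4,
                    effect_size = 5, noise_sd = 1, k_range = 2:8)
  )
}

merge_config <- function(user, template, path = "config") {
  if (is.null(user)) return(template)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) stopf("unknown %s key(s): %s", path,
                             paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    template[[nm]] <- if (is.list(template[[nm]]) && is.list(user[[nm]])) {
      merge_config(user[[nm]], template[[nm]], paste0(path, "$", nm))
    } else user[[nm]]
  }
  template
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate, qc, matrices, then
#' cnv and motifs, then circuits, then classify), writing each stage's
#' outputs and a deterministic JSON manifest (per-stage seeds, file
#' checksums and matrix dimensions) into the run directory. The cnv stage
#' is independent of circuits: disabling it does not block downstream
#' stages. Re-running with the same configuration reproduces the manifest
#' byte for byte.
#'
#' @param config A configuration list (see [pipeline_config()]), a path to
#'   a YAML file with the same structure, or NULL for the defaults.
#' @param outdir Optional override of the configured run directory.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, pipeline_config())
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("mbcircuits")),
                   seed = cfg$seed, stages = list())
  paths <- function(...) file.path(cfg$outdir, ...)

  record <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- c(list(
      complete = TRUE,
      seed = derive_seed(cfg$seed, stage),
      files = lapply(setNames(files, basename(files)), function(f)
        unname(tools::md5sum(f)))
    ), info)
  }
  require_stage <- function(stage, needed) {
    missing <- needed[!vapply(needed, function(s)
      isTRUE(manifest$stages[[s]]$complete), logical(1))]
    if (length(missing))
      stopf("stage '%s' needs stage '%s' to run first", stage, missing[1])
  }

  scen <- NULL; kept <- NULL; tiles <- NULL; gscore <- NULL; lsi <- NULL
  pmat <- NULL; mpm <- NULL; dev <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    scen <- do.call(default_regulatory_scenario,
                    c(list(seed = derive_seed(cfg$seed, "simulate")),
                      cfg$simulate))
    write_fragments(scen$fragments, paths("fragments.tsv.gz"))
    data.table::fwrite(scen$genes, paths("genes.tsv"), sep = "\t")
    data.table::fwrite(scen$peaks, paths("peaks.bed"), sep = "\t", col.names = FALSE)
    data.table::fwrite(scen$motif_sites, paths("motif_sites.bed"), sep = "\t",
                       col.names = FALSE)
    jsonlite::write_json(
      list(cells = scen$truth$cells,
           programs = lapply(scen$programs, function(p)
             p[c("program_id", "motif_id", "tf_gene", "targets")])),
      paths("truth.json"), auto_unbox = TRUE, digits = NA)
    record("simulate", paths(c("fragments.tsv.gz", "genes.tsv", "peaks.bed",
                               "motif_sites.bed", "truth.json")),
           list(n_cells = nrow(scen$truth$cells), n_fragments = nrow(scen$fragments)))
  }

  if (isTRUE(cfg$stages$qc)) {
    require_stage("qc", "simulate")
    qc <- compute_cell_qc(scen$fragments, scen$genes)
    kept <- filter_cells(qc, cfg$qc$min_fragments, cfg$qc$min_tss,
                         cfg$qc$top_n_by_tss)
    qc$passed <- qc$barcode %in% kept
    data.table::fwrite(qc, paths("cell_qc.tsv"), sep = "\t")
    record("qc", paths("cell_qc.tsv"),
           list(n_cells = nrow(qc), n_kept = length(kept)))
  }

  if (isTRUE(cfg$stages$matrices)) {
    require_stage("matrices", c("simulate", "qc"))
    tiles <- build_tile_matrix(scen$fragments, scen$genome, kept,
                               tile_size = cfg$matrices$tile_size)
    gscore <- compute_gene_scores(tiles, scen$genes,
                                  window_bp = cfg$matrices$window_bp,
                                  decay_bp = cfg$matrices$decay_bp)
    lsi <- lsi_cluster(tiles, n_dims = cfg$matrices$n_dims,
                       n_clusters = cfg$matrices$n_clusters,
                       seed = derive_seed(cfg$seed, "matrices"),
                       n_features = cfg$matrices$n_features)
    Matrix::writeMM(tiles$counts, paths("tile_matrix.mtx"))
    data.table::fwrite(data.table::data.table(barcode = rownames(tiles$counts)),
                       paths("tile_matrix_cells.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(gscore$scores), paths("gene_scores.tsv"),
                       sep = "\t")
    data.table::fwrite(data.table::data.table(barcode = rownames(tiles$counts),
                                              cluster = lsi$labels),
                       paths("clusters.tsv"), sep = "\t")
    record("matrices", paths(c("tile_matrix.mtx", "tile_matrix_cells.tsv",
                               "gene_scores.tsv", "clusters.tsv")),
           list(n_cells = nrow(tiles$counts), n_tiles = ncol(tiles$counts)))
  }

  if (isTRUE(cfg$stages$cnv)) {
    require_stage("cnv", c("simulate", "matrices"))
    win <- make_cnv_windows(scen$genome, width = cfg$cnv$width,
                            step = cfg$cnv$step)
    cw <- count_window_reads(tiles, win)
    raw <- gc_matched_log2fc(cw, win, k = cfg$cnv$k,
                             pseudocount = cfg$cnv$pseudocount)
    ref <- scen$truth$cells$barcode[scen$truth$cells$reference]
    cnv <- reference_correct_and_call(raw, win, ref,
                                      threshold = cfg$cnv$threshold,
                                      min_consecutive = cfg$cnv$min_consecutive)
    data.table::fwrite(as.data.frame(cnv$corrected), paths("cnv_matrix.tsv"),
                       sep = "\t", row.names = TRUE)
    data.table::fwrite(win, paths("cnv_windows.bed"), sep = "\t")
    record("cnv", paths(c("cnv_matrix.tsv", "cnv_windows.bed")),
           list(n_windows = sum(win$kept)))
  }

  if (isTRUE(cfg$stages$motifs)) {
    require_stage("motifs", c("simulate", "matrices"))
    pmat <- build_peak_matrix(scen$fragments, scen$peaks, kept)
    mpm <- annotate_motif_peaks(pmat$peaks, scen$motif_sites)
    dev <- compute_deviations(pmat, mpm, scen$genome,
                              n_background = cfg$motifs$n_background,
                              n_neighbors = cfg$motifs$n_neighbors,
                              seed = derive_seed(cfg$seed, "motifs"))
    data.table::fwrite(as.data.frame(dev$raw), paths("deviations.tsv"),
                       sep = "\t", row.names = TRUE)
    data.table::fwrite(as.data.frame(dev$z), paths("deviations_z.tsv"),
                       sep = "\t", row.names = TRUE)
    record("motifs", paths(c("deviations.tsv", "deviations_z.tsv")),
           list(n_motifs = nrow(dev$raw)))
  }

  if (isTRUE(cfg$stages$circuits)) {
    require_stage("circuits", c("simulate", "matrices", "motifs"))
    truth_groups <- scen$truth$cells$group[match(rownames(tiles$counts),
                                                 scen$truth$cells$barcode)]
    links <- co_accessibility(pmat, lsi$embedding,
                              max_dist = cfg$circuits$max_dist,
                              cor_cut = cfg$circuits$cor_cut,
                              k_agg = cfg$circuits$k_agg,
                              seed = derive_seed(cfg$seed, "circuits"))
    ccans <- assemble_ccans(links, scen$genes)
    regs <- identify_positive_regulators(gscore, dev, truth_groups, scen$genes,
                                         r_cut = cfg$circuits$r_cut,
                                         padj_cut = cfg$circuits$padj_cut,
                                         delta_quantile = cfg$circuits$delta_quantile)
    screen <- correlation_screen(gscore, dev, truth_groups,
                                 r_cut = cfg$circuits$r_cut,
                                 padj_cut = cfg$circuits$padj_cut)
    net <- build_tf_target_network(regs, screen, mpm, scen$genes, ccans,
                                   promoter_flank = cfg$circuits$promoter_flank)
    ntr <- extract_ntr_circuit(net, scen$genes$gene_id[scen$genes$is_ntr])
    data.table::fwrite(as.data.frame(links), paths("coaccess_links.tsv"), sep = "\t")
    data.table::fwrite(regs, paths("regulators.tsv"), sep = "\t")
    data.table::fwrite(net$edges, paths("network_edges.tsv"), sep = "\t")
    data.table::fwrite(ntr$edges, paths("ntr_network_edges.tsv"), sep = "\t")
    record("circuits", paths(c("coaccess_links.tsv", "regulators.tsv",
                               "network_edges.tsv", "ntr_network_edges.tsv")),
           list(n_links = nrow(links), n_positive = sum(regs$positive),
                n_edges = nrow(net$edges)))
  }

  if (isTRUE(cfg$stages$classify)) {
    sim <- simulate_cohort(n_samples = cfg$classify$n_samples,
                           n_ntr_genes = cfg$classify$n_ntr_genes,
                           k_groups = cfg$classify$k_groups,
                           effect_size = cfg$classify$effect_size,
                           noise_sd = cfg$classify$noise_sd,
                           seed = derive_seed(cfg$seed, "classify"))
    cohort <- normalize_cohort(sim$expression, colnames(sim$expression))
    res <- cluster_cohort(cohort, k_range = cfg$classify$k_range,
                          seed = derive_seed(cfg$seed, "classify"))
    markers <- anova_marker_genes(cohort, res$labels)
    data.table::fwrite(data.table::data.table(sample = rownames(cohort$z),
                                              cluster = res$labels,
                                              planted = sim$labels),
                       paths("cohort_labels.tsv"), sep = "\t")
    data.table::fwrite(res$silhouette, paths("cohort_silhouette.tsv"), sep = "\t")
    data.table::fwrite(markers, paths("cohort_markers.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(res$centroids), paths("cohort_centroids.tsv"),
                       sep = "\t")
    record("classify", paths(c("cohort_labels.tsv", "cohort_silhouette.tsv",
                               "cohort_markers.tsv", "cohort_centroids.tsv")),
           list(chosen_k = res$k))
  }

  jsonlite::write_json(manifest, paths("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
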