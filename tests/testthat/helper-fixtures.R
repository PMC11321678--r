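# Shared fixtures, built lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

# the default regulatory scenario plus the standard analysis objects
# derived from it (tile/peak/gene-score matrices, motif annotation,
# deviations, group labels)
reg_fixture <- function() {
  if (!is.null(.fixtures$reg)) return(.fixtures$reg)
  scen <- default_regulatory_scenario(seed = 42)
  cells <- scen$truth$cells$barcode
  tm <- build_tile_matrix(scen$fragments, scen$genome, cells)
  pm <- build_peak_matrix(scen$fragments, scen$peaks, cells)
  gs <- compute_gene_scores(tm, scen$genes)
  mpm <- annotate_motif_peaks(pm$peaks, scen$motif_sites)
  dev <- compute_deviations(pm, mpm, scen$genome, seed = 99)
  labels <- scen$truth$cells$group[match(rownames(pm$counts),
                                         scen$truth$cells$barcode)]
  .fixtures$reg <- c(scen, list(tm = tm, pm = pm, gs = gs, mpm = mpm,
                                dev = dev, labels = labels))
  .fixtures$reg
}

flat_genome <- function(len = 1e6, n_chrom = 1) {
  generate_genome(n_chrom = n_chrom, chrom_length_bp = len,
                  gc_smoothness = 1e9, n_blacklist = 0, seed = 7)
}

# quick fragment table constructor
frags <- function(chrom, start, end, barcode = "BC1", count = 1) {
  data.table::data.table(chrom = chrom, start = as.numeric(start),
                         end = as.numeric(end), barcode = barcode,
                         count = as.numeric(count))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force insertion-in-interval counter (the O(n*m) oracle)
brute_force_peak_counts <- function(fragments, peaks, barcodes) {
  out <- matrix(0, length(barcodes), nrow(peaks),
                dimnames = list(barcodes, peaks$peak_id))
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    for (pos in c(f$start, f$end - 1)) {
      for (j in seq_len(nrow(peaks))) {
        if (peaks$chrom[j] == f$chrom && pos >= peaks$start[j] &&
            pos < peaks$end[j]) {
          out[f$barcode, j] <- out[f$barcode, j] + f$count
        }
      }
    }
  }
  out
}
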