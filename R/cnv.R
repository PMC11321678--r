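#' Sliding copy-number windows with blacklist and GC filtering
#'
#' Tiles each chromosome into overlapping windows (default 10 Mb, 2 Mb
#' step). Window starts advance while `start < length - width + step`, so a
#' truncated trailing window (width > width - step) appears only when the
#' chromosome length minus the width is not a step multiple; truncated
#' windows shorter than half the nominal width are dropped. A window is then
#' excluded when the blacklist covers more than `max_blacklist_frac` of it
#' or its GC fraction falls below `min_gc` (default: the 5th percentile of
#' window GC, removing the low-GC tail where composition bias produces
#' false-positive copy-number signal).
#'
#' @param genome A `GenomeSpec`.
#' @param width Window width in bp (default 10 Mb).
#' @param step Window step in bp (default 2 Mb).
#' @param blacklist Interval data.frame (chrom, start, end); defaults to the
#'   genome's own blacklist.
#' @param min_gc GC threshold; `NULL` uses the 5th percentile.
#' @param max_blacklist_frac Maximum tolerated blacklist coverage.
#' @return A `CnvWindowSet` data.frame: window, chrom, start, end, gc,
#'   blacklist_frac, kept.
#' @export
make_cnv_windows <- function(genome, width = 10e6, step = 2e6,
                             blacklist = genome$blacklist, min_gc = NULL,
                             max_blacklist_frac = 0.5) {
  check_positive(width, "width")
  check_positive(step, "step")
  if (width < step) stopf("'width' must be >= 'step'")
  if (all(genome$chromosomes$length < width))
    stopf("genome shorter than one window")

  win <- data.table::rbindlist(lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    if (len < width) return(NULL)
    starts <- seq(0, len, by = step)
    starts <- starts[starts < len - width + step]
    ends <- pmin(starts + width, len)
    data.table::data.table(chrom = genome$chromosomes$chrom[i],
                           start = starts, end = ends)
  }))
  win <- win[(end - start) >= width / 2]
  win[, window := .I]
  win[, gc := region_gc(genome, .SD), .SDcols = c("chrom", "start", "end")]
  win[, blacklist_frac := coverage_fraction(as.data.frame(win), blacklist)]
  if (is.null(min_gc)) min_gc <- as.numeric(quantile(win$gc, 0.05))
  win[, kept := blacklist_frac <= max_blacklist_frac & gc >= min_gc]
  out <- as.data.frame(win[, .(window, chrom, start, end, gc, blacklist_frac, kept)])
  class(out) <- c("CnvWindowSet", "data.frame")
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

#' Insertion counts per copy-number window
#'
#' Aggregates per-cell insertion counts over each kept window. Windows
#' overlap, so a shared insertion contributes to every window containing
#' it; the windows are not a partition of the genome.
#'
#' @param x A `TileMatrix` (tile width must divide the window step) or a
#'   fragments table plus `genome`.
#' @param windows A `CnvWindowSet`.
#' @param genome Required when `x` is a fragments table.
#' @return Dense cells x kept-windows matrix; columns named by window id.
#' @export
count_window_reads <- function(x, windows, genome = NULL) {
  kept <- windows[windows$kept, , drop = FALSE]
  if (nrow(kept) == 0L) stopf("no kept windows; lower the filters")
  if (!inherits(x, "TileMatrix")) {
    if (is.null(genome)) stopf("'genome' is required when counting from fragments")
    barcodes <- sort(unique(x$barcode))
    x <- build_tile_matrix(x, genome, barcodes)
  }
  tiles <- x$tiles
  trip <- lapply(seq_len(nrow(kept)), function(j) {
    idx <- tiles[chrom == kept$chrom[j] & start >= kept$start[j] &
                   end <= kept$end[j], tile]
    cbind(idx, rep(j, length(idx)))
  })
  trip <- do.call(rbind, trip)
  agg <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = 1,
                              dims = c(nrow(tiles), nrow(kept)))
  counts <- as.matrix(x$counts %*% agg)
  colnames(counts) <- as.character(kept$window)
  counts
}

#' GC-matched log2 coverage ratios
#'
#' For each cell and window, the raw log2 fold change compares the window's
#' count to the mean count over the `k` other kept windows with the most
#' similar GC content (the window itself is excluded from its own
#' background; GC ties break by genomic order). A pseudocount guards
#' against empty windows at single-cell sparsity.
#'
#' @param counts Cells x kept-windows matrix from [count_window_reads()].
#' @param windows The `CnvWindowSet` the counts were made from.
#' @param k Number of GC-matched background windows (default 100).
#' @param pseudocount Added to numerator count and background mean.
#' @return Cells x windows matrix of raw log2 fold changes.
#' @export
gc_matched_log2fc <- function(counts, windows, k = 100, pseudocount = 1) {
  kept <- windows[windows$kept, , drop = FALSE]
  nw <- nrow(kept)
  if (ncol(counts) != nw) stopf("counts do not match the kept windows")
  if (nw < k + 1) stopf("only %d kept windows; need at least k + 1 = %d (lower k)",
                        nw, k + 1)
  # background selector: k nearest-GC windows per window, self excluded
  sel <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nw, nw))
  trip <- lapply(seq_len(nw), function(w) {
    d <- abs(kept$gc - kept$gc[w])
    ord <- order(d, kept$window)          # ties by genomic order
    ord <- ord[ord != w][seq_len(k)]
    cbind(ord, rep(w, k))
  })
  trip <- do.call(rbind, trip)
  sel <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = 1 / k,
                              dims = c(nw, nw))
  bg <- as.matrix(counts %*% sel)
  log2((counts + pseudocount) / (bg + pseudocount))
}

#' Reference-corrected copy-number matrix and gain/loss calls
#'
#' Subtracts the per-window mean of the reference (diploid) cells' raw
#' log2 fold changes from every cell, then calls a window `gain` when the
#' corrected value exceeds `threshold` and `loss` below `-threshold`
#' (symmetric deletion rule). Runs of fewer than `min_consecutive`
#' same-signed calls within a chromosome are smoothed to neutral, since a
#' single called window on an overlapping 10 Mb / 2 Mb grid is almost
#' always noise; set `min_consecutive = 1` for the unsmoothed rule.
#'
#' @param raw Cells x windows raw log2FC matrix.
#' @param windows The `CnvWindowSet`.
#' @param reference_cells Barcodes of the diploid reference population.
#' @param threshold Call threshold on the corrected log2 ratio (default 1,
#'   the candidate-amplification rule; see the methods vignette for the
#'   operating point used in single-copy recovery analyses).
#' @param min_consecutive Minimum run length of a call (default 2).
#' @return A `CnvMatrix`: list with `raw`, `corrected`, `call` (-1/0/+1
#'   cells x windows), `windows`, `reference_cells`, `threshold`.
#' @export
reference_correct_and_call <- function(raw, windows, reference_cells,
                                       threshold = 1, min_consecutive = 2) {
  ref <- intersect(reference_cells, rownames(raw))
  if (length(ref) == 0L) stopf("empty reference cell set")
  ref_mean <- colMeans(raw[ref, , drop = FALSE])
  corrected <- sweep(raw, 2, ref_mean)

  call <- matrix(0L, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  call[corrected > threshold] <- 1L
  call[corrected < -threshold] <- -1L

  kept <- windows[windows$kept, , drop = FALSE]
  if (min_consecutive > 1L) {
    for (ch in unique(kept$chrom)) {
      cols <- which(kept$chrom == ch)
      if (length(cols) < 2L) { call[, cols] <- 0L; next }
      block <- call[, cols, drop = FALSE]
      for (i in seq_len(nrow(block))) {
        r <- rle(block[i, ])
        r$values[r$values != 0L & r$lengths < min_consecutive] <- 0L
        block[i, ] <- inverse.rle(r)
      }
      call[, cols] <- block
    }
  }
  structure(list(raw = raw, corrected = corrected, call = call,
                 windows = windows, reference_cells = ref,
                 threshold = threshold),
            class = "CnvMatrix")
}

#' @export
print.CnvMatrix <- function(x, ...) {
  cat("CnvMatrix:", nrow(x$corrected), "cells x", ncol(x$corrected),
      "windows;", sum(x$call == 1L), "gain and", sum(x$call == -1L),
      "loss calls\n")
  invisible(x)
}

# per-window planted truth state: +1 inside a gain segment, -1 inside a
# loss, 0 outside all segments, NA for boundary (partially overlapping)
# windows, which have intermediate expected coverage by construction
window_truth_states <- function(windows, segments) {
  kept <- windows[windows$kept, , drop = FALSE]
  state <- rep(0L, nrow(kept))
  if (is.null(segments) || nrow(segments) == 0L) return(state)
  for (j in seq_len(nrow(segments))) {
    s <- segments[j, ]
    overl <- kept$chrom == s$chrom & kept$end > s$start & kept$start < s$end
    full <- overl & kept$start >= s$start & kept$end <= s$end
    dir <- if (s$copy_number > 2) 1L else if (s$copy_number < 2) -1L else 0L
    state[full] <- dir
    state[overl & !full] <- NA_integer_
  }
  state
}

#' Score planted copy-number recovery
#'
#' Compares per-cell window calls of the non-reference cells against the
#' planted clone segments. Windows fully inside a segment are positives
#' (signed by gain/loss), windows not touching any segment are negatives,
#' and boundary windows that partially overlap a segment are excluded from
#' scoring, since at 10-Mb window resolution their expected coverage is
#' intermediate and no truth state applies.
#'
#' @param cnv A `CnvMatrix`.
#' @param truth A `TruthSet` with `cells` and `cnv_segments`.
#' @return List with precision, recall, and the count table.
#' @export
evaluate_cnv_calls <- function(cnv, truth) {
  cells <- truth$cells
  tumor <- cells$barcode[!cells$reference]
  tumor <- intersect(tumor, rownames(cnv$call))
  clones <- cells$clone[match(tumor, cells$barcode)]
  tp <- fp <- fn <- 0L
  for (cl in unique(clones)) {
    segs <- truth$cnv_segments[truth$cnv_segments$clone == cl, , drop = FALSE]
    state <- window_truth_states(cnv$windows, segs)
    calls <- cnv$call[tumor[clones == cl], , drop = FALSE]
    scored <- !is.na(state)
    truth_m <- matrix(state[scored], nrow(calls), sum(scored), byrow = TRUE)
    calls <- calls[, scored, drop = FALSE]
    tp <- tp + sum(calls != 0L & calls == truth_m)
    fp <- fp + sum(calls != 0L & calls != truth_m)
    fn <- fn + sum(calls == 0L & truth_m != 0L)
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
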