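#' Binary motif-by-peak membership matrix
#'
#' Marks a motif as present in a peak when at least one of its site
#' intervals shares at least 1 bp with the peak (half-open intervals, so
#' abutting intervals do not overlap). Site lists are inputs; no sequence
#' scanning is performed.
#'
#' @param peaks Peak table (peak_id, chrom, start, end).
#' @param motif_sites data.frame chrom, start, end, motif_id.
#' @param motifs Optional motif catalogue; sites with a motif_id outside it
#'   raise an error.
#' @return A `MotifPeakMatrix`: list with `membership` (sparse binary
#'   motifs x peaks), `motifs`, `peaks` and the retained `sites`.
#' @export
annotate_motif_peaks <- function(peaks, motif_sites, motifs = NULL) {
  peaks <- as.data.frame(peaks)
  motif_sites <- as.data.frame(motif_sites)
  if (is.null(motifs)) motifs <- sort(unique(motif_sites$motif_id))
  unknown <- setdiff(unique(motif_sites$motif_id), motifs)
  if (length(unknown)) stopf("motif id(s) absent from catalogue: %s",
                             paste(unknown, collapse = ", "))
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)

  hits <- GenomicRanges::findOverlaps(as_granges0(motif_sites), as_granges0(peaks))
  mi <- match(motif_sites$motif_id[S4Vectors::queryHits(hits)], motifs)
  pj <- S4Vectors::subjectHits(hits)
  pair <- unique(cbind(mi, pj))
  membership <- Matrix::sparseMatrix(
    i = pair[, 1], j = pair[, 2], x = 1,
    dims = c(length(motifs), nrow(peaks)),
    dimnames = list(motifs, peaks$peak_id)
  )
  structure(list(membership = membership, motifs = motifs, peaks = peaks,
                 sites = motif_sites),
            class = "MotifPeakMatrix")
}

#' @export
print.MotifPeakMatrix <- function(x, ...) {
  cat("MotifPeakMatrix:", nrow(x$membership), "motifs x", ncol(x$membership),
      "peaks,", sum(x$membership), "memberships\n")
  invisible(x)
}

#' Hypergeometric motif enrichment in marker peaks
#'
#' Tests, per motif, whether motif-bearing peaks are over-represented among
#' a cluster's marker peaks relative to the full peak set: upper-tail
#' hypergeometric p-value on the 2x2 table, odds ratio, and BH adjustment
#' across motifs.
#'
#' @param motif_peaks A `MotifPeakMatrix`.
#' @param marker_peaks Character vector of marker peak ids (subset of all
#'   peaks).
#' @param all_peaks Optional universe; defaults to the matrix columns.
#' @return data.frame motif, n_marker_with, n_marker, n_with, n_total,
#'   odds_ratio, p, q (BH), sorted by p.
#' @export
motif_enrichment_in_markers <- function(motif_peaks, marker_peaks,
                                        all_peaks = NULL) {
  M <- motif_peaks$membership
  if (is.null(all_peaks)) all_peaks <- colnames(M)
  if (!all(marker_peaks %in% all_peaks))
    stopf("marker peaks must be a subset of all peaks")
  if (length(marker_peaks) == 0L)
    return(data.frame(motif = character(0), n_marker_with = integer(0),
                      n_marker = integer(0), n_with = integer(0),
                      n_total = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  M <- M[, all_peaks, drop = FALSE]
  n_total <- length(all_peaks)
  n_marker <- length(marker_peaks)
  in_marker <- colnames(M) %in% marker_peaks

  n_with <- Matrix::rowSums(M)
  a <- Matrix::rowSums(M[, in_marker, drop = FALSE])
  b <- n_marker - a
  c_ <- n_with - a
  d <- n_total - n_marker - c_
  odds <- ifelse(b * c_ > 0, (a * d) / (b * c_),
                 ifelse(a * d > 0, Inf, ifelse(a == 0, 0, 1)))
  # motif in every peak carries no information: odds ratio 1 by convention
  odds[n_with == n_total] <- 1
  p <- phyper(a - 1, n_with, n_total - n_with, n_marker, lower.tail = FALSE)
  out <- data.frame(motif = rownames(M), n_marker_with = as.integer(a),
                    n_marker = n_marker, n_with = as.integer(n_with),
                    n_total = n_total, odds_ratio = odds, p = p,
                    q = p.adjust(p, "BH"), row.names = NULL)
  out[order(out$p, out$motif), ]
}

#' Per-cell motif accessibility deviations and background z-scores
#'
#' For motif m and cell c, the expected insertion count is
#' `f_m * T_c`, where `f_m` is the fraction of all insertions falling in
#' motif-m peaks and `T_c` the cell's total; the raw deviation is
#' `(observed - expected) / expected`, so it sums to zero over cells for
#' every motif, exactly. Each deviation is then z-scored against
#' `n_background` matched background peak sets, built by replacing every
#' motif peak with one sampled from its nearest neighbours in standardised
#' (GC, log1p mean accessibility) space.
#'
#' @param peak_matrix A `PeakMatrix` (counts used as-is, not binarised).
#' @param motif_peaks A `MotifPeakMatrix` on the same peaks.
#' @param peak_gc Per-peak GC fraction (same order as the peak matrix
#'   columns); computed with [region_gc()] if a genome is given instead.
#' @param n_background Number of background sets (default 50).
#' @param n_neighbors Size of the matched-neighbour pool per peak (default
#'   50).
#' @param seed Integer seed for background sampling.
#' @return A `DeviationMatrix`: list with `raw` and `z` (motifs x cells),
#'   `dropped` (motifs with zero expectation), `n_background`, `seed`.
#' @export
compute_deviations <- function(peak_matrix, motif_peaks, peak_gc,
                               n_background = 50, n_neighbors = 50, seed = 1) {
  X <- peak_matrix$counts                      # cells x peaks
  M <- motif_peaks$membership                  # motifs x peaks
  if (ncol(X) != ncol(M)) stopf("peak matrix and motif matrix disagree on peaks")
  if (inherits(peak_gc, "GenomeSpec")) peak_gc <- region_gc(peak_gc, peak_matrix$peaks)
  if (length(peak_gc) != ncol(X)) stopf("'peak_gc' must have one value per peak")

  T_c <- Matrix::rowSums(X)
  peak_tot <- Matrix::colSums(X)
  grand <- sum(T_c)
  Xt <- Matrix::t(X)                           # peaks x cells

  f <- as.numeric(M %*% peak_tot) / grand
  dropped <- rownames(M)[f == 0]
  if (length(dropped)) {
    warnf("dropping %d motif(s) with zero expected counts: %s",
          length(dropped), paste(dropped, collapse = ", "))
    M <- M[f > 0, , drop = FALSE]
    f <- f[f > 0]
  }
  obs <- as.matrix(M %*% Xt)
  expected <- f %o% T_c
  raw <- (obs - expected) / expected

  # matched background pool: nearest neighbours in standardised
  # (GC, log1p mean accessibility) space, self included
  feats <- cbind(scale(peak_gc), scale(log1p(peak_tot / nrow(X))))
  feats[is.na(feats)] <- 0
  np <- ncol(X)
  kn <- min(n_neighbors, np)
  d2 <- as.matrix(dist(feats))
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(kn)]))

  s1 <- matrix(0, nrow(raw), ncol(raw))
  s2 <- matrix(0, nrow(raw), ncol(raw))
  withr::with_seed(seed, {
    for (b in seq_len(n_background)) {
      map <- nn[cbind(seq_len(np), sample.int(kn, np, replace = TRUE))]
      P <- Matrix::sparseMatrix(i = seq_len(np), j = map, x = 1, dims = c(np, np))
      Mb <- M %*% P
      fb <- as.numeric(Mb %*% peak_tot) / grand
      fb[fb == 0] <- .Machine$double.eps
      raw_b <- (as.matrix(Mb %*% Xt) - fb %o% T_c) / (fb %o% T_c)
      s1 <- s1 + raw_b
      s2 <- s2 + raw_b^2
    }
  })
  mu <- s1 / n_background
  sigma <- sqrt(pmax(s2 / n_background - mu^2, 0))
  z <- (raw - mu) / sigma
  z[sigma == 0] <- NA_real_
  dimnames(raw) <- dimnames(z) <- list(rownames(M), rownames(X))
  structure(list(raw = raw, z = z, dropped = dropped,
                 n_background = n_background, seed = seed),
            class = "DeviationMatrix")
}

#' @export
print.DeviationMatrix <- function(x, ...) {
  cat("DeviationMatrix:", nrow(x$raw), "motifs x", ncol(x$raw), "cells (",
      x$n_background, "background sets )\n")
  invisible(x)
}
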