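#' Marker features per cluster
#'
#' For every cluster with at least 3 cells, each feature is tested cluster
#' vs all other cells with a two-sided rank-sum test (tie- and
#' continuity-corrected normal approximation), and the log2 fold change of
#' means is computed with pseudocount 1. P-values are BH-adjusted within
#' each cluster; a feature is a marker when `fdr <= fdr_cut` and
#' `log2fc >= lfc_cut`.
#'
#' @param x Cells x features matrix (or `TileMatrix`/`PeakMatrix`/
#'   `GeneScoreMatrix`).
#' @param labels Cluster label per cell.
#' @param fdr_cut FDR threshold (default 0.01).
#' @param lfc_cut log2 fold-change threshold (default 0.5).
#' @return data.frame feature, cluster, log2fc, p, fdr, is_marker.
#' @export
marker_features <- function(x, labels, fdr_cut = 0.01, lfc_cut = 0.5) {
  m <- extract_counts(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stopf("one label per cell is required")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stopf("at least 2 clusters are required")

  dense <- as.matrix(m)
  n <- nrow(dense)
  ranks <- apply(dense, 2, rank)
  # tie correction term per feature for the rank-sum variance
  tie_term <- apply(dense, 2, function(v) {
    t <- table(v); sum(t^3 - t)
  })

  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- n - n1
    if (n1 < 3L) { warnf("cluster '%s' has fewer than 3 cells; skipped", cl); next }
    w <- colSums(ranks[in_cl, , drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
    z[sigma2 == 0] <- 0
    p <- 2 * pnorm(-abs(z))
    mean_in <- colMeans(dense[in_cl, , drop = FALSE])
    mean_out <- colMeans(dense[!in_cl, , drop = FALSE])
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    fdr <- p.adjust(p, "BH")
    out[[cl]] <- data.frame(feature = colnames(dense), cluster = cl,
                            log2fc = lfc, p = p, fdr = fdr,
                            is_marker = fdr <= fdr_cut & lfc >= lfc_cut,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

extract_counts <- function(x) {
  if (inherits(x, c("TileMatrix", "PeakMatrix"))) x$counts
  else if (inherits(x, "GeneScoreMatrix")) x$scores
  else x
}

#' Cis-co-accessibility links between peak pairs
#'
#' Cells are aggregated once into pseudo-bulk groups of about `k_agg` cells
#' by greedy nearest-neighbour grouping in the embedding (each cell
#' assigned exactly once), the aggregate profiles are depth-normalised and
#' log1p-transformed, and the Pearson correlation is computed for every
#' peak pair on the same chromosome whose midpoints lie within `max_dist`.
#' Pairs with correlation at or above `cor_cut` become links.
#'
#' @param peak_matrix A `PeakMatrix`.
#' @param embedding Cells x dims matrix (e.g. from [lsi_cluster()]).
#' @param max_dist Maximum midpoint distance in bp (default 250000).
#' @param cor_cut Correlation threshold (default 0.5).
#' @param k_agg Pseudo-bulk group size (default 20).
#' @param seed Integer seed for the grouping order.
#' @return A `CoAccessLinks` data.frame: peak_a, peak_b (canonical genomic
#'   order), cor, dist; the peak table is attached as an attribute.
#' @export
co_accessibility <- function(peak_matrix, embedding, max_dist = 250000,
                             cor_cut = 0.5, k_agg = 20, seed = 1) {
  if (max_dist <= 0) stopf("'max_dist' must be positive")
  X <- peak_matrix$counts
  nc <- nrow(X)
  if (nc < k_agg) stopf("need at least k_agg cells")

  # greedy KNN pseudo-bulk grouping, each cell once
  D <- as.matrix(dist(embedding))
  group <- integer(nc)
  withr::with_seed(seed, ord <- sample.int(nc))
  g <- 0L
  for (i in ord) {
    if (group[i] != 0L) next
    g <- g + 1L
    free <- which(group == 0L)
    take <- free[order(D[i, free])][seq_len(min(k_agg, length(free)))]
    group[take] <- g
  }
  agg <- rowsum(as.matrix(X), group)
  depth <- rowSums(agg)
  depth[depth == 0] <- 1
  prof <- log1p(agg / depth * 1e4)

  peaks <- peak_matrix$peaks
  mid <- (peaks$start + peaks$end) / 2
  pairs <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    if (length(idx) < 2L) next
    idx <- idx[order(mid[idx])]
    for (a in seq_len(length(idx) - 1L)) {
      b <- a + 1L
      while (b <= length(idx) && mid[idx[b]] - mid[idx[a]] <= max_dist) {
        pairs[[length(pairs) + 1L]] <- c(idx[a], idx[b])
        b <- b + 1L
      }
    }
  }
  if (!length(pairs)) {
    links <- data.frame(peak_a = character(0), peak_b = character(0),
                        cor = numeric(0), dist = numeric(0))
  } else {
    pm <- do.call(rbind, pairs)
    r <- vapply(seq_len(nrow(pm)), function(i) {
      suppressWarnings(cor(prof[, pm[i, 1]], prof[, pm[i, 2]]))
    }, numeric(1))
    links <- data.frame(peak_a = peaks$peak_id[pm[, 1]],
                        peak_b = peaks$peak_id[pm[, 2]],
                        cor = r, dist = abs(mid[pm[, 2]] - mid[pm[, 1]]))
    links <- links[!is.na(links$cor) & links$cor >= cor_cut, , drop = FALSE]
    rownames(links) <- NULL
  }
  class(links) <- c("CoAccessLinks", "data.frame")
  attr(links, "peaks") <- peaks
  attr(links, "k_agg") <- k_agg
  links
}

#' Assemble CCANs and link genes to candidate regulatory elements
#'
#' Builds the co-accessibility graph's connected components (CCANs). A gene
#' is linked to a component when one of the component's peaks overlaps the
#' gene's promoter (TSS plus `promoter_window`); the component's other
#' members become the gene's distal candidate cis-regulatory elements.
#'
#' @param links A `CoAccessLinks` table.
#' @param genes Gene table with tss.
#' @param promoter_window Offsets around the TSS defining the promoter
#'   (default c(-2000, 2000)).
#' @return A `CCANSet`: list with `membership` (peak_id, ccan), `ccres`
#'   (gene_id, ccan, peak_id, distal) and `gene_links` (gene_id, ccan,
#'   n_ccre).
#' @export
assemble_ccans <- function(links, genes, promoter_window = c(-2000, 2000)) {
  peaks <- attr(links, "peaks")
  if (nrow(links) == 0L) {
    return(structure(list(membership = data.frame(peak_id = character(0), ccan = integer(0)),
                          ccres = data.frame(gene_id = character(0), ccan = integer(0),
                                             peak_id = character(0), distal = logical(0)),
                          gene_links = data.frame(gene_id = character(0), ccan = integer(0),
                                                  n_ccre = integer(0))),
                     class = "CCANSet"))
  }
  gr <- igraph::graph_from_data_frame(links[, c("peak_a", "peak_b")], directed = FALSE)
  comp <- igraph::components(gr)
  membership <- data.frame(peak_id = names(comp$membership),
                           ccan = as.integer(comp$membership), row.names = NULL)

  member_peaks <- peaks[match(membership$peak_id, peaks$peak_id), , drop = FALSE]
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss + promoter_window[1]),
                     end = genes$tss + promoter_window[2] + 1)
  hits <- GenomicRanges::findOverlaps(as_granges0(member_peaks), as_granges0(prom))

  ccres <- list()
  if (length(hits)) {
    prom_df <- data.frame(gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                          ccan = membership$ccan[S4Vectors::queryHits(hits)],
                          promoter_peak = membership$peak_id[S4Vectors::queryHits(hits)],
                          stringsAsFactors = FALSE)
    prom_df <- unique(prom_df[, c("gene_id", "ccan")])
    for (i in seq_len(nrow(prom_df))) {
      members <- membership$peak_id[membership$ccan == prom_df$ccan[i]]
      # distal members: those not overlapping this gene's promoter
      gp <- membership$peak_id[S4Vectors::queryHits(hits)][
        genes$gene_id[S4Vectors::subjectHits(hits)] == prom_df$gene_id[i]]
      ccres[[i]] <- data.frame(gene_id = prom_df$gene_id[i],
                               ccan = prom_df$ccan[i], peak_id = members,
                               distal = !(members %in% gp),
                               stringsAsFactors = FALSE)
    }
  }
  ccres <- if (length(ccres)) do.call(rbind, ccres) else
    data.frame(gene_id = character(0), ccan = integer(0),
               peak_id = character(0), distal = logical(0))
  gene_links <- if (nrow(ccres)) {
    agg <- aggregate(distal ~ gene_id + ccan, data = ccres, FUN = sum)
    names(agg)[3] <- "n_ccre"
    agg
  } else data.frame(gene_id = character(0), ccan = integer(0), n_ccre = integer(0))

  structure(list(membership = membership, ccres = ccres, gene_links = gene_links),
            class = "CCANSet")
}

#' @export
print.CCANSet <- function(x, ...) {
  cat("CCANSet:", length(unique(x$membership$ccan)), "CCANs over",
      nrow(x$membership), "peaks;", length(unique(x$ccres$gene_id)),
      "linked genes\n")
  invisible(x)
}

#' Identify positive TF regulators
#'
#' For every TF gene with a motif, correlates the cluster-mean gene
#' activity score (expression proxy) with the cluster-mean motif deviation
#' z-score (binding-activity proxy) across clusters. A TF is a positive
#' regulator when the correlation is strictly above the correlation
#' cut-off, the BH-adjusted p-value is below `padj_cut`, and the motif
#' delta (max minus min cluster-mean z) reaches the `delta_quantile` of
#' all tested TFs' deltas.
#'
#' @param gene_scores `GeneScoreMatrix` or cells x genes matrix.
#' @param deviations `DeviationMatrix` or motifs x cells z-score matrix.
#' @param cluster_labels Cluster label per cell.
#' @param genes Gene table with is_tf and motif_id, mapping TFs to motifs.
#' @param r_cut Correlation cut-off (strict, default 0.5).
#' @param padj_cut BH-adjusted p cut-off (default 0.01).
#' @param delta_quantile Delta quantile rule (default 0.75).
#' @return A `RegulatorTable` data.frame: tf, motif, r, p, padj, delta,
#'   positive, reason.
#' @export
identify_positive_regulators <- function(gene_scores, deviations,
                                         cluster_labels, genes, r_cut = 0.5,
                                         padj_cut = 0.01,
                                         delta_quantile = 0.75) {
  gs <- extract_counts(gene_scores)
  z <- if (inherits(deviations, "DeviationMatrix")) deviations$z else deviations
  labels <- as.character(cluster_labels)
  if (length(unique(labels)) < 3L) stopf("at least 3 clusters are required")

  tfs <- genes[genes$is_tf & !is.na(genes$motif_id), , drop = FALSE]
  tfs <- tfs[tfs$gene_id %in% colnames(gs) & tfs$motif_id %in% rownames(z), ,
             drop = FALSE]
  gm <- cluster_means(gs[, tfs$gene_id, drop = FALSE], labels)   # tf x clusters
  zm <- cluster_means(Matrix::t(z[tfs$motif_id, , drop = FALSE]), labels)
  k <- ncol(gm)

  r <- vapply(seq_len(nrow(tfs)), function(i) {
    suppressWarnings(cor(gm[i, ], zm[i, ]))
  }, numeric(1))
  delta <- apply(zm, 1, max) - apply(zm, 1, min)
  p <- cor_pvalue(r, k)
  p[is.na(r)] <- NA
  padj <- p.adjust(p, "BH")
  delta_cut <- as.numeric(quantile(delta, delta_quantile, na.rm = TRUE))

  reason <- rep("", nrow(tfs))
  reason[is.na(r)] <- "constant cluster means"
  reason[!is.na(r) & r <= r_cut] <- "correlation below cut-off"
  ok_r <- !is.na(r) & r > r_cut
  reason[ok_r & padj >= padj_cut] <- "not significant"
  reason[ok_r & padj < padj_cut & delta < delta_cut] <- "low motif delta"
  positive <- ok_r & !is.na(padj) & padj < padj_cut & delta >= delta_cut
  reason[positive] <- "positive"

  out <- data.frame(tf = tfs$gene_id, motif = tfs$motif_id, r = r, p = p,
                    padj = padj, delta = delta, positive = positive,
                    reason = reason, row.names = NULL)
  class(out) <- c("RegulatorTable", "data.frame")
  attr(out, "delta_cut") <- delta_cut
  out
}

#' Exhaustive gene-by-motif correlation screen
#'
#' Pairs every gene with every motif and computes the Pearson correlation
#' of their cluster-mean profiles, with BH adjustment across all pairs. A
#' pair is kept when its correlation exceeds `r_cut` (strictly) and its
#' adjusted p-value is below `padj_cut`.
#'
#' @inheritParams identify_positive_regulators
#' @return data.frame gene, motif, r, p, padj, kept with attribute
#'   `n_pairs` (= genes x motifs, the exhaustive enumeration size).
#' @export
correlation_screen <- function(gene_scores, deviations, cluster_labels,
                               r_cut = 0.5, padj_cut = 0.01) {
  gs <- extract_counts(gene_scores)
  z <- if (inherits(deviations, "DeviationMatrix")) deviations$z else deviations
  labels <- as.character(cluster_labels)
  gm <- cluster_means(gs, labels)                     # genes x clusters
  zm <- cluster_means(Matrix::t(z), labels)           # motifs x clusters
  k <- ncol(gm)

  r <- suppressWarnings(cor(t(gm), t(zm)))            # genes x motifs
  p <- cor_pvalue(r, k)
  p[is.na(r)] <- NA
  padj <- matrix(p.adjust(p, "BH"), nrow(p), ncol(p), dimnames = dimnames(p))
  out <- data.frame(
    gene = rep(rownames(r), times = ncol(r)),
    motif = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), padj = as.vector(padj),
    row.names = NULL
  )
  out$kept <- !is.na(out$r) & out$r > r_cut & !is.na(out$padj) & out$padj < padj_cut
  attr(out, "n_pairs") <- screen_pair_count(nrow(gm), nrow(zm))
  out
}

#' Size of the exhaustive gene-motif pairing
#'
#' The correlation screen enumerates every gene paired with every motif;
#' this returns that count (`n_genes * n_motifs`) for a catalogue of given
#' dimensions.
#'
#' @param n_genes,n_motifs Catalogue sizes (positive integers).
#' @return The exact pair count as a numeric scalar.
#' @examples
#' screen_pair_count(23274, 870)
#' @export
screen_pair_count <- function(n_genes, n_motifs) {
  check_positive(n_genes, "n_genes")
  check_positive(n_motifs, "n_motifs")
  as.numeric(n_genes) * as.numeric(n_motifs)
}

#' Assemble the directed TF-to-target network
#'
#' Draws an edge from a positive TF to a gene when (i) a peak within
#' `promoter_flank` of the gene's TSS carries the TF's motif, or a distal
#' candidate regulatory element of the gene (from the CCANs) carries it,
#' and (ii) the (gene, motif) pair passes the correlation screen. Every
#' edge therefore holds both motif-location and correlation evidence.
#'
#' @param regulators A `RegulatorTable`.
#' @param screen Output of [correlation_screen()].
#' @param motif_peaks A `MotifPeakMatrix`.
#' @param genes Gene table.
#' @param ccans Optional `CCANSet` providing distal elements.
#' @param promoter_flank Promoter half-width in bp (default 5000).
#' @return A `CircuitGraph`: list with `edges` (tf, target, motif,
#'   evidence, r) and `graph` (igraph object).
#' @export
build_tf_target_network <- function(regulators, screen, motif_peaks, genes,
                                    ccans = NULL, promoter_flank = 5000) {
  pos <- regulators[regulators$positive, , drop = FALSE]
  M <- motif_peaks$membership
  peaks <- motif_peaks$peaks
  kept_pairs <- screen[screen$kept, c("gene", "motif", "r")]

  edges <- list()
  for (i in seq_len(nrow(pos))) {
    motif <- pos$motif[i]
    if (!motif %in% rownames(M) || sum(M[motif, ]) == 0) {
      warnf("TF '%s' has no motif sites; no edges contributed", pos$tf[i])
      next
    }
    motif_peak_ids <- colnames(M)[M[motif, ] > 0]

    # promoter evidence: motif-bearing peak within TSS +/- flank
    prom <- data.frame(chrom = genes$chrom,
                       start = pmax(0, genes$tss - promoter_flank),
                       end = genes$tss + promoter_flank + 1)
    mp <- peaks[peaks$peak_id %in% motif_peak_ids, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(as_granges0(mp), as_granges0(prom))
    prom_genes <- unique(genes$gene_id[S4Vectors::subjectHits(hits)])

    # distal evidence: motif-bearing distal cCRE of the gene
    distal_genes <- character(0)
    if (!is.null(ccans) && nrow(ccans$ccres)) {
      dd <- ccans$ccres[ccans$ccres$distal & ccans$ccres$peak_id %in% motif_peak_ids, ]
      distal_genes <- unique(dd$gene_id)
    }

    cand <- union(prom_genes, distal_genes)
    pair_ok <- kept_pairs[kept_pairs$motif == motif & kept_pairs$gene %in% cand, ]
    if (!nrow(pair_ok)) next
    ev <- ifelse(pair_ok$gene %in% prom_genes & pair_ok$gene %in% distal_genes,
                 "promoter-motif;distal-motif",
                 ifelse(pair_ok$gene %in% prom_genes, "promoter-motif", "distal-motif"))
    edges[[length(edges) + 1L]] <- data.frame(
      tf = pos$tf[i], target = pair_ok$gene, motif = motif,
      evidence = ev, r = pair_ok$r, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(0), target = character(0), motif = character(0),
               evidence = character(0), r = numeric(0))
  rownames(edges) <- NULL
  graph <- if (nrow(edges)) {
    igraph::graph_from_data_frame(edges[, c("tf", "target")], directed = TRUE)
  } else igraph::make_empty_graph(directed = TRUE)
  structure(list(edges = edges, graph = graph), class = "CircuitGraph")
}

#' @export
print.CircuitGraph <- function(x, ...) {
  cat("CircuitGraph:", nrow(x$edges), "edges from",
      length(unique(x$edges$tf)), "TF(s)\n")
  invisible(x)
}

#' Restrict a circuit graph to neurotransmitter-receptor targets
#'
#' @param graph A `CircuitGraph`.
#' @param ntr_gene_ids Character vector of NTR gene ids.
#' @return A `CircuitGraph` containing only edges whose target is an NTR
#'   gene; TFs without NTR targets are dropped.
#' @export
extract_ntr_circuit <- function(graph, ntr_gene_ids) {
  edges <- graph$edges[graph$edges$target %in% ntr_gene_ids, , drop = FALSE]
  rownames(edges) <- NULL
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(edges[, c("tf", "target")], directed = TRUE)
  } else igraph::make_empty_graph(directed = TRUE)
  structure(list(edges = edges, graph = g), class = "CircuitGraph")
}

#' Fraction of query peaks overlapping a reference interval set
#'
#' A query peak counts as overlapping when it shares at least 1 bp with any
#' reference interval (half-open coordinates). Used to validate peak sets
#' against external catalogues such as H3K27ac-marked enhancers.
#'
#' @param query_peaks,reference_intervals data.frames with chrom, start,
#'   end (0-based half-open).
#' @return List with `n_overlapping` and `fraction`.
#' @export
interval_overlap_fraction <- function(query_peaks, reference_intervals) {
  if (is.null(query_peaks) || nrow(query_peaks) == 0L)
    stopf("empty query set: overlap fraction undefined")
  n <- sum(GenomicRanges::countOverlaps(as_granges0(query_peaks),
                                        as_granges0(reference_intervals)) > 0)
  list(n_overlapping = n, fraction = n / nrow(query_peaks))
}

#' Assign each cluster the best-matching gene signature
#'
#' Gene scores are z-scored per gene across cells; each cluster receives
#' the signature whose member genes have the highest mean z in that
#' cluster. Ties break alphabetically and are flagged; clusters with no
#' scorable signature genes are labelled "unassigned".
#'
#' @param gene_scores `GeneScoreMatrix` or cells x genes matrix.
#' @param cluster_labels Cluster label per cell.
#' @param signature_sets Named list of gene-id vectors (each with >= 2
#'   genes present in the matrix).
#' @return data.frame cluster, label, score, tie.
#' @export
annotate_clusters_by_signature <- function(gene_scores, cluster_labels,
                                           signature_sets) {
  gs <- extract_counts(gene_scores)
  labels <- as.character(cluster_labels)
  z <- scale(as.matrix(gs))
  ok_gene <- colnames(gs)[!is.na(colSums(z))]
  present <- lapply(signature_sets, intersect, ok_gene)
  if (any(vapply(present, length, 1L) >= 1 & vapply(present, length, 1L) < 2))
    stopf("every signature needs at least 2 scorable genes")

  clusters <- sort(unique(labels))
  out <- lapply(clusters, function(cl) {
    zc <- z[labels == cl, , drop = FALSE]
    sig_scores <- vapply(present, function(g) {
      if (length(g) < 2) return(NA_real_)
      mean(zc[, g, drop = FALSE])
    }, numeric(1))
    if (all(is.na(sig_scores)))
      return(data.frame(cluster = cl, label = "unassigned", score = NA_real_,
                        tie = FALSE))
    best <- max(sig_scores, na.rm = TRUE)
    hit <- sort(names(sig_scores)[!is.na(sig_scores) & sig_scores == best])
    data.frame(cluster = cl, label = hit[1], score = best,
               tie = length(hit) > 1)
  })
  do.call(rbind, out)
}
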