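#' Normalise a cohort expression matrix over the NTR catalogue
#'
#' Restricts the expression matrix to the neurotransmitter-receptor gene
#' list (missing genes dropped with a warning), removes zero-variance
#' genes, and z-scores each gene across samples. The per-gene centre and
#' scale are stored so held-out samples can be projected identically.
#'
#' @param expression Samples x genes matrix or data.frame.
#' @param ntr_gene_list Character vector of gene names (the 94-gene
#'   catalogue in the default workflow).
#' @return A `CohortMatrix`: list with `z` (samples x genes), `genes`,
#'   `center`, `scale`.
#' @export
normalize_cohort <- function(expression, ntr_gene_list) {
  x <- as.matrix(expression)
  if (nrow(x) < 2L) stopf("at least 2 samples are required")
  missing <- setdiff(ntr_gene_list, colnames(x))
  if (length(missing))
    warnf("%d NTR gene(s) missing from the expression matrix", length(missing))
  genes <- intersect(ntr_gene_list, colnames(x))
  if (!length(genes)) stopf("no NTR genes present in the expression matrix")
  x <- x[, genes, drop = FALSE]

  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warnf("dropping %d zero-variance gene(s)", sum(sds == 0))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(z = z, genes = colnames(x), center = ctr, scale = sds),
            class = "CohortMatrix")
}

#' @export
print.CohortMatrix <- function(x, ...) {
  cat("CohortMatrix:", nrow(x$z), "samples x", length(x$genes),
      "NTR genes (z-scored)\n")
  invisible(x)
}

#' K-means subgrouping with silhouette-guided k
#'
#' Runs seeded k-means (with `n_init` restarts) for every candidate k and
#' computes the mean Euclidean silhouette width; the chosen k maximises the
#' mean silhouette (ties towards smaller k) unless `k_fixed` overrides it.
#'
#' @param cohort A `CohortMatrix`.
#' @param k_range Candidate cluster numbers (default 2:8).
#' @param k_fixed Optional fixed k (must be >= 2: the silhouette is
#'   undefined for one cluster).
#' @param seed Integer seed.
#' @param n_init Number of k-means restarts (default 50).
#' @return A `ClusterResult`: list with `k`, `labels`, `silhouette`
#'   (data.frame k, mean_silhouette), `centroids`, plus the training gene
#'   order and z-parameters for later prediction.
#' @export
cluster_cohort <- function(cohort, k_range = 2:8, k_fixed = NULL, seed = 1,
                           n_init = 50) {
  z <- cohort$z
  if (!is.null(k_fixed)) {
    if (k_fixed < 2) stopf("'k_fixed' must be >= 2 (silhouette undefined for k = 1)")
    if (k_fixed > nrow(z)) stopf("'k_fixed' exceeds the number of samples")
    k_range <- unique(sort(c(k_range, k_fixed)))
  }
  if (max(k_range) >= nrow(z)) stopf("max(k_range) must be below the sample count")
  d <- dist(z)

  fits <- list()
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- withr::with_seed(derive_seed(seed, paste0("kmeans", k)), {
      kmeans(z, centers = k, nstart = n_init, iter.max = 100)
    })
    sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, d)[, 3])
  }
  chosen <- if (!is.null(k_fixed)) k_fixed else k_range[which.max(sil)]
  fit <- fits[[match(chosen, k_range)]]
  structure(
    list(k = chosen, labels = as.integer(fit$cluster),
         silhouette = data.frame(k = k_range, mean_silhouette = sil),
         centroids = fit$centers, genes = cohort$genes,
         center = cohort$center, scale = cohort$scale, seed = seed),
    class = "ClusterResult"
  )
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult: k =", x$k, "over", length(x$labels), "samples; mean",
      "silhouette", round(x$silhouette$mean_silhouette[match(x$k, x$silhouette$k)], 3), "\n")
  invisible(x)
}

#' Nominate per-cluster marker genes by one-way ANOVA
#'
#' Each gene is tested across clusters with a classical one-way ANOVA
#' (equal-variance F test); p-values are BH-adjusted over genes. For every
#' cluster, the significant gene (q below `q_cut`) with the highest
#' within-cluster mean is nominated as that cluster's marker.
#'
#' @param cohort A `CohortMatrix`.
#' @param labels Cluster label per sample (each cluster needs >= 3
#'   samples).
#' @param q_cut BH-adjusted significance cut-off (default 0.05).
#' @return A `MarkerGeneTable` data.frame (gene, F, p, q and per-cluster
#'   means) with the nominations in `attr(, "nominated")`.
#' @export
anova_marker_genes <- function(cohort, labels, q_cut = 0.05) {
  z <- cohort$z
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (any(sizes < 3))
    stopf("cluster '%s' has fewer than 3 samples", names(sizes)[which(sizes < 3)[1]])

  stats_list <- apply(z, 2, function(v) {
    ft <- oneway.test(v ~ labels, var.equal = TRUE)
    c(F = unname(ft$statistic), p = ft$p.value)
  })
  out <- data.frame(gene = colnames(z), F = stats_list["F", ],
                    p = stats_list["p", ], row.names = NULL)
  out$q <- p.adjust(out$p, "BH")
  means_in <- cluster_means(z, labels)            # genes x clusters
  for (cl in colnames(means_in)) out[[paste0("mean_", cl)]] <- means_in[, cl]

  nominated <- do.call(rbind, lapply(colnames(means_in), function(cl) {
    ok <- out$q < q_cut
    if (!any(ok)) return(data.frame(cluster = cl, gene = NA_character_))
    cand <- out[ok, ]
    data.frame(cluster = cl,
               gene = cand$gene[which.max(means_in[match(cand$gene, out$gene), cl])])
  }))
  class(out) <- c("MarkerGeneTable", "data.frame")
  attr(out, "nominated") <- nominated
  out
}

#' Predict subgroups for new samples by nearest centroid
#'
#' Projects new samples onto the training z-scale (stored per-gene centre
#' and scale) over the genes shared with the training run (at least half
#' must be present) and assigns each sample to the nearest centroid in
#' Euclidean distance.
#'
#' @param cohort_new Samples x genes matrix of new expression values (raw
#'   scale, as given to [normalize_cohort()]).
#' @param trained A `ClusterResult`.
#' @return data.frame sample, label, distance.
#' @export
predict_subgroup <- function(cohort_new, trained) {
  x <- as.matrix(cohort_new)
  shared <- intersect(trained$genes, colnames(x))
  if (!length(shared)) stopf("no genes shared with the trained classifier")
  if (length(shared) < 0.5 * length(trained$genes))
    stopf("fewer than half of the trained genes are present (%d of %d)",
          length(shared), length(trained$genes))
  z <- scale(x[, shared, drop = FALSE],
             center = trained$center[shared], scale = trained$scale[shared])
  cent <- trained$centroids[, shared, drop = FALSE]
  d <- vapply(seq_len(nrow(cent)), function(k) {
    rowSums(sweep(z, 2, cent[k, ])^2)
  }, numeric(nrow(z)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  lab <- apply(d, 1, which.min)
  data.frame(sample = rownames(x) %||% as.character(seq_len(nrow(x))),
             label = as.integer(lab),
             distance = sqrt(d[cbind(seq_len(nrow(d)), lab)]),
             row.names = NULL)
}
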