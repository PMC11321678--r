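`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit sub-seed for a named pipeline stage
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% (.Machine$integer.max - 1L)) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be a positive number", name)
  invisible(x)
}

#' Express a count as a percentage of a total
#'
#' Small reporting helper used when summarising peak sets (for example the
#' share of peaks that are cluster-specific, or the share validated by an
#' external enhancer catalogue). Supports both decimal conventions seen in
#' published tables: rounding and truncation at a fixed number of decimals.
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Number of decimals to keep.
#' @param method "round" (default) or "truncate".
#' @return A single numeric percentage.
#' @examples
#' percent_of(130616, 341426, digits = 2, method = "truncate")
#' percent_of(11159, 32276, digits = 1)
#' @export
percent_of <- function(n, total, digits = 1, method = c("round", "truncate")) {
  method <- match.arg(method)
  check_positive(total, "total")
  if (n < 0) stopf("'n' must be non-negative")
  pct <- 100 * n / total
  f <- 10^digits
  if (method == "round") round(pct * f) / f else floor(pct * f + 1e-9) / f
}

# convert 0-based half-open intervals to GRanges (1-based closed)
as_granges0 <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

# fraction of each 0-based half-open interval covered by a reference set
coverage_fraction <- function(df, reference) {
  if (is.null(reference) || nrow(reference) == 0L) return(rep(0, nrow(df)))
  q <- as_granges0(df)
  r <- GenomicRanges::reduce(as_granges0(reference))
  hits <- GenomicRanges::findOverlaps(q, r)
  cov <- rep(0, nrow(df))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(q)[qi], IRanges::ranges(r)[S4Vectors::subjectHits(hits)]
    ))
    agg <- rowsum(as.numeric(ov), qi)
    cov[as.integer(rownames(agg))] <- agg[, 1]
  }
  cov / (df$end - df$start)
}

# column means of a (cells x features) matrix within each cluster,
# returned as features x clusters
cluster_means <- function(x, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  out <- vapply(groups, function(g) {
    Matrix::colMeans(x[labels == g, , drop = FALSE])
  }, numeric(ncol(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(x), dimnames = list(colnames(x), groups))
  out
}

# Pearson correlation p-value matrix given r and the number of points
cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r2, .Machine$double.eps))
  t[r2 >= 1] <- Inf
  2 * stats::pt(-t, df = n - 2)
}
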