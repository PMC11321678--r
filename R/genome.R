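#' Generate a synthetic genome specification
#'
#' Builds a compact multi-chromosome genome carrying everything the
#' accessibility pipeline needs: a fixed 500-bp tiling grid, a per-tile GC
#' fraction track, and a small blacklist of artifact-prone intervals. The GC
#' track is a smoothed, standardised random walk squashed into
#' `0.5 +/- 0.25 * tanh(z)`, so it stays inside (0.25, 0.75) while retaining
#' long-range structure: means over multi-megabase windows still differ,
#' which keeps GC-matched background selection non-trivial for the
#' copy-number module.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length_bp Length in bp of each chromosome; scalar or vector
#'   of length `n_chrom`. Must be at least `20 * tile_size`.
#' @param tile_size Width of the tiling grid in bp (default 500).
#' @param gc_smoothness Moving-average window (in tiles) applied to the GC
#'   random walk. Values at or above the tile count give a constant track.
#' @param n_blacklist Number of blacklist intervals per chromosome.
#' @param blacklist_width_bp Width of each blacklist interval.
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @return An object of class `GenomeSpec`: a list with `chromosomes`
#'   (data.frame of name and length), `tile_size`, `gc` (named list of
#'   per-tile GC fractions) and `blacklist` (0-based half-open intervals).
#' @examples
#' g <- generate_genome(n_chrom = 1, chrom_length_bp = 1e6, seed = 1)
#' length(g$gc$chr1)  # ceiling(1e6 / 500) tiles
#' @export
generate_genome <- function(n_chrom = 3, chrom_length_bp = 60e6, tile_size = 500,
                            gc_smoothness = 2000, n_blacklist = 4,
                            blacklist_width_bp = 1e5, seed = 1) {
  check_positive(n_chrom, "n_chrom")
  check_positive(chrom_length_bp, "chrom_length_bp")
  check_positive(tile_size, "tile_size")
  check_positive(gc_smoothness, "gc_smoothness")
  if (length(chrom_length_bp) == 1L) chrom_length_bp <- rep(chrom_length_bp, n_chrom)
  if (length(chrom_length_bp) != n_chrom)
    stopf("'chrom_length_bp' must have length 1 or n_chrom")
  if (any(chrom_length_bp < 20 * tile_size))
    stopf("'chrom_length_bp' must be >= 20 * tile_size")

  chroms <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = as.numeric(chrom_length_bp),
    stringsAsFactors = FALSE
  )

  withr::with_seed(seed, {
    gc <- lapply(seq_len(n_chrom), function(i) {
      n_t <- ceiling(chroms$length[i] / tile_size)
      if (gc_smoothness >= n_t) return(rep(0.5, n_t))
      walk <- cumsum(rnorm(n_t))
      w <- max(1L, as.integer(gc_smoothness))
      sm <- as.numeric(stats::filter(walk, rep(1 / w, w), sides = 2))
      sm <- fill_na_ends(sm)
      s <- sd(sm)
      if (!is.finite(s) || s == 0) return(rep(0.5, n_t))
      0.5 + 0.25 * tanh((sm - mean(sm)) / s)
    })
    names(gc) <- chroms$chrom

    blacklist <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      if (n_blacklist < 1) return(NULL)
      len <- chroms$length[i]
      w <- min(blacklist_width_bp, floor(len / 20))
      starts <- sort(sample.int(max(1, len - w), n_blacklist))
      data.frame(chrom = chroms$chrom[i], start = starts, end = starts + w,
                 stringsAsFactors = FALSE)
    }))
  })

  structure(
    list(chromosomes = chroms, tile_size = as.integer(tile_size),
         gc = gc, blacklist = blacklist, seed = seed),
    class = "GenomeSpec"
  )
}

fill_na_ends <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(rep(0, length(x)))
  if (ok[1] > 1L) x[seq_len(ok[1] - 1L)] <- x[ok[1]]
  last <- ok[length(ok)]
  if (last < length(x)) x[(last + 1L):length(x)] <- x[last]
  x
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", nrow(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes$length), big.mark = ","), "bp,",
      x$tile_size, "bp tiles\n")
  invisible(x)
}

n_tiles <- function(genome) {
  as.integer(ceiling(genome$chromosomes$length / genome$tile_size))
}

# genome-ordered tile table with global tile ids and per-tile GC
tile_table <- function(genome) {
  nt <- n_tiles(genome)
  ts <- genome$tile_size
  dt <- data.table::rbindlist(lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    starts <- (seq_len(nt[i]) - 1) * as.numeric(ts)
    data.table::data.table(
      chrom = genome$chromosomes$chrom[i],
      start = starts,
      end = pmin(starts + ts, genome$chromosomes$length[i]),
      gc = genome$gc[[i]]
    )
  }))
  dt[, tile := .I]
  dt
}

#' Mean GC fraction of genomic regions
#'
#' Averages the genome's per-tile GC track over the tiles each 0-based
#' half-open region overlaps; used for copy-number window GC and for
#' matched-background peak features.
#'
#' @param genome A `GenomeSpec`.
#' @param regions data.frame with chrom, start, end.
#' @return Numeric vector of GC fractions.
#' @export
region_gc <- function(genome, regions) {
  ts <- genome$tile_size
  chrom_idx <- match(regions$chrom, genome$chromosomes$chrom)
  if (anyNA(chrom_idx)) stopf("unknown chromosome in regions")
  vapply(seq_len(nrow(regions)), function(i) {
    g <- genome$gc[[chrom_idx[i]]]
    a <- regions$start[i] %/% ts + 1
    b <- (regions$end[i] - 1) %/% ts + 1
    mean(g[a:min(b, length(g))])
  }, numeric(1))
}

chrom_length <- function(genome, chrom) {
  genome$chromosomes$length[match(chrom, genome$chromosomes$chrom)]
}

#' Generate synthetic gene models
#'
#' Places genes on a jittered grid along the genome (so that the 100-kb
#' gene-score windows of neighbouring genes rarely entangle), assigns
#' strands and lengths, and derives the TSS from the strand: the TSS is the
#' body start on `+` genes and `end - 1` on `-` genes. Regulatory roles
#' (`is_tf`, `is_ntr`, `motif_id`) default to none and are filled in by the
#' scenario builders.
#'
#' @param genome A `GenomeSpec`.
#' @param n_genes Number of genes to place.
#' @param length_range Min/max gene body length in bp.
#' @param margin_bp Distance kept clear at each chromosome end.
#' @param seed Integer seed.
#' @return A data.frame with columns gene_id, chrom, strand, start, end, tss,
#'   length, is_ntr, is_tf, motif_id (0-based half-open bodies).
#' @export
generate_gene_models <- function(genome, n_genes = 100,
                                 length_range = c(5e3, 2e4),
                                 margin_bp = 3e5, seed = 1) {
  check_positive(n_genes, "n_genes")
  chroms <- genome$chromosomes
  usable <- pmax(chroms$length - 2 * margin_bp, 0)
  if (sum(usable) <= 0) stopf("chromosomes too short for margin_bp = %g", margin_bp)
  per_chrom <- pmax(1L, round(n_genes * usable / sum(usable)))
  while (sum(per_chrom) > n_genes) per_chrom[which.max(per_chrom)] <- per_chrom[which.max(per_chrom)] - 1L
  while (sum(per_chrom) < n_genes) per_chrom[which.max(usable)] <- per_chrom[which.max(usable)] + 1L

  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(chroms)), function(i) {
      k <- per_chrom[i]
      if (k == 0L) return(NULL)
      slots <- margin_bp + usable[i] * (seq_len(k) - 0.5) / k
      jitter <- runif(k, -0.2, 0.2) * usable[i] / k
      anchor <- round(slots + jitter)
      len <- round(runif(k, length_range[1], length_range[2]))
      start <- pmax(0, pmin(anchor, chroms$length[i] - len - 1))
      data.frame(chrom = chroms$chrom[i], start = start, end = start + len,
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  })
  df$gene_id <- sprintf("gene%03d", seq_len(nrow(df)))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$length <- df$end - df$start
  df$is_ntr <- FALSE
  df$is_tf <- FALSE
  df$motif_id <- NA_character_
  df[, c("gene_id", "chrom", "strand", "start", "end", "tss", "length",
         "is_ntr", "is_tf", "motif_id")]
}
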