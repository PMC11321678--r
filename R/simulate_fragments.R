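#' Expected relative per-tile insertion rates for one cell group
#'
#' The generator's rate law, exposed so tests can check sampled data against
#' the model that produced it. For a cell of a given group the sampling
#' probability of a tile is proportional to
#' `exp(gc_bias_strength * (gc - 0.5)) * (copy_number / 2) * program multiplier`,
#' where the copy number comes from the group's clone segments (2 elsewhere)
#' and the program multiplier applies to tiles overlapping the intervals of
#' any TF program active in the group.
#'
#' @param genome A `GenomeSpec`.
#' @param group Group name.
#' @param groups_spec data.frame with columns group, reference (logical) and
#'   clone (NA for reference groups).
#' @param cnv_segments Optional data.frame clone, chrom, start, end,
#'   copy_number (0-based half-open).
#' @param tf_programs Optional list of programs; each a list with at least
#'   `intervals` (data.frame chrom,start,end) and `effects` (named numeric,
#'   multiplier per group).
#' @param gc_bias_strength Strength of the exponential GC coverage bias.
#' @return Numeric vector over global tiles, normalised to sum to 1.
#' @export
expected_tile_rates <- function(genome, group, groups_spec,
                                cnv_segments = NULL, tf_programs = NULL,
                                gc_bias_strength = 1) {
  tiles <- tile_table(genome)
  rate <- exp(gc_bias_strength * (tiles$gc - 0.5))

  row <- groups_spec[groups_spec$group == group, , drop = FALSE]
  if (nrow(row) != 1L) stopf("unknown group '%s'", group)
  clone <- row$clone[1]
  if (!row$reference[1] && !is.na(clone) && !is.null(cnv_segments)) {
    segs <- cnv_segments[cnv_segments$clone == clone, , drop = FALSE]
    if (nrow(segs)) {
      idx <- tiles_in_intervals(tiles, segs)
      for (j in seq_len(nrow(segs))) {
        rate[idx[[j]]] <- rate[idx[[j]]] * (segs$copy_number[j] / 2)
      }
    }
  }
  if (!is.null(tf_programs)) {
    for (pr in tf_programs) {
      eff <- pr$effects[group]
      if (is.null(eff) || is.na(eff) || eff == 1) next
      idx <- unlist(tiles_in_intervals(tiles, pr$intervals))
      idx <- unique(idx)
      rate[idx] <- rate[idx] * eff
    }
  }
  rate / sum(rate)
}

# list of global tile indices whose tile overlaps each interval
tiles_in_intervals <- function(tiles, intervals) {
  lapply(seq_len(nrow(intervals)), function(j) {
    tiles[chrom == intervals$chrom[j] & end > intervals$start[j] &
            start < intervals$end[j], tile]
  })
}

#' Simulate a fragments file with planted ground truth
#'
#' Draws per-cell Tn5 fragments under the rate law of
#' [expected_tile_rates()]: the per-cell fragment count is negative binomial
#' with mean `depth_mean`, the first insertion position is sampled from the
#' per-tile rates, and the second insertion sits one fragment length
#' downstream (fragment start and `end - 1` are the two insertion sites, the
#' 10x fragments-file convention). Reference groups are diploid and carry no
#' program, emulating the conserved immune populations used as the
#' copy-number reference.
#'
#' @inheritParams expected_tile_rates
#' @param genes Optional gene table, carried into the truth object.
#' @param n_cells_per_group Integer, scalar or named per group.
#' @param depth_mean Mean fragments per cell.
#' @param nb_size Negative-binomial size (dispersion) of the depth law.
#' @param frag_len_range Min/max fragment length in bp.
#' @param seed Integer seed.
#' @param path Optional path; when given the sorted fragments are written
#'   there (tab-separated chrom/start/end/barcode/count, gzip by extension).
#' @return List with `fragments` (data.table sorted by chrom, start),
#'   `truth` (a `TruthSet`: per-cell group/clone table, CNV segments,
#'   program metadata, seed) and `path` (or NULL).
#' @export
simulate_fragments <- function(genome, genes = NULL, groups_spec,
                               n_cells_per_group = 100, depth_mean = 5000,
                               cnv_segments = NULL, tf_programs = NULL,
                               gc_bias_strength = 1, nb_size = 20,
                               frag_len_range = c(80, 300), seed = 1,
                               path = NULL) {
  check_positive(depth_mean, "depth_mean")
  check_positive(n_cells_per_group, "n_cells_per_group")
  if (!any(groups_spec$reference))
    stopf("groups_spec must include at least one reference (diploid) group")
  if (!is.null(cnv_segments)) {
    ref_clones <- groups_spec$clone[groups_spec$reference]
    if (any(cnv_segments$clone %in% ref_clones[!is.na(ref_clones)]))
      stopf("reference groups cannot carry CNV segments")
    bad <- is.na(match(cnv_segments$chrom, genome$chromosomes$chrom)) |
      cnv_segments$start < 0 |
      cnv_segments$end > chrom_length(genome, cnv_segments$chrom)
    if (any(bad)) stopf("CNV segment outside genome bounds")
  }

  groups <- groups_spec$group
  if (length(n_cells_per_group) == 1L)
    n_cells_per_group <- setNames(rep(n_cells_per_group, length(groups)), groups)
  n_cells_per_group <- n_cells_per_group[groups]

  tiles <- tile_table(genome)
  ts <- genome$tile_size
  tile_chrom <- tiles$chrom
  tile_start <- tiles$start
  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)

  frag_parts <- vector("list", length(groups))
  cell_rows <- vector("list", length(groups))

  withr::with_seed(seed, {
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      nc <- n_cells_per_group[[g]]
      barcodes <- sprintf("%s-%04d", toupper(gsub("[^A-Za-z0-9]", "", g)), seq_len(nc))
      rates <- expected_tile_rates(genome, g, groups_spec, cnv_segments,
                                   tf_programs, gc_bias_strength)
      nfrag <- rnbinom(nc, mu = depth_mean, size = nb_size)
      nfrag[nfrag == 0L] <- 1L
      total <- sum(nfrag)
      tile_idx <- sample.int(nrow(tiles), total, replace = TRUE, prob = rates)
      pos <- tile_start[tile_idx] + sample.int(ts, total, replace = TRUE) - 1
      lens <- sample.int(frag_len_range[2] - frag_len_range[1] + 1L, total,
                         replace = TRUE) + frag_len_range[1] - 1L
      chromv <- tile_chrom[tile_idx]
      maxlen <- chrom_len[chromv]
      start <- pmin(pos, maxlen - 2)
      end <- pmin(start + lens, maxlen)
      frag_parts[[gi]] <- data.table::data.table(
        chrom = chromv, start = start, end = end,
        barcode = rep(barcodes, nfrag)
      )
      cell_rows[[gi]] <- data.frame(
        barcode = barcodes, group = g,
        clone = groups_spec$clone[gi],
        reference = groups_spec$reference[gi],
        stringsAsFactors = FALSE
      )
    }
  })

  frags <- data.table::rbindlist(frag_parts)
  # collapse PCR-duplicate-identical records into a count column
  frags <- frags[, .(count = .N), by = .(chrom, start, end, barcode)]
  data.table::setorder(frags, chrom, start, end, barcode)

  truth <- structure(
    list(cells = do.call(rbind, cell_rows),
         cnv_segments = cnv_segments,
         tf_programs = tf_programs,
         genes = genes,
         depth_mean = depth_mean,
         gc_bias_strength = gc_bias_strength,
         seed = seed),
    class = "TruthSet"
  )

  if (!is.null(path)) write_fragments(frags, path)
  list(fragments = frags, truth = truth, path = path)
}

#' Write a fragments table to a 10x-style fragments file
#'
#' Five tab-separated columns (chrom, start, end, barcode, count), no
#' header, 0-based half-open, gzip-compressed when the path ends in `.gz`.
#'
#' @param fragments data.frame/data.table with the five columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  cols <- c("chrom", "start", "end", "barcode", "count")
  if (!all(cols %in% names(fragments))) stopf("fragments must have columns %s",
                                              paste(cols, collapse = ", "))
  data.table::fwrite(as.data.table(fragments)[, ..cols], path, sep = "\t",
                     col.names = FALSE, compress = "auto")
  invisible(path)
}

#' @export
print.TruthSet <- function(x, ...) {
  cat("TruthSet:", nrow(x$cells), "cells in",
      length(unique(x$cells$group)), "groups;",
      if (is.null(x$cnv_segments)) 0L else nrow(x$cnv_segments),
      "CNV segments;",
      length(x$tf_programs %||% list()), "TF programs\n")
  invisible(x)
}
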