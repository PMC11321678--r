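#' Read and validate a fragments file
#'
#' Reads a 10x-style fragments file (tab-separated chrom, start, end,
#' barcode, count; 0-based half-open; optionally gzipped; leading comment
#' lines starting with `#` are skipped) and validates every record against
#' the genome: known chromosome, integer coordinates, `0 <= start < end <=
#' chromosome length`, `count >= 1`. Validation failures report the
#' offending file line.
#'
#' @param path Path to the fragments file.
#' @param genome A `GenomeSpec` (or any list with a `chromosomes`
#'   data.frame of chrom/length).
#' @return A data.table with columns chrom, start, end, barcode, count, in
#'   file order.
#' @export
read_fragments <- function(path, genome) {
  if (!file.exists(path)) stopf("fragments file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 1000L)
  close(con)
  n_comment <- 0L
  while (n_comment < length(head_lines) && startsWith(head_lines[n_comment + 1L], "#"))
    n_comment <- n_comment + 1L

  dt <- if (grepl("\\.gz$", path)) {
    # avoid fread's optional gz dependency: stream through a connection
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    lines <- readLines(con)
    if (n_comment > 0L) lines <- lines[-seq_len(n_comment)]
    data.table::fread(text = lines, header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  } else {
    data.table::fread(path, skip = n_comment, header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  }
  if (ncol(dt) < 5L) stopf("fragments file must have 5 columns, found %d", ncol(dt))
  dt <- dt[, 1:5]
  data.table::setnames(dt, c("chrom", "start", "end", "barcode", "count"))

  line_of <- function(i) n_comment + i
  fail_at <- function(bad, what) {
    i <- which(bad)[1]
    stopf("line %d: %s", line_of(i), what)
  }

  for (col in c("start", "end", "count")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num)) fail_at(is.na(num), sprintf("non-integer '%s' coordinate", col))
      v <- num
    }
    if (any(v != floor(v))) fail_at(v != floor(v), sprintf("non-integer '%s' value", col))
    data.table::set(dt, j = col, value = as.numeric(v))
  }

  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  unknown <- !(dt$chrom %in% names(chrom_len))
  if (any(unknown)) fail_at(unknown, sprintf("unknown chromosome '%s'", dt$chrom[which(unknown)[1]]))
  if (any(dt$start < 0)) fail_at(dt$start < 0, "negative start")
  bad_order <- dt$start >= dt$end
  if (any(bad_order)) fail_at(bad_order, "start >= end")
  over <- dt$end > chrom_len[dt$chrom]
  if (any(over)) fail_at(over, "end beyond chromosome length")
  if (any(dt$count < 1)) fail_at(dt$count < 1, "count < 1")
  dt[]
}

# two Tn5 insertions per fragment record: positions start and end - 1,
# weighted by the collapsed duplicate count
insertion_table <- function(fragments) {
  dt <- as.data.table(fragments)
  ins <- data.table::rbindlist(list(
    dt[, .(chrom, pos = start, barcode, count)],
    dt[, .(chrom, pos = end - 1, barcode, count)]
  ))
  ins
}

#' Per-cell quality-control metrics
#'
#' Computes, per barcode, the number of unique fragment records and the TSS
#' enrichment score: the mean per-bp insertion count inside `TSS +/-
#' center_bp`, divided by the mean per-bp insertion count in the two distal
#' flanks (`flank_bp[1]`..`flank_bp[2]` bp away on either side) plus a
#' pseudocount, aggregated over all TSS. Every fragment contributes two
#' insertions (start and end - 1).
#'
#' @param fragments Validated fragments table.
#' @param tss Either a data.frame with chrom and a tss (or pos) column, or a
#'   gene table from [generate_gene_models()].
#' @param center_bp Half-width of the central window (default 50, i.e. a
#'   101-bp window).
#' @param flank_bp Distal flank, bp from the TSS (default c(1901, 2000)).
#' @param pseudocount Added to the flank per-bp mean (default 0.1).
#' @return data.frame with barcode, n_unique_fragments, tss_enrichment.
#' @export
compute_cell_qc <- function(fragments, tss, center_bp = 50,
                            flank_bp = c(1901, 2000), pseudocount = 0.1) {
  tss_dt <- tss_positions(tss)
  if (nrow(tss_dt) == 0L) stopf("at least one TSS is required")
  frag <- as.data.table(fragments)
  n_frag <- frag[, .(n_unique_fragments = .N), by = barcode]

  ins <- insertion_table(frag)
  windows <- data.table::rbindlist(list(
    tss_dt[, .(chrom, wstart = pos - center_bp, wend = pos + center_bp, kind = "center")],
    tss_dt[, .(chrom, wstart = pos - flank_bp[2], wend = pos - flank_bp[1], kind = "flank")],
    tss_dt[, .(chrom, wstart = pos + flank_bp[1], wend = pos + flank_bp[2], kind = "flank")]
  ))
  data.table::setkey(windows, chrom, wstart, wend)
  ins[, `:=`(pstart = pos, pend = pos)]
  ov <- data.table::foverlaps(ins, windows,
                              by.x = c("chrom", "pstart", "pend"),
                              by.y = c("chrom", "wstart", "wend"), nomatch = NULL)
  counts <- ov[, .(total = sum(count)), by = .(barcode, kind)]
  wide <- data.table::dcast(counts, barcode ~ kind, value.var = "total", fill = 0)
  if (!"center" %in% names(wide)) wide[, center := 0]
  if (!"flank" %in% names(wide)) wide[, flank := 0]

  center_width <- 2 * center_bp + 1
  flank_width <- 2 * (flank_bp[2] - flank_bp[1] + 1)
  qc <- merge(n_frag, wide, by = "barcode", all.x = TRUE)
  for (col in c("center", "flank")) data.table::set(qc, which(is.na(qc[[col]])), col, 0)
  qc[, tss_enrichment := (center / center_width) / (flank / flank_width + pseudocount)]
  out <- as.data.frame(qc[order(barcode), .(barcode, n_unique_fragments, tss_enrichment)])
  stopifnot(all(is.finite(out$tss_enrichment)), all(out$tss_enrichment >= 0))
  out
}

tss_positions <- function(tss) {
  df <- as.data.frame(tss)
  if ("tss" %in% names(df)) {
    data.table::data.table(chrom = df$chrom, pos = as.numeric(df$tss))
  } else if ("pos" %in% names(df)) {
    data.table::data.table(chrom = df$chrom, pos = as.numeric(df$pos))
  } else if (all(c("start", "end", "strand") %in% names(df))) {
    data.table::data.table(chrom = df$chrom,
                           pos = ifelse(df$strand == "+", df$start, df$end - 1))
  } else stopf("cannot derive TSS positions: need 'tss', 'pos', or start/end/strand")
}

#' Filter cells on QC thresholds
#'
#' Keeps barcodes with at least `min_fragments` unique fragments AND a TSS
#' enrichment of at least `min_tss` (both thresholds inclusive), then
#' retains at most `top_n_by_tss` cells ranked by TSS enrichment (ties
#' broken by barcode lexical order).
#'
#' @param qc Table from [compute_cell_qc()].
#' @param min_fragments Minimum unique fragments (default 1000).
#' @param min_tss Minimum TSS enrichment (default 4).
#' @param top_n_by_tss Cap on cells kept, ranked by enrichment (default 12000).
#' @param exclude_barcodes Optional barcodes to drop first (e.g. an external
#'   doublet list).
#' @return Sorted character vector of kept barcodes.
#' @export
filter_cells <- function(qc, min_fragments = 1000, min_tss = 4,
                         top_n_by_tss = 12000, exclude_barcodes = NULL) {
  if (min_fragments < 0 || min_tss < 0 || top_n_by_tss < 0)
    stopf("thresholds must be >= 0")
  keep <- qc[qc$n_unique_fragments >= min_fragments &
               qc$tss_enrichment >= min_tss, , drop = FALSE]
  if (!is.null(exclude_barcodes))
    keep <- keep[!(keep$barcode %in% exclude_barcodes), , drop = FALSE]
  ord <- order(-keep$tss_enrichment, keep$barcode)
  kept <- keep$barcode[ord]
  if (length(kept) > top_n_by_tss) kept <- kept[seq_len(top_n_by_tss)]
  sort(kept)
}
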