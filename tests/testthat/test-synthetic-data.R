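test_that("genome generation is deterministic and respects the tiling grid", {
  g1 <- generate_genome(n_chrom = 2, chrom_length_bp = c(1e6, 5e5), seed = 3)
  g2 <- generate_genome(n_chrom = 2, chrom_length_bp = c(1e6, 5e5), seed = 3)
  expect_identical(g1, g2)
  expect_length(g1$gc$chr1, ceiling(1e6 / 500))
  expect_length(g1$gc$chr2, ceiling(5e5 / 500))
  g3 <- generate_genome(1, 1e7, tile_size = 500, seed = 1)
  expect_length(g3$gc$chr1, 20000)
  expect_true(all(unlist(g1$gc) >= 0.25 & unlist(g1$gc) <= 0.75))
})

test_that("infinite GC smoothness collapses to a constant track", {
  g <- generate_genome(1, 1e6, gc_smoothness = 1e9, seed = 5)
  expect_true(all(g$gc$chr1 == 0.5))
})

test_that("invalid genome parameters are rejected by name", {
  expect_error(generate_genome(n_chrom = 0), "n_chrom")
  expect_error(generate_genome(1, chrom_length_bp = -5), "chrom_length_bp")
  expect_error(generate_genome(1, chrom_length_bp = 5000, tile_size = 500),
               "20 \\* tile_size")
  expect_error(generate_genome(1, 1e6, tile_size = 0), "tile_size")
})

test_that("fragment simulation is deterministic and validates its inputs", {
  g <- flat_genome(2e5)
  groups <- data.frame(group = c("ref", "tum"), reference = c(TRUE, FALSE),
                       clone = c(NA, "c1"))
  segs <- data.frame(clone = "c1", chrom = "chr1", start = 0, end = 5e4,
                     copy_number = 4)
  s1 <- simulate_fragments(g, groups_spec = groups, n_cells_per_group = 5,
                           depth_mean = 200, cnv_segments = segs, seed = 8)
  s2 <- simulate_fragments(g, groups_spec = groups, n_cells_per_group = 5,
                           depth_mean = 200, cnv_segments = segs, seed = 8)
  expect_identical(s1$fragments, s2$fragments)

  bad_seg <- data.frame(clone = "c1", chrom = "chr1", start = 0, end = 5e6,
                        copy_number = 4)
  expect_error(simulate_fragments(g, groups_spec = groups, cnv_segments = bad_seg),
               "outside genome")
  ref_seg <- data.frame(clone = "c1", chrom = "chr1", start = 0, end = 5e4,
                        copy_number = 4)
  groups_ref <- data.frame(group = "ref", reference = TRUE, clone = "c1")
  expect_error(simulate_fragments(g, groups_spec = groups_ref,
                                  cnv_segments = ref_seg),
               "reference groups cannot carry CNV")
  expect_error(simulate_fragments(g, groups_spec = data.frame(
    group = "a", reference = FALSE, clone = NA)), "reference")
})

test_that("a copy-4 segment doubles expected per-tile rates vs the reference", {
  g <- flat_genome(60e6)
  groups <- data.frame(group = c("ref", "tum"), reference = c(TRUE, FALSE),
                       clone = c(NA, "c1"))
  # small segment so rate renormalisation is negligible
  segs <- data.frame(clone = "c1", chrom = "chr1", start = 10e6, end = 11e6,
                     copy_number = 4)
  r_ref <- expected_tile_rates(g, "ref", groups, segs, gc_bias_strength = 0)
  r_tum <- expected_tile_rates(g, "tum", groups, segs, gc_bias_strength = 0)
  tiles_in <- seq(10e6 / 500 + 1, 11e6 / 500)
  ratio <- mean(r_tum[tiles_in]) / mean(r_ref[tiles_in])
  expect_equal(ratio, 2, tolerance = 0.05)
  # ... and the sampled data agree with the generator's own rate function
  sim <- simulate_fragments(g, groups_spec = groups,
                            n_cells_per_group = c(ref = 40, tum = 40),
                            depth_mean = 3000, cnv_segments = segs,
                            gc_bias_strength = 0, seed = 21)
  ins <- sim$fragments[, .(n = sum(count) * 2), by = barcode]
  tum_cells <- sim$truth$cells$barcode[sim$truth$cells$group == "tum"]
  in_seg <- sim$fragments$chrom == "chr1" & sim$fragments$start >= 10e6 &
    sim$fragments$start < 11e6
  n_tum <- sum(sim$fragments$count[in_seg & sim$fragments$barcode %in% tum_cells])
  n_ref <- sum(sim$fragments$count[in_seg & !(sim$fragments$barcode %in% tum_cells)])
  tot_tum <- sum(sim$fragments$count[sim$fragments$barcode %in% tum_cells])
  tot_ref <- sum(sim$fragments$count[!(sim$fragments$barcode %in% tum_cells)])
  expect_equal((n_tum / tot_tum) / (n_ref / tot_ref), 2, tolerance = 0.15)
})

test_that("switching off the GC bias flattens the rate law", {
  g <- generate_genome(1, 1e6, gc_smoothness = 100, seed = 2)
  groups <- data.frame(group = "ref", reference = TRUE, clone = NA)
  r0 <- expected_tile_rates(g, "ref", groups, gc_bias_strength = 0)
  expect_true(max(r0) - min(r0) < 1e-12)
  r1 <- expected_tile_rates(g, "ref", groups, gc_bias_strength = 1)
  expect_gt(max(r1) - min(r1), 0)
  expect_gt(cor(r1, exp(g$gc$chr1 - 0.5)), 0.999)
})

test_that("a planted TF program scales group accessibility by its effect size", {
  fx <- reg_fixture()
  pr <- fx$programs[[1]]
  hi <- names(pr$effects)[1]
  cells_hi <- fx$truth$cells$barcode[fx$truth$cells$group == hi]
  cells_ref <- fx$truth$cells$barcode[fx$truth$cells$group == "reference"]
  X <- fx$pm$counts
  depth <- Matrix::rowSums(X)
  peak_cols <- intersect(pr$peak_ids, colnames(X))
  m_hi <- mean(Matrix::colSums(X[cells_hi, peak_cols, drop = FALSE]) /
                 sum(depth[cells_hi]))
  m_ref <- mean(Matrix::colSums(X[cells_ref, peak_cols, drop = FALSE]) /
                  sum(depth[cells_ref]))
  # depth-normalised program-peak accessibility close to the planted
  # multiplier, damped slightly by per-group rate renormalisation
  expect_gt(m_hi / m_ref, 2)
  expect_lt(m_hi / m_ref, pr$effects[[1]] * 1.15)
})

test_that("every fragment contributes exactly two insertions", {
  g <- flat_genome(2e5)
  groups <- data.frame(group = "ref", reference = TRUE, clone = NA)
  sim <- simulate_fragments(g, groups_spec = groups, n_cells_per_group = 10,
                            depth_mean = 500, seed = 4)
  tm <- build_tile_matrix(sim$fragments, g, sim$truth$cells$barcode)
  expect_identical(sum(tm$counts), 2 * sum(sim$fragments$count))
})

test_that("cohort simulation has the documented shape and a valid null", {
  sim <- simulate_cohort(seed = 1)
  expect_equal(dim(sim$expression), c(763, 94))
  expect_error(simulate_cohort(effect_size = -1), "effect_size")
  expect_error(simulate_cohort(k_groups = 1), "k_groups")

  null <- simulate_cohort(n_samples = 200, effect_size = 0, seed = 2)
  cohort <- normalize_cohort(null$expression, colnames(null$expression))
  res <- cluster_cohort(cohort, k_range = 2:5, seed = 3, n_init = 10)
  expect_lt(max(res$silhouette$mean_silhouette), 0.1)
})

test_that("fragments are written position-sorted in five-column form", {
  fx <- reg_fixture()
  f <- fx$fragments
  expect_named(f, c("chrom", "start", "end", "barcode", "count"))
  expect_true(!is.unsorted(order(f$chrom, f$start)))
  expect_true(all(f$count >= 1))
  by_chrom <- split(f$start, f$chrom)
  expect_true(all(vapply(by_chrom, function(s) !is.unsorted(s), logical(1))))
})
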