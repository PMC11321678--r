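test_that("planted program targets surface as cluster markers; null data give none", {
  fx <- reg_fixture()
  mk <- marker_features(fx$gs, fx$labels, fdr_cut = 0.01, lfc_cut = 0.25)
  for (p in seq_along(fx$programs)) {
    pr <- fx$programs[[p]]
    hi <- names(pr$effects)[1]
    hits <- mk$feature[mk$cluster == hi & mk$is_marker]
    expect_true(all(pr$targets %in% hits),
                label = sprintf("targets of program %d are markers of %s", p, hi))
  }

  set.seed(22)
  null_x <- matrix(rnorm(200 * 50, 10), 200, 50,
                   dimnames = list(NULL, sprintf("f%02d", 1:50)))
  mk0 <- marker_features(null_x, rep(1:2, each = 100))
  expect_equal(sum(mk0$is_marker), 0)

  mk_inf <- marker_features(null_x, rep(1:2, each = 100), lfc_cut = Inf)
  expect_equal(sum(mk_inf$is_marker), 0)

  expect_warning(marker_features(null_x, c(rep(1, 198), 2, 2)), "fewer than 3")
})

test_that("co-accessibility links are cis-only and respect the correlation cut", {
  fx <- reg_fixture()
  lsi <- lsi_cluster(fx$tm, n_dims = 15, n_clusters = 9, seed = 5)
  links <- co_accessibility(fx$pm, lsi$embedding, seed = 5)
  peaks <- fx$peaks
  chr_of <- setNames(peaks$chrom, peaks$peak_id)
  expect_true(all(chr_of[links$peak_a] == chr_of[links$peak_b]))
  expect_true(all(links$dist <= 250000))
  expect_true(all(links$cor >= 0.5))

  # peaks driven by the same planted program end up linked
  prog_pairs <- 0
  for (pr in fx$programs) {
    ids <- pr$peak_ids
    prog_pairs <- prog_pairs +
      sum(links$peak_a %in% ids & links$peak_b %in% ids)
  }
  expect_gt(prog_pairs, 0)

  none <- co_accessibility(fx$pm, lsi$embedding, cor_cut = 1.01, seed = 5)
  expect_equal(nrow(none), 0)
  expect_error(co_accessibility(fx$pm, lsi$embedding, max_dist = 0), "max_dist")
})

test_that("CCAN assembly links genes through promoter members only", {
  peaks <- data.frame(peak_id = c("prom", "d1", "d2", "d3", "d4", "x1", "x2"),
                      chrom = "chr1",
                      start = c(9500, 20000, 40000, 60000, 80000, 200000, 220000),
                      end = c(10500, 20500, 40500, 60500, 80500, 200500, 220500))
  genes <- data.frame(gene_id = "G", chrom = "chr1", strand = "+",
                      start = 10000, end = 15000, tss = 10000, length = 5000)
  links <- data.frame(peak_a = c("prom", "d1", "d2", "d3", "x1"),
                      peak_b = c("d1", "d2", "d3", "d4", "x2"),
                      cor = 0.9, dist = 1000)
  attr(links, "peaks") <- peaks
  cc <- assemble_ccans(links, genes)
  expect_equal(length(unique(cc$membership$ccan)), 2)
  g_ccres <- cc$ccres[cc$ccres$gene_id == "G", ]
  expect_equal(sum(g_ccres$distal), 4)            # the 4 distal members
  expect_false(any(c("x1", "x2") %in% g_ccres$peak_id))
  expect_equal(cc$gene_links$n_ccre, 4)
})

test_that("positive-regulator calls are strict at the correlation boundary", {
  # 3 one-cell clusters engineered so the Pearson correlation is exactly 0.5
  # in floating point: centred profiles (1, 0, -1) and (2, -2, 0) give
  # cov = 1, sd = 1 and sd = 2, all binary-exact
  gs <- matrix(c(2, 1, 0), 3, 1, dimnames = list(c("a", "b", "c"), "TF1"))
  z <- matrix(c(2, -2, 0), 1, 3, dimnames = list("M1", c("a", "b", "c")))
  genes <- data.frame(gene_id = "TF1", is_tf = TRUE, motif_id = "M1")
  reg <- identify_positive_regulators(gs, z, c("k1", "k2", "k3"), genes)
  expect_equal(reg$r, 0.5)
  expect_false(reg$positive)
  expect_match(reg$reason, "below cut-off")

  z_neg <- matrix(c(-3, 0, 0), 1, 3, dimnames = list("M1", c("a", "b", "c")))
  reg_neg <- identify_positive_regulators(gs, z_neg, c("k1", "k2", "k3"), genes)
  expect_lt(reg_neg$r, 0)
  expect_false(reg_neg$positive)

  z_const <- matrix(1, 1, 3, dimnames = list("M1", c("a", "b", "c")))
  reg_c <- identify_positive_regulators(gs, z_const, c("k1", "k2", "k3"), genes)
  expect_false(reg_c$positive)
  expect_match(reg_c$reason, "constant")

  expect_error(identify_positive_regulators(gs, z, c("k1", "k1", "k2"), genes),
               "3 clusters")
})

test_that("planted TFs are recovered as positive regulators, decoys are not", {
  fx <- reg_fixture()
  regs <- identify_positive_regulators(fx$gs, fx$dev, fx$labels, fx$genes)
  planted <- regs[regs$motif %in% paste0("MOTIF_P", 1:4), ]
  expect_true(all(planted$positive))
  decoys <- regs[grepl("MOTIF_D", regs$motif), ]
  expect_equal(sum(decoys$positive), 0)
})

test_that("the correlation screen enumerates exactly genes x motifs pairs", {
  gs <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  z <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(paste0("M", 1:4), NULL))
  labels <- rep(1:5, each = 6)
  scr <- correlation_screen(gs, z, labels)
  expect_equal(nrow(scr), 12)
  expect_equal(attr(scr, "n_pairs"), 12)

  # independent-noise null keeps (almost) nothing at the BH cut-off
  set.seed(12)
  gs_null <- matrix(rnorm(400 * 150), 400, 150,
                    dimnames = list(NULL, sprintf("g%03d", 1:150)))
  z_null <- matrix(rnorm(20 * 400), 20, 400,
                   dimnames = list(sprintf("M%02d", 1:20), NULL))
  scr0 <- correlation_screen(gs_null, z_null, rep(1:8, each = 50))
  expect_lte(sum(scr0$kept), 0.01 * nrow(scr0))
})

test_that("pair-count arithmetic validates its inputs", {
  expect_equal(screen_pair_count(3, 4), 12)
  expect_error(screen_pair_count(0, 10), "n_genes")
  expect_error(screen_pair_count(10, -1), "n_motifs")
})

test_that("the TF-target network recovers the planted circuits exactly", {
  fx <- reg_fixture()
  regs <- identify_positive_regulators(fx$gs, fx$dev, fx$labels, fx$genes)
  scr <- correlation_screen(fx$gs, fx$dev, fx$labels)
  lsi <- lsi_cluster(fx$tm, n_dims = 15, n_clusters = 9, seed = 5)
  links <- co_accessibility(fx$pm, lsi$embedding, seed = 5)
  cc <- assemble_ccans(links, fx$genes)
  net <- build_tf_target_network(regs, scr, fx$mpm, fx$genes, cc)

  for (pr in fx$programs) {
    got <- sort(net$edges$target[net$edges$tf == pr$tf_gene])
    expect_identical(got, sort(pr$targets),
                     label = sprintf("edges of %s", pr$tf_gene))
  }
  truth <- unlist(lapply(fx$programs, function(p) paste(p$tf_gene, p$targets)))
  expect_true(all(paste(net$edges$tf, net$edges$target) %in% truth))

  # no positive regulators -> empty graph
  regs0 <- regs; regs0$positive <- FALSE
  net0 <- build_tf_target_network(regs0, scr, fx$mpm, fx$genes, cc)
  expect_equal(nrow(net0$edges), 0)

  # NTR restriction keeps only NTR-targeted edges
  ntr_ids <- fx$genes$gene_id[fx$genes$is_ntr]
  sub <- extract_ntr_circuit(net, ntr_ids)
  expect_true(all(sub$edges$target %in% ntr_ids))
  expect_equal(nrow(sub$edges), 8)
  all_in <- extract_ntr_circuit(net, unique(net$edges$target))
  expect_equal(all_in$edges, net$edges)
  expect_equal(nrow(extract_ntr_circuit(net, character(0))$edges), 0)
})

test_that("interval overlap fractions match the brute-force oracle", {
  q <- data.frame(chrom = "chr1", start = (1:10) * 1000, end = (1:10) * 1000 + 100)
  expect_equal(interval_overlap_fraction(q, q)$fraction, 1)
  r <- data.frame(chrom = "chr1", start = (1:10) * 1000 + 500,
                  end = (1:10) * 1000 + 600)
  expect_equal(interval_overlap_fraction(q, r)$fraction, 0)
  expect_error(interval_overlap_fraction(q[0, ], r), "empty query")

  set.seed(6)
  qs <- sample.int(1e6, 1000)
  qq <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                   start = qs, end = qs + sample(50:500, 1000, TRUE))
  rs <- sample.int(1e6, 300)
  rr <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   start = rs, end = rs + sample(50:2000, 300, TRUE))
  got <- interval_overlap_fraction(qq, rr)
  want <- 0
  for (i in seq_len(nrow(qq))) {
    hit <- any(rr$chrom == qq$chrom[i] & rr$start < qq$end[i] & rr$end > qq$start[i])
    want <- want + hit
  }
  expect_equal(got$n_overlapping, want)
  expect_equal(got$fraction, want / 1000)
})

test_that("signature annotation labels clusters by their planted programs", {
  fx <- reg_fixture()
  sigs <- setNames(lapply(fx$programs, function(p) p$targets),
                   sprintf("prog%d", 1:4))
  ann <- annotate_clusters_by_signature(fx$gs, fx$labels, sigs)
  for (p in 1:4) {
    expect_equal(ann$label[ann$cluster == paste0("g", p, "hi")],
                 sprintf("prog%d", p))
    expect_equal(ann$label[ann$cluster == paste0("g", p, "lo")],
                 sprintf("prog%d", p))
  }

  zero <- matrix(0, 6, 4, dimnames = list(letters[1:6], c("w", "x", "y", "z")))
  ann0 <- annotate_clusters_by_signature(zero, rep(1:2, 3), list(s1 = c("w", "x")))
  expect_true(all(ann0$label == "unassigned"))

  one <- matrix(rnorm(24), 6, 4, dimnames = list(letters[1:6], c("w", "x", "y", "z")))
  ann1 <- annotate_clusters_by_signature(one, rep(1:2, 3), list(only = c("w", "x")))
  expect_true(all(ann1$label == "only"))
  expect_false(any(ann1$tie))
})
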