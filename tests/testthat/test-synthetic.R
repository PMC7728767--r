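test_that("generators are bit-identical under a fixed seed", {
  a <- gen_expression(50, 3, n_down = 5, n_up = 5, seed = 42)
  b <- gen_expression(50, 3, n_down = 5, n_up = 5, seed = 42)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  p1 <- gen_promoters(20, length = 201, planted_fraction = 0.5, seed = 9)
  p2 <- gen_promoters(20, length = 201, planted_fraction = 0.5, seed = 9)
  expect_identical(p1$promoters$seqs, p2$promoters$seqs)
  expect_identical(p1$truth$offsets, p2$truth$offsets)

  g1 <- gen_annotation(8, 500, "ER-skew", 60, seed = 4)
  g2 <- gen_annotation(8, 500, "ER-skew", 60, seed = 4)
  expect_identical(g1$annotation$term_sets, g2$annotation$term_sets)
  expect_identical(g1$gene_list, g2$gene_list)

  tss <- tss_index(c("g1", "g2"), "chr1", c(10000, 30000))
  k1 <- gen_peaks(tss, 5, 100, 5, c(chr1 = 50000), seed = 3)
  k2 <- gen_peaks(tss, 5, 100, 5, c(chr1 = 50000), seed = 3)
  expect_identical(k1$peaks, k2$peaks)

  j1 <- gen_junctions(0.4, 100, seed = 11)
  j2 <- gen_junctions(0.4, 100, seed = 11)
  expect_identical(j1$counts, j2$counts)
})

test_that("zero-noise expression reproduces planted effects exactly", {
  sim <- gen_expression(100, 3, n_down = 30, n_up = 20, effect_log2fc = 2,
                        noise_sd = 0, seed = 5)
  vals <- sim$matrix$values
  kd <- rowMeans(vals[, sim$matrix$group == "knockdown"])
  ctrl <- rowMeans(vals[, sim$matrix$group == "control"])
  diff <- kd - ctrl
  expect_equal(unname(diff[sim$truth$down_ids]), rep(-2, 30))
  expect_equal(unname(diff[sim$truth$up_ids]), rep(2, 20))
  expect_equal(unname(diff[setdiff(names(diff),
                                   c(sim$truth$down_ids, sim$truth$up_ids))]),
               rep(0, 50))
  expect_length(intersect(sim$truth$down_ids, sim$truth$up_ids), 0)
})

test_that("planted truth sets have the requested disjoint sizes", {
  sim <- gen_expression(500, 4, n_down = 100, n_up = 50, seed = 1)
  expect_length(sim$truth$down_ids, 100)
  expect_length(sim$truth$up_ids, 50)
  expect_length(intersect(sim$truth$down_ids, sim$truth$up_ids), 0)
  expect_error(gen_expression(100, 4, n_down = 80, n_up = 30),
               "must not exceed")
  expect_error(gen_expression(0, 4), "positive")
  expect_error(gen_expression(10, 4, effect_log2fc = 0), "nonzero")
})

test_that("rnaseq mode produces integer counts around the planted means", {
  sim <- gen_expression(300, 4, n_down = 30, n_up = 0, effect_log2fc = 3,
                        mode = "rnaseq", seed = 8)
  expect_true(all(sim$matrix$values == round(sim$matrix$values)))
  expect_true(all(sim$matrix$values >= 0))
  lc <- log2(sim$matrix$values + 1)
  diff <- rowMeans(lc[, sim$matrix$group == "knockdown"]) -
    rowMeans(lc[, sim$matrix$group == "control"])
  expect_lt(mean(diff[sim$truth$down_ids]), -1.5)
})

test_that("promoter planting honours placement, fraction and strand symmetry", {
  all0 <- gen_promoters(30, length = 401, planted_fraction = 1,
                        placement = "centered", sd_bp = 0, seed = 2)
  expect_equal(unname(all0$truth$offsets), rep(0, 30))
  none <- gen_promoters(30, length = 401, planted_fraction = 0, seed = 2)
  expect_length(none$truth$offsets, 0)
  expect_error(gen_promoters(5, length = 11, motif_consensus = paste(rep("A", 11), collapse = "")),
               "longer")
  # uniform placement: empirical mean offset within 3 SE of 0
  u <- gen_promoters(2000, length = 2001, planted_fraction = 1,
                     placement = "uniform", seed = 77)
  half_range <- (2001 - 5) / 2
  se <- sqrt((2 * half_range + 1)^2 / 12 / 2000)
  expect_lt(abs(mean(u$truth$offsets)), 3 * se)
  # planted copies are really in the sequences (either strand)
  p <- gen_promoters(50, length = 201, planted_fraction = 1,
                     placement = "centered", sd_bp = 20, seed = 13)
  hits <- vapply(p$promoters$seqs, function(s)
    grepl("CCAAT", s) || grepl("ATTGG", s), logical(1))
  expect_true(all(hits))
})

test_that("annotation profiles produce the designed block skews", {
  flat <- gen_annotation(12, 2000, "flat", 400, seed = 3)
  e <- enrich(flat$gene_list, flat$annotation)
  # flat: all per-term expected populations equal; observed spread is
  # binomial noise around a common mean
  expect_lt(max(abs(e$population_pct - mean(e$population_pct))), 5)

  ann <- gen_annotation_map(12, 2000, seed = 21)
  er <- gen_annotated_list(ann, "ER-skew", 400, seed = 22)
  cc <- gen_annotated_list(ann, "cellcycle-skew", 400, seed = 23)
  pop <- population_matrix(list(er = er, cc = cc), ann)
  b2 <- ann$blocks[rownames(pop)] == 2
  expect_true(all(pop[b2, "er"] > pop[b2, "cc"]))

  # same seed family, same profile: population vectors strongly correlated
  er2 <- gen_annotated_list(ann, "ER-skew", 400, seed = 24)
  pop2 <- population_matrix(list(a = er, b = er2), ann)
  expect_gt(correlate(pop2, "a", "b")$r, 0.9)

  expect_error(gen_annotation(3, 100, "flat", 10), ">= 4")
})

test_that("peak generator places near peaks on TSSs and is span-checked", {
  tss <- tss_index(sprintf("g%02d", 1:20), "chr1",
                   seq(10000, by = 10000, length.out = 20))
  exact <- gen_peaks(tss, 15, near_sd_bp = 0, n_background = 0,
                     genome_span = c(chr1 = 210000), peak_width = 200, seed = 6)
  centre <- floor((exact$peaks$start + exact$peaks$end) / 2)
  src_tss <- tss$tss[match(exact$truth$source_gene, tss$gene_id)]
  expect_equal(centre, src_tss)
  expect_equal(unique(exact$peaks$end - exact$peaks$start), 200)
  expect_error(gen_peaks(tss, 5, 0, 0, genome_span = c(chr1 = 1000)),
               "cover")
  # background-only: fraction within +/- 2000 of a TSS close to covered-span
  bg <- gen_peaks(tss, 0, 0, 4000, genome_span = c(chr1 = 210000), seed = 7)
  cb <- floor((bg$peaks$start + bg$peaks$end) / 2)
  near <- vapply(cb, function(x) any(abs(x - tss$tss) <= 2000), logical(1))
  covered <- 20 * 4001 / 210000
  expect_lt(abs(mean(near) - covered), 3 * sqrt(covered * (1 - covered) / 4000))
})

test_that("junction generator hits the Poisson limits and its PSI converges", {
  j1 <- gen_junctions(1, 50, seed = 1)
  expect_equal(j1$counts$n24, 0L)
  expect_equal(psi(j1$counts)$value, 1)
  j0 <- gen_junctions(0, 50, seed = 2)
  expect_equal(j0$counts$n23 + j0$counts$n34, 0L)
  expect_equal(psi(j0$counts)$value, 0)
  for (f in c(0.2, 0.7, 0.9)) {
    m <- mean(vapply(1:500, function(s)
      psi(gen_junctions(f, 200, seed = s)$counts)$value, numeric(1)),
      na.rm = TRUE)
    expect_lt(abs(m - f), 0.01)
  }
  expect_error(gen_junctions(1.2, 10), "\\[0, 1\\]")
  expect_error(gen_junctions(0.5, 0), "positive")
})
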