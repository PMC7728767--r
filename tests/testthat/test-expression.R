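make_matrix <- function(vals, group, mode = "array") {
  rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("s%d", seq_len(ncol(vals)))
  expression_matrix(vals, group, mode)
}

test_that("low-expression filters match their definitions and an oracle", {
  # rnaseq: max-count rule
  vals <- matrix(rep(seq(0, 900, by = 100), 3), ncol = 3)
  x <- make_matrix(vals, c("control", "control", "knockdown"), "rnaseq")
  f <- filter_low_expression(x, min_max_count = 200)
  expect_equal(nrow(f$values), 8)
  expect_false(any(c("g001", "g002") %in% rownames(f$values)))
  # idempotent in rnaseq mode
  expect_identical(filter_low_expression(f, min_max_count = 200)$values, f$values)

  # array: 100 distinct means at p = 20 -> exactly 20 removed
  vals2 <- matrix(rep(1:100, 4) + 0.0, ncol = 4)
  x2 <- make_matrix(vals2, c("control", "control", "knockdown", "knockdown"))
  f2 <- filter_low_expression(x2, percentile = 20)
  expect_equal(nrow(f2$values), 80)

  # random matrix vs sort-and-cut oracle
  set.seed(31)
  vals3 <- matrix(rnorm(500 * 6, 8, 2), ncol = 6)
  x3 <- make_matrix(vals3, rep(c("control", "knockdown"), each = 3))
  f3 <- filter_low_expression(x3, percentile = 20)
  means <- rowMeans(vals3)
  cut <- quantile(means, 0.2)
  oracle_keep <- sprintf("g%03d", which(means >= cut))
  expect_identical(rownames(f3$values), oracle_keep)

  expect_error(filter_low_expression(x, min_max_count = 1e9), "every gene")
})

test_that("identical groups yield no DEGs and degenerate genes follow the p conventions", {
  set.seed(5)
  half <- matrix(rnorm(50 * 3, 8, 1), ncol = 3)
  x <- make_matrix(cbind(half, half), rep(c("control", "knockdown"), each = 3))
  d <- call_degs(x, fc_min = 1, q_max = 0.05)
  expect_equal(sum(d$direction != "ns"), 0)
  # constant gene, equal means -> p = 1; constant, different means -> p = 0
  vals <- rbind(c(5, 5, 5, 5), c(5, 5, 9, 9))
  x2 <- make_matrix(vals, rep(c("control", "knockdown"), each = 2))
  d2 <- call_degs(x2)
  expect_equal(d2$p_value, c(1, 0))
  expect_error(call_degs(make_matrix(matrix(1:4, 2), c("control", "knockdown"))),
               "at least 2")
})

test_that("direction thresholds are inclusive at the boundary", {
  # one clean gene at exactly log2fc = -1 plus null genes; q for the clean
  # gene is far below q_max, so the boundary being tested is the fold change
  set.seed(7)
  null_vals <- matrix(rnorm(40 * 8, 8, 0.1), ncol = 8)
  hit <- c(rep(8, 4), rep(7, 4)) + rnorm(8, 0, 1e-6)
  vals <- rbind(hit, null_vals)
  x <- make_matrix(vals, rep(c("control", "knockdown"), each = 4))
  d <- call_degs(x, fc_min = abs(d_lfc <- mean(vals[1, 5:8]) - mean(vals[1, 1:4])),
                 q_max = 0.05)
  expect_equal(d$direction[1], "down")
  expect_equal(d$log2fc[1], d_lfc)
})

test_that("BH q-values dominate p-values and calls are order-invariant", {
  sim <- gen_expression(300, 4, n_down = 30, n_up = 20, noise_sd = 0.3, seed = 12)
  d <- call_degs(sim$matrix)
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  expect_equal(d$q_value, p.adjust(d$p_value, "BH"))
  # permuted gene order gives identical per-gene results
  perm <- sample(nrow(sim$matrix$values))
  xp <- expression_matrix(sim$matrix$values[perm, ], sim$matrix$group, "array")
  dp <- call_degs(xp)
  m <- match(d$gene_id, dp$gene_id)
  expect_equal(d$log2fc, dp$log2fc[m])
  expect_equal(d$q_value, dp$q_value[m])
  expect_equal(d$direction, dp$direction[m])
})

test_that("null simulation keeps the q <= 0.05 call rate near nominal", {
  rates <- vapply(1:20, function(s) {
    sim <- gen_expression(200, 4, n_down = 0, n_up = 0, noise_sd = 0.3,
                          seed = 400 + s)
    d <- call_degs(sim$matrix)
    mean(d$q_value <= 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("non-neuronal filter reproduces the fivefold rule and an oracle", {
  genes <- sprintf("g%02d", 1:20)
  neuron <- stats::setNames(rep(100, 20), genes)
  total <- neuron
  same <- filter_non_neuronal(genes, neuron, total)
  expect_equal(same$retained, genes)
  # neuron = total / 8: ratio 2^-3 < 1/5 -> removed
  neuron2 <- stats::setNames(rep(100, 20), genes)
  total2 <- stats::setNames(rep(807, 20), genes)  # (100+1)/(807+1) = 1/8
  gone <- filter_non_neuronal(genes, neuron2, total2)
  expect_length(gone$retained, 0)
  expect_equal(gone$removed, genes)

  set.seed(9)
  nv <- stats::setNames(rexp(200, 1 / 100), sprintf("g%03d", 1:200))
  tv <- stats::setNames(rexp(200, 1 / 100), sprintf("g%03d", 1:200))
  res <- filter_non_neuronal(names(nv), nv, tv, fold = 5)
  oracle_removed <- names(nv)[log2((nv + 1) / (tv + 1)) < -log2(5)]
  expect_setequal(res$removed, oracle_removed)
  expect_setequal(c(res$retained, res$removed), names(nv))

  expect_error(filter_non_neuronal(c("g01", "zzz"), nv, tv), "zzz")
})

test_that("Venn-region counts partition the union and match a membership tabulation", {
  a <- sprintf("g%03d", 1:50)
  same <- overlap_gene_sets(list(A = a, B = a))
  expect_equal(same$count[same$region == "A&B"], 50)
  expect_equal(sum(same$count), 50)
  disj <- overlap_gene_sets(list(A = a, B = sprintf("h%03d", 1:30)))
  expect_equal(disj$count[disj$region == "A&B"], 0)
  expect_equal(sum(disj$count), 80)

  set.seed(17)
  universe <- sprintf("u%04d", 1:1000)
  sets <- list(A = sample(universe, 200), B = sample(universe, 200),
               C = sample(universe, 200))
  res <- overlap_gene_sets(sets)
  union_genes <- unique(unlist(sets))
  for (i in seq_len(nrow(res))) {
    inside <- strsplit(res$region[i], "&")[[1]]
    outside <- setdiff(names(sets), inside)
    oracle <- sum(vapply(union_genes, function(g)
      all(vapply(inside, function(s) g %in% sets[[s]], logical(1))) &&
        !any(vapply(outside, function(s) g %in% sets[[s]], logical(1))),
      logical(1)))
    expect_equal(res$count[i], oracle)
  }
  expect_equal(sum(res$count), length(union_genes))
})
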