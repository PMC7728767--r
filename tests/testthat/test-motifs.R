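test_that("consensus PWM pseudocount arithmetic and log-odds follow the stated rules", {
  pw <- consensus_pwm("CCAAT", pseudocount = 0.01)
  # a consensus column (1,0,0,0): zero cells get the pseudocount, then the
  # column renormalises to (1, .01, .01, .01)/1.03
  expect_equal(pw$prob["C", 1], 1 / 1.03, tolerance = 1e-12)
  expect_equal(pw$prob["A", 1], 0.01 / 1.03, tolerance = 1e-12)
  expect_equal(colSums(pw$prob), rep(1, 5), ignore_attr = TRUE)
  lo <- log_odds(pw)
  expect_equal(lo["A", 3], log2((1 / 1.03) / 0.25), tolerance = 1e-12)
  # uniform column scores 0 everywhere
  uni <- pwm(matrix(0.25, 4, 4))
  expect_equal(log_odds(uni), matrix(0, 4, 4), ignore_attr = TRUE)
  # zero probability without pseudocount is rejected with advice
  raw <- matrix(c(1, 0, 0, 0), 4, 4)
  expect_error(log_odds(pwm(raw)), "pseudocount")
  # sequence score = sum of per-position entries
  s <- "CCAAT"
  expect_equal(best_site(s, pw)$score, sum(diag(lo[c("C", "C", "A", "A", "T"), ])))
})

test_that("best_site finds planted sites with strand symmetry and N handling", {
  pw <- consensus_pwm("CCAAT")
  bg <- paste(rep("G", 98), collapse = "")
  seq_f <- paste0(bg, "CCAAT", bg)  # 201 bp, site centred at the TSS
  b <- best_site(seq_f, pw)
  expect_equal(b$offset, 0)
  expect_equal(b$strand, "+")
  seq_r <- paste0(bg, "ATTGG", bg)
  br <- best_site(seq_r, pw)
  expect_equal(br$offset, 0)
  expect_equal(br$strand, "-")
  expect_equal(br$score, b$score)
  # all-N sequence has no site
  bn <- best_site(paste(rep("N", 30), collapse = ""), pw)
  expect_equal(bn$score, -Inf)
  expect_true(is.na(bn$offset))
})

test_that("best_site equals the exhaustive position-by-strand oracle", {
  pw <- consensus_pwm("CCAAT")
  lo <- log_odds(pw)
  set.seed(41)
  for (i in 1:60) {
    L <- sample(10:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    got <- best_site(s, pw)
    want <- oracle_best_site(s, lo)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
  # also with an even-length motif (half-integer offsets) and N bases
  pw6 <- consensus_pwm("CACGTG")
  lo6 <- log_odds(pw6)
  for (i in 1:30) {
    L <- sample(12:120, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- best_site(s, pw6)
    want <- oracle_best_site(s, lo6)
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("central enrichment reproduces closed-form binomial cases", {
  pw <- consensus_pwm("CCAAT")
  # GT-only background cannot contain CCAAT or ATTGG by chance, so each
  # planted copy is the unique maximal site
  set.seed(55)
  mk <- function(n, L) vapply(seq_len(n), function(i)
    paste(sample(c("G", "T"), L, replace = TRUE), collapse = ""), character(1))
  L <- 2001
  seqs <- mk(100, L)
  centre_start <- (L - 1) / 2 - 2
  substr(seqs, centre_start + 1, centre_start + 5) <- "CCAAT"
  prom <- promoter_set(seqs)
  ce <- central_enrichment(prom, pw, window_widths = 11)
  expect_equal(ce$n_scored, 100)
  expect_equal(ce$windows$k, 100)
  # all offsets 0: raw p = (11/1997)^100
  expect_equal(ce$windows$log10_raw_p, 100 * log10(11 / 1997), tolerance = 1e-6)
  # saturated window: k = n_scored, p0 = 1, raw p = 1
  sat <- central_enrichment(prom, pw, window_widths = 1997)
  expect_equal(sat$windows$p0, 1)
  expect_equal(sat$windows$raw_p, 1)
  expect_equal(sat$windows$k, 100)
  # adjusted p never below raw p
  multi <- central_enrichment(prom, pw)
  expect_true(all(multi$windows$adj_p >= multi$windows$raw_p - 1e-15))
  # no sequence above threshold -> flagged, p = 1
  none <- central_enrichment(promoter_set(mk(20, 2001)), pw)
  expect_true(none$no_sites)
  expect_equal(none$best$raw_p, 1)
})

test_that("binomial tail is monotone nonincreasing in k", {
  ks <- 0:50
  tails <- vapply(ks, function(k)
    nfypipe:::log10_binom_tail(k, 50, 0.1), numeric(1))
  expect_true(all(diff(tails) <= 1e-12))
})

test_that("the window count is invariant to sequence labels and reverse complement", {
  pw <- consensus_pwm("CCAAT")
  p <- gen_promoters(80, length = 1001, planted_fraction = 0.4,
                     placement = "centered", sd_bp = 80, seed = 19)
  ce <- central_enrichment(p$promoters, pw)
  # shuffled identity labels: a sequence-set statistic only
  shuffled <- p$promoters$seqs[sample(length(p$promoters$seqs))]
  ce_shuf <- central_enrichment(promoter_set(shuffled), pw)
  expect_equal(ce_shuf$windows$k, ce$windows$k)
  expect_equal(ce_shuf$n_scored, ce$n_scored)
  # reverse-complementing every sequence flips strands but not counts
  rc <- vapply(p$promoters$seqs, revcomp, character(1))
  ce_rc <- central_enrichment(promoter_set(rc), pw)
  expect_equal(ce_rc$windows$k, ce$windows$k, tolerance = 1e-12)
  expect_equal(ce_rc$n_scored, ce$n_scored)
})

test_that("panel comparison mirrors the down-specific CCAAT contrast", {
  down <- gen_promoters(500, planted_fraction = 0.3, placement = "centered",
                        sd_bp = 50, seed = 101)
  up <- gen_promoters(500, planted_fraction = 0.3, placement = "uniform",
                      seed = 102)
  tab <- compare_motif_panels(down$promoters, up$promoters,
                              pwm_panel = list(NFY_CCAAT = consensus_pwm("CCAAT")))
  p_down <- tab$adj_p[tab$set == "down"]
  p_up <- tab$adj_p[tab$set == "up"]
  expect_lt(p_down, 0.01)
  expect_gt(p_up, 0.05)
  # identical sets give identical results
  same <- compare_motif_panels(down$promoters, down$promoters)
  down_rows <- same[same$set == "down", -1]
  up_rows <- same[same$set == "up", -1]
  rownames(down_rows) <- rownames(up_rows) <- NULL
  expect_equal(down_rows, up_rows)
})

test_that("a GC-box motif lights up in both sets when both are centrally GC-rich", {
  # central GC-rich composition in both sets mirrors the shared SP2 signal
  mk_gc_centre <- function(seed) {
    p <- gen_promoters(200, length = 1001, planted_fraction = 0, seed = seed)
    seqs <- p$promoters$seqs
    set.seed(seed + 1)
    core <- vapply(seq_along(seqs), function(i)
      paste(sample(c("G", "C"), 61, replace = TRUE, prob = c(.6, .4)),
            collapse = ""), character(1))
    substr(seqs, 471, 531) <- core
    promoter_set(seqs)
  }
  sp2 <- consensus_pwm("GGGCGGG")
  r_down <- central_enrichment(mk_gc_centre(7), sp2)
  r_up <- central_enrichment(mk_gc_centre(8), sp2)
  expect_lt(r_down$best$adj_p, 0.01)
  expect_lt(r_up$best$adj_p, 0.01)
})

test_that("PFM files round-trip into PWMs", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c("10 0 0 0", "0 10 0 5", "0 0 10 5", "0 0 0 0"), path)
  pw <- read_pfm(path, name = "toy", pseudocount = 0.01)
  expect_equal(unname(pw$prob["A", 1]), 10 / 10.03, tolerance = 1e-12)
  expect_equal(unname(pw$prob["T", 1]), 0.01 / 10.03, tolerance = 1e-12)
  expect_error(read_pfm({
    p2 <- tempfile(); writeLines(c("1 2", "1 2", "1 2"), p2); p2
  }), "4 rows")
})
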