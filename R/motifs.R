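## Promoter-proximal motif centrality.
##
## Re-implements the centered-window binomial test popularised by CentriMo:
## for each promoter the best PWM site is located (both strands); for each
## centred window of width w the number of best sites falling inside is
## compared with a Binomial(n_scored, w/S) null, S being the number of valid
## site centres, with a Bonferroni correction over the tested widths.

#' Construct a position weight matrix
#'
#' @param prob 4 x m numeric matrix of per-position base probabilities, rows
#'   named A, C, G, T; each column must sum to 1 (within 1e-9). Motif length
#'   m >= 4.
#' @param name Motif name.
#' @param pseudocount Pseudocount that was used to regularise zero cells
#'   (recorded for provenance).
#' @return Object of class `pwm`.
#' @export
pwm <- function(prob, name = "motif", pseudocount = 0) {
  if (!is.matrix(prob) || nrow(prob) != 4)
    stopf("`prob` must be a 4-row matrix (A, C, G, T)")
  rownames(prob) <- c("A", "C", "G", "T")
  if (ncol(prob) < 4) stopf("motif length must be >= 4")
  if (any(abs(colSums(prob) - 1) > 1e-9))
    stopf("PWM columns must sum to 1")
  structure(list(name = name, prob = prob, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (length %d, pseudocount %g)\n",
              x$name, ncol(x$prob), x$pseudocount))
  print(round(x$prob, 4))
  invisible(x)
}

# Regularise a count/probability column: the pseudocount is added to zero
# cells only, then the column is renormalised (so a consensus column
# (1,0,0,0) with pseudocount 0.01 becomes (1, .01, .01, .01)/1.03).
regularise_counts <- function(counts, pseudocount) {
  counts[counts == 0] <- pseudocount
  sweep(counts, 2, colSums(counts), "/")
}

#' Build a PWM from a consensus string
#'
#' Each consensus base gets count 1 in its column; zero cells receive the
#' pseudocount and columns are renormalised.
#'
#' @param consensus Consensus string over ACGT (e.g. `"CCAAT"`).
#' @param name Motif name (defaults to the consensus).
#' @param pseudocount Pseudocount for zero cells (default 0.01).
#' @return A [pwm()].
#' @export
consensus_pwm <- function(consensus, name = consensus, pseudocount = 0.01) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T")))
    stopf("consensus must use only ACGT")
  counts <- vapply(bases, function(b) as.numeric(c("A", "C", "G", "T") == b),
                   numeric(4))
  pwm(regularise_counts(counts, pseudocount), name = name,
      pseudocount = pseudocount)
}

#' The default motif panel
#'
#' NF-Y CCAAT box, SP2-style GC box (GGGCGGG) and USF E-box (CACGTG), built
#' from their consensus strings with pseudocount 0.01.
#'
#' @return Named list of [pwm()] objects.
#' @export
default_pwm_panel <- function() {
  list(NFY_CCAAT = consensus_pwm("CCAAT", name = "NFY_CCAAT"),
       SP2_GCBOX = consensus_pwm("GGGCGGG", name = "SP2_GCBOX"),
       USF_EBOX = consensus_pwm("CACGTG", name = "USF_EBOX"))
}

#' Log-odds score matrix of a PWM
#'
#' Entry (b, i) is `log2(prob[b, i] / background[b])`. N bases score 0 by
#' convention (handled by the scanner, not the matrix).
#'
#' @param x A [pwm()].
#' @param background Background base probabilities (A, C, G, T); default
#'   uniform 0.25.
#' @return 4 x m numeric matrix of log2 odds.
#' @export
log_odds <- function(x, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$prob == 0))
    stopf("PWM contains zero probabilities; rebuild it with a pseudocount")
  log2(x$prob / background)
}

# Maximum achievable log-odds score of a PWM.
max_score <- function(x, background = rep(0.25, 4)) {
  sum(apply(log_odds(x, background), 2, max))
}

# Scan a promoter set with one PWM. Returns per-sequence best sites plus the
# full tied-maximum offset lists used for fractional window counting.
scan_promoters <- function(promoters, x, background = rep(0.25, 4)) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(x, "pwm"))
  if (promoters$length < ncol(x$prob)) stopf("sequences shorter than motif")
  scan_pwm_cpp(unname(promoters$seqs), log_odds(x, background))
}

#' Best PWM site of a single sequence
#'
#' Maximal log-odds site over all start positions and both strands (the
#' reverse strand is scored on the reverse complement). The site centre is
#' reported in bp relative to the sequence centre (the TSS for promoter
#' input). Ties are broken by smallest |offset|, then + strand, then
#' leftmost. An all-N sequence has no site (score `-Inf`).
#'
#' @param sequence A single ACGTN string (length >= motif length).
#' @param x A [pwm()].
#' @return List with `offset` (bp relative to the centre; half-integer for
#'   even motif length), `strand` and `score`.
#' @export
best_site <- function(sequence, x) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            inherits(x, "pwm"))
  if (nchar(sequence) < ncol(x$prob)) stopf("sequence shorter than motif")
  res <- scan_pwm_cpp(sequence, log_odds(x))
  list(offset = res$offset[1], strand = as.character(res$strand[1]),
       score = res$score[1])
}

# log10 of the upper binomial tail P(X >= k | n, p), computed in log space.
log10_binom_tail <- function(k, n, p) {
  if (k <= 0) return(0)
  if (k > n) return(-Inf)
  pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Test local (TSS-proximal) enrichment of a motif in a promoter set
#'
#' For each promoter the best site is located; promoters whose best score
#' reaches `score_threshold` are "scored". For each odd window width w the
#' number k of best-site centres with |offset| <= (w-1)/2 is compared with
#' the Binomial(n_scored, w/S) null, S = L - m + 1 being the number of valid
#' site centres; raw tail probabilities are computed in log space and
#' Bonferroni-adjusted by the number of tested widths. When several sites
#' tie for a sequence's maximum score, each of the t tied sites contributes
#' 1/t to k (so the expected k is `n_scored * w/S` exactly under a uniform site law and
#' the binomial reference is conservative).
#'
#' @param promoters A [promoter_set()].
#' @param x A [pwm()].
#' @param score_threshold Minimum best-site log-odds for a sequence to count
#'   as scored; default `threshold_fraction` of the motif's maximum
#'   achievable score.
#' @param window_widths Odd centred window widths to test.
#' @param threshold_fraction Fraction of the maximum score used when
#'   `score_threshold` is NULL (default 0.6).
#' @return Object of class `local_enrichment`: list with `motif`,
#'   `n_scored`, `n_input`, `windows` (data.frame: width, k, p0,
#'   log10_raw_p, raw_p, adj_p), `best` (row of `windows` with minimal
#'   adjusted p), `population_pct` (100 * best-window k / n_input) and
#'   `no_sites` flag.
#' @export
central_enrichment <- function(promoters, x, score_threshold = NULL,
                               window_widths = c(11, 21, 51, 101, 201, 401, 801),
                               threshold_fraction = 0.6) {
  stopifnot(inherits(promoters, "promoter_set"), inherits(x, "pwm"))
  m <- ncol(x$prob)
  L <- promoters$length
  S <- L - m + 1
  if (any(window_widths %% 2 == 0)) stopf("window widths must be odd")
  if (any(window_widths > S)) stopf("window width exceeds the %d valid centres", S)
  if (is.null(score_threshold))
    score_threshold <- threshold_fraction * max_score(x)
  scan <- scan_promoters(promoters, x)
  scored <- is.finite(scan$score) & scan$score >= score_threshold
  n_scored <- sum(scored)
  nw <- length(window_widths)
  if (n_scored == 0) {
    windows <- data.frame(width = window_widths, k = 0, p0 = window_widths / S,
                          log10_raw_p = 0, raw_p = 1, adj_p = 1,
                          log10_adj_p = 0)
    out <- list(motif = x$name, n_scored = 0L, n_input = length(promoters$seqs),
                windows = windows, best = windows[1, ],
                population_pct = 0, no_sites = TRUE,
                score_threshold = score_threshold)
    class(out) <- "local_enrichment"
    return(out)
  }
  ties <- scan$tie_offsets[scored]
  k <- vapply(window_widths, function(w) {
    h <- (w - 1) / 2
    sum(vapply(ties, function(off) mean(abs(off) <= h), numeric(1)))
  }, numeric(1))
  p0 <- window_widths / S
  log10_raw <- mapply(function(kk, pp)
    log10_binom_tail(ceiling(kk - 1e-9), n_scored, pp), k, p0)
  log10_adj <- pmin(0, log10_raw + log10(nw))
  windows <- data.frame(width = window_widths, k = k, p0 = p0,
                        log10_raw_p = log10_raw, raw_p = 10^log10_raw,
                        adj_p = 10^log10_adj, log10_adj_p = log10_adj)
  best <- windows[which.min(log10_adj + window_widths * 1e-12), , drop = FALSE]
  out <- list(motif = x$name, n_scored = n_scored,
              n_input = length(promoters$seqs),
              windows = windows, best = best,
              population_pct = 100 * best$k / length(promoters$seqs),
              no_sites = FALSE, score_threshold = score_threshold)
  class(out) <- "local_enrichment"
  out
}

#' @export
print.local_enrichment <- function(x, ...) {
  if (x$no_sites) {
    cat(sprintf("<local_enrichment> %s: no sites above threshold\n", x$motif))
    return(invisible(x))
  }
  cat(sprintf(
    "<local_enrichment> %s: %d/%d sequences scored; best window %d bp (k = %.1f, adj p = %.3g, population %.1f%%)\n",
    x$motif, x$n_scored, x$n_input, x$best$width, x$best$k, x$best$adj_p,
    x$population_pct))
  invisible(x)
}

#' Compare motif centrality between down- and up-regulated promoter sets
#'
#' Runs [central_enrichment()] for every (promoter set, motif) combination,
#' mirroring the contrast in which the CCAAT box is proximally enriched for
#' down-regulated genes only while a GC box shows up in both sets.
#'
#' @param down_promoters,up_promoters [promoter_set()] objects.
#' @param pwm_panel Named list of [pwm()] objects (default
#'   [default_pwm_panel()]).
#' @param ... Passed to [central_enrichment()].
#' @return data.frame with one row per (set, motif): `set`, `motif`,
#'   `n_scored`, `best_width`, `k`, `raw_p`, `adj_p`, `population_pct`.
#'   Attribute `results` keeps the full `local_enrichment` objects.
#' @export
compare_motif_panels <- function(down_promoters, up_promoters,
                                 pwm_panel = default_pwm_panel(), ...) {
  if (length(pwm_panel) == 0) stopf("empty motif panel")
  sets <- list(down = down_promoters, up = up_promoters)
  rows <- list()
  results <- list()
  for (set_name in names(sets)) {
    for (motif_name in names(pwm_panel)) {
      r <- central_enrichment(sets[[set_name]], pwm_panel[[motif_name]], ...)
      results[[paste(set_name, motif_name, sep = ".")]] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, motif = r$motif, n_scored = r$n_scored,
        best_width = r$best$width, k = r$best$k,
        raw_p = r$best$raw_p, adj_p = r$best$adj_p,
        population_pct = r$population_pct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
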