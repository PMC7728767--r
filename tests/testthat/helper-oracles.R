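# Brute-force reference implementations used as independent oracles.
# These deliberately use naive enumeration, never the package's code paths.

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Score one subsequence against a 4 x m log-odds matrix; N scores 0.
oracle_window_score <- function(chars, lo) {
  idx <- match(chars, c("A", "C", "G", "T"))
  sum(vapply(seq_along(idx), function(i)
    if (is.na(idx[i])) 0 else lo[idx[i], i], numeric(1)))
}

# Exhaustive best site over all (start, strand) pairs with the tie rule:
# smallest |offset|, then '+' strand, then leftmost.
oracle_best_site <- function(seq, lo) {
  m <- ncol(lo)
  L <- nchar(seq)
  chars_f <- strsplit(seq, "")[[1]]
  chars_r <- strsplit(revcomp(seq), "")[[1]]
  rows <- list()
  for (start in 0:(L - m)) {
    fs <- oracle_window_score(chars_f[start + seq_len(m)], lo)
    # reverse-strand site occupying the same positions: the reverse
    # complement of the window, read 5'->3'
    rs <- oracle_window_score(chars_r[(L - m - start) + seq_len(m)], lo)
    off <- start + (m - 1) / 2 - (L - 1) / 2
    rows[[length(rows) + 1]] <- data.frame(off = off, strand = "+", score = fs)
    rows[[length(rows) + 1]] <- data.frame(off = off, strand = "-", score = rs)
  }
  tab <- do.call(rbind, rows)
  best <- tab[abs(tab$score - max(tab$score)) <= 1e-9, ]
  best <- best[order(abs(best$off), best$strand != "+", best$off), ]
  list(offset = best$off[1], strand = best$strand[1], score = max(tab$score))
}

# Exact two-sided Fisher p by full hypergeometric enumeration: sum of all
# table probabilities not exceeding that of the observed table.
oracle_fisher_two_sided <- function(k, n_list, K, N) {
  lo <- max(0, n_list + K - N)
  hi <- min(n_list, K)
  probs <- dhyper(lo:hi, K, N - K, n_list)
  p_obs <- dhyper(k, K, N - K, n_list)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive consensus peaks: enumerate every tuple taking one peak per set
# (per chromosome), keep tuples whose max start minus min end is <= max_gap,
# take union spans, and merge overlapping spans.
oracle_consensus <- function(peak_sets, max_gap) {
  chroms <- unique(unlist(lapply(peak_sets, function(p) p$chrom)))
  out <- NULL
  for (ch in chroms) {
    per <- lapply(peak_sets, function(p) p[p$chrom == ch, , drop = FALSE])
    if (any(vapply(per, nrow, integer(1)) == 0)) next
    grid <- expand.grid(lapply(per, function(p) seq_len(nrow(p))))
    spans <- NULL
    for (r in seq_len(nrow(grid))) {
      starts <- mapply(function(p, i) p$start[i], per, grid[r, ])
      ends <- mapply(function(p, i) p$end[i], per, grid[r, ])
      if (max(starts) - min(ends) <= max_gap)
        spans <- rbind(spans, data.frame(lo = min(starts), hi = max(ends)))
    }
    if (is.null(spans)) next
    spans <- unique(spans[order(spans$lo, spans$hi), ])
    merged <- spans[1, ]
    for (r in seq_len(nrow(spans))[-1]) {
      last <- nrow(merged)
      if (spans$lo[r] < merged$hi[last]) {
        merged$hi[last] <- max(merged$hi[last], spans$hi[r])
      } else {
        merged <- rbind(merged, spans[r, ])
      }
    }
    out <- rbind(out, data.frame(chrom = ch, lo = merged$lo, hi = merged$hi))
  }
  if (is.null(out)) return(out)
  out[order(out$chrom, out$lo), , drop = FALSE]
}

# All-pairs TSS annotation scan.
oracle_annotate <- function(peaks, tss, window) {
  centre <- floor((peaks$start + peaks$end) / 2)
  do.call(rbind, lapply(seq_len(nrow(tss)), function(i) {
    cc <- centre[peaks$chrom == tss$chrom[i]]
    d <- abs(cc - tss$tss[i])
    data.frame(gene_id = tss$gene_id[i],
               proximal = length(d) > 0 && any(d <= window),
               min_dist = if (length(d) > 0) min(d) else NA_real_)
  }))
}

# Small random peak set on one chromosome.
random_peak_set <- function(n, span = 10000, seed = 1, chrom = "chr1") {
  set.seed(seed)
  start <- sort(sample.int(span, n))
  peak_set(rep(chrom, n), start, start + sample(20:200, n, replace = TRUE))
}
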