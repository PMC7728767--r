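## Consensus ChIP peaks and TSS-proximal target assignment.
##
## Peaks are plain data.frames in BED convention (0-based half-open). A
## consensus peak is emitted wherever every input experiment contributes a
## peak such that all pairwise gaps are at most `max_gap` (overlap counts as
## gap 0); a gene is a proximal target when some peak centre lies within a
## closed +/- window around its TSS.

#' Construct a peak set
#'
#' @param chrom,start,end Vectors describing 0-based half-open intervals
#'   (`start < end`).
#' @param name,score,strand Optional BED6 columns.
#' @return `peak_set` data.frame with columns chrom, start, end, name,
#'   score, strand.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0, strand = ".") {
  if (any(start >= end)) stopf("peak intervals need start < end")
  if (any(!nzchar(chrom))) stopf("chrom names must be nonempty")
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   name = if (is.null(name)) sprintf("peak%05d", seq_len(n)) else name,
                   score = rep_len(score, n), strand = rep_len(strand, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Construct a TSS index
#'
#' One TSS per gene id; genes with multiple annotated TSSs must be
#' pre-selected upstream.
#'
#' @param gene_id,chrom,tss,strand Per-gene vectors (`tss` in bp).
#' @return `tss_index` data.frame.
#' @export
tss_index <- function(gene_id, chrom, tss, strand = "+") {
  if (anyDuplicated(gene_id)) stopf("gene ids must be unique (one TSS per gene)")
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = as.numeric(tss), strand = rep_len(strand, length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("tss_index", "data.frame")
  df
}

# Gap between two half-open intervals; negative or zero when they overlap.
interval_gap <- function(s1, e1, s2, e2) pmax(s1, s2) - pmin(e1, e2)

#' Build consensus peaks supported by every input set
#'
#' A consensus peak is emitted wherever each input set contributes one peak
#' such that all pairwise gaps are `<= max_gap` (equivalently: the maximum
#' start minus the minimum end over the tuple is `<= max_gap`; overlapping
#' peaks have gap 0). The consensus interval is the union span of the
#' contributing peaks; overlapping consensus intervals are merged.
#'
#' @param peak_sets Named list of >= 2 `peak_set` data.frames.
#' @param max_gap Maximum pairwise end-to-start gap in bp (default 100).
#' @return A [peak_set()] of consensus intervals.
#' @export
overlap_peak_sets <- function(peak_sets, max_gap = 100) {
  if (length(peak_sets) < 2) stopf("need at least two peak sets")
  chroms <- unique(unlist(lapply(peak_sets, function(p) p$chrom)))
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  for (ch in chroms) {
    per_set <- lapply(peak_sets, function(p) p[p$chrom == ch, , drop = FALSE])
    if (any(vapply(per_set, nrow, integer(1)) == 0)) next
    # depth-first join: extend partial tuples set by set, pruning with the
    # running span condition max(starts) - min(ends) <= max_gap
    spans <- data.frame(max_start = per_set[[1]]$start,
                        min_end = per_set[[1]]$end,
                        lo = per_set[[1]]$start, hi = per_set[[1]]$end)
    for (j in seq_along(per_set)[-1]) {
      pj <- per_set[[j]]
      new <- vector("list", 0)
      for (t in seq_len(nrow(spans))) {
        ok <- pmax(spans$max_start[t], pj$start) -
          pmin(spans$min_end[t], pj$end) <= max_gap
        if (any(ok)) {
          new[[length(new) + 1L]] <- data.frame(
            max_start = pmax(spans$max_start[t], pj$start[ok]),
            min_end = pmin(spans$min_end[t], pj$end[ok]),
            lo = pmin(spans$lo[t], pj$start[ok]),
            hi = pmax(spans$hi[t], pj$end[ok]))
        }
      }
      if (length(new) == 0) { spans <- spans[0, ]; break }
      spans <- do.call(rbind, new)
    }
    if (nrow(spans) == 0) next
    # merge overlapping consensus unions
    ir <- IRanges::reduce(IRanges::IRanges(start = spans$lo + 1, end = spans$hi),
                          min.gapwidth = 0L)
    out_chrom <- c(out_chrom, rep(ch, length(ir)))
    out_start <- c(out_start, IRanges::start(ir) - 1)
    out_end <- c(out_end, IRanges::end(ir))
  }
  if (length(out_chrom) == 0)
    return(peak_set(character(0), numeric(0), numeric(0))[0, ])
  ord <- order(out_chrom, out_start)
  peak_set(out_chrom[ord], out_start[ord], out_end[ord],
           name = sprintf("consensus%05d", seq_along(ord)))
}

#' Assign peaks to genes by TSS proximity
#'
#' A gene is a proximal target iff some peak centre (floor of the interval
#' midpoint) lies within the closed window `[TSS - window, TSS + window]`.
#' Genes whose chromosome carries peaks but none within the window are
#' classed `distal-only`. Peaks on chromosomes absent from the TSS index
#' raise a warning and stay unassigned.
#'
#' @param peaks A [peak_set()].
#' @param tss A [tss_index()].
#' @param window Half-window in bp (default 2000).
#' @return `target_calls` data.frame: `gene_id`, `class` (`proximal` /
#'   `distal-only`), `n_supporting` (peaks within the window), `min_dist`
#'   (bp from nearest peak centre on the chromosome; NA when the chromosome
#'   has no peak).
#' @export
annotate_to_tss <- function(peaks, tss, window = 2000) {
  stopifnot(inherits(tss, "tss_index"))
  if (window <= 0) stopf("window must be positive")
  orphan <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(orphan) > 0)
    warning(sprintf("peaks on %d chromosome(s) absent from the TSS index were not assigned: %s",
                    length(orphan), paste(orphan, collapse = ", ")),
            call. = FALSE)
  centre <- floor((peaks$start + peaks$end) / 2)
  res <- lapply(seq_len(nrow(tss)), function(i) {
    cc <- centre[peaks$chrom == tss$chrom[i]]
    if (length(cc) == 0)
      return(data.frame(gene_id = tss$gene_id[i], class = "distal-only",
                        n_supporting = 0L, min_dist = NA_real_,
                        stringsAsFactors = FALSE))
    d <- abs(cc - tss$tss[i])
    n_sup <- sum(d <= window)
    data.frame(gene_id = tss$gene_id[i],
               class = if (n_sup > 0) "proximal" else "distal-only",
               n_supporting = n_sup, min_dist = min(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  attr(out, "window") <- window
  out
}

#' Proximal target gene ids from target calls
#'
#' @param calls A `target_calls` data.frame from [annotate_to_tss()].
#' @return Character vector of proximal target gene ids.
#' @export
target_ids <- function(calls) calls$gene_id[calls$class == "proximal"]

#' Overlap structure of named target-gene sets
#'
#' @param named_target_sets Named list of >= 2 gene-id vectors.
#' @return List with `venn` (exclusive Venn-region counts, see
#'   [overlap_gene_sets()]) and `jaccard` (pairwise Jaccard indices).
#' @export
target_set_overlap <- function(named_target_sets) {
  list(venn = overlap_gene_sets(named_target_sets),
       jaccard = pairwise_jaccard(named_target_sets))
}
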