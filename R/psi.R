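## Exon-3 inclusion (percent spliced in) from splice-junction read counts.
##
## Reads spanning the exon2-exon3 or exon3-exon4 junctions support the
## inclusion isoform (NF-YA-L); reads spanning exon2-exon4 support the
## skipping isoform (NF-YA-S). The inclusion fraction is
## (n23 + n34) / (n23 + n34 + 2 * n24): the skipping count is doubled
## because one skipping transcript offers a single junction where an
## inclusion transcript offers two.

#' Construct junction counts
#'
#' @param n23,n34,n24 Nonnegative integer read counts spanning the
#'   exon2-exon3, exon3-exon4 and exon2-exon4 junctions.
#' @param sample_id Sample label.
#' @return Object of class `junction_counts`.
#' @export
junction_counts <- function(n23, n34, n24, sample_id = "sample") {
  counts <- c(n23 = n23, n34 = n34, n24 = n24)
  if (any(counts < 0)) stopf("junction counts must be nonnegative")
  if (any(counts != round(counts))) stopf("junction counts must be integers")
  structure(list(n23 = as.integer(n23), n34 = as.integer(n34),
                 n24 = as.integer(n24), sample_id = sample_id),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("<junction_counts> %s: n23 = %d, n34 = %d, n24 = %d\n",
              x$sample_id, x$n23, x$n34, x$n24))
  invisible(x)
}

#' Exon-inclusion fraction (percent spliced in) from junction counts
#'
#' `value = (n23 + n34) / (n23 + n34 + 2 * n24)`. Undefined (NA) when the
#' denominator is 0; an undefined estimate propagates as missing, never 0.
#'
#' @param counts A [junction_counts()], or `n23` given as a plain count with
#'   `n34`, `n24`.
#' @param n34,n24 Counts when `counts` is given as a number.
#' @return Object of class `psi_estimate`: list with `value` (in `[0, 1]` or
#'   NA), `total` (informative count `n23 + n34 + 2 * n24`) and `sample_id`.
#' @export
psi <- function(counts, n34 = NULL, n24 = NULL) {
  if (!inherits(counts, "junction_counts")) {
    if (is.null(n34) || is.null(n24))
      stopf("supply a junction_counts object or all three counts")
    counts <- junction_counts(counts, n34, n24)
  }
  total <- counts$n23 + counts$n34 + 2 * counts$n24
  value <- if (total > 0) (counts$n23 + counts$n34) / total else NA_real_
  structure(list(value = value, total = total, sample_id = counts$sample_id),
            class = "psi_estimate")
}

#' @export
print.psi_estimate <- function(x, ...) {
  cat(sprintf("<psi_estimate> %s: PSI = %s (informative count %d)\n",
              x$sample_id,
              if (is.na(x$value)) "undefined" else sprintf("%.3f", x$value),
              x$total))
  invisible(x)
}

#' Construct a three-exon splicing model
#'
#' Genomic coordinates of exons 2, 3 and 4 of the cassette (0-based
#' half-open), ordered and non-overlapping.
#'
#' @param chrom Chromosome name.
#' @param starts,ends Length-3 vectors of exon coordinates (exons 2, 3, 4).
#' @param strand `"+"` or `"-"`.
#' @return Object of class `exon_model`.
#' @export
exon_model <- function(chrom, starts, ends, strand = "+") {
  if (length(starts) != 3 || length(ends) != 3)
    stopf("need coordinates for exactly exons 2, 3 and 4")
  if (any(starts >= ends)) stopf("exons need start < end")
  if (is.unsorted(starts, strictly = TRUE) || any(ends[-3] > starts[-1]))
    stopf("exons must be ordered and non-overlapping")
  structure(list(chrom = chrom, start = starts, end = ends, strand = strand,
                 exon = c(2L, 3L, 4L)), class = "exon_model")
}

# The three informative introns of an exon model (0-based half-open):
# 2-3, 3-4 and 2-4.
informative_introns <- function(model) {
  data.frame(junction = c("n23", "n34", "n24"),
             start = c(model$end[1], model$end[2], model$end[1]),
             end = c(model$start[2], model$start[3], model$start[3]),
             stringsAsFactors = FALSE)
}

#' Extract exon-cassette junction counts from a junction table
#'
#' Sums the counts of junction records whose intron coordinates (0-based
#' half-open, same chromosome convention as the model) exactly match the
#' exon2-exon3, exon3-exon4 or exon2-exon4 introns; all other records are
#' ignored. Duplicate identical intron records are summed with a warning.
#'
#' @param junction_table data.frame with columns `chrom`, `intron_start`,
#'   `intron_end`, `count`.
#' @param model An [exon_model()].
#' @param sample_id Sample label for the result.
#' @return A [junction_counts()].
#' @export
extract_junction_counts <- function(junction_table, model,
                                    sample_id = "sample") {
  need <- c("chrom", "intron_start", "intron_end", "count")
  if (!all(need %in% names(junction_table)))
    stopf("junction table needs columns %s", paste(need, collapse = ", "))
  introns <- informative_introns(model)
  key <- paste(junction_table$chrom, junction_table$intron_start,
               junction_table$intron_end)
  want <- paste(model$chrom, introns$start, introns$end)
  hits <- key %in% want
  if (anyDuplicated(key[hits]))
    warning("duplicate junction records for the same intron were summed",
            call. = FALSE)
  counts <- vapply(want, function(w)
    sum(junction_table$count[key == w]), numeric(1))
  junction_counts(counts[1], counts[2], counts[3], sample_id = sample_id)
}

#' Long-isoform fraction from protein band amounts
#'
#' `ratio_L = L / (L + S)` from densitometric amounts of the NF-YA-L and
#' NF-YA-S bands.
#'
#' @param L_amount,S_amount Nonnegative amounts, not both zero.
#' @param cell Cell label.
#' @return List with `ratio_L` and `cell`.
#' @export
isoform_ratio <- function(L_amount, S_amount, cell = "cell") {
  if (L_amount < 0 || S_amount < 0) stopf("amounts must be nonnegative")
  if (L_amount + S_amount == 0) stopf("amounts must not both be zero")
  list(ratio_L = L_amount / (L_amount + S_amount), cell = cell)
}

#' Correlate isoform ratios with functional-block populations
#'
#' For each term block, the block population of a cell is the sum of its
#' term populations; the Pearson correlation of that quantity with the
#' per-cell long-isoform ratio is reported, reproducing the contrast in
#' which ER/trafficking blocks correlate positively and cell-cycle blocks
#' negatively with exon-3 inclusion.
#'
#' @param ratios Named numeric vector: long-isoform ratio per cell.
#' @param pop_matrix Term x cell population matrix (see
#'   [population_matrix()]).
#' @param blocks Named integer vector term -> block id (see
#'   [assign_blocks()] or the generator's block labels).
#' @return data.frame with columns `block`, `r`, `n_cells`.
#' @export
correlate_isoform_with_clusters <- function(ratios, pop_matrix, blocks) {
  cells <- intersect(names(ratios), colnames(pop_matrix))
  if (length(cells) < 3) stopf("need at least 3 cells shared between ratios and matrix")
  if (stats::sd(ratios[cells]) == 0)
    stopf("isoform ratios are constant; correlation undefined")
  blocks <- blocks[rownames(pop_matrix)]
  rows <- lapply(sort(unique(blocks)), function(b) {
    y <- colSums(pop_matrix[blocks == b, cells, drop = FALSE])
    if (stats::sd(y) == 0)
      stopf("block %s populations are constant; correlation undefined", b)
    data.frame(block = b, r = cor(ratios[cells], y), n_cells = length(cells))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
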