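## Differential expression calling and the study's expression filters.
##
## The filtering constants follow the knockdown study design: array genes
## below the 20th percentile of mean expression are dropped; RNA-seq genes
## whose maximum count is below 200 are dropped; genes depleted more than
## fivefold in isolated striatal neurons relative to total striatum are
## treated as non-neuronal and removed from DEG sets.

#' Remove lowly expressed genes
#'
#' In array mode, genes whose mean log2 intensity (across all samples) lies
#' strictly below the `percentile`-th percentile of all gene means are
#' removed. In rnaseq mode, genes whose maximum count across samples is
#' strictly below `min_max_count` are removed. Gene order is preserved.
#'
#' @param x An [expression_matrix()].
#' @param percentile Percentile cut in (0, 100) (array mode). Percentiles use
#'   linear interpolation (`stats::quantile` type 7).
#' @param min_max_count Minimum maximum-count `c >= 0` (rnaseq mode).
#' @return The filtered [expression_matrix()].
#' @export
filter_low_expression <- function(x, percentile = 20, min_max_count = 200) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$mode == "array") {
    if (percentile <= 0 || percentile >= 100)
      stopf("percentile must lie in (0, 100)")
    means <- rowMeans(x$values)
    cut <- quantile(means, percentile / 100, names = FALSE)
    keep <- means >= cut
  } else {
    if (min_max_count < 0) stopf("min_max_count must be >= 0")
    keep <- apply(x$values, 1, max) >= min_max_count
  }
  if (!any(keep))
    stopf("low-expression filter removed every gene; check the threshold")
  expression_matrix(x$values[keep, , drop = FALSE], x$group, x$mode)
}

# Welch two-sample t-test p-value for one gene, with the degenerate-data
# convention: both groups constant -> p = 1 if the means agree, 0 otherwise.
welch_p <- function(kd, ctrl) {
  if (stats::sd(kd) == 0 && stats::sd(ctrl) == 0) {
    return(if (isTRUE(all.equal(mean(kd), mean(ctrl)))) 1 else 0)
  }
  tryCatch(t.test(kd, ctrl)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(kd), mean(ctrl)))) 1 else 0)
}

#' Call differentially expressed genes
#'
#' Per-gene Welch two-sample t-test of knockdown vs control on the log2
#' scale (rnaseq counts are transformed `log2(x + 1)` first), with
#' Benjamini-Hochberg adjustment across all tested genes. Direction
#' thresholds are inclusive: a gene is `down` iff `log2fc <= -fc_min` and
#' `q <= q_max`, `up` iff `log2fc >= fc_min` and `q <= q_max`, else `ns`.
#'
#' @param x An [expression_matrix()] (normally already filtered with
#'   [filter_low_expression()]).
#' @param fc_min Minimum absolute log2 fold change (> 0). Default 1 mirrors a
#'   standard twofold cut; 0.58 (1.5-fold) suits a low-cutoff run.
#' @param q_max BH FDR threshold in (0, 1).
#' @return A `deg_table` data.frame with columns `gene_id`, `log2fc`
#'   (knockdown minus control), `p_value`, `q_value`, `direction`.
#' @export
call_degs <- function(x, fc_min = 1, q_max = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (fc_min <= 0) stopf("fc_min must be positive")
  if (q_max <= 0 || q_max >= 1) stopf("q_max must lie in (0, 1)")
  if (any(table(x$group) < 2))
    stopf("each group needs at least 2 samples for the Welch test")
  vals <- x$values
  if (x$mode == "rnaseq") vals <- log2(vals + 1)
  kd <- vals[, x$group == "knockdown", drop = FALSE]
  ctrl <- vals[, x$group == "control", drop = FALSE]
  log2fc <- rowMeans(kd) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(vals)),
              function(i) welch_p(kd[i, ], ctrl[i, ]), numeric(1))
  q <- p.adjust(p, method = "BH")
  direction <- rep("ns", nrow(vals))
  direction[log2fc <= -fc_min & q <= q_max] <- "down"
  direction[log2fc >= fc_min & q <= q_max] <- "up"
  res <- data.frame(gene_id = rownames(vals), log2fc = log2fc,
                    p_value = p, q_value = q, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("deg_table", "data.frame")
  attr(res, "fc_min") <- fc_min
  attr(res, "q_max") <- q_max
  res
}

#' @export
print.deg_table <- function(x, ...) {
  n <- table(factor(x$direction, levels = c("down", "up", "ns")))
  cat(sprintf("<deg_table> %d genes tested: %d down, %d up (|log2FC| >= %g, q <= %g)\n",
              nrow(x), n[["down"]], n[["up"]],
              attr(x, "fc_min"), attr(x, "q_max")))
  invisible(print.data.frame(head(as.data.frame(x), 6)))
}

#' Extract the gene ids called in one direction
#'
#' @param degs A `deg_table` from [call_degs()].
#' @param direction `"down"` or `"up"`.
#' @return Character vector of gene ids.
#' @export
deg_ids <- function(degs, direction = c("down", "up")) {
  direction <- match.arg(direction)
  degs$gene_id[degs$direction == direction]
}

#' Remove non-neuronal genes from a gene set
#'
#' A gene is non-neuronal when its expression in isolated neurons is depleted
#' more than `fold`-fold relative to the total tissue:
#' `log2((neuron + 1) / (total + 1)) < -log2(fold)` (linear-scale inputs, +1
#' pseudocount).
#'
#' @param gene_set Character vector of gene ids.
#' @param neuron_expr,total_expr Named linear-scale expression vectors
#'   covering every gene in `gene_set`.
#' @param fold Depletion fold threshold (default 5).
#' @return List with `retained` and `removed` gene-id vectors.
#' @export
filter_non_neuronal <- function(gene_set, neuron_expr, total_expr, fold = 5) {
  missing <- setdiff(gene_set, intersect(names(neuron_expr), names(total_expr)))
  if (length(missing) > 0)
    stopf("genes missing from reference expression vectors: %s",
          paste(missing, collapse = ", "))
  ratio <- log2((neuron_expr[gene_set] + 1) / (total_expr[gene_set] + 1))
  removed <- gene_set[ratio < -log2(fold)]
  list(retained = setdiff(gene_set, removed), removed = removed)
}

#' Venn-region counts for named gene sets
#'
#' Counts every exclusive region of the Venn partition of `named_sets`;
#' the counts sum to the size of the union.
#'
#' @param named_sets Named list of >= 2 character vectors.
#' @return data.frame with columns `region` (set names joined by `&`) and
#'   `count`; attribute `union_size`.
#' @export
overlap_gene_sets <- function(named_sets) {
  if (length(named_sets) < 2 || is.null(names(named_sets)))
    stopf("need a named list of at least two sets")
  sets <- lapply(named_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  k <- length(sets)
  all_patterns <- unlist(lapply(seq_len(k), function(i)
    utils::combn(names(sets), i, paste, collapse = "&")))
  counts <- table(factor(pattern, levels = all_patterns))
  res <- data.frame(region = names(counts), count = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "union_size") <- length(universe)
  res
}

#' Pairwise Jaccard indices of named gene sets
#'
#' @param named_sets Named list of >= 2 character vectors.
#' @return data.frame with columns `set_a`, `set_b`, `jaccard`.
#' @export
pairwise_jaccard <- function(named_sets) {
  if (length(named_sets) < 2) stopf("need at least two sets")
  pairs <- utils::combn(names(named_sets), 2)
  jac <- apply(pairs, 2, function(p) {
    a <- unique(named_sets[[p[1]]]); b <- unique(named_sets[[p[2]]])
    u <- length(union(a, b))
    if (u == 0) return(NA_real_)
    length(intersect(a, b)) / u
  })
  data.frame(set_a = pairs[1, ], set_b = pairs[2, ], jaccard = jac,
             stringsAsFactors = FALSE)
}
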