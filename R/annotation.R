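## Functional-annotation enrichment, population matrices and clustering.
##
## "Population" is used throughout in the pie-graph sense: the percentage of
## an input gene list annotated to a term (100 * k / n_list). It is the
## quantity assembled into cross-cell-type matrices, correlated between
## platforms and clustered with Ward linkage.

#' Construct an annotation map
#'
#' @param term_sets Named list mapping term -> character vector of gene ids;
#'   terms must be nonempty and every annotated gene must belong to the
#'   universe.
#' @param universe Character vector: the background gene universe.
#' @param blocks Optional named integer vector of term block labels
#'   (functional-cluster analogue).
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(term_sets, universe, blocks = NULL) {
  if (length(term_sets) == 0 || is.null(names(term_sets)))
    stopf("`term_sets` must be a nonempty named list")
  if (any(lengths(term_sets) == 0)) stopf("terms must be nonempty")
  universe <- unique(universe)
  term_sets <- lapply(term_sets, unique)
  outside <- setdiff(unlist(term_sets, use.names = FALSE), universe)
  if (length(outside) > 0)
    stopf("%d annotated genes are missing from the universe", length(outside))
  if (!is.null(blocks)) blocks <- blocks[names(term_sets)]
  structure(list(term_sets = term_sets, universe = universe, blocks = blocks),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d terms over a universe of %d genes%s\n",
              length(x$term_sets), length(x$universe),
              if (is.null(x$blocks)) "" else
                sprintf(" (%d blocks)", length(unique(x$blocks)))))
  invisible(x)
}

#' Per-term enrichment of a gene list
#'
#' For each term with K universe hits and k list hits out of a list of size
#' n in a universe of size N: population percentage `100 * k / n`, fold
#' enrichment `(k/n) / (K/N)` and the exact two-sided Fisher p of the 2x2
#' table (k, n-k; K-k, N-K-n+k). Genes outside the universe are dropped with
#' a warning.
#'
#' @param gene_list Character vector of gene ids.
#' @param annotation An [annotation_map()].
#' @return `enrichment_table` data.frame: `term`, `k`, `n_list`, `K`, `N`,
#'   `population_pct`, `fold`, `fisher_p`.
#' @export
enrich <- function(gene_list, annotation) {
  stopifnot(inherits(annotation, "annotation_map"))
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0) stopf("empty gene list")
  outside <- setdiff(gene_list, annotation$universe)
  if (length(outside) > 0) {
    warning(sprintf("%d genes outside the universe were dropped",
                    length(outside)), call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
    if (length(gene_list) == 0) stopf("no list genes inside the universe")
  }
  n <- length(gene_list)
  N <- length(annotation$universe)
  rows <- lapply(names(annotation$term_sets), function(term) {
    genes <- annotation$term_sets[[term]]
    K <- length(genes)
    k <- length(intersect(gene_list, genes))
    p <- fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2))$p.value
    data.frame(term = term, k = k, n_list = n, K = K, N = N,
               population_pct = 100 * k / n,
               fold = (k / n) / (K / N), fisher_p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Assemble a term x list population matrix
#'
#' @param named_lists Named list (>= 2) of gene-id vectors, one per cell
#'   type / condition.
#' @param annotation An [annotation_map()].
#' @param term_subset Optional character vector restricting the rows.
#' @return Numeric matrix (terms x lists) of population percentages; absent
#'   term/list combinations are 0.
#' @export
population_matrix <- function(named_lists, annotation, term_subset = NULL) {
  if (length(named_lists) < 2 || is.null(names(named_lists)))
    stopf("need a named list of at least two gene lists")
  terms <- names(annotation$term_sets)
  if (!is.null(term_subset)) {
    terms <- intersect(terms, term_subset)
    if (length(terms) == 0) stopf("term_subset matches no terms")
  }
  cols <- lapply(named_lists, function(lst) {
    e <- suppressWarnings(enrich(lst, annotation))
    stats::setNames(e$population_pct, e$term)[terms]
  })
  mat <- do.call(cbind, cols)
  mat[is.na(mat)] <- 0
  dimnames(mat) <- list(terms, names(named_lists))
  mat
}

#' Pearson correlation between two columns of a population matrix
#'
#' @param mat Numeric matrix (terms x lists).
#' @param col_a,col_b Column names or indices.
#' @return List with `r` and `n_pairs` (rows with finite values in both).
#' @export
correlate <- function(mat, col_a, col_b) {
  x <- mat[, col_a]
  y <- mat[, col_b]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stopf("need at least 3 shared terms with finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stopf("zero variance in a column; correlation undefined")
  list(r = cor(x[ok], y[ok]), n_pairs = sum(ok))
}

#' Ward hierarchical clustering of a population matrix
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage in the
#' squared-distance convention (`hclust` method `"ward.D2"`), over either
#' the list (column) axis or the term (row) axis.
#'
#' @param mat Numeric matrix (terms x lists).
#' @param axis `"lists"` (cluster columns) or `"terms"` (cluster rows).
#' @return An `hclust` object.
#' @export
cluster_populations <- function(mat, axis = c("lists", "terms")) {
  axis <- match.arg(axis)
  if (any(!is.finite(mat))) stopf("matrix contains non-finite values")
  items <- if (axis == "lists") t(mat) else mat
  if (nrow(items) < 2) stopf("need at least 2 items on the '%s' axis", axis)
  hclust(dist(items, method = "euclidean"), method = "ward.D2")
}

#' Cut a term dendrogram into labelled blocks
#'
#' Cuts the tree at the height yielding exactly `n_clusters` groups and
#' relabels cluster ids 1..n by order of first appearance along the leaf
#' order, so ids are stable for a given tree.
#'
#' @param hc An `hclust` object (e.g. from [cluster_populations()]).
#' @param n_clusters Number of blocks (<= number of leaves).
#' @return Named integer vector term -> block id.
#' @export
assign_blocks <- function(hc, n_clusters = 4) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (n_clusters > n) stopf("n_clusters exceeds the number of leaves")
  raw <- cutree(hc, k = n_clusters)
  leaf_order <- hc$labels[hc$order]
  first_seen <- unique(raw[leaf_order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
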