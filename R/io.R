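## Readers and writers for the plain-text interchange formats.
##
## Expression matrices travel as TSV with the group label embedded in the
## sample header (`sample|group`); promoters as FASTA; annotations as GMT;
## peaks and TSS tables as BED6; junction tables as 4-column TSV with
## 0-based half-open introns.

#' Write / read an expression matrix TSV
#'
#' The header row is `gene_id` followed by one `sample|group` column per
#' sample, so the two-group design round-trips with the values.
#'
#' @param x An [expression_matrix()].
#' @param path File path.
#' @return `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste(colnames(x$values), x$group, sep = "|")
  attr_line <- sprintf("#mode=%s", x$mode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  mode <- sub("^#mode=", "", first)
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(names(df)[-1], "|", fixed = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  colnames(vals) <- vapply(parts, `[`, character(1), 1)
  expression_matrix(vals, vapply(parts, `[`, character(1), 2), mode)
}

#' Write / read promoters as FASTA
#'
#' Headers carry `gene_id|-H:H` where H is the TSS half-window implied by
#' the sequence length.
#'
#' @param promoters A [promoter_set()].
#' @param path File path.
#' @return `read_promoters_fasta` returns a [promoter_set()].
#' @export
write_promoters_fasta <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  h <- (promoters$length - 1) / 2
  dna <- Biostrings::DNAStringSet(promoters$seqs)
  names(dna) <- sprintf("%s|-%d:%d", names(promoters$seqs), h, h)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\|.*$", "", names(dna))
  promoter_set(seqs)
}

#' Write / read an annotation map as GMT
#'
#' One line per term: term, description (the block label or `NA`), then the
#' gene ids. The universe is not part of the GMT format; on reading it
#' defaults to the union of all term genes unless supplied.
#'
#' @param annotation An [annotation_map()].
#' @param path File path.
#' @param universe Optional universe for `read_gmt`.
#' @return `read_gmt` returns an [annotation_map()].
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  lines <- vapply(names(annotation$term_sets), function(term) {
    desc <- if (is.null(annotation$blocks)) "NA" else
      as.character(annotation$blocks[[term]])
    paste(c(term, desc, annotation$term_sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  term_sets <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t"), `[`, character(1), 2)
  blocks <- suppressWarnings(as.integer(desc))
  names(blocks) <- names(term_sets)
  if (all(is.na(blocks))) blocks <- NULL
  if (is.null(universe))
    universe <- unique(unlist(term_sets, use.names = FALSE))
  annotation_map(term_sets, universe, blocks = blocks)
}

#' Write / read peaks or a TSS table as BED6
#'
#' Files go through `rtracklayer`; coordinates are converted between the
#' 1-based `GRanges` convention and the 0-based half-open data frames used
#' here.
#'
#' @param peaks A [peak_set()] (or `tss_index` for the TSS variants).
#' @param path File path (`.bed`).
#' @return Readers return a [peak_set()] / [tss_index()].
#' @export
write_bed6 <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = ifelse(peaks$strand %in% c("+", "-"), peaks$strand, "*"),
    name = peaks$name, score = peaks$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- if (!is.null(gr$name)) gr$name else sprintf("peak%05d", seq_along(gr))
  sc <- if (!is.null(gr$score)) gr$score else 0
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
           name = nm, score = sc, strand = strand)
}

#' @rdname write_bed6
#' @export
write_tss_bed6 <- function(tss, path) {
  stopifnot(inherits(tss, "tss_index"))
  write_bed6(peak_set(tss$chrom, tss$tss, tss$tss + 1,
                      name = tss$gene_id, strand = tss$strand), path)
}

#' @rdname write_bed6
#' @export
read_tss_bed6 <- function(path) {
  p <- read_bed6(path)
  tss_index(p$name, p$chrom, p$start, p$strand)
}

#' Write / read a junction table TSV
#'
#' Columns chrom, intron_start, intron_end, count; introns are 0-based
#' half-open.
#'
#' @param tab data.frame with the four junction columns.
#' @param path File path.
#' @return `read_junction_tsv` returns the data.frame.
#' @export
write_junction_tsv <- function(tab, path) {
  write.table(tab[, c("chrom", "intron_start", "intron_end", "count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_tsv
#' @export
read_junction_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a DEG table TSV
#'
#' @param degs A `deg_table` from [call_degs()].
#' @param path File path.
#' @return `read_deg_tsv` returns the `deg_table`.
#' @export
write_deg_tsv <- function(degs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fc_min=%g\tq_max=%g",
                     attr(degs, "fc_min"), attr(degs, "q_max")), con)
  write.table(as.data.frame(degs), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_tsv
#' @export
read_deg_tsv <- function(path) {
  first <- readLines(path, n = 1)
  nums <- as.numeric(regmatches(first, gregexpr("[0-9.]+", first))[[1]])
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                   stringsAsFactors = FALSE)
  class(df) <- c("deg_table", "data.frame")
  attr(df, "fc_min") <- nums[1]
  attr(df, "q_max") <- nums[2]
  df
}

#' Write / read a one-id-per-line gene list
#'
#' @param ids Character vector of gene ids.
#' @param path File path.
#' @return `read_gene_list` returns the character vector.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) readLines(path)

#' Read a plain-text PFM motif file
#'
#' Four whitespace-separated rows in A, C, G, T order holding counts or
#' probabilities; zero cells receive the pseudocount before columns are
#' normalised.
#'
#' @param path File path.
#' @param name Motif name (defaults to the file name).
#' @param pseudocount Pseudocount for zero cells.
#' @return A [pwm()].
#' @export
read_pfm <- function(path, name = NULL, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  if (length(lines) != 4)
    stopf("PFM file must contain exactly 4 rows (A, C, G, T)")
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(unique(lengths(rows))) != 1)
    stopf("PFM rows have unequal lengths")
  counts <- do.call(rbind, rows)
  if (anyNA(counts)) stopf("PFM contains non-numeric entries")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pwm(regularise_counts(counts, pseudocount), name = name,
      pseudocount = pseudocount)
}
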