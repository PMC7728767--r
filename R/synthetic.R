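## Synthetic-data generators.
##
## Every input the pipeline consumes can be simulated here with known ground
## truth (which genes were perturbed, where motifs were planted, the true
## exon-inclusion fraction, ...), so each downstream stage has a recovery
## test that does not depend on external downloads.

#' Construct an expression matrix object
#'
#' Container for a genes x samples expression matrix with a two-group design,
#' either array-style log2 intensities or RNA-seq counts.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns. Log2 intensities in `"array"` mode, nonnegative integer
#'   counts in `"rnaseq"` mode.
#' @param group Character/factor of per-sample labels, `"control"` or
#'   `"knockdown"`, one per column.
#' @param mode `"array"` or `"rnaseq"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `group` (factor) and `mode`.
#' @export
expression_matrix <- function(values, group, mode = c("array", "rnaseq")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stopf("`values` must have unique rownames (gene ids)")
  if (length(group) != ncol(values))
    stopf("`group` must have one label per sample column")
  group <- factor(as.character(group), levels = c("control", "knockdown"))
  if (anyNA(group))
    stopf("group labels must be 'control' or 'knockdown'")
  if (any(!is.finite(values)))
    stopf("expression values must be finite")
  if (mode == "rnaseq" && any(values < 0 | values != round(values)))
    stopf("rnaseq values must be nonnegative integers")
  structure(list(values = values, group = group, mode = mode),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s mode; %d control, %d knockdown)\n",
              nrow(x$values), ncol(x$values), x$mode,
              sum(x$group == "control"), sum(x$group == "knockdown")))
  invisible(x)
}

#' Simulate a two-group expression experiment with planted effects
#'
#' Emulates a control-vs-knockdown design. In `"array"` mode per-gene
#' baseline log2 intensities are drawn from Normal(`baseline_mean`,
#' `baseline_sd`) with Gaussian replicate noise; in `"rnaseq"` mode counts
#' are drawn from a negative binomial around `2^baseline` with fixed
#' dispersion. Planted genes are shifted by `-effect_log2fc` (down set) or
#' `+effect_log2fc` (up set) in the knockdown group.
#'
#' @param n_genes,n_per_group Dimensions of the experiment.
#' @param n_down,n_up Numbers of planted down-/up-regulated genes.
#' @param effect_log2fc Planted absolute log2 fold change (nonzero).
#' @param noise_sd Replicate noise SD on the log2 scale (array mode;
#'   may be 0 for the exact zero-noise limit).
#' @param mode `"array"` or `"rnaseq"`.
#' @param baseline_mean,baseline_sd Baseline log2-intensity distribution.
#' @param dispersion Negative-binomial dispersion (rnaseq mode).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`, a list
#'   holding `down_ids`, `up_ids` (disjoint) and the generator parameters.
#' @export
gen_expression <- function(n_genes, n_per_group, n_down = 0, n_up = 0,
                           effect_log2fc = 2, noise_sd = 0.5,
                           mode = c("array", "rnaseq"),
                           baseline_mean = 8, baseline_sd = 2,
                           dispersion = 0.1, seed = 1) {
  mode <- match.arg(mode)
  if (n_genes < 1 || n_per_group < 1)
    stopf("n_genes and n_per_group must be positive")
  if (n_down + n_up > n_genes)
    stopf("n_down + n_up must not exceed n_genes")
  if (effect_log2fc == 0) stopf("effect_log2fc must be nonzero")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  with_seed(seed, {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    planted <- sample(ids, n_down + n_up)
    down_ids <- planted[seq_len(n_down)]
    up_ids <- setdiff(planted, down_ids)
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    names(baseline) <- ids
    n_s <- 2L * n_per_group
    group <- rep(c("control", "knockdown"), each = n_per_group)
    shift <- numeric(n_genes)
    names(shift) <- ids
    shift[down_ids] <- -abs(effect_log2fc)
    shift[up_ids] <- abs(effect_log2fc)
    mu_log2 <- outer(baseline, rep(1, n_s)) +
      outer(shift, as.numeric(group == "knockdown"))
    if (mode == "array") {
      vals <- mu_log2 + matrix(rnorm(n_genes * n_s, 0, noise_sd), n_genes)
    } else {
      vals <- matrix(rnbinom(n_genes * n_s, mu = 2^mu_log2,
                             size = 1 / dispersion), n_genes)
    }
    dimnames(vals) <- list(ids, sprintf("%s_%d", group,
                                        rep(seq_len(n_per_group), 2)))
    list(matrix = expression_matrix(vals, group, mode),
         truth = list(down_ids = down_ids, up_ids = up_ids,
                      effect_log2fc = effect_log2fc, mode = mode))
  })
}

#' Construct a promoter set
#'
#' Equal-length strand-oriented promoter sequences centred on the TSS:
#' position `(L-1)/2` (0-based) is the TSS and increasing index runs
#' downstream of the gene.
#'
#' @param seqs Named character vector of equal-length ACGTN sequences
#'   (odd length).
#' @return Object of class `promoter_set`.
#' @export
promoter_set <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0)
    stopf("`seqs` must be a nonempty character vector")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stopf("all promoter sequences must have equal length")
  if (L %% 2 == 0) stopf("promoter length must be odd (TSS-centred)")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("sequences contain characters outside ACGTN")
  structure(list(seqs = seqs, length = L), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d sequences of length %d (TSS +/- %d bp)\n",
              length(x$seqs), x$length, (x$length - 1) / 2))
  invisible(x)
}

#' Simulate TSS-centred promoter sequences with planted motif copies
#'
#' Background bases are i.i.d. with the given GC fraction. In a chosen
#' fraction of sequences one exact copy of `motif_consensus` replaces the
#' background bases at an offset drawn from the placement law (strand chosen
#' fairly; a reverse-strand copy is written as the reverse complement).
#'
#' @param n Number of promoters.
#' @param length Sequence length (odd; default 2001 = TSS +/- 1000 bp).
#' @param motif_consensus Consensus string planted verbatim (e.g. "CCAAT").
#' @param planted_fraction Fraction of sequences receiving a planted copy.
#' @param placement `"centered"` (offset ~ Normal(0, `sd_bp`), clamped to the
#'   valid range) or `"uniform"` (all valid start positions equally likely).
#' @param sd_bp SD of the centered placement law, in bp.
#' @param gc_fraction Background GC content.
#' @param seed Integer seed.
#' @return List with `promoters` (a [promoter_set()]) and `truth`; truth
#'   element `offsets` is a named numeric vector of planted site centres in
#'   bp relative to the TSS (absent sequences are not listed).
#' @export
gen_promoters <- function(n, length = 2001, motif_consensus = "CCAAT",
                          planted_fraction = 0, placement = c("centered", "uniform"),
                          sd_bp = 50, gc_fraction = 0.5, seed = 1) {
  placement <- match.arg(placement)
  m <- nchar(motif_consensus)
  if (m >= length) stopf("motif longer than sequence")
  if (planted_fraction < 0 || planted_fraction > 1)
    stopf("planted_fraction must lie in [0, 1]")
  if (length %% 2 == 0) stopf("`length` must be odd")
  with_seed(seed, {
    L <- length
    base_prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                   G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    chars <- matrix(sample(names(base_prob), n * L, replace = TRUE,
                           prob = base_prob), nrow = n)
    ids <- sprintf("gene%05d", seq_len(n))
    n_planted <- round(planted_fraction * n)
    planted_idx <- if (n_planted > 0) sort(sample.int(n, n_planted)) else integer(0)
    tss0 <- (L - 1) / 2              # 0-based TSS index
    max_start0 <- L - m              # 0-based start range [0, L - m]
    centre_start <- tss0 - (m - 1) / 2
    motif_f <- strsplit(motif_consensus, "")[[1]]
    motif_r <- rev(chartr("ACGT", "TGCA", motif_f))
    offsets <- numeric(0)
    if (n_planted > 0) {
      starts <- if (placement == "centered") {
        pmin(pmax(round(centre_start + rnorm(n_planted, 0, sd_bp)), 0), max_start0)
      } else {
        sample.int(max_start0 + 1L, n_planted, replace = TRUE) - 1L
      }
      strands <- sample(c("+", "-"), n_planted, replace = TRUE)
      for (j in seq_len(n_planted)) {
        i <- planted_idx[j]
        cols <- starts[j] + seq_len(m)   # 1-based columns
        chars[i, cols] <- if (strands[j] == "+") motif_f else motif_r
      }
      offsets <- starts + (m - 1) / 2 - tss0
      names(offsets) <- ids[planted_idx]
    }
    seqs <- apply(chars, 1, paste0, collapse = "")
    names(seqs) <- ids
    list(promoters = promoter_set(seqs),
         truth = list(offsets = offsets, motif = motif_consensus,
                      placement = placement, planted_ids = ids[planted_idx]))
  })
}

#' Simulate a block-structured annotation map
#'
#' Partitions a gene universe into four disjoint pools, one per term block
#' (mirroring functional clusters such as endosome/Golgi, ER/lipid,
#' cell cycle/mitosis, mitochondrion/DNA damage), plus an unannotated
#' remainder. Each pool gene is annotated to each term of its block
#' independently with probability `within_block_rate`.
#'
#' @param n_terms Number of terms (>= 4; split as evenly as possible over the
#'   four blocks).
#' @param universe_size Size of the background gene universe.
#' @param within_block_rate Per-term annotation probability inside a pool.
#' @param seed Integer seed.
#' @return An [annotation_map()] whose `blocks` attribute labels each term
#'   with its block (1-4).
#' @export
gen_annotation_map <- function(n_terms, universe_size,
                               within_block_rate = 0.7, seed = 1) {
  if (n_terms < 4) stopf("n_terms must be >= 4 (four term blocks)")
  with_seed(seed, {
    universe <- sprintf("gene%05d", seq_len(universe_size))
    pool_size <- floor(universe_size / 5)
    pools <- split(universe[seq_len(4 * pool_size)],
                   rep(1:4, each = pool_size))
    blocks <- sort(rep(1:4, length.out = n_terms))
    term_ids <- sprintf("term%02d_block%d", seq_len(n_terms), blocks)
    term_sets <- lapply(seq_len(n_terms), function(t) {
      pool <- pools[[blocks[t]]]
      pool[rbinom(length(pool), 1, within_block_rate) == 1]
    })
    names(term_sets) <- term_ids
    annotation_map(term_sets, universe, blocks = stats::setNames(blocks, term_ids))
  })
}

# Block composition multipliers for the three designed list profiles.
profile_multipliers <- function(profile) {
  switch(profile,
         "flat" = c(1, 1, 1, 1),
         "ER-skew" = c(2, 3, 0.5, 0.5),
         "cellcycle-skew" = c(0.5, 0.5, 3, 2),
         stopf("unknown profile '%s'", profile))
}

#' Sample a gene list with a designed annotation-population skew
#'
#' Draws `list_size` genes from the pools of a [gen_annotation_map()] map so
#' that per-term populations follow the chosen profile: a flat profile draws
#' equally from all four blocks, `"ER-skew"` over-samples blocks 1-2 (with
#' block 2 at ~3x the flat rate) and `"cellcycle-skew"` over-samples blocks
#' 3-4. The remainder of the list is filled from unannotated genes.
#'
#' @param annotation An [annotation_map()] with block labels and pooled
#'   structure from [gen_annotation_map()].
#' @param profile `"flat"`, `"ER-skew"` or `"cellcycle-skew"`.
#' @param list_size Number of genes in the list.
#' @param base_fraction Fraction of the list drawn from each block pool under
#'   the flat profile.
#' @param seed Integer seed.
#' @return Character vector of gene ids (attribute `profile` records truth).
#' @export
gen_annotated_list <- function(annotation, profile = c("flat", "ER-skew", "cellcycle-skew"),
                               list_size, base_fraction = 0.1, seed = 1) {
  profile <- match.arg(profile)
  if (list_size > length(annotation$universe))
    stopf("list_size exceeds universe size")
  mult <- profile_multipliers(profile)
  with_seed(seed, {
    universe <- annotation$universe
    pool_size <- floor(length(universe) / 5)
    pools <- split(universe[seq_len(4 * pool_size)],
                   rep(1:4, each = pool_size))
    rest <- universe[(4 * pool_size + 1):length(universe)]
    n_b <- round(base_fraction * mult * list_size)
    if (any(n_b > pool_size))
      stopf("list_size too large for the block pools")
    picked <- unlist(lapply(1:4, function(b) sample(pools[[b]], n_b[b])),
                     use.names = FALSE)
    n_fill <- list_size - length(picked)
    if (n_fill > length(rest)) stopf("list_size too large for the universe")
    if (n_fill > 0) picked <- c(picked, sample(rest, n_fill))
    structure(picked, profile = profile)
  })
}

#' Simulate an annotation map plus one skewed gene list
#'
#' Convenience wrapper combining [gen_annotation_map()] and
#' [gen_annotated_list()]; the map is derived from the same seed so repeated
#' calls with one seed are bit-identical.
#'
#' @inheritParams gen_annotation_map
#' @inheritParams gen_annotated_list
#' @return List with `annotation`, `gene_list` and `truth` (profile label).
#' @export
gen_annotation <- function(n_terms, universe_size,
                           profile = c("flat", "ER-skew", "cellcycle-skew"),
                           list_size, seed = 1) {
  profile <- match.arg(profile)
  ann <- gen_annotation_map(n_terms, universe_size, seed = derive_seed(seed, 1))
  lst <- gen_annotated_list(ann, profile, list_size, seed = derive_seed(seed, 2))
  list(annotation = ann, gene_list = lst,
       truth = list(profile = profile))
}

#' Simulate ChIP peaks clustered near TSSs plus uniform background
#'
#' `n_near` peaks are centred at a sampled TSS plus Normal(0, `near_sd_bp`)
#' jitter; `n_background` peak centres are uniform over the genome span. All
#' peaks have fixed width `peak_width`.
#'
#' @param tss_index A [tss_index()] (one TSS per gene).
#' @param n_near,n_background Peak counts of each class.
#' @param near_sd_bp SD of the TSS-proximal jitter in bp.
#' @param genome_span Named numeric vector of chromosome lengths; must cover
#'   every TSS.
#' @param peak_width Fixed peak width in bp.
#' @param seed Integer seed.
#' @return List with `peaks` (a `peak_set` data.frame: chrom, start, end,
#'   name, score, strand; 0-based half-open) and `truth` (`source_gene` per
#'   near peak, NA for background peaks).
#' @export
gen_peaks <- function(tss_index, n_near, near_sd_bp, n_background,
                      genome_span, peak_width = 200, seed = 1) {
  if (is.null(names(genome_span)))
    stopf("genome_span must be a named vector of chromosome lengths")
  if (!all(tss_index$chrom %in% names(genome_span)) ||
      any(tss_index$tss > genome_span[tss_index$chrom]))
    stopf("genome_span must cover every TSS")
  with_seed(seed, {
    src <- if (n_near > 0)
      tss_index[sample.int(nrow(tss_index), n_near, replace = TRUE), ] else
      tss_index[0, ]
    near_centre <- if (n_near > 0)
      src$tss + round(rnorm(n_near, 0, near_sd_bp)) else numeric(0)
    bg_chrom <- if (n_background > 0)
      sample(names(genome_span), n_background, replace = TRUE,
             prob = genome_span / sum(genome_span)) else character(0)
    bg_centre <- if (n_background > 0)
      floor(runif(n_background, 0, genome_span[bg_chrom])) else numeric(0)
    chrom <- c(src$chrom, bg_chrom)
    centre <- c(near_centre, bg_centre)
    start <- pmax(0, round(centre - peak_width / 2))
    peaks <- data.frame(chrom = chrom, start = start,
                        end = start + peak_width,
                        name = sprintf("peak%05d", seq_along(chrom)),
                        score = 0, strand = ".",
                        stringsAsFactors = FALSE)
    rownames(peaks) <- NULL
    list(peaks = peaks,
         truth = list(source_gene = c(src$gene_id,
                                      rep(NA_character_, n_background)),
                      n_near = n_near, peak_width = peak_width))
  })
}

#' Simulate splice-junction read counts at a known inclusion fraction
#'
#' Reads spanning the exon2-exon3 and exon3-exon4 junctions arise from the
#' inclusion isoform, reads spanning exon2-exon4 from the skipping isoform:
#' `n23 ~ Poisson(depth * f)`, `n34 ~ Poisson(depth * f)`,
#' `n24 ~ Poisson(depth * (1 - f))`, independently.
#'
#' @param true_fraction True exon-3 inclusion fraction `f` in `[0, 1]`.
#' @param depth Expected junction read depth (lambda > 0).
#' @param seed Integer seed.
#' @param sample_id Label carried on the counts.
#' @return List with `counts` (a [junction_counts()]) and `truth`.
#' @export
gen_junctions <- function(true_fraction, depth, seed = 1, sample_id = "sim") {
  if (true_fraction < 0 || true_fraction > 1)
    stopf("true_fraction must lie in [0, 1]")
  if (depth <= 0) stopf("depth must be positive")
  with_seed(seed, {
    n23 <- rpois(1, depth * true_fraction)
    n34 <- rpois(1, depth * true_fraction)
    n24 <- rpois(1, depth * (1 - true_fraction))
    list(counts = junction_counts(n23, n34, n24, sample_id = sample_id),
         truth = list(true_fraction = true_fraction, depth = depth))
  })
}

#' Render junction counts as a junction table with decoy records
#'
#' Produces the tab-delimited junction format (chrom, intron_start,
#' intron_end, count; 0-based half-open introns) that
#' [extract_junction_counts()] consumes, with the three informative introns
#' of an exon model plus optional non-matching decoy records.
#'
#' @param counts A [junction_counts()].
#' @param model An [exon_model()].
#' @param n_decoys Number of random non-matching junction records to add.
#' @param seed Integer seed for the decoys.
#' @return data.frame with columns chrom, intron_start, intron_end, count.
#' @export
gen_junction_table <- function(counts, model, n_decoys = 0, seed = 1) {
  introns <- informative_introns(model)
  tab <- data.frame(chrom = model$chrom,
                    intron_start = introns$start,
                    intron_end = introns$end,
                    count = c(counts$n23, counts$n34, counts$n24))
  if (n_decoys > 0) {
    tab <- with_seed(seed, {
      span <- max(model$end) + 10000
      ds <- sort(sample.int(span, n_decoys))
      decoys <- data.frame(chrom = model$chrom, intron_start = ds,
                           intron_end = ds + sample(50:500, n_decoys,
                                                    replace = TRUE),
                           count = rpois(n_decoys, 20))
      keep <- !(paste(decoys$intron_start, decoys$intron_end) %in%
                  paste(introns$start, introns$end))
      rbind(tab, decoys[keep, ])
    })
  }
  rownames(tab) <- NULL
  tab
}
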