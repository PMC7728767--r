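## End-to-end orchestration on synthetic inputs.
##
## One configuration drives every stage with the study's constants as
## defaults; per-stage seeds are derived from the master seed so a fixed
## (config, seed) pair yields a byte-identical report.

#' Build a pipeline configuration
#'
#' Defaults are the study constants: promoters TSS +/- 1000 bp, ChIP window
#' TSS +/- 2000 bp, consensus max gap 100 bp, array low-expression cut at
#' the 20th percentile, RNA-seq minimum max-count 200, fivefold
#' non-neuronal rule, |log2FC| >= 1 and q <= 0.05 DEG thresholds.
#'
#' @param tss_half_window,chip_half_window,max_gap Window constants in bp.
#' @param low_expr_percentile,min_max_count,neuron_fold Filter constants.
#' @param fc_min,q_max DEG thresholds.
#' @param seed Master integer seed (nonnegative).
#' @param n_genes,n_per_group,n_down,n_up,effect_log2fc,noise_sd Synthetic
#'   experiment design.
#' @param n_promoters,motif_planted_fraction,motif_sd_bp Promoter simulation
#'   design.
#' @param ... Unknown keys are rejected by [validate_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tss_half_window = 1000, chip_half_window = 2000,
                            max_gap = 100, low_expr_percentile = 20,
                            min_max_count = 200, neuron_fold = 5,
                            fc_min = 1, q_max = 0.05, seed = 1,
                            n_genes = 2000, n_per_group = 4,
                            n_down = 100, n_up = 50, effect_log2fc = 2,
                            noise_sd = 0.25, n_promoters = 300,
                            motif_planted_fraction = 0.3, motif_sd_bp = 50,
                            ...) {
  extra <- list(...)
  cfg <- c(list(tss_half_window = tss_half_window,
                chip_half_window = chip_half_window, max_gap = max_gap,
                low_expr_percentile = low_expr_percentile,
                min_max_count = min_max_count, neuron_fold = neuron_fold,
                fc_min = fc_min, q_max = q_max, seed = seed,
                n_genes = n_genes, n_per_group = n_per_group,
                n_down = n_down, n_up = n_up,
                effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                n_promoters = n_promoters,
                motif_planted_fraction = motif_planted_fraction,
                motif_sd_bp = motif_sd_bp),
           extra)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain named list).
#' @return Character vector of violations; empty when the configuration is
#'   valid. Unknown keys are reported as violations.
#' @export
validate_config <- function(config) {
  known <- names(formals(pipeline_config))
  known <- setdiff(known, "...")
  v <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    v <- c(v, sprintf("unknown key: %s", unknown))
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$tss_half_window > 0, "tss_half_window must be > 0")
  chk(config$chip_half_window > 0, "chip_half_window must be > 0")
  chk(config$max_gap >= 0, "max_gap must be >= 0")
  chk(config$low_expr_percentile > 0 && config$low_expr_percentile < 100,
      "low_expr_percentile must lie in (0, 100)")
  chk(config$min_max_count >= 0, "min_max_count must be >= 0")
  chk(config$neuron_fold > 1, "neuron_fold must be > 1")
  chk(config$fc_min > 0, "fc_min must be > 0")
  chk(config$q_max > 0 && config$q_max < 1, "q_max must lie in (0, 1)")
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed) && config$seed >= 0 &&
        config$seed == as.integer(config$seed),
      "seed must be a nonnegative integer")
  chk(config$n_genes >= 1, "n_genes must be >= 1")
  chk(config$n_per_group >= 2, "n_per_group must be >= 2")
  chk(config$n_down + config$n_up <= config$n_genes,
      "n_down + n_up must not exceed n_genes")
  v
}

#' Read / write a flat key = value configuration file
#'
#' @param path File path; lines of the form `key = value`, `#` comments.
#' @param overrides Named list applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    utils::type.convert(p[2], as.is = TRUE)
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

run_stage <- function(stage, report, code) {
  tryCatch(code, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> deg -> motif -> annotate/cluster -> chip -> psi ->
#' correlate on generated inputs, writes every intermediate file under
#' `out_dir` and returns (and writes) a machine-readable report. A fixed
#' (config, seed) pair gives an identical report.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; any of `"deg"`,
#'   `"motif"`, `"annotate"`, `"chip"`, `"psi"`. The simulate step always
#'   runs (it feeds whichever stages are requested).
#' @return The report, invisibly; also written as `report.json` in
#'   `out_dir`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("nfypipe_run_"),
                    stages = c("deg", "motif", "annotate", "chip", "psi")) {
  violations <- validate_config(config)
  if (length(violations) > 0)
    stopf("invalid configuration:\n%s", paste("-", violations, collapse = "\n"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(config = unclass(config), stages = list())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if ("deg" %in% stages) {
    report$stages$deg <- run_stage("deg", report, {
      sim <- gen_expression(config$n_genes, config$n_per_group,
                            n_down = config$n_down, n_up = config$n_up,
                            effect_log2fc = config$effect_log2fc,
                            noise_sd = config$noise_sd, mode = "array",
                            seed = derive_seed(seed, 11))
      write_expression_tsv(sim$matrix, file.path(out_dir, "expression.tsv"))
      filtered <- filter_low_expression(sim$matrix,
                                        percentile = config$low_expr_percentile)
      degs <- call_degs(filtered, fc_min = config$fc_min, q_max = config$q_max)
      write_deg_tsv(degs, file.path(out_dir, "degs.tsv"))
      write_gene_list(deg_ids(degs, "down"), file.path(out_dir, "down_genes.txt"))
      write_gene_list(deg_ids(degs, "up"), file.path(out_dir, "up_genes.txt"))
      down <- deg_ids(degs, "down"); up <- deg_ids(degs, "up")
      log_stage("deg", "%d down, %d up of %d tested", length(down),
                length(up), nrow(degs))
      list(n_tested = nrow(degs), n_down = length(down), n_up = length(up),
           recovered_down = length(intersect(down, sim$truth$down_ids)),
           recovered_up = length(intersect(up, sim$truth$up_ids)))
    })
  }

  if ("motif" %in% stages) {
    report$stages$motif <- run_stage("motif", report, {
      L <- 2 * config$tss_half_window + 1
      down_prom <- gen_promoters(config$n_promoters, length = L,
                                 planted_fraction = config$motif_planted_fraction,
                                 placement = "centered", sd_bp = config$motif_sd_bp,
                                 seed = derive_seed(seed, 21))
      up_prom <- gen_promoters(config$n_promoters, length = L,
                               planted_fraction = config$motif_planted_fraction,
                               placement = "uniform",
                               seed = derive_seed(seed, 22))
      write_promoters_fasta(down_prom$promoters,
                            file.path(out_dir, "promoters_down.fasta"))
      write_promoters_fasta(up_prom$promoters,
                            file.path(out_dir, "promoters_up.fasta"))
      panel <- compare_motif_panels(down_prom$promoters, up_prom$promoters)
      write.table(panel, file.path(out_dir, "motif_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log_stage("motif", "CCAAT best window (down set): %d bp, adj p = %.3g",
                panel$best_width[panel$set == "down" & panel$motif == "NFY_CCAAT"],
                panel$adj_p[panel$set == "down" & panel$motif == "NFY_CCAAT"])
      lapply(split(panel, paste(panel$set, panel$motif, sep = ".")),
             function(r) list(best_width = r$best_width, adj_p = r$adj_p,
                              population_pct = r$population_pct))
    })
  }

  if ("annotate" %in% stages || "psi" %in% stages) {
    ann <- gen_annotation_map(24, 2000, seed = derive_seed(seed, 31))
    profiles <- c(N2a = "ER-skew", striatum = "ER-skew",
                  HeLa = "cellcycle-skew", ES = "cellcycle-skew")
    lists <- lapply(seq_along(profiles), function(i)
      gen_annotated_list(ann, profiles[i], 400,
                         seed = derive_seed(seed, 31 + i)))
    names(lists) <- names(profiles)
    pop <- population_matrix(lists, ann)
  }

  if ("annotate" %in% stages) {
    report$stages$annotate <- run_stage("annotate", report, {
      write_gmt(ann, file.path(out_dir, "annotation.gmt"))
      write.table(data.frame(term = rownames(pop), pop, check.names = FALSE),
                  file.path(out_dir, "population_matrix.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      hc_lists <- cluster_populations(pop, axis = "lists")
      hc_terms <- cluster_populations(pop, axis = "terms")
      dendrogram_newick(hc_lists, file.path(out_dir, "lists_dendrogram.nwk"))
      dendrogram_newick(hc_terms, file.path(out_dir, "terms_dendrogram.nwk"))
      r <- correlate(pop, "N2a", "striatum")
      log_stage("annotate", "r(N2a, striatum) = %.3f over %d terms",
                r$r, r$n_pairs)
      list(r_n2a_striatum = r$r,
           r_hela_es = correlate(pop, "HeLa", "ES")$r,
           r_hela_n2a = correlate(pop, "HeLa", "N2a")$r,
           two_cluster_cut = as.list(cutree(hc_lists, k = 2)))
    })
  }

  if ("chip" %in% stages) {
    report$stages$chip <- run_stage("chip", report, {
      tss <- tss_index(sprintf("gene%05d", 1:200), "chr1",
                       seq(50000, by = 50000, length.out = 200))
      span <- c(chr1 = 50000 * 201)
      sets <- lapply(1:2, function(i)
        gen_peaks(tss, n_near = 150, near_sd_bp = 300, n_background = 50,
                  genome_span = span, seed = derive_seed(seed, 41 + i))$peaks)
      names(sets) <- c("chip_a", "chip_b")
      for (nm in names(sets))
        write_bed6(peak_set(sets[[nm]]$chrom, sets[[nm]]$start, sets[[nm]]$end,
                            name = sets[[nm]]$name),
                   file.path(out_dir, paste0(nm, ".bed")))
      write_tss_bed6(tss, file.path(out_dir, "tss.bed"))
      consensus <- overlap_peak_sets(sets, max_gap = config$max_gap)
      calls <- annotate_to_tss(consensus, tss, window = config$chip_half_window)
      write.table(as.data.frame(calls), file.path(out_dir, "target_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_list(target_ids(calls), file.path(out_dir, "target_genes.txt"))
      log_stage("chip", "%d consensus peaks -> %d proximal target genes",
                nrow(consensus), length(target_ids(calls)))
      list(n_consensus = nrow(consensus), n_targets = length(target_ids(calls)))
    })
  }

  if ("psi" %in% stages) {
    report$stages$psi <- run_stage("psi", report, {
      model <- exon_model("chrX", c(1000, 3000, 5000), c(1200, 3100, 5400))
      regimes <- c(N2a = 0.9, striatum = 0.9, HeLa = 0.2, ES = 0.35)
      psis <- vapply(seq_along(regimes), function(i) {
        sim <- gen_junctions(regimes[i], depth = 200,
                             seed = derive_seed(seed, 51 + i),
                             sample_id = names(regimes)[i])
        tab <- gen_junction_table(sim$counts, model, n_decoys = 5,
                                  seed = derive_seed(seed, 61 + i))
        write_junction_tsv(tab, file.path(out_dir,
                                          sprintf("junctions_%s.tsv", names(regimes)[i])))
        psi(extract_junction_counts(tab, model,
                                    sample_id = names(regimes)[i]))$value
      }, numeric(1))
      names(psis) <- names(regimes)
      ratios <- stats::setNames(c(0.9, 0.9, 0.25, 0.35), names(regimes))
      blocks_cor <- correlate_isoform_with_clusters(ratios, pop, ann$blocks)
      write.table(blocks_cor, file.path(out_dir, "block_correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("psi", "estimated inclusion: %s",
                paste(sprintf("%s=%.2f", names(psis), psis), collapse = ", "))
      list(psi = as.list(psis),
           block_r = stats::setNames(as.list(blocks_cor$r),
                                     paste0("block", blocks_cor$block)))
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
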