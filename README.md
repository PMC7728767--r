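# nfypipe

Analysis toolkit for knockdown transcriptomics of NF-Y, the heterotrimeric
CCAAT-box binding transcription factor. In neurons NF-Y maintains
endoplasmic-reticulum (ER) gene programs, while in proliferating cells it
drives cell-cycle genes; comparing knockdown transcriptomes across cell
types requires a recurring chain of analyses that this package implements
as tested, composable functions:

* **Differential expression** — per-gene Welch t-test of knockdown vs
  control on the log2 scale with Benjamini–Hochberg FDR, plus the study
  filters: genes below the 20th percentile of mean expression (arrays) or
  with maximum count < 200 (RNA-seq) are excluded, and genes depleted
  > 5-fold in isolated neurons are removed as non-neuronal.
* **Promoter-proximal motif centrality** — a centred-window binomial test
  on per-sequence best PWM sites in TSS ± 1000 bp promoters: for window
  width *w* and *S* valid site centres, *k* best sites in the window out of
  *n* scored sequences are tested against Binomial(*n*, *w/S*), Bonferroni
  over the tested widths. Detects the CCAAT box clustering at the TSS of
  down-regulated genes.
* **Annotation populations** — per-term population (100·k/n, the percent of
  a gene list annotated to the term), fold enrichment ((k/n)/(K/N)) and
  exact two-sided Fisher p; population matrices across cell types are
  correlated (Pearson) and clustered (Euclidean distance, Ward.D2).
* **ChIP targets** — consensus peaks supported by every experiment within a
  100 bp pairwise gap, and proximal target genes whose TSS lies within a
  closed ± 2000 bp window of a peak centre.
* **Exon-3 inclusion (PSI)** — from junction-spanning read counts,
  PSI = (n23 + n34) / (n23 + n34 + 2·n24), separating the NF-YA-L–dominant
  neuronal regime (inclusion ≥ 0.7) from the NF-YA-S–dominant HeLa-like
  regime (≈ 0.2).
* **Synthetic data** — seeded generators for every input (expression with
  planted effects, promoters with planted motif copies, block-structured
  annotations, TSS-clustered peaks, Poisson junction counts) with ground
  truth recorded, so the whole pipeline is testable offline.

## Worked example

```r
library(nfypipe)

## two-group expression with 100 down- and 50 up-regulated genes planted
sim <- gen_expression(2000, 4, n_down = 100, n_up = 50,
                      effect_log2fc = 2, noise_sd = 0.25, seed = 1)
sim$matrix
#> <expr_matrix> 2000 genes x 8 samples (array mode; 4 control, 4 knockdown)

degs <- call_degs(filter_low_expression(sim$matrix, percentile = 20),
                  fc_min = 1, q_max = 0.05)
degs
#> <deg_table> 1600 genes tested: 64 down, 48 up (|log2FC| >= 1, q <= 0.05)

## CCAAT centrality: centred planting vs uniform placement
down <- gen_promoters(500, planted_fraction = 0.3, placement = "centered",
                      sd_bp = 50, seed = 2)
up <- gen_promoters(500, planted_fraction = 0.3, placement = "uniform",
                    seed = 3)
central_enrichment(down$promoters, consensus_pwm("CCAAT"))
#> <local_enrichment> CCAAT: 490/500 sequences scored; best window 201 bp
#>   (k = 85.7, adj p = 2.05e-06, population 17.1%)
central_enrichment(up$promoters, consensus_pwm("CCAAT"))
#> <local_enrichment> CCAAT: 494/500 sequences scored; best window 11 bp
#>   (k = 1.9, adj p = 1, population 0.4%)

## exon-3 inclusion from junction counts
psi(6, 2, 1)
#> <psi_estimate> sample: PSI = 0.800 (informative count 10)
```

The DEG counts are below the planted 150 because the 20th-percentile
filter runs first and removes part of the low-expressed planted genes —
the same behaviour the filter has on real arrays. In the motif contrast,
the centred set concentrates best sites in the ± 100 bp window (85.7 of
490 scored sequences against 49 expected under the uniform null) while the
uniformly placed set shows no window above chance. `run_all()` chains all
stages on one seed and writes TSV/FASTA/GMT/BED/Newick intermediates plus
a JSON report.

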