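---
title: "Methods: knockdown transcriptome analysis for the NF-Y CCAAT-box regulator"
author: "nfypipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockdown transcriptome analysis for NF-Y}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfypipe)
```

## The scientific setting

NF-Y is a heterotrimeric transcription factor (subunits NF-YA, NF-YB,
NF-YC) that binds the CCAAT pentanucleotide in proximal promoters. In
dividing cells it is best known as a cell-cycle regulator, but in neurons it
maintains endoplasmic-reticulum (ER) homeostasis. Comparing knockdown
transcriptomes across cell types therefore involves a recurring set of
analysis steps: calling differentially expressed genes (DEGs) under the
study's filters, asking whether the CCAAT motif is enriched near the
transcription start sites (TSSs) of the down-regulated genes, profiling
which functional annotations the DEGs populate and clustering those
profiles across cell types, assigning NF-Y target genes from ChIP peaks,
and estimating the inclusion of NF-YA's alternatively spliced exon 3, whose
long (NF-YA-L) and short (NF-YA-S) isoforms track the neuronal and
proliferative transcriptome types.

`nfypipe` implements each step as a tested, reusable function, together
with a synthetic-data module that generates every input with known ground
truth. All statistical claims made by the test suite are claims about data
from these generators, whose assumptions are spelled out below.

## Differential expression

Expression matrices are two-group (control vs knockdown) and come in two
modes. Array mode holds log2 intensities; RNA-seq mode holds counts, which
are transformed `log2(x + 1)` before testing. The test is the per-gene
Welch two-sample t-test with Benjamini–Hochberg adjustment over all tested
genes. The upstream studies this mirrors used vendor software whose exact
test is not published; the Welch-on-log2 choice is the closest transparent
equivalent, and both thresholds are exposed (`fc_min`, default 1.0 in log2
units, with 0.58 suiting a low-cutoff run; `q_max`, default 0.05).
Threshold comparisons are inclusive at the boundary, so a gene at exactly
`log2fc = -fc_min` and `q = q_max` is called down.

Two degenerate-data conventions matter for synthetic input: a gene that is
constant in both groups gets `p = 1` when the group means agree and `p = 0`
otherwise.

The filters are the study constants: array genes with mean expression
strictly below the 20th percentile of gene means are removed (percentiles
by linear interpolation, `quantile` type 7, with the mean across all
samples as the per-gene statistic); RNA-seq genes whose maximum count is
below 200 are removed; and a gene is "non-neuronal" when
`log2((neuron + 1)/(total + 1)) < -log2(5)`, i.e. more than fivefold
depleted in isolated neurons relative to total tissue. The `+1`
pseudocount (applied before both the log transform and the fivefold ratio)
is our choice; the sources are silent on it.

## Promoter-proximal motif centrality

Promoters are strand-oriented sequences of odd length `L` (default 2001,
TSS ± 1000 bp) with the TSS at the central position. Motifs are position
weight matrices; the bundled panel builds the NF-Y CCAAT box, an SP2-style
GC box (GGGCGGG) and the USF E-box (CACGTG) from their consensus strings.
Consensus columns are regularised by adding a pseudocount (default 0.01) to
zero cells only and renormalising, so a consensus column becomes
`(1, .01, .01, .01)/1.03`; scores are log2 odds against a uniform
background, and N bases score 0.

For each sequence the scanner finds the maximal-scoring site over all start
positions and both strands (the reverse strand is scored on the reverse
complement; the site centre maps to the same TSS-relative offset). A
sequence is *scored* when its best site reaches a threshold, by default 60%
of the motif's maximum achievable score — for the 5-bp CCAAT model this
admits only exact consensus matches.

The centrality test is a centred-window binomial test. For each odd window
width `w` (defaults 11, 21, 51, 101, 201, 401, 801) let `k` be the number
of best-site centres with `|offset| <= (w-1)/2` among the `n` scored
sequences; under a uniform site law the null probability is `p0 = w/S`
with `S = L - m + 1` valid centres, and the reported p-value is the upper
binomial tail `P(X >= k)` computed in log space, Bonferroni-multiplied by
the number of widths tested.

**Tie handling.** A short consensus motif matches a 2-kb random sequence
several times by chance (about four exact CCAAT/ATTGG hits are expected at
GC 0.5), and every exact match scores identically, so "the" best site is
frequently tied. Resolving ties toward the most central site would make
the central windows systematically over-occupied under the uniform null
(the binomial `p0 = w/S` would be wrong by roughly the expected number of
tied sites), while resolving toward one end would discard planted central
sites and destroy power. The window count therefore weights tied maximal
sites fractionally: a sequence with `t` tied best sites contributes `1/t`
of a count for each tied site inside the window. Under a uniform site law
this makes `E[k] = n * p0` exact, and because averaging shrinks the
variance of `k` below binomial, the test is slightly conservative — which
is the right side to err on for an enrichment screen. The single reported
best site (`best_site()`) still uses a deterministic rule — smallest
|offset|, then + strand, then leftmost — which is what the per-sequence
oracle checks.

`compare_motif_panels()` runs the test for down- and up-regulated promoter
sets against the panel and reports, per combination, the best window and
the "population": the percentage of input sequences whose (fractional)
best site lies in the best window, the analogue of statements like "~28%
of down-regulated genes carry a proximal CCAAT motif".

## Annotation populations, clustering and correlation

An annotation map is a term → gene-set mapping over an explicit gene
universe (read from GMT). For a gene list of size `n` in a universe of
size `N`, a term with `K` universe hits and `k` list hits gets:

* population percentage `100 * k/n` — *population* always means "percent
  of the input list annotated to the term";
* fold enrichment `(k/n)/(K/N)`;
* the exact two-sided Fisher p of the 2×2 table. This is plain Fisher,
  deliberately not DAVID's jackknifed EASE score, which is not reproducible
  from the published description; tests verify it against full
  hypergeometric enumeration.

Population matrices (terms × gene lists) are clustered with Euclidean
distance and Ward linkage in the squared-distance convention
(`hclust(method = "ward.D2")`, the tool the original analysis names), on
either axis. Populations are left unscaled: they share units (percent)
across rows and columns, so variance-normalising would erase exactly the
block contrasts of interest. `assign_blocks()` cuts the term tree into a
chosen number of blocks (default 4, the endosome/Golgi, ER/lipid,
cell-cycle/mitosis, mitochondrion/DNA-damage analogue) with ids stable by
leaf order. Pearson correlations between matrix columns use rows finite in
both columns and refuse zero-variance input rather than return NaN.

## ChIP consensus peaks and target genes

Peaks are 0-based half-open intervals (BED convention). A consensus peak
across experiments is emitted wherever every input set contributes one
peak such that all pairwise gaps are at most `max_gap` (default 100 bp;
overlap counts as gap 0). Because the pairwise-gap condition over a tuple
reduces to `max(starts) - min(ends) <= max_gap`, the implementation joins
candidate tuples set by set under that span condition; the emitted interval
is the union span of the contributing peaks, and overlapping consensus
intervals are merged. With identical, well-separated inputs the consensus
is the input itself.

A gene is a *proximal target* when some peak centre lies within the closed
window `[TSS - 2000, TSS + 2000]` (both constants configurable). The peak
"location" is its centre, `floor((start + end)/2)` — summit information is
not consumed — and distances ignore strand, since no strand-specific rule
is published. Genes whose chromosome carries peaks only outside the window
are classed `distal-only`. The TSS index carries exactly one TSS per gene;
multi-TSS annotations must be pre-selected upstream.

## Exon-3 inclusion from junction reads

With `n23`, `n34`, `n24` the reads spanning the exon2–exon3, exon3–exon4
and exon2–exon4 junctions, the inclusion estimate is

$$\mathrm{PSI} = \frac{n_{23} + n_{34}}{n_{23} + n_{34} + 2\,n_{24}},$$

the skipping count doubled because one skipping transcript presents a
single informative junction where an inclusion transcript presents two.
The estimate is undefined (missing, never zero) when the denominator is 0.
Junction tables are aligner-style records (chrom, intron start, intron
end, count; 0-based half-open introns); counting matches intron
coordinates exactly against the exon model and sums duplicate records with
a warning. Protein-level isoform ratios `L/(L+S)` and per-block
correlations between isoform ratio and block population (positive for the
ER/trafficking blocks, negative for the cell-cycle blocks in the neuronal
vs proliferative contrast) complete the module.

## The synthetic-data generators

Every generator takes an explicit integer seed, leaves the caller's RNG
state untouched, and returns a truth object alongside the data.

* **Expression**: baseline log2 intensities are Normal(8, 2); array
  replicate noise is Gaussian (default SD 0.25 in the bundled designs);
  RNA-seq counts are negative binomial around `2^baseline` with dispersion
  0.1. These are stated stand-ins — the source studies do not characterise
  their noise — and are configurable. Planted genes shift by
  ±`effect_log2fc` (default 2) in the knockdown group; the default design
  (2000 genes, 4 per group, 100 down, 50 up) mirrors a two-group microarray
  screen at desk scale.
* **Promoters**: i.i.d. backgrounds at a chosen GC fraction with one exact
  consensus copy written over the background (sequence length invariant)
  in a planted fraction of sequences, at a Normal(0, sd) or uniform offset,
  strand fair. No CpG islands, no repeats, no composition gradients — so a
  real promoter set's GC-skewed centre will score GC-rich motifs centrally
  (as the SP2 control does) even without planting.
* **Annotations**: the universe is partitioned into four block pools plus
  a remainder; block terms annotate their pool genes at rate 0.7. A list
  with a profile draws block fractions (flat: 10% per block; ER-skew:
  20/30/5/5%; cellcycle-skew: 5/5/30/20%), giving block-2 populations ~3×
  flat under ER-skew. List size 400 in the bundled designs keeps binomial
  noise on populations near 1–2 percentage points.
* **Peaks**: fixed 200-bp width, centres at TSS + Normal(0, 300 bp) or
  uniform background over the genome span.
* **Junctions**: independent Poisson counts, `n23, n34 ~ Pois(λf)`,
  `n24 ~ Pois(λ(1-f))` — simpler than a multinomial over transcripts and
  preserving the estimator's target; λ = 200 and f ∈ {0.2, 0.7, 0.9} match
  the observed HeLa-like vs neuronal regimes.

What passing tests do **not** show: performance on vendor-normalised array
data, on promoters with realistic composition, or against a live DAVID
database. The headline counts of the motivating study (e.g. 745 DEGs)
depend on deposited raw data and unpublished vendor cutoffs and are not
desk-scale reproducible; the suite instead verifies recovery of planted
truth under the stated conditions.

## Numerical choices and problem sizes

Binomial tails are computed in log space, so adjusted p-values far below
double underflow are still comparable (`log10_adj_p` is carried alongside
`adj_p`). Fractional window counts enter the binomial tail through
`ceiling(k)`. Score-tie equality uses a 1e-9 tolerance on bit-identical
sums. Percentile filtering keeps genes at the cut (inclusive `>=`).
`overlap_peak_sets` merges only strictly overlapping consensus spans;
touching spans stay separate.

The bundled Monte-Carlo designs — 500 promoters × 20 seeds for motif
power, 1000 seeds for the size simulation, 2000 genes × 20 seeds for DEG
recovery, 50 null seeds, 500 junction replicates, 20 clustering seeds —
were chosen as the smallest sizes at which the binomial/normal error bands
of the checked quantities are comfortably inside the asserted margins.

## Pipeline orchestration

`pipeline_config()` holds the study constants as defaults and
`validate_config()` returns named violations (unknown keys included)
rather than failing piecemeal mid-run. `run_all()` executes
simulate → DEG → motif → annotate/cluster → ChIP → PSI on generated
inputs, derives one sub-seed per stage from the master seed, writes every
intermediate in its interchange format plus a JSON report, and fails with
the offending stage named while retaining partial outputs. Identical
(config, seed) pairs produce identical reports. The package is driven from
R; the orchestration functions and the format readers/writers are the
command surface.

## Known limitations

* The Welch/BH caller has no covariates, pairing, or moderated variance;
  it is the transparent baseline the study's unspecified vendor pipeline
  is replaced with, not a DESeq2/limma substitute.
* The centrality test uses best sites and centred windows only — no
  likelihood-ratio scoring across window positions, no higher-order
  background, no motif discovery.
* Fisher enrichment is unadjusted across terms by design (the original
  reports raw p values); BH across terms is left to the caller.
* One TSS per gene; distal regulation beyond the `distal-only` class is
  out of scope.
* PSI is a junction-count ratio, not an EM isoform quantifier; it inherits
  the usual small-count ratio bias (visible as ~0.001–0.005 at λ = 200).
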