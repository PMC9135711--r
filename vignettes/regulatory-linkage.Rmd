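---
title: "Methods: regulatory linkage analysis on synthetic paired multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory linkage analysis on synthetic paired multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reglink)
```

## Scope and rationale

`reglink` reimplements, as a tested and reusable pipeline, the regulatory
analysis pattern used in case/control single-cell multiome studies of immune
disease: paired scATAC-seq and scRNA-seq data are filtered, scored for
transcription-factor (TF) motif activity and footprints, tested for
differential accessibility and expression, aggregated into pseudobulk
profiles to link peaks to genes, assembled into TF-target networks, and
finally connected to patient outcomes through a target-gene signature and
survival analysis. Everything runs end to end on synthetic data with planted
ground truth, so each stage's behaviour is verifiable without any external
download.

The package deliberately excludes the upstream engineering that real data
require (read alignment, peak calling, batch correction, clustering,
embedding, doublet removal, modality integration): a peak set, count
matrices, an embedding and motif annotations are inputs where needed.

## The synthetic multiome generator

The generator defines the study conditions; its defaults are fixed once and
used by the tests and the acceptance script.

**Universe.** Peaks (width 500 bp) and genes occupy disjoint slots of a
declared toy genome (three 10-Mb contigs), so non-overlap holds by
construction. Per-peak GC is Beta(5, 5); each motif annotates a fixed
fraction of peaks (default 10%). Each planted peak-gene link pairs a gene
with one peak within 250 kb of its TSS.

**Counts.** Per-cell fragment depth is log-normal with meanlog 8.5 and
sdlog 0.5, i.e. a median around 5,000 fragments per cell — a desk-scale
stand-in for deeply sequenced experiments (the scale is a parameter). Peak
counts are multinomial given the depth, with per-peak log-rates composed of
a baseline, a cell-type modulation, the planted motif-driven group effect
(patient group only), and a per-link latent factor drawn per
donor-by-cell-type aggregate. UMI counts are negative-binomial (size 10)
with the same latent factor and gene-level group effects on the log scale.
Because the latent factor enters the peak's log-rate and the linked gene's
log-mean with equal strength (default loading 1.0, chosen once as a strong,
unambiguous coupling), linked pairs co-vary across aggregates without
prescribing the correlation magnitude.

**QC fields.** Fragment totals and detected genes are derived from the
realized matrices (so conservation is exact); TSS enrichment and
mitochondrial fraction are declared noise (Normal(12, 2) truncated at zero;
Beta(2, 38)) so the printed QC thresholds remove a realistic minority of
cells.

**Footprint tracks.** Aggregate Tn5 insertion counts at offsets -250..250
around motif centers are Poisson with mean proportional to a strictly
positive bias track times `1 - depth` inside the protected core. The bias is
an input; estimating it from sequence is out of scope.

**Cohort.** Each patient carries a latent signature `s ~ N(0, 1)`; event
times are exponential with rate `lambda0 * exp(beta * s)`, administratively
censored at the horizon that gives the declared null censoring fraction, and
a complication is an event inside the horizon (time-to-first-complication).
Target-gene expression is `10 * exp(s + noise)`, FPKM-like and positive.

**What the generator does not emulate:** batch effects, doublets, ambient
contamination, zero-inflation beyond the NB, unbalanced designs, genuinely
nonlinear peak-gene coupling, non-proportional hazards. Passing tests
therefore demonstrate correctness of the computations and recoverability of
planted structure under clean conditions — not robustness to those artefacts.

All randomness flows from one user seed: each generator derives a child seed
from the master seed and a fixed stream label, so stages are independently
reproducible and identical seeds give bit-identical outputs.

## Quality control and gene-level scores

Cells are kept when fragments >= 2500 and TSS enrichment >= 9 (ATAC), and
when the mitochondrial fraction <= 0.11 with 200-3000 detected genes (RNA);
all bounds inclusive, matching the printed rules. The TSS enrichment
estimator itself is not fixed by those rules, so the package declares one:
mean per-bp insertion density within +/-50 bp of TSSs divided by the density
in the distal 1901-2000 bp flanks, with merged windows so nothing is double
counted; 0/0 scores 0 and a zero flank with signal scores infinite.

Gene activity combines nearby peak counts with weight 1 for peaks
overlapping the gene body or the 2-kb upstream promoter and `exp(-d/5000)`
for distal peaks (d = peak center to nearest body edge, window 100 kb).
These weights are declared and configurable; the linearity of the score in
the counts is a tested invariant. For annotation (not scoring), each peak is
assigned the gene with the nearest TSS, promoter iff within 3 kb as printed,
ties broken by lexicographic gene id so results are deterministic.

## Motif deviations, backgrounds and footprints

For annotation matrix M and counts X, the expected fraction of reads in
peak p is `f_p` (peak total over grand total); a cell's expected motif count
is its depth times the summed `f_p` of annotated peaks, the raw deviation is
`(obs - exp) / exp`, and the bias-corrected z standardizes the raw deviation
by the mean and standard deviation over background peak sets. Backgrounds
are matched on a 10x10 grid over (GC, log1p mean accessibility) with 50
draws per peak — a deliberately simple, reproducible surrogate for
Mahalanobis-distance sampling; singleton bins background themselves and are
logged. A motif annotating every peak has raw deviation exactly zero (a
conservation identity used as a test), and cells with zero background spread
are flagged undefined rather than silently scored.

Footprints are corrected by scaling the bias track to match the observed
mass over the +/-200-250 bp flanks and dividing (subtraction in log space);
a plain subtraction mode is available behind a flag. Correction precedes
flank normalization — the order the printed normalization window leaves
open — and the normalized profile has flank mean exactly 1 by construction,
so a planted core of depth d reads as a dip to about `1 - d`.

Tissue peak-set enrichment extends external intervals by +/-2.5 kb, keeps
own peaks with strictly more than 3 co-accessibility connections ("over 3"
read as a count of connected partner peaks, since correlations are bounded
by 1), and scores the resulting feature set like a one-motif annotation.

## Differential testing and derived statistics

Differential accessibility and expression use a two-sided Wilcoxon rank-sum
test at single-cell level on depth-normalized counts (cell counts scaled to
the median depth), with the normal approximation, tie correction and
continuity correction, vectorized across features and verified against both
`stats::wilcox.test` and exact enumeration. Fold changes are log2 ratios of
normalized group means with pseudocount 1; multiplicity is handled by
Benjamini-Hochberg. DARs are `FDR <= 0.1` and `|log2FC| >= 0.5`, inclusive.
For DEGs the package applies the 0.05 significance level to the BH-adjusted
p (the conservative reading) with a 0.25 log2FC floor. A donor-aware
pseudobulk test is possible by aggregating first; the single-cell route is
the default because the compared studies test at cell level within
pseudobulk-derived peak sets.

Motif enrichment in a differential peak set is the upper-tail
hypergeometric probability, exact by construction. Signature scores come in
both published flavours — UMI fraction of the set (bounded in [0, 1],
depth-scale invariant) and mean per-gene z of log-normalized expression —
with neither privileged. Ligand-receptor interactions are scored as the
CellPhoneDB-style mean of the ligand's log-normalized mean in the sender and
the receptor's in the receiver, with significance from cluster-label
permutation and the add-one rule so p is never zero; pairs under 10%
expressing cells are not tested.

Backbone pseudotime computes cluster centroids along a declared backbone,
trims cells beyond the 0.95 within-cluster distance quantile, projects each
cell onto the nearest point of the polyline restricted to the segments
adjacent to its cluster, trims again on residuals at the 0.95 quantile, and
rescales arc-length positions to [0, 100]. The adjacency-restricted
projection was chosen because it is exactly symmetric — reversing the
backbone maps t to 100 - t — and reduces to centroid order for cells at
centroids.

## Linkage, networks and cohort survival

Pseudobulk aggregates are donor-by-cell-type sums (24 under the default
design), a reproducible, donor-aware metacell definition. Peak-gene links
are Pearson correlations of log1p counts-per-million profiles for peaks
within 250 kb of a TSS, kept at signed `r >= 0.2` (positive links only,
consistent with scoring jointly upregulated pairs). Co-accessibility uses
the same correlation within 500 kb at cutoff 0.35 as a declared surrogate
for graphical-lasso co-accessibility; it feeds only the tissue feature
filter. With ~24 aggregates the null spread of r is roughly 0.2, so a
non-trivial false-link fraction at the 0.2 cutoff is expected and planted
links are instead validated by sensitivity (>= 0.8 at the default effect
sizes); users wanting specific links should raise the cutoff or the number
of aggregates.

A TF's target table keeps links whose peak carries the TF motif, whose peak
is an up-DAR and whose gene is an up-DEG; each gene's differential linkage
score is the sum of squared correlations over its qualifying links, and
network edges carry the link correlation as weight. GWAS SNPs are reported
per cell type when they fall inside that cell type's up-DARs, with gene
attribution only through links strictly above 0.2.

Cohort stratification averages per-gene expression z-scores (sample sd,
n - 1) over target genes and splits at the median (ties to low; tertile and
fixed-threshold rules available); survival uses the hand-implemented
product-limit estimator and two-group log-rank with hypergeometric variance,
referred two-sided to chi-squared(1), and is cross-checked against the
survival package in the tests. Cohorts with no events return an undefined-p
sentinel. Complication rates are reported with half-up one-decimal rounding,
the convention that makes 35 of 89 read 39.3%.

## Numerical choices and degenerate inputs

Zero denominators are handled by sentinels, never silently: 0/0 TSS
enrichment scores 0, zero-flank footprints error, zero-variance genes are
dropped with a warning, all-identical signature scores refuse to stratify.
Ties break deterministically (lexicographic gene ids, median ties to low).
Permutation p values use the add-one rule. All file coordinates are 0-based
half-open BED convention, and the I/O layer round-trips every generator
output byte-exactly.

## Problem sizes

The default configuration — 800 peaks, 250 genes, 10 motifs, 40 links, 24
donor-by-cell-type strata of 25 cells, a 10,000-site footprint track, an
89-patient cohort, 50 background draws and 1000 permutations — was chosen so
a complete pipeline run takes seconds on a laptop while leaving every
statistic comfortably powered for the planted effect sizes (log-scale motif
effect 0.75, gene effect 0.7, link loading 1.0, hazard coefficient 1.0).
Null-calibration checks use 400-peak universes with 200 cells per group and
500 simulated 89-patient cohorts.

## Known limitations

Background matching by binning is coarser than Mahalanobis sampling near
bin edges; the Wilcoxon normal approximation is inaccurate below ~8 cells
per group (the exact-enumeration tests bound the error at n = 5);
single-cell-level differential testing treats cells as exchangeable within
groups, so donor pseudo-replication is only addressed by the pseudobulk
route; the co-accessibility surrogate measures marginal, not conditional,
association; and the survival module implements two-group comparison only —
no Cox regression, adjustment or competing risks.
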