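# reglink

Regulatory linkage analysis for paired single-cell ATAC and RNA data from a
case/control design — built for studies that ask how disease rewires
chromatin in peripheral immune cells and whether the resulting
transcription-factor (TF) programs predict patient outcomes.

The package covers the full analysis chain downstream of preprocessing:

- **QC and gene-level scores** — printed-threshold cell filters
  (fragments ≥ 2500, TSS enrichment ≥ 9, mitochondrial fraction ≤ 0.11,
  200–3000 detected genes), TSS enrichment, distance-weighted gene activity
  scores, nearest-gene peak annotation (promoter = within 3 kb of a TSS).
- **Motif deviations and footprints** — bias-corrected motif deviation z
  scores against GC/accessibility-matched background peaks: with expected
  read fraction f_p per peak, raw = (obs − exp)/exp and
  z = (raw − mean_bg)/sd_bg; TF footprints corrected for Tn5 insertion bias
  and normalized to unit mean over the ±200–250 bp flanks.
- **Differential statistics** — depth-normalized two-sided Wilcoxon
  rank-sum tests with Benjamini–Hochberg adjustment; DARs at FDR ≤ 0.1 and
  |log2FC| ≥ 0.5; exact hypergeometric motif enrichment; UMI-fraction and
  mean-z gene-set signatures; permutation-tested ligand–receptor
  interactions; centroid-backbone pseudotime.
- **Linkage and networks** — donor × cell-type pseudobulk aggregation;
  peak-to-gene links as Pearson r of log1p CPM profiles (window 250 kb,
  cutoff r ≥ 0.2); co-accessibility connections; TF–target tables with the
  differential linkage score (per gene, Σ r² over motif-bearing,
  jointly-upregulated links); GWAS SNP overlap with cell-type DARs; tissue
  peak-set deviation enrichment (±2.5 kb extension, > 3 connections).
- **Cohort survival** — average expression z-score signatures, median
  stratification, Kaplan–Meier curves and the two-group log-rank test
  ((O − E)²/V against χ²(1)).
- **Synthetic multiome generator** — paired counts, insertion tracks and a
  follow-up cohort with planted motif effects, peak–gene links, expression
  shifts and a signature-driven hazard, so every stage is testable against
  known truth. `run_pipeline()` chains everything from one seeded config
  into a directory of standard-format files plus a manifest.

## Worked example

```r
library(reglink)

cfg <- default_config(seed = 1, out_dir = "reglink_demo")
res <- run_pipeline(cfg)
#> [simulate]   1.3s 600 cells, 800 peaks, 250 genes
#> [qc]         2.3s 462 cells retained
#> [deviations] 0.3s
#> [differential] 2.9s 152 up-DARs, 15 up-DEGs
#> [linkage]    0.3s 1184 links, 15 TF targets
#> [survival]   0.0s log-rank p = 2.37e-06

# planted differentially accessible peaks recovered by the Wilcoxon/BH test
mean(res$sim$truth$true_dars %in% res$differential$up_dars)
#> [1] 0.974026

# patient-minus-control motif deviation for the two planted motifs
z <- res$deviations$z
grp <- res$cells$group[match(colnames(z), res$cells$barcode)]
round(rowMeans(z[1:2, grp == "VKH"]) - rowMeans(z[1:2, grp == "HC"]), 2)
#> motif_001 motif_002
#>      7.04      7.03

# cohort stratified by the planted target-gene signature
res$survival$km$p
#> [1] 2.365645e-06
```

The run directory contains `peaks.bed`, `atac.mtx`/`rna.mtx` with index
files, `cells.csv`, `motif_hits.bed`, `deviations.csv`, `footprints.csv`,
`differential_*.csv`, `dars.bed`, `links.csv`, `tf_targets.csv`,
`network_edges.csv`, `gwas_overlap.csv`, `tissue_z.csv`, `km_curves.csv`,
`logrank.json`, `truth.json` and `manifest.json`; rerunning the same config
reproduces all of them byte-identically.

A worked cohort fact useful as a sanity check: a follow-up table of 89
patients of whom 35 developed at least one complication gives
`complication_rate()` = 39.3 (percent, half-up one-decimal rounding).

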