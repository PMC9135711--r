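#' Default pipeline configuration
#'
#' All analysis thresholds default to the study's printed parameters
#' (minimum 2500 fragments, TSS enrichment 9, mitochondrial fraction 0.11,
#' 200-3000 detected genes, DAR rule FDR 0.1 / log2FC 0.5, link correlation
#' cutoff 0.2, tissue extension 2500 bp, more than 3 co-accessibility
#' connections, 1000 permutations, footprint normalization window 200-250
#' bp); simulation sizes are desk-scale defaults documented in the methods
#' vignette. Every stage derives its random stream from the single `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("reglink_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    universe = list(n_peaks = 800, n_genes = 250, n_motifs = 10,
                    motif_density = 0.1, n_links = 40),
    design = list(n_donors = 4, cell_types = c("Tcell", "Mono", "cDC"),
                  cells_per_stratum = 25),
    effects = list(n_affected_motifs = 2, motif_effect = 0.75,
                   deg_effect = 0.7, link_strength = 1),
    qc = list(min_fragments = 2500, min_tss = 9, max_mito = 0.11,
              min_genes = 200, max_genes = 3000),
    activity = list(decay = 5000, max_dist = 100000, promoter_upstream = 2000),
    background = list(n_bg = 50, n_bins = c(10, 10)),
    dar = list(fdr_max = 0.1, lfc_min = 0.5),
    deg = list(fdr_max = 0.05, lfc_min = 0.25),
    link = list(max_dist = 250000, cor_cutoff = 0.2),
    coaccess = list(max_dist = 500000, co_cutoff = 0.35),
    tissue = list(extend = 2500, min_connections = 3),
    lr = list(n_perm = 1000, min_expr_frac = 0.1, n_pairs = 8),
    footprint = list(n_sites = 10000, footprint_depth = 0.5,
                     core_halfwidth = 10, norm_window = c(200, 250)),
    cohort = list(n_patients = 89, hazard_beta = 1, censor_rate = 0.5),
    survival = list(rule = "median")
  )
}

#' Load and cross-validate pipeline inputs from disk
#'
#' Reads the standard file set written by the simulation stage (or prepared
#' externally in the same formats) and enforces cross-file consistency:
#' matrix dimensions against index files, unique peak ids, barcodes shared
#' between modalities and the cell table, and motif hits referencing known
#' peaks. Parse and consistency failures name the offending file (and line
#' where applicable).
#'
#' @param paths named list with `peaks` (BED3+id+gc), `atac` and `rna`
#'   (MatrixMarket prefixes), `cells` (CSV), `motif_hits` (BED), and
#'   optionally `cohort` (CSV), `gene_sets` (GMT), `snps` (BED4),
#'   `insertions` (CSV).
#' @return validated in-memory bundle (list).
#' @export
load_inputs <- function(paths) {
  need <- c("peaks", "atac", "rna", "cells", "motif_hits")
  missing <- setdiff(need, names(paths))
  if (length(missing)) stopf("paths is missing entries: %s",
                             paste(missing, collapse = ", "))
  peaks <- read_peaks_bed(paths$peaks)
  atac <- read_counts_mtx(paths$atac)
  rna <- read_counts_mtx(paths$rna)
  cells <- read.csv(paths$cells)
  assert_columns(cells, c("barcode", "donor", "group", "cell_type"),
                 basename(paths$cells))
  if (!setequal(colnames(atac), peaks$peak_id)) {
    stopf("ATAC features do not match the peak set in %s", paths$peaks)
  }
  if (!setequal(rownames(atac), cells$barcode) ||
      !setequal(rownames(rna), cells$barcode)) {
    stopf("barcodes differ between matrices and %s", paths$cells)
  }
  motifs <- read_motif_hits(paths$motif_hits, peaks)
  bundle <- list(peaks = peaks,
                 atac = atac[cells$barcode, peaks$peak_id, drop = FALSE],
                 rna = rna[cells$barcode, , drop = FALSE],
                 cells = cells, motifs = motifs)
  if (!is.null(paths$cohort)) bundle$cohort <- read_cohort_csv(paths$cohort)
  if (!is.null(paths$gene_sets)) bundle$gene_sets <- read_gmt(paths$gene_sets)
  if (!is.null(paths$snps)) {
    snps <- read_bed(paths$snps)
    bundle$snps <- data.frame(snp_id = snps$name, chrom = snps$chrom,
                              pos = snps$start, stringsAsFactors = FALSE)
  }
  if (!is.null(paths$insertions)) {
    bundle$insertions <- read_insertions_csv(paths$insertions)
  }
  bundle
}

#' Run the full synthetic-multiome regulatory pipeline
#'
#' Executes the stages in dependency order — simulate, QC, motif deviations
#' and footprints, differential testing, linkage and networks, GWAS overlap
#' and tissue enrichment, cohort survival — writing every table under
#' `config$out_dir` together with a machine-readable `manifest.json`
#' recording parameters, seed and record counts. Rerunning with the same
#' configuration reproduces the tables byte-identically.
#'
#' @param config configuration list from [default_config()].
#' @return (invisibly) a list with the output directory, the manifest and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_stage <- function(name, t0, info = "") {
    message(sprintf("[%s] %5.1fs %s", name,
                    as.numeric(proc.time()[3] - t0), info))
  }
  t0 <- proc.time()[3]

  ## --- stage: simulate ----------------------------------------------------
  uni <- do.call(generate_universe, c(config$universe, list(seed = seed)))
  design <- do.call(default_design, config$design)
  eff <- config$effects
  affected <- colnames(uni$motifs)[seq_len(eff$n_affected_motifs)]
  motif_effects <- setNames(rep(eff$motif_effect, length(affected)), affected)
  affected_peaks <- unique(unlist(uni$truth$motif_peaks[affected]))
  target_genes <- sort(unique(
    uni$truth$true_links$gene_id[uni$truth$true_links$peak_id %in%
                                   affected_peaks]))
  deg_genes <- sort(unique(c(target_genes, uni$truth$true_links$gene_id[
    seq_len(min(5, nrow(uni$truth$true_links)))])))
  deg_effects <- setNames(rep(eff$deg_effect, length(deg_genes)), deg_genes)
  sim <- simulate_multiome(uni, design, motif_effects = motif_effects,
                           deg_effects = deg_effects,
                           link_strength = eff$link_strength, seed = seed)
  fp_cfg <- config$footprint[c("n_sites", "footprint_depth", "core_halfwidth")]
  tracks <- lapply(affected, function(m) {
    do.call(simulate_insertions,
            c(list(motif_id = m, group_effects = c(HC = 1, VKH = 1.4),
                   seed = seed), fp_cfg))
  })
  names(tracks) <- affected
  cohort <- do.call(simulate_cohort,
                    c(list(target_genes = if (length(target_genes)) target_genes
                           else uni$genes$gene_id[1:5],
                           seed = seed), config$cohort))

  ## GWAS SNPs: half inside planted differential peaks, half elsewhere
  set.seed(child_seed(seed, "snps"))
  dar_pick <- sample(sim$truth$true_dars, min(5, length(sim$truth$true_dars)))
  other_pick <- sample(setdiff(uni$peaks$peak_id, sim$truth$true_dars), 5)
  snp_peaks <- match(c(dar_pick, other_pick), uni$peaks$peak_id)
  snps <- data.frame(
    snp_id = sprintf("rs%06d", seq_along(snp_peaks)),
    chrom = uni$peaks$chrom[snp_peaks],
    pos = floor((uni$peaks$start[snp_peaks] + uni$peaks$end[snp_peaks]) / 2),
    stringsAsFactors = FALSE)

  ## synthetic external tissue peak sets: subsets of own peaks (plus one
  ## set that overlaps nothing, to exercise the empty-tissue path)
  set.seed(child_seed(seed, "tissues"))
  mk_tissue <- function(n) {
    i <- sort(sample.int(nrow(uni$peaks), min(n, nrow(uni$peaks) %/% 4)))
    uni$peaks[i, c("chrom", "start", "end")]
  }
  tissues <- list(eye = mk_tissue(150), skin = mk_tissue(150))

  ## ligand-receptor pairs drawn from the gene universe
  set.seed(child_seed(seed, "lrpairs"))
  lr_genes <- matrix(sample(uni$genes$gene_id, 2 * config$lr$n_pairs),
                     ncol = 2)
  lr_pairs <- data.frame(ligand = lr_genes[, 1], receptor = lr_genes[, 2],
                         stringsAsFactors = FALSE)

  write_peaks_bed(uni$peaks, file.path(out, "peaks.bed"))
  write.csv(uni$genes, file.path(out, "genes.csv"), row.names = FALSE)
  write_motif_hits(uni$motifs, uni$peaks, file.path(out, "motif_hits.bed"))
  write_counts_mtx(sim$atac, file.path(out, "atac"))
  write_counts_mtx(sim$rna, file.path(out, "rna"))
  write.csv(sim$cells, file.path(out, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_cohort_csv(cohort, file.path(out, "cohort.csv"))
  write_insertions_csv(tracks, file.path(out, "insertions.csv"))
  write_bed(data.frame(chrom = snps$chrom, start = snps$pos,
                       end = snps$pos + 1L, name = snps$snp_id),
            file.path(out, "snps.bed"))
  for (tn in names(tissues)) {
    write_bed(tissues[[tn]], file.path(out, sprintf("tissue_%s.bed", tn)))
  }
  write_gmt(list(planted_target_genes = target_genes),
            file.path(out, "gene_sets.gmt"))
  write.csv(lr_pairs, file.path(out, "lr_pairs.csv"), row.names = FALSE)
  log_stage("simulate", t0, sprintf("%d cells, %d peaks, %d genes",
                                    nrow(sim$cells), nrow(uni$peaks),
                                    nrow(uni$genes)))

  ## --- stage: qc ----------------------------------------------------------
  t0 <- proc.time()[3]
  qc <- config$qc
  cells_atac <- filter_atac_cells(sim$cells, qc$min_fragments, qc$min_tss)
  cells_rna <- filter_rna_cells(sim$cells, qc$max_mito, qc$min_genes,
                                qc$max_genes)
  keep <- intersect(cells_atac$barcode, cells_rna$barcode)
  if (length(keep) == 0L) {
    stopf("qc stage: no cell passes both QC filters; check thresholds against the simulated depths")
  }
  cells_f <- sim$cells[sim$cells$barcode %in% keep, , drop = FALSE]
  atac_f <- sim$atac[keep, , drop = FALSE]
  rna_f <- sim$rna[keep, , drop = FALSE]
  activity <- do.call(gene_activity_scores,
                      c(list(atac = atac_f, peaks = uni$peaks,
                             genes = uni$genes), config$activity))
  annotation <- annotate_nearest_gene(uni$peaks, uni$genes)
  write.csv(cells_f, file.path(out, "cells_filtered.csv"), row.names = FALSE)
  write_counts_mtx(methods::as(round(activity, 4), "CsparseMatrix"),
                   file.path(out, "gene_activity"))
  write.csv(annotation, file.path(out, "peak_annotation.csv"),
            row.names = FALSE)
  log_stage("qc", t0, sprintf("%d cells retained", length(keep)))

  ## --- stage: deviations --------------------------------------------------
  t0 <- proc.time()[3]
  bgc <- config$background
  bg <- sample_background_peaks(uni$peaks, Matrix::colMeans(atac_f),
                                n_bg = bgc$n_bg, n_bins = bgc$n_bins,
                                seed = seed)
  dev <- compute_deviations(atac_f, uni$motifs, bg)
  fps <- do.call(rbind, lapply(tracks, footprint_profile,
                               norm_window = config$footprint$norm_window))
  write.csv(data.frame(motif = rownames(dev$z), round(dev$z, 6),
                       check.names = FALSE),
            file.path(out, "deviations.csv"), row.names = FALSE)
  write.csv(data.frame(motif = names(dev$variability),
                       variability = round(dev$variability, 6)),
            file.path(out, "variability.csv"), row.names = FALSE)
  write.csv(fps, file.path(out, "footprints.csv"), row.names = FALSE)
  log_stage("deviations", t0)

  ## --- stage: differential ------------------------------------------------
  t0 <- proc.time()[3]
  vkh <- cells_f$barcode[cells_f$group == "VKH"]
  hc <- cells_f$barcode[cells_f$group == "HC"]
  diff_atac <- differential_features(atac_f, vkh, hc)
  diff_rna <- differential_features(rna_f, vkh, hc)
  up_dars <- call_dars(diff_atac, config$dar$fdr_max, config$dar$lfc_min)
  up_degs <- call_dars(diff_rna, config$deg$fdr_max, config$deg$lfc_min)
  dars_by_ct <- lapply(split(cells_f$barcode, cells_f$cell_type), function(bc) {
    a <- intersect(bc, vkh); b <- intersect(bc, hc)
    call_dars(differential_features(atac_f[bc, , drop = FALSE], a, b),
              config$dar$fdr_max, config$dar$lfc_min)
  })
  enr <- motif_enrichment(up_dars, uni$motifs, uni$peaks$peak_id)
  sig <- signature_score(rna_f, if (length(target_genes)) target_genes
                         else uni$genes$gene_id[1:5], mode = "umi_ratio")
  lr <- do.call(ligand_receptor_test,
                c(list(umi = rna_f, labels = cells_f$cell_type,
                       lr_pairs = lr_pairs, seed = seed),
                  config$lr[c("n_perm", "min_expr_frac")]))
  ## embedding for the backbone ordering: PCA of log-normalized expression
  ln <- log1p(as.matrix(rna_f) / pmax(Matrix::rowSums(rna_f), 1) * 1e4)
  emb <- stats::prcomp(ln, rank. = 5)$x
  pt <- pseudotime_backbone(emb, cells_f$cell_type,
                            backbone = config$design$cell_types)
  write.csv(diff_atac, file.path(out, "differential_atac.csv"),
            row.names = FALSE)
  write.csv(diff_rna, file.path(out, "differential_rna.csv"),
            row.names = FALSE)
  dar_rows <- uni$peaks[uni$peaks$peak_id %in% up_dars, , drop = FALSE]
  write_peaks_bed(dar_rows, file.path(out, "dars.bed"))
  write.csv(enr, file.path(out, "motif_enrichment.csv"), row.names = FALSE)
  write.csv(data.frame(barcode = names(sig), score = round(sig, 6)),
            file.path(out, "signature_scores.csv"), row.names = FALSE)
  write.csv(lr, file.path(out, "lr_results.csv"), row.names = FALSE)
  write.csv(data.frame(barcode = names(pt), pseudotime = round(pt, 4)),
            file.path(out, "pseudotime.csv"), row.names = FALSE)
  log_stage("differential", t0,
            sprintf("%d up-DARs, %d up-DEGs", length(up_dars),
                    length(up_degs)))

  ## --- stage: linkage -----------------------------------------------------
  t0 <- proc.time()[3]
  agg <- aggregate_groups(atac_f, rna_f, cells_f)
  links <- do.call(link_peaks_to_genes,
                   c(list(agg = agg, peaks = uni$peaks, genes = uni$genes),
                     config$link))
  coa <- do.call(coaccessibility_connections,
                 c(list(agg = agg, peaks = uni$peaks), config$coaccess))
  tft <- tf_target_table(links, uni$motifs, up_dars, up_degs,
                         tf_list = affected)
  gwas <- gwas_overlap(snps, dars_by_ct, uni$peaks, links,
                       min_link_cor = config$link$cor_cutoff)
  tis <- do.call(tissue_peakset_enrichment,
                 c(list(tissues = tissues, peaks = uni$peaks,
                        connections = coa$connections, atac = atac_f,
                        bg = bg), config$tissue))
  write.csv(links, file.path(out, "links.csv"), row.names = FALSE)
  write.csv(coa$edges, file.path(out, "coaccess_edges.csv"),
            row.names = FALSE)
  write.csv(tft$targets, file.path(out, "tf_targets.csv"), row.names = FALSE)
  write.csv(tft$edges, file.path(out, "network_edges.csv"), row.names = FALSE)
  write.csv(gwas, file.path(out, "gwas_overlap.csv"), row.names = FALSE)
  if (!is.null(tis$z)) {
    write.csv(data.frame(tissue = rownames(tis$z), round(tis$z, 6),
                         check.names = FALSE),
              file.path(out, "tissue_z.csv"), row.names = FALSE)
  }
  log_stage("linkage", t0, sprintf("%d links, %d TF targets", nrow(links),
                                   nrow(tft$targets)))

  ## --- stage: survival ----------------------------------------------------
  t0 <- proc.time()[3]
  score <- cohort_signature(cohort, rownames(cohort$expression)[
    rownames(cohort$expression) %in% c(target_genes, uni$genes$gene_id)])
  strata <- stratify(score, rule = config$survival$rule)
  km <- km_logrank(cohort, strata)
  write.csv(km$curves, file.path(out, "km_curves.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(chisq = km$chisq, p = km$p, observed = km$observed,
         expected = km$expected,
         complication_rate = complication_rate(cohort)),
    file.path(out, "logrank.json"), auto_unbox = TRUE, digits = NA)
  log_stage("survival", t0, sprintf("log-rank p = %.3g", km$p))

  ## --- manifest -----------------------------------------------------------
  files <- sort(list.files(out))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = seed,
    parameters = config[setdiff(names(config), c("seed", "out_dir"))],
    outputs = lapply(setNames(files, files), function(f) {
      list(lines = length(readLines(file.path(out, f), warn = FALSE)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    out_dir = out, manifest = manifest, universe = uni, sim = sim,
    cells = cells_f, deviations = dev, footprints = fps,
    differential = list(atac = diff_atac, rna = diff_rna,
                        up_dars = up_dars, up_degs = up_degs,
                        by_celltype = dars_by_ct),
    enrichment = enr, signature = sig, lr = lr, pseudotime = pt,
    aggregates = agg, links = links, coaccess = coa, tf_targets = tft,
    gwas = gwas, tissue = tis, cohort = cohort,
    survival = list(score = score, strata = strata, km = km)
  ))
}
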