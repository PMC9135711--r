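#' Default donor-by-group-by-cell-type design
#'
#' Two clinical groups (healthy controls and patients), `n_donors` donors per
#' group and `cell_types` labels per donor, with `cells_per_stratum` cells in
#' every donor-by-cell-type stratum. The resulting number of donor-by-cell-type
#' aggregates (2 x n_donors x length(cell_types)) is what powers peak-to-gene
#' correlation; the default gives 24 aggregates.
#'
#' @param n_donors donors per group.
#' @param cell_types character vector of cell-type labels.
#' @param cells_per_stratum cells per donor-by-cell-type stratum.
#' @return data.frame with columns donor, group, cell_type, n_cells.
#' @export
default_design <- function(n_donors = 4,
                           cell_types = c("Tcell", "Mono", "cDC"),
                           cells_per_stratum = 25) {
  if (cells_per_stratum < 1) stopf("design needs >= 1 cell per stratum")
  grid <- expand.grid(cell_type = cell_types,
                      donor_i = seq_len(n_donors),
                      group = c("HC", "VKH"),
                      stringsAsFactors = FALSE)
  data.frame(
    donor = sprintf("%s_d%d", grid$group, grid$donor_i),
    group = grid$group,
    cell_type = grid$cell_type,
    n_cells = cells_per_stratum,
    stringsAsFactors = FALSE
  )
}

#' Simulate a paired single-cell multiome experiment
#'
#' Draws paired scATAC fragment counts and scRNA UMI counts for every cell in
#' the design, with three planted signal layers recorded in the returned truth:
#'
#' * **motif effects**: a multiplicative (log-scale additive) accessibility
#'   shift in the patient group for every peak annotated by an affected motif;
#'   these peaks are the true differentially accessible regions.
#' * **gene group effects** (`deg_effects`): a log-scale expression shift in
#'   the patient group; these genes are the true differentially expressed
#'   genes.
#' * **latent link factors**: each true peak-gene link carries its own latent
#'   factor drawn per donor-by-cell-type aggregate, added to the peak's
#'   log-rate and the gene's log-mean with strength `link_strength`, so
#'   linked pairs co-vary across aggregates.
#'
#' Per-cell sequencing depth is log-normal (default meanlog 8.5, sdlog 0.5,
#' median about 5000 fragments per cell); peak counts are multinomial given
#' the depth, UMI counts are negative-binomial. QC fields are derived from the
#' realized counts (fragment totals, detected genes) plus declared noise
#' (TSS enrichment, mitochondrial fraction).
#'
#' @param universe output of [generate_universe()].
#' @param design data.frame as from [default_design()].
#' @param motif_effects named numeric, log-scale patient-group accessibility
#'   effect per motif (names must exist in the universe).
#' @param deg_effects named numeric, log-scale patient-group expression effect
#'   per gene.
#' @param link_strength latent-factor loading shared by the peak (log-rate)
#'   and gene (log-mean) of every true link.
#' @param depth_meanlog,depth_sdlog log-normal fragment-depth parameters.
#' @param rna_depth_meanlog,rna_depth_sdlog log-normal UMI-depth parameters.
#' @param nb_size negative-binomial size (inverse overdispersion) for UMIs.
#' @param seed integer seed.
#' @return list with `atac` and `rna` (sparse cells x features count
#'   matrices), `cells` (per-cell table with QC fields) and `truth` (the
#'   universe truth updated with effects, true_dars and true_degs).
#' @export
simulate_multiome <- function(universe, design = default_design(),
                              motif_effects = NULL, deg_effects = NULL,
                              link_strength = 1,
                              depth_meanlog = 8.5, depth_sdlog = 0.5,
                              rna_depth_meanlog = log(4000),
                              rna_depth_sdlog = 0.4,
                              nb_size = 10, seed = 1) {
  stopifnot(inherits(universe, "reglink_universe"))
  assert_columns(design, c("donor", "group", "cell_type", "n_cells"), "design")
  if (any(design$n_cells < 1)) stopf("design lists a stratum with < 1 cell")
  peaks <- universe$peaks; genes <- universe$genes
  n_peaks <- nrow(peaks); n_genes <- nrow(genes)

  motif_effects <- motif_effects %||% setNames(numeric(0), character(0))
  deg_effects <- deg_effects %||% setNames(numeric(0), character(0))
  bad_m <- setdiff(names(motif_effects), colnames(universe$motifs))
  if (length(bad_m)) stopf("motif_effects references unknown motif(s): %s",
                           paste(bad_m, collapse = ", "))
  bad_g <- setdiff(names(deg_effects), genes$gene_id)
  if (length(bad_g)) stopf("deg_effects references unknown gene(s): %s",
                           paste(bad_g, collapse = ", "))

  set.seed(child_seed(seed, "multiome"))

  cells <- design[rep(seq_len(nrow(design)), design$n_cells),
                  c("donor", "group", "cell_type")]
  n_cells <- nrow(cells)
  cells$barcode <- sprintf("cell_%05d", seq_len(n_cells))
  rownames(cells) <- NULL

  agg_key <- paste(cells$donor, cells$cell_type, sep = ".")
  agg_levels <- unique(agg_key)
  agg_idx <- match(agg_key, agg_levels)
  n_agg <- length(agg_levels)

  ## planted per-peak group load (log scale) from motif effects
  peak_load <- numeric(n_peaks)
  for (m in names(motif_effects)) {
    peak_load <- peak_load + motif_effects[[m]] * as.numeric(universe$motifs[, m])
  }

  gene_load <- numeric(n_genes)
  gene_load[match(names(deg_effects), genes$gene_id)] <- unname(deg_effects)

  ## one latent factor per true link, drawn per aggregate
  links <- universe$truth$true_links
  n_links <- nrow(links)
  s <- if (n_links > 0) {
    matrix(rnorm(n_agg * n_links), n_agg, n_links)
  } else {
    matrix(0, n_agg, 0)
  }
  link_peak_idx <- match(links$peak_id, peaks$peak_id)
  link_gene_idx <- match(links$gene_id, genes$gene_id)

  ## baseline and cell-type modulation of log-rates
  cts <- unique(cells$cell_type)
  b_peak <- rnorm(n_peaks, 0, 0.5)
  ct_peak <- matrix(rnorm(n_peaks * length(cts), 0, 0.25), n_peaks,
                    dimnames = list(NULL, cts))
  b_gene <- rnorm(n_genes, 0, 1)
  ct_gene <- matrix(rnorm(n_genes * length(cts), 0, 0.25), n_genes,
                    dimnames = list(NULL, cts))

  ## per-aggregate log-rate matrices (group and latent structure live at the
  ## aggregate level; within an aggregate cells are exchangeable)
  agg_meta <- cells[!duplicated(agg_idx), c("donor", "group", "cell_type")]
  agg_meta <- agg_meta[order(unique(agg_idx)), , drop = FALSE]
  eta_peak <- matrix(b_peak, n_peaks, n_agg)
  eta_gene <- matrix(b_gene, n_genes, n_agg)
  for (a in seq_len(n_agg)) {
    ct <- agg_meta$cell_type[a]
    eta_peak[, a] <- eta_peak[, a] + ct_peak[, ct]
    eta_gene[, a] <- eta_gene[, a] + ct_gene[, ct]
    if (agg_meta$group[a] == "VKH") {
      eta_peak[, a] <- eta_peak[, a] + peak_load
      eta_gene[, a] <- eta_gene[, a] + gene_load
    }
    if (n_links > 0) {
      eta_peak[link_peak_idx, a] <- eta_peak[link_peak_idx, a] +
        link_strength * s[a, ]
      eta_gene[link_gene_idx, a] <- eta_gene[link_gene_idx, a] +
        link_strength * s[a, ]
    }
  }
  p_peak <- apply(eta_peak, 2, function(e) { w <- exp(e); w / sum(w) })
  p_gene_rel <- apply(eta_gene, 2, function(e) { w <- exp(e); w / sum(w) })

  depth <- pmax(100, round(rlnorm(n_cells, depth_meanlog, depth_sdlog)))
  rna_depth <- pmax(100, round(rlnorm(n_cells, rna_depth_meanlog,
                                      rna_depth_sdlog)))

  atac_cols <- vector("list", n_cells)
  rna_cols <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    a <- agg_idx[c]
    atac_cols[[c]] <- rmultinom(1, depth[c], p_peak[, a])[, 1]
    mu <- rna_depth[c] * p_gene_rel[, a]
    rna_cols[[c]] <- rnbinom(n_genes, mu = mu, size = nb_size)
  }
  atac <- methods::as(t(matrix(unlist(atac_cols), n_peaks, n_cells)),
                      "CsparseMatrix")
  rna <- methods::as(t(matrix(unlist(rna_cols), n_genes, n_cells)),
                     "CsparseMatrix")
  dimnames(atac) <- list(cells$barcode, peaks$peak_id)
  dimnames(rna) <- list(cells$barcode, genes$gene_id)

  cells$n_fragments <- as.integer(Matrix::rowSums(atac))
  cells$tss_enrichment <- round(pmax(0.1, rnorm(n_cells, 12, 2)), 3)
  cells$n_genes_detected <- as.integer(Matrix::rowSums(rna > 0))
  cells$mito_fraction <- round(rbeta(n_cells, 2, 38), 4)
  cells <- cells[, c("barcode", "donor", "group", "cell_type", "n_fragments",
                     "tss_enrichment", "n_genes_detected", "mito_fraction")]

  truth <- universe$truth
  truth$motif_effects[names(motif_effects)] <- motif_effects
  truth$deg_effects[names(deg_effects)] <- deg_effects
  truth$true_dars <- peaks$peak_id[peak_load > 0]
  truth$true_degs <- genes$gene_id[gene_load > 0]

  list(atac = atac, rna = rna, cells = cells, truth = truth)
}

#' Simulate aggregate Tn5 insertion tracks around motif sites
#'
#' Counts at offset o from the motif center, summed over `n_sites` sites,
#' are Poisson with mean
#' `n_sites * bias(o) * flank_level * (1 - footprint_depth * core(o)) * group_mult`,
#' where `core(o)` indicates `|o| <= core_halfwidth`. The Tn5 bias track is an
#' input (default: a smooth positive periodic profile); the protected core
#' makes bias correction and footprint-depth recovery testable.
#'
#' @param motif_id label for the track.
#' @param n_sites number of motif sites aggregated.
#' @param footprint_depth fraction of insertions blocked in the core, in
#'   `[0, 1]`.
#' @param core_halfwidth half-width of the protected core in bp.
#' @param flank_level expected per-site insertion rate at unit bias.
#' @param bias positive numeric of length 501 (offsets -250..250), the Tn5
#'   insertion propensity; `NULL` for the default smooth profile.
#' @param group_effects named positive multipliers, one track column per group.
#' @param seed integer seed.
#' @return list of class `reglink_insertion_track` with `motif_id`, `offsets`
#'   (-250..250), `counts` (offsets x groups), `bias`, `n_sites`,
#'   `footprint_depth`, `core_halfwidth`.
#' @export
simulate_insertions <- function(motif_id, n_sites = 10000,
                                footprint_depth = 0.5, core_halfwidth = 10,
                                flank_level = 0.2, bias = NULL,
                                group_effects = c(HC = 1, VKH = 1),
                                seed = 1) {
  offsets <- -250:250
  if (is.null(bias)) {
    bias <- exp(0.4 * sin(offsets / 23) + 0.2 * cos(offsets / 7))
  }
  if (length(bias) != length(offsets)) {
    stopf("bias must have length %d (offsets -250..250)", length(offsets))
  }
  if (any(bias <= 0)) stopf("Tn5 bias must be strictly positive at all offsets")
  if (footprint_depth < 0 || footprint_depth > 1) {
    stopf("footprint_depth must be in [0, 1]")
  }
  if (any(group_effects <= 0)) stopf("group effects must be positive")
  set.seed(child_seed(seed, paste0("insertions.", motif_id)))

  core <- as.numeric(abs(offsets) <= core_halfwidth)
  lam0 <- n_sites * bias * flank_level * (1 - footprint_depth * core)
  counts <- vapply(group_effects, function(mult) {
    rpois(length(offsets), lam0 * mult)
  }, numeric(length(offsets)))
  dimnames(counts) <- list(NULL, names(group_effects))

  structure(list(motif_id = motif_id, offsets = offsets, counts = counts,
                 bias = bias, n_sites = n_sites,
                 footprint_depth = footprint_depth,
                 core_halfwidth = core_halfwidth),
            class = "reglink_insertion_track")
}

#' Simulate a follow-up cohort with a signature-driven hazard
#'
#' Each patient carries a latent signature score `s ~ N(0, 1)`. Event times
#' are exponential with rate `baseline_rate * exp(hazard_beta * s)`, censored
#' administratively at a fixed horizon chosen so that, under `hazard_beta = 0`,
#' the expected censored fraction equals `censor_rate`. A complication is an
#' event observed within the horizon (time-to-first-complication endpoint).
#' Target-gene expression is FPKM-like, `scale * exp(s + noise)`, so the
#' latent signature is recoverable as an average expression z-score; noise
#' genes are independent log-normals.
#'
#' @param n_patients number of patients (>= 2).
#' @param target_genes character vector of signature gene names (non-empty).
#' @param hazard_beta log-hazard per unit latent signature.
#' @param censor_rate expected censored fraction under the null, in `[0, 1)`;
#'   `1` puts the horizon at 0+ so nothing is observed.
#' @param baseline_rate exponential baseline event rate (per unit time).
#' @param n_noise_genes number of unrelated genes added to the expression
#'   table.
#' @param expr_noise_sd log-scale noise on target-gene expression.
#' @param seed integer seed.
#' @return list of class `reglink_cohort` with `expression` (genes x patients
#'   FPKM-like matrix), `clinical` (data.frame: patient, time, event,
#'   complication) and `latent` (the true per-patient signature).
#' @export
simulate_cohort <- function(n_patients = 89, target_genes,
                            hazard_beta = 1, censor_rate = 0.5,
                            baseline_rate = 0.1, n_noise_genes = 50,
                            expr_noise_sd = 0.5, seed = 1) {
  if (n_patients < 2) stopf("cohort needs >= 2 patients")
  if (length(target_genes) == 0L) stopf("target_genes must be non-empty")
  if (censor_rate < 0 || censor_rate > 1) stopf("censor_rate must be in [0, 1]")
  set.seed(child_seed(seed, "cohort"))

  s <- rnorm(n_patients)
  rate <- baseline_rate * exp(hazard_beta * s)
  t_event <- rexp(n_patients, rate)
  horizon <- if (censor_rate >= 1) 1e-9 else qexp(1 - censor_rate, baseline_rate)
  time <- pmax(pmin(t_event, horizon), 1e-9)
  event <- as.integer(t_event <= horizon)

  patients <- sprintf("patient_%03d", seq_len(n_patients))
  tg <- unique(target_genes)
  expr_t <- t(vapply(tg, function(g) {
    10 * exp(s + rnorm(n_patients, 0, expr_noise_sd))
  }, numeric(n_patients)))
  noise_names <- sprintf("noise_gene_%03d", seq_len(n_noise_genes))
  expr_n <- matrix(rlnorm(n_noise_genes * n_patients, log(10), 1),
                   n_noise_genes, n_patients)
  expression <- rbind(expr_t, expr_n)
  dimnames(expression) <- list(c(tg, noise_names), patients)

  clinical <- data.frame(patient = patients, time = time, event = event,
                         complication = event, stringsAsFactors = FALSE)
  structure(list(expression = expression, clinical = clinical, latent = s),
            class = "reglink_cohort")
}
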