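## Shared in-code fixtures; everything is generated at test time.

tiny_universe <- function(seed = 11, n_links = 10) {
  generate_universe(n_peaks = 100, n_genes = 40, n_motifs = 5,
                    motif_density = 0.2, n_links = n_links, seed = seed)
}

tiny_sim <- function(seed = 11, ...) {
  u <- tiny_universe(seed)
  sim <- simulate_multiome(u, default_design(n_donors = 2,
                                             cells_per_stratum = 10),
                           seed = seed, ...)
  sim$universe <- u
  sim
}

## a minimal cell table covering all QC fields
mk_cells <- function(n_fragments = 5000, tss = 12, mito = 0.05, genes = 1500) {
  n <- max(lengths(list(n_fragments, tss, mito, genes)))
  data.frame(barcode = sprintf("bc%03d", seq_len(n)),
             donor = "d1", group = "HC", cell_type = "Tcell",
             n_fragments = rep_len(n_fragments, n),
             tss_enrichment = rep_len(tss, n),
             n_genes_detected = rep_len(genes, n),
             mito_fraction = rep_len(mito, n),
             stringsAsFactors = FALSE)
}

## independently coded brute-force motif deviations (the oracle for
## compute_deviations): plain loops over cells, motifs and background draws
brute_force_deviations <- function(counts, ann, bg) {
  counts <- as.matrix(counts); ann <- as.matrix(ann)
  n_cells <- nrow(counts); n_motifs <- ncol(ann)
  grand <- sum(counts)
  f <- colSums(counts) / grand
  raw_one <- function(members) {
    ## members: peak index per annotated slot (multiplicity allowed)
    sapply(seq_len(n_cells), function(ci) {
      obs <- sum(counts[ci, members])
      e <- sum(counts[ci, ]) * sum(f[members])
      (obs - e) / e
    })
  }
  raw <- matrix(NA_real_, n_motifs, n_cells)
  z <- matrix(NA_real_, n_motifs, n_cells)
  for (m in seq_len(n_motifs)) {
    members <- which(ann[, m] != 0)
    raw[m, ] <- raw_one(members)
    bg_raw <- sapply(seq_len(ncol(bg)), function(b) raw_one(bg[members, b]))
    mu <- apply(bg_raw, 1, mean)
    sdv <- apply(bg_raw, 1, sd)
    z[m, ] <- ifelse(sdv == 0, NA_real_, (raw[m, ] - mu) / sdv)
  }
  list(raw = raw, z = z)
}

## exact two-sided rank-sum p by exhaustive enumeration of group assignments
exact_wilcoxon_p <- function(x, y) {
  v <- c(x, y); n <- length(v); na <- length(x)
  r <- rank(v)
  obs <- abs(sum(r[seq_len(na)]) - na * (n + 1) / 2)
  combos <- utils::combn(n, na)
  stat <- abs(colSums(matrix(r[combos], nrow = na)) - na * (n + 1) / 2)
  mean(stat >= obs - 1e-9)
}

## exact hypergeometric upper tail by exhaustive enumeration of draws
exact_hyper_p <- function(N, K, n, k) {
  combos <- utils::combn(N, n)
  succ <- colSums(matrix(combos <= K, nrow = n))  # first K items are successes
  mean(succ >= k)
}
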