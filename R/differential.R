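#' Wilcoxon differential test between two cell groups
#'
#' Counts are depth-normalized per cell (cell counts divided by the cell
#' total and rescaled to the median total over the tested cells), then each
#' feature is tested with a two-sided Wilcoxon rank-sum test using the normal
#' approximation with tie correction and continuity correction, vectorized
#' across features. The log2 fold change is the log2 ratio of normalized
#' group means with a pseudocount. P values are Benjamini-Hochberg adjusted
#' over all tested features.
#'
#' @param counts sparse cells x features count matrix with row names.
#' @param group_a,group_b barcodes (row names) of the two disjoint groups.
#' @param pseudocount added to both group means before the log ratio.
#' @return data.frame: feature, log2fc, p, fdr, direction ("up" means higher
#'   in `group_a`).
#' @export
differential_features <- function(counts, group_a, group_b, pseudocount = 1) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stopf("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stopf("groups overlap: differential test requires disjoint groups")
  }
  missing <- setdiff(c(group_a, group_b), rownames(counts))
  if (length(missing)) stopf("barcodes absent from matrix: %s",
                             paste(utils::head(missing, 5), collapse = ", "))

  x <- counts[c(group_a, group_b), , drop = FALSE]
  tot <- Matrix::rowSums(x)
  scale_to <- median(tot)
  norm <- as.matrix(x / pmax(tot, 1) * scale_to)

  na <- length(group_a); nb <- length(group_b); n <- na + nb
  is_a <- seq_len(n) <= na

  stat <- apply(norm, 2, function(v) {
    r <- rank(v)
    u <- sum(r[is_a]) - na * (na + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    c(u = u, sig2 = sig2)
  })
  u <- stat["u", ]; sig2 <- stat["sig2", ]
  mu <- na * nb / 2
  zn <- u - mu
  z <- ifelse(sig2 <= 0, 0, (zn - sign(zn) * 0.5) / sqrt(sig2))
  p <- 2 * pnorm(-abs(z))
  p <- pmin(p, 1)
  p[sig2 <= 0] <- 1

  mean_a <- colMeans(norm[is_a, , drop = FALSE])
  mean_b <- colMeans(norm[!is_a, , drop = FALSE])
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  data.frame(feature = colnames(counts), log2fc = lfc, p = p,
             fdr = p.adjust(p, method = "BH"),
             direction = ifelse(lfc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differential features at FDR and fold-change thresholds
#'
#' A feature is called iff `fdr <= fdr_max` and `log2fc >= lfc_min`
#' (direction `"up"`), `log2fc <= -lfc_min` (`"down"`), or either
#' (`"both"`). Both bounds are inclusive, matching the printed rule
#' FDR <= 0.1 and |log2FC| >= 0.5.
#'
#' @param results output of [differential_features()].
#' @param fdr_max,lfc_min thresholds (inclusive).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of called feature ids.
#' @export
call_dars <- function(results, fdr_max = 0.1, lfc_min = 0.5,
                      direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (nrow(results) == 0L) return(character())
  sig <- results$fdr <= fdr_max
  hit <- switch(direction,
                up = sig & results$log2fc >= lfc_min,
                down = sig & results$log2fc <= -lfc_min,
                both = sig & abs(results$log2fc) >= lfc_min)
  results$feature[hit]
}

#' Hypergeometric motif enrichment in a differential peak set
#'
#' For each motif, the upper-tail hypergeometric probability of observing at
#' least the seen number of motif-annotated peaks among the differential
#' peaks, drawn from the peak universe. P values are BH adjusted across
#' motifs.
#'
#' @param dar_set character vector of differential peak ids (must be a subset
#'   of the universe).
#' @param ann binary peaks x motifs annotation with peak ids as row names.
#' @param universe character vector of all peak ids.
#' @return data.frame: motif, k (observed), K (motif peaks), n (draws),
#'   N (universe), p, fdr.
#' @export
motif_enrichment <- function(dar_set, ann, universe) {
  if (length(setdiff(dar_set, universe)) > 0L) {
    stopf("dar_set contains peaks outside the universe")
  }
  ann <- methods::as(ann, "CsparseMatrix") * 1
  N <- length(universe)
  n <- length(dar_set)
  in_dar <- rownames(ann) %in% dar_set
  K <- Matrix::colSums(ann != 0)
  k <- Matrix::colSums(ann[in_dar, , drop = FALSE] != 0)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(motif = colnames(ann), k = as.integer(k), K = as.integer(K),
             n = n, N = N, p = as.numeric(p),
             fdr = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell gene-set signature score
#'
#' Two estimators:
#' * `"umi_ratio"`: the summed UMIs of the set's genes in a cell divided by
#'   the cell's total UMIs (a fraction in `[0, 1]`; cells with zero total get
#'   `NA`).
#' * `"z_mean"`: the mean across the set of per-gene z-scores of log1p
#'   depth-normalized expression (10k scale); genes with zero variance are
#'   dropped with a message.
#'
#' Genes absent from the matrix are ignored with a warning.
#'
#' @param umi sparse cells x genes count matrix.
#' @param gene_set character vector of gene ids.
#' @param mode `"umi_ratio"` or `"z_mean"`.
#' @return named per-cell numeric score.
#' @export
signature_score <- function(umi, gene_set, mode = c("umi_ratio", "z_mean")) {
  mode <- match.arg(mode)
  present <- intersect(gene_set, colnames(umi))
  if (length(present) == 0L) stopf("no gene of the set is in the matrix")
  if (length(present) < length(unique(gene_set))) {
    warnf("%d gene(s) of the set are absent from the matrix and ignored",
          length(unique(gene_set)) - length(present))
  }
  if (mode == "umi_ratio") {
    tot <- Matrix::rowSums(umi)
    score <- as.numeric(Matrix::rowSums(umi[, present, drop = FALSE])) / tot
    score[tot == 0] <- NA_real_
  } else {
    tot <- Matrix::rowSums(umi)
    ln <- log1p(as.matrix(umi[, present, drop = FALSE]) / pmax(tot, 1) * 1e4)
    sds <- apply(ln, 2, sd)
    if (any(sds == 0)) {
      message(sprintf("signature_score: dropping %d zero-variance gene(s)",
                      sum(sds == 0)))
      ln <- ln[, sds > 0, drop = FALSE]
      if (ncol(ln) == 0L) stopf("all set genes have zero variance")
    }
    score <- rowMeans(scale(ln))
  }
  setNames(as.numeric(score), rownames(umi))
}

#' Permutation test for ligand-receptor interactions between clusters
#'
#' Expression is log1p depth-normalized (10k scale). For an ordered cluster
#' pair A -> B and a ligand/receptor pair, the interaction mean is the average
#' of the ligand's mean in A and the receptor's mean in B. Pairs whose ligand
#' is expressed in fewer than `min_expr_frac` of A's cells, or receptor in
#' fewer than `min_expr_frac` of B's cells, are not tested. Significance is by
#' shuffling cluster labels over cells: `p = (1 + #[permuted >= observed]) /
#' (n_perm + 1)`, so p is never zero.
#'
#' @param umi sparse cells x genes count matrix.
#' @param labels per-cell cluster labels (aligned to rows of `umi`).
#' @param lr_pairs data.frame with columns `ligand`, `receptor`.
#' @param min_expr_frac minimum expressing-cell fraction per cluster.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return data.frame: ligand, receptor, cluster_a, cluster_b, mean, p.
#' @export
ligand_receptor_test <- function(umi, labels, lr_pairs, min_expr_frac = 0.1,
                                 n_perm = 1000, seed = 1) {
  assert_columns(lr_pairs, c("ligand", "receptor"), "lr_pairs")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stopf("need >= 2 clusters")
  genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  known <- intersect(genes, colnames(umi))
  skipped <- lr_pairs$ligand %in% setdiff(genes, known) |
    lr_pairs$receptor %in% setdiff(genes, known)
  if (any(skipped)) {
    warnf("skipping %d pair(s) with unknown genes", sum(skipped))
    lr_pairs <- lr_pairs[!skipped, , drop = FALSE]
  }
  if (nrow(lr_pairs) == 0L) {
    return(data.frame(ligand = character(), receptor = character(),
                      cluster_a = character(), cluster_b = character(),
                      mean = numeric(), p = numeric()))
  }
  set.seed(child_seed(seed, "lr"))

  tot <- Matrix::rowSums(umi)
  ln <- log1p(as.matrix(umi[, known, drop = FALSE]) / pmax(tot, 1) * 1e4)
  lab <- factor(labels, clusters)
  n_by <- as.numeric(table(lab))

  cl_mean <- function(l) rowsum(ln, l) / as.numeric(table(l))
  cl_frac <- rowsum((ln > 0) * 1, lab) / n_by
  obs_mean <- cl_mean(lab)

  perm_means <- array(0, c(length(clusters), length(known), n_perm),
                      dimnames = list(clusters, known, NULL))
  for (b in seq_len(n_perm)) {
    perm_means[, , b] <- cl_mean(sample(lab))
  }

  grid <- expand.grid(pair = seq_len(nrow(lr_pairs)),
                      a = clusters, b = clusters, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    lg <- lr_pairs$ligand[grid$pair[i]]; rc <- lr_pairs$receptor[grid$pair[i]]
    a <- grid$a[i]; b <- grid$b[i]
    if (cl_frac[a, lg] < min_expr_frac || cl_frac[b, rc] < min_expr_frac) {
      return(NULL)
    }
    obs <- (obs_mean[a, lg] + obs_mean[b, rc]) / 2
    perm <- (perm_means[a, lg, ] + perm_means[b, rc, ]) / 2
    data.frame(ligand = lg, receptor = rc, cluster_a = a, cluster_b = b,
               mean = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(ligand = character(), receptor = character(),
                      cluster_a = character(), cluster_b = character(),
                      mean = numeric(), p = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Centroid-backbone pseudotime
#'
#' Cluster centroids along a user-declared backbone order define a polyline
#' in the embedding. Cells farther from their own cluster centroid than the
#' `pre_filter_q` quantile (within cluster) are dropped; each remaining cell
#' is projected onto the nearest point of the polyline restricted to the
#' segments adjacent to its cluster, giving an arc-length position. Cells
#' whose residual distance to the path exceeds the within-cluster
#' `post_filter_q` quantile are dropped, and positions are rescaled to
#' `[0, 100]`. The projection rule is symmetric: reversing the backbone maps
#' pseudotime t to 100 - t.
#'
#' @param embedding numeric cells x dims matrix with row names.
#' @param labels per-cell cluster labels.
#' @param backbone ordered character vector of backbone cluster labels.
#' @param pre_filter_q,post_filter_q within-cluster distance quantiles for
#'   the two trims.
#' @return named per-cell pseudotime in `[0, 100]`; `NA` for cells off the
#'   backbone or trimmed by either filter.
#' @export
pseudotime_backbone <- function(embedding, labels, backbone,
                                pre_filter_q = 0.95, post_filter_q = 0.95) {
  if (!all(backbone %in% labels)) {
    stopf("backbone cluster(s) absent from labels: %s",
          paste(setdiff(backbone, labels), collapse = ", "))
  }
  if (any(!is.finite(embedding))) stopf("embedding must be finite")
  embedding <- as.matrix(embedding)
  K <- length(backbone)
  if (K < 2L) stopf("backbone needs >= 2 clusters")
  for (cl in backbone) {
    if (sum(labels == cl) < 2L) stopf("backbone cluster %s has < 2 cells", cl)
  }

  centroids <- t(vapply(backbone, function(cl) {
    colMeans(embedding[labels == cl, , drop = FALSE])
  }, numeric(ncol(embedding))))
  seg_len <- sqrt(rowSums((centroids[-1, , drop = FALSE] -
                             centroids[-K, , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))

  pos <- setNames(rep(NA_real_, nrow(embedding)), rownames(embedding))
  resid <- pos
  for (ci in seq_len(K)) {
    cl <- backbone[ci]
    idx <- which(labels == cl)
    d_ctr <- sqrt(rowSums((embedding[idx, , drop = FALSE] -
                             matrix(centroids[ci, ], length(idx),
                                    ncol(embedding), byrow = TRUE))^2))
    keep <- idx[d_ctr <= quantile(d_ctr, pre_filter_q)]
    segs <- intersect(c(ci - 1L, ci), seq_len(K - 1L))
    for (cell in keep) {
      x <- embedding[cell, ]
      best <- Inf
      for (si in segs) {
        a <- centroids[si, ]; b <- centroids[si + 1L, ]
        v <- b - a
        t <- if (sum(v^2) == 0) 0 else
          min(1, max(0, sum((x - a) * v) / sum(v^2)))
        proj <- a + t * v
        r <- sqrt(sum((x - proj)^2))
        if (r < best) {
          best <- r
          pos[cell] <- cum_len[si] + t * seg_len[si]
        }
      }
      resid[cell] <- best
    }
    ## post filter: residual distance to the fitted path, within cluster
    kept <- keep[!is.na(resid[keep])]
    cut <- quantile(resid[kept], post_filter_q)
    pos[kept[resid[kept] > cut]] <- NA_real_
  }

  ok <- !is.na(pos)
  rng <- range(pos[ok])
  if (diff(rng) == 0) stopf("degenerate backbone: all projections coincide")
  pos[ok] <- (pos[ok] - rng[1]) / diff(rng) * 100
  pos
}
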