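mk_counts <- function(mat, prefix = "c") {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(nrow(mat))),
                      sprintf("f%03d", seq_len(ncol(mat))))
  m
}

test_that("identical groups give zero fold change and p = 1", {
  x <- mk_counts(matrix(rep(c(5, 3, 8, 1), each = 6), 6, 4))
  res <- differential_features(x, rownames(x)[1:3], rownames(x)[4:6])
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
  expect_equal(res$fdr, rep(1, 4))
})

test_that("group validation rejects overlap and empty groups", {
  x <- mk_counts(matrix(1:12, 4, 3))
  expect_error(differential_features(x, rownames(x)[1:2], rownames(x)[2:3]),
               "disjoint")
  expect_error(differential_features(x, character(), rownames(x)[1:2]),
               "non-empty")
  expect_error(differential_features(x, "nope", rownames(x)[1:2]), "absent")
})

test_that("vectorized Wilcoxon matches stats::wilcox.test per feature", {
  set.seed(7)
  x <- mk_counts(matrix(rpois(200, 10), 20, 10))
  ga <- rownames(x)[1:12]; gb <- rownames(x)[13:20]
  res <- differential_features(x, ga, gb)
  tot <- Matrix::rowSums(x)
  norm <- as.matrix(x / tot * median(tot))
  for (j in seq_len(ncol(x))) {
    ref <- suppressWarnings(
      stats::wilcox.test(norm[ga, j], norm[gb, j], exact = FALSE,
                         correct = TRUE))$p.value
    expect_equal(res$p[j], ref, tolerance = 1e-10)
  }
})

test_that("normal approximation is close to exact enumeration at n = 5 vs 5", {
  set.seed(21)
  for (rep in 1:20) {
    v <- rnorm(10)
    x <- mk_counts(matrix(c(exp(v) * 10, rep(10, 10)), 10, 2))
    res <- differential_features(x, rownames(x)[1:5], rownames(x)[6:10],
                                 pseudocount = 1)
    p_exact <- exact_wilcoxon_p(v[1:5], v[6:10])
    ## feature 1 carries the signal; ranks of normalized values follow v
    expect_lt(abs(res$p[1] - p_exact), 0.02)
  }
})

test_that("BH adjustment matches the hand-computed triple and is monotone", {
  x <- mk_counts(matrix(1, 2, 3))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))  # the rule the differential table applies
  set.seed(1)
  p <- runif(20)
  adj <- stats::p.adjust(p, "BH")
  p2 <- p; p2[5] <- min(1, p[5] + 0.3)
  adj2 <- stats::p.adjust(p2, "BH")
  expect_true(all(adj2 >= adj - 1e-12))
})

test_that("DAR calling uses inclusive thresholds and shrinks monotonically", {
  res <- data.frame(feature = paste0("f", 1:5),
                    log2fc = c(0.5, 0.49, 2, -2, 0.5),
                    p = rep(0.001, 5),
                    fdr = c(0.1, 0.1, 0.11, 0.05, 0.05),
                    direction = c("up", "up", "up", "down", "up"))
  expect_setequal(call_dars(res), c("f1", "f5"))
  expect_setequal(call_dars(res, direction = "down"), "f4")
  expect_setequal(call_dars(res, direction = "both"), c("f1", "f4", "f5"))
  ## tightening either threshold never adds features
  loose <- call_dars(res, fdr_max = 0.2, lfc_min = 0.25)
  tight1 <- call_dars(res, fdr_max = 0.05, lfc_min = 0.25)
  tight2 <- call_dars(res, fdr_max = 0.2, lfc_min = 1)
  expect_true(all(tight1 %in% loose))
  expect_true(all(tight2 %in% loose))
  expect_equal(call_dars(res[0, ]), character())
})

test_that("hypergeometric enrichment matches exact enumeration for N <= 12", {
  ## worked example: N=10, K=5, n=4, k=4 -> 5/210
  ann10 <- Matrix::sparseMatrix(i = 1:5, j = rep(1, 5), x = 1, dims = c(10, 1),
                                dimnames = list(paste0("p", 1:10), "m1"))
  res <- motif_enrichment(paste0("p", c(1, 2, 3, 4)), ann10, paste0("p", 1:10))
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, exact_hyper_p(10, 5, 4, 4), tolerance = 1e-12)
  ## random small instances against exhaustive enumeration
  set.seed(3)
  for (rep in 1:10) {
    N <- sample(6:12, 1); K <- sample(2:(N - 1), 1); n <- sample(1:(N - 1), 1)
    universe <- paste0("p", seq_len(N))
    ann <- Matrix::sparseMatrix(i = seq_len(K), j = rep(1, K), x = 1,
                                dims = c(N, 1),
                                dimnames = list(universe, "m"))
    dar <- sample(universe, n)
    k <- sum(dar %in% universe[seq_len(K)])
    expect_equal(motif_enrichment(dar, ann, universe)$p,
                 exact_hyper_p(N, K, n, k), tolerance = 1e-12)
  }
  ## k = 0 -> p = 1; motif covering every peak -> k = n, p = 1
  res0 <- motif_enrichment(paste0("p", 6:9), ann10, paste0("p", 1:10))
  expect_equal(res0$p, 1, tolerance = 1e-12)
  ann_all <- Matrix::sparseMatrix(i = 1:10, j = rep(1, 10), x = 1,
                                  dims = c(10, 1),
                                  dimnames = list(paste0("p", 1:10), "m"))
  expect_equal(motif_enrichment(paste0("p", 1:4), ann_all,
                                paste0("p", 1:10))$p, 1, tolerance = 1e-12)
  expect_error(motif_enrichment("nope", ann_all, paste0("p", 1:10)),
               "outside")
})

test_that("signature scores follow both declared estimators", {
  x <- mk_counts(matrix(c(2, 3, 5, 4, 6, 10), 2, 3, byrow = TRUE))
  ## set {g1, g2} in a cell with UMIs (2, 3, 5) -> (2+3)/10 = 0.5
  s <- signature_score(x, colnames(x)[1:2], mode = "umi_ratio")
  expect_equal(unname(s), c(0.5, 0.5))
  ## set of all genes -> exactly 1 everywhere
  expect_equal(unname(signature_score(x, colnames(x))), c(1, 1))
  ## invariant to integer depth rescaling of a cell
  x2 <- x * 3L
  expect_equal(signature_score(x2, colnames(x)[1:2]), s)
  ## unknown genes are ignored with a warning
  expect_warning(s2 <- signature_score(x, c(colnames(x)[1:2], "nope")),
                 "absent")
  expect_equal(s2, s)
  expect_error(signature_score(x, "nope"), "no gene")
  ## zero-variance genes are dropped in z_mean mode (equal-depth cells, so
  ## the constant gene stays constant after normalization)
  m <- mk_counts(rbind(c(5, 1, 9), c(5, 4, 6), c(5, 2, 8), c(5, 9, 1)))
  expect_message(sz <- signature_score(m, colnames(m), mode = "z_mean"),
                 "zero-variance")
  expect_equal(unname(sz),
               unname(signature_score(m, colnames(m)[2:3], mode = "z_mean")))
})

test_that("ligand-receptor permutation p agrees with the exhaustive oracle", {
  ## 4 cells, 2 clusters of 2; exact null distribution has choose(4,2) = 6
  ## equally likely label assignments
  umi <- mk_counts(rbind(c(10, 0), c(8, 0), c(0, 10), c(0, 12)))
  colnames(umi) <- c("L", "R")
  labels <- c("A", "A", "B", "B")
  pairs <- data.frame(ligand = "L", receptor = "R")
  res <- ligand_receptor_test(umi, labels, pairs, min_expr_frac = 0,
                              n_perm = 4000, seed = 5)
  ab <- res[res$cluster_a == "A" & res$cluster_b == "B", ]
  ## exhaustive reference
  tot <- Matrix::rowSums(umi)
  ln <- log1p(as.matrix(umi) / tot * 1e4)
  all_labels <- t(utils::combn(4, 2))
  stats_all <- apply(all_labels, 1, function(a_idx) {
    lab <- rep("B", 4); lab[a_idx] <- "A"
    (mean(ln[lab == "A", "L"]) + mean(ln[lab == "B", "R"])) / 2
  })
  obs <- (mean(ln[1:2, "L"]) + mean(ln[3:4, "R"])) / 2
  p_exact <- mean(stats_all >= obs - 1e-12)
  expect_lt(abs(ab$p - p_exact), 0.05)
  ## the add-one rule keeps p strictly positive
  expect_true(all(res$p >= 1 / 4001))
})

test_that("unexpressed ligands and unknown genes are skipped", {
  umi <- mk_counts(rbind(c(0, 5), c(0, 4), c(3, 1), c(2, 2)))
  colnames(umi) <- c("L", "R")
  labels <- c("A", "A", "B", "B")
  res <- ligand_receptor_test(umi, labels,
                              data.frame(ligand = "L", receptor = "R"),
                              min_expr_frac = 0.1, n_perm = 10, seed = 1)
  ## ligand never expressed in cluster A -> the A->B pair is not tested
  expect_false(any(res$cluster_a == "A" & res$cluster_b == "B"))
  expect_warning(
    res2 <- ligand_receptor_test(umi, labels,
                                 data.frame(ligand = "ghost", receptor = "R"),
                                 n_perm = 10, seed = 1),
    "unknown")
  expect_equal(nrow(res2), 0)
})

test_that("null ligand-receptor p values are calibrated", {
  set.seed(13)
  n_cells <- 60
  umi <- mk_counts(matrix(rpois(n_cells * 40, 5), n_cells, 40))
  labels <- rep(c("A", "B"), each = n_cells / 2)
  pairs <- data.frame(ligand = colnames(umi)[1:20],
                      receptor = colnames(umi)[21:40])
  res <- ligand_receptor_test(umi, labels, pairs, n_perm = 400, seed = 2)
  rate <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(rate, 0.05 + 3 * se + 1e-9)
})

test_that("backbone pseudotime orders centroids and respects symmetry", {
  set.seed(5)
  ## three clusters on a line with small jitter
  emb <- cbind(x = rep(c(0, 1, 2), each = 30) + rnorm(90, 0, 0.01),
               y = rnorm(90, 0, 0.01))
  rownames(emb) <- sprintf("c%03d", 1:90)
  labels <- rep(c("k1", "k2", "k3"), each = 30)
  pt <- pseudotime_backbone(emb, labels, c("k1", "k2", "k3"))
  ok <- !is.na(pt)
  expect_gt(sum(ok), 70)
  expect_gt(min(pt[ok][labels[ok] == "k3"]), max(pt[ok][labels[ok] == "k1"]))
  ## monotone in x
  expect_gt(cor(pt[ok], emb[ok, "x"], method = "spearman"), 0.95)
  ## reversing the backbone mirrors pseudotime exactly
  ptr <- pseudotime_backbone(emb, labels, c("k3", "k2", "k1"))
  expect_equal(ptr[ok], 100 - pt[ok], tolerance = 1e-8)
  expect_error(pseudotime_backbone(emb, labels, c("k1", "ghost")), "absent")
  expect_error(pseudotime_backbone(emb, c(labels[-1], "solo"),
                                   c("k1", "solo")), "< 2 cells")
})
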