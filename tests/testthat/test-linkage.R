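mk_agg_fixture <- function(seed = 17) {
  sim <- tiny_sim(seed = seed)
  agg <- suppressWarnings(aggregate_groups(sim$atac, sim$rna, sim$cells,
                                           min_cells = 2))
  list(sim = sim, agg = agg, u = sim$universe)
}

test_that("aggregation conserves counts, drops small groups, ignores order", {
  fx <- mk_agg_fixture()
  agg <- fx$agg
  ## conservation per feature
  expect_equal(unname(colSums(agg$atac_sum)),
               unname(Matrix::colSums(fx$sim$atac)))
  expect_equal(unname(colSums(agg$rna_sum)),
               unname(Matrix::colSums(fx$sim$rna)))
  ## one group -> column sums
  one <- fx$sim$cells
  one$donor <- "d"; one$cell_type <- "t"
  a1 <- aggregate_groups(fx$sim$atac, fx$sim$rna, one, min_cells = 1)
  expect_equal(as.numeric(a1$atac_sum), unname(Matrix::colSums(fx$sim$atac)))
  ## min_cells drops a 4-cell group
  small <- fx$sim$cells
  small$donor[1:4] <- "tiny"
  small$cell_type[1:4] <- "solo"
  expect_warning(a2 <- aggregate_groups(fx$sim$atac, fx$sim$rna, small,
                                        min_cells = 5),
                 "dropping")
  expect_false("tiny.solo" %in% a2$groups$group_id)
  ## permuting cell order leaves profiles unchanged
  perm <- sample(nrow(fx$sim$cells))
  a3 <- suppressWarnings(aggregate_groups(fx$sim$atac[perm, ], fx$sim$rna[perm, ],
                                          fx$sim$cells[perm, ], min_cells = 2))
  expect_equal(a3$atac_sum[rownames(agg$atac_sum), ], agg$atac_sum)
  expect_error(aggregate_groups(fx$sim$atac, fx$sim$rna, fx$sim$cells,
                                min_cells = 1e6), "min_cells")
})

test_that("peak-gene links keep proportional profiles and apply the cutoff", {
  fx <- mk_agg_fixture()
  agg <- fx$agg
  ## plant a perfectly proportional peak/gene pair within the window: pick
  ## the first (peak, gene) pair on a shared contig within 250 kb
  ctr <- floor((fx$u$peaks$start + fx$u$peaks$end) / 2)
  pair <- NULL
  for (i in seq_len(nrow(fx$u$peaks))) {
    j <- which(fx$u$genes$chrom == fx$u$peaks$chrom[i] &
                 abs(fx$u$genes$tss - ctr[i]) <= 250000)
    if (length(j)) { pair <- c(i, j[1]); break }
  }
  expect_false(is.null(pair))  # fixture always has an in-window pair
  pid <- fx$u$peaks$peak_id[pair[1]]
  gid <- fx$u$genes$gene_id[pair[2]]
  ## profiles proportional on the correlation (log1p) scale
  prof <- seq_len(nrow(agg$atac_cpm)) / 2
  agg$atac_cpm[, pid] <- expm1(prof)
  agg$rna_cpm[, gid] <- expm1(2 + 0.5 * prof)
  links <- link_peaks_to_genes(agg, fx$u$peaks, fx$u$genes)
  hit <- links[links$peak_id == pid & links$gene_id == gid, ]
  expect_equal(hit$r, 1, tolerance = 1e-10)
  ## monotone in the cutoff; r below 0.2 is filtered
  l_strict <- link_peaks_to_genes(agg, fx$u$peaks, fx$u$genes,
                                  cor_cutoff = 0.5)
  key <- function(l) paste(l$peak_id, l$gene_id)
  expect_true(all(key(l_strict) %in% key(links)))
  expect_true(all(links$r >= 0.2))
  ## fewer than 3 aggregates is an error
  agg3 <- agg
  agg3$atac_cpm <- agg$atac_cpm[1:2, , drop = FALSE]
  expect_error(link_peaks_to_genes(agg3, fx$u$peaks, fx$u$genes), ">= 3")
})

test_that("planted links are recovered with high sensitivity", {
  u <- generate_universe(n_peaks = 300, n_genes = 100, n_motifs = 4,
                         n_links = 25, seed = 8)
  sim <- simulate_multiome(u, default_design(n_donors = 4,
                                             cells_per_stratum = 15),
                           seed = 8)
  agg <- aggregate_groups(sim$atac, sim$rna, sim$cells)
  links <- link_peaks_to_genes(agg, u$peaks, u$genes)
  truth_keys <- paste(u$truth$true_links$peak_id, u$truth$true_links$gene_id)
  found <- paste(links$peak_id, links$gene_id)
  expect_gte(mean(truth_keys %in% found), 0.8)
})

test_that("co-accessibility edges follow correlation and distance rules", {
  fx <- mk_agg_fixture()
  agg <- fx$agg
  ## duplicate one peak's profile onto the closest same-chrom neighbour
  pk <- fx$u$peaks[order(fx$u$peaks$chrom, fx$u$peaks$start), ]
  gap <- ifelse(pk$chrom[-1] == pk$chrom[-nrow(pk)],
                pk$start[-1] - pk$start[-nrow(pk)], Inf)
  i <- which.min(gap)
  skip_if(gap[i] > 500000, "no same-chrom pair within the window")
  pa <- pk$peak_id[i]; pb <- pk$peak_id[i + 1]
  agg$atac_cpm[, pb] <- agg$atac_cpm[, pa] + 0.5
  coa <- coaccessibility_connections(agg, fx$u$peaks)
  edge <- coa$edges[(coa$edges$peak_a == pa & coa$edges$peak_b == pb) |
                      (coa$edges$peak_a == pb & coa$edges$peak_b == pa), ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$r, 1, tolerance = 1e-10)
  expect_gte(coa$connections[[pa]], 1)
  ## max_dist 0 gives no edges at all
  coa0 <- coaccessibility_connections(agg, fx$u$peaks, max_dist = 0)
  expect_equal(nrow(coa0$edges), 0)
  expect_true(all(coa0$connections == 0))
})

test_that("TF-target scores sum squared correlations over qualifying links", {
  ann <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = 1, dims = c(3, 1),
                              dimnames = list(paste0("p", 1:3), "TF1"))
  links <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("gX", "gX", "gX"),
                      r = c(0.5, 0.3, 0.9), distance = 0L)
  ## worked example: r = 0.5 and 0.3 qualify -> 0.25 + 0.09 = 0.34
  tft <- tf_target_table(links, ann, up_dars = c("p1", "p2", "p3"),
                         up_degs = "gX", tf_list = "TF1")
  expect_equal(tft$targets$score, 0.34, tolerance = 1e-12)
  expect_equal(tft$targets$n_links, 2L)
  ## additivity over disjoint qualifying link sets
  t1 <- tf_target_table(links[1, ], ann, c("p1", "p2"), "gX", "TF1")
  t2 <- tf_target_table(links[2, ], ann, c("p1", "p2"), "gX", "TF1")
  expect_equal(t1$targets$score + t2$targets$score, 0.34, tolerance = 1e-12)
  ## empty DAR set -> empty table; unknown TF -> error
  expect_equal(nrow(tf_target_table(links, ann, character(), "gX",
                                    "TF1")$targets), 0)
  expect_error(tf_target_table(links, ann, "p1", "gX", "ghost"), "absent")
  ## network edges carry the link correlation as weight
  expect_setequal(tft$edges$r, c(0.5, 0.3))
})

test_that("with no planted effects the TF-target table is empty", {
  reps <- 3
  empties <- vapply(seq_len(reps), function(i) {
    u <- generate_universe(n_peaks = 200, n_genes = 60, n_motifs = 4,
                           n_links = 0, seed = 100 + i)
    sim <- simulate_multiome(u, default_design(n_donors = 3,
                                               cells_per_stratum = 15),
                             seed = 100 + i)
    cells <- sim$cells
    da <- differential_features(sim$atac,
                                cells$barcode[cells$group == "VKH"],
                                cells$barcode[cells$group == "HC"])
    dr <- differential_features(sim$rna,
                                cells$barcode[cells$group == "VKH"],
                                cells$barcode[cells$group == "HC"])
    agg <- aggregate_groups(sim$atac, sim$rna, cells)
    links <- link_peaks_to_genes(agg, u$peaks, u$genes)
    tft <- tf_target_table(links, u$motifs, call_dars(da),
                           call_dars(dr, 0.05, 0.25), colnames(u$motifs))
    nrow(tft$targets) == 0
  }, logical(1))
  expect_true(all(empties))
})

test_that("GWAS SNP overlap follows the containment and correlation rules", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(1500, 5500), peak_id = c("pA", "pB"), gc = 0.5)
  links <- data.frame(peak_id = c("pA", "pA", "pB"),
                      gene_id = c("g1", "g2", "g3"),
                      r = c(0.25, 0.15, 0.5), distance = 0L)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(1200, 9999))
  dars <- list(Tcell = "pA", Mono = "pB")
  res <- gwas_overlap(snps, dars, peaks, links)
  ## rs1 sits in pA (a T-cell DAR); only the r = 0.25 link attributes a gene
  tcell <- res[res$cell_type == "Tcell", ]
  expect_equal(tcell$snp_id, "rs1")
  expect_equal(tcell$gene_id, "g1")
  expect_equal(tcell$r, 0.25)
  ## rs2 overlaps nothing; Mono has no overlapping SNP
  expect_false("rs2" %in% res$snp_id)
  ## r exactly at the cutoff is not attributed (strictly "over 0.2")
  links2 <- transform(links, r = c(0.2, 0.15, 0.5))
  res2 <- gwas_overlap(snps, dars, peaks, links2)
  expect_true(is.na(res2$gene_id[res2$cell_type == "Tcell"]))
  ## empty SNP table -> empty result
  expect_equal(nrow(gwas_overlap(snps[0, ], dars, peaks, links)), 0)
})
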