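#' Aggregate paired counts to pseudobulk groups
#'
#' Sums ATAC and RNA counts over cells within each donor-by-cell-type group
#' (the default metacell definition: reproducible and donor-aware). Groups
#' with fewer than `min_cells` cells are dropped with a warning.
#' Depth-normalized (counts-per-million) profiles are returned alongside the
#' raw sums.
#'
#' @param atac,rna sparse cells x features count matrices sharing barcodes
#'   with `cells`.
#' @param cells per-cell table.
#' @param key columns of `cells` defining the grouping.
#' @param min_cells minimum group size.
#' @return list of class `reglink_aggregates` with `groups` (data.frame of
#'   group key columns and n_cells), `atac_sum`, `atac_cpm`, `rna_sum`,
#'   `rna_cpm` (groups x features matrices).
#' @export
aggregate_groups <- function(atac, rna, cells, key = c("donor", "cell_type"),
                             min_cells = 5) {
  assert_columns(cells, c("barcode", key), "cell table")
  gid <- do.call(paste, c(cells[key], sep = "."))
  sizes <- table(gid)
  keep_groups <- names(sizes)[sizes >= min_cells]
  if (length(keep_groups) == 0L) {
    stopf("no group reaches min_cells = %d", min_cells)
  }
  if (length(keep_groups) < length(sizes)) {
    warnf("dropping %d group(s) below min_cells = %d",
          length(sizes) - length(keep_groups), min_cells)
  }
  keep <- gid %in% keep_groups
  gid_f <- factor(gid[keep], keep_groups)
  ind <- Matrix::sparseMatrix(i = seq_len(sum(keep)),
                              j = as.integer(gid_f), x = 1,
                              dims = c(sum(keep), length(keep_groups)))
  sum_mat <- function(m) {
    s <- as.matrix(Matrix::crossprod(ind, m[cells$barcode[keep], , drop = FALSE]))
    rownames(s) <- keep_groups
    s
  }
  atac_sum <- sum_mat(atac)
  rna_sum <- sum_mat(rna)
  cpm <- function(m) m / pmax(rowSums(m), 1) * 1e6

  groups <- cells[keep, key, drop = FALSE][!duplicated(gid_f), , drop = FALSE]
  groups <- groups[order(match(gid[keep][!duplicated(gid_f)], keep_groups)), ,
                   drop = FALSE]
  groups$group_id <- keep_groups
  groups$n_cells <- as.integer(sizes[keep_groups])
  rownames(groups) <- NULL

  structure(list(groups = groups, atac_sum = atac_sum,
                 atac_cpm = cpm(atac_sum), rna_sum = rna_sum,
                 rna_cpm = cpm(rna_sum)),
            class = "reglink_aggregates")
}

## Pearson correlation between selected column pairs of two matrices,
## computed on log1p CPM profiles across aggregates; constant profiles -> NA
pair_cor <- function(xm, ym, xi, yi) {
  xs <- scale(xm); ys <- scale(ym)
  n <- nrow(xm)
  r <- colSums(xs[, xi, drop = FALSE] * ys[, yi, drop = FALSE]) / (n - 1)
  r[!is.finite(r)] <- NA_real_
  as.numeric(r)
}

#' Link peaks to genes by pseudobulk correlation
#'
#' Candidate pairs are peaks whose center lies within `max_dist` of a gene's
#' TSS; for each, the Pearson correlation of log1p CPM peak accessibility and
#' gene expression across aggregates is computed, and links with signed
#' `r >= cor_cutoff` are kept (positive links only, consistent with scoring
#' jointly upregulated peak-gene pairs). Constant profiles give undefined
#' correlations and are skipped.
#'
#' @param agg output of [aggregate_groups()] (needs >= 3 aggregates).
#' @param peaks,genes universe tables.
#' @param max_dist peak-center-to-TSS window in bp.
#' @param cor_cutoff minimum signed correlation.
#' @return data.frame: peak_id, gene_id, r, distance.
#' @export
link_peaks_to_genes <- function(agg, peaks, genes, max_dist = 250000,
                                cor_cutoff = 0.2) {
  if (nrow(agg$atac_cpm) < 3L) {
    stopf("need >= 3 aggregates to correlate profiles")
  }
  ctr <- peak_centers_granges(peaks)
  tssr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(ctr, tssr, maxgap = max_dist)
  pi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  if (length(pi) == 0L) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      r = numeric(), distance = integer()))
  }
  r <- pair_cor(log1p(agg$atac_cpm[, peaks$peak_id, drop = FALSE]),
                log1p(agg$rna_cpm[, genes$gene_id, drop = FALSE]), pi, gi)
  dist <- abs(floor((peaks$start[pi] + peaks$end[pi]) / 2) - genes$tss[gi])
  keep <- !is.na(r) & r >= cor_cutoff
  out <- data.frame(peak_id = peaks$peak_id[pi][keep],
                    gene_id = genes$gene_id[gi][keep],
                    r = r[keep], distance = as.integer(dist[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

#' Peak-peak co-accessibility connections
#'
#' All peak pairs whose centers lie within `max_dist` are correlated
#' (Pearson, log1p CPM across aggregates); pairs with `r >= co_cutoff` form
#' an edge, and a peak's connection count is its degree in this graph.
#'
#' @param agg output of [aggregate_groups()].
#' @param peaks peak table.
#' @param max_dist pairing window in bp.
#' @param co_cutoff minimum correlation for an edge.
#' @return list with `edges` (data.frame: peak_a, peak_b, r) and
#'   `connections` (named per-peak degree, zeros included).
#' @export
coaccessibility_connections <- function(agg, peaks, max_dist = 500000,
                                        co_cutoff = 0.35) {
  if (nrow(agg$atac_cpm) < 3L) {
    stopf("need >= 3 aggregates to correlate profiles")
  }
  ctr <- peak_centers_granges(peaks)
  hits <- GenomicRanges::findOverlaps(ctr, maxgap = max_dist,
                                      drop.self = TRUE, drop.redundant = TRUE)
  pa <- S4Vectors::queryHits(hits); pb <- S4Vectors::subjectHits(hits)
  conn <- setNames(integer(nrow(peaks)), peaks$peak_id)
  if (length(pa) == 0L) {
    return(list(edges = data.frame(peak_a = character(), peak_b = character(),
                                   r = numeric()),
                connections = conn))
  }
  x <- log1p(agg$atac_cpm[, peaks$peak_id, drop = FALSE])
  r <- pair_cor(x, x, pa, pb)
  keep <- !is.na(r) & r >= co_cutoff
  edges <- data.frame(peak_a = peaks$peak_id[pa][keep],
                      peak_b = peaks$peak_id[pb][keep],
                      r = r[keep], stringsAsFactors = FALSE)
  deg <- table(c(edges$peak_a, edges$peak_b))
  conn[names(deg)] <- as.integer(deg)
  list(edges = edges, connections = conn)
}

#' TF-target table with differential linkage scores
#'
#' A link qualifies for a TF iff its peak carries the TF motif, the peak is
#' an upregulated differentially accessible region and the gene is an
#' upregulated differentially expressed gene. Per TF and gene, the
#' differential linkage score is the sum of squared correlations over
#' qualifying links; genes with at least one qualifying link appear. Network
#' edges carry the link correlation as weight.
#'
#' @param links output of [link_peaks_to_genes()].
#' @param ann binary peaks x motifs annotation with dimnames.
#' @param up_dars,up_degs character vectors of upregulated peaks and genes.
#' @param tf_list motif ids to build tables for (must exist in `ann`).
#' @return list with `targets` (data.frame: tf, gene_id, score, n_links) and
#'   `edges` (data.frame: tf, peak_id, gene_id, r).
#' @export
tf_target_table <- function(links, ann, up_dars, up_degs, tf_list) {
  missing <- setdiff(tf_list, colnames(ann))
  if (length(missing)) stopf("TF(s) absent from annotation: %s",
                             paste(missing, collapse = ", "))
  ann <- methods::as(ann, "CsparseMatrix") * 1
  empty <- list(
    targets = data.frame(tf = character(), gene_id = character(),
                         score = numeric(), n_links = integer()),
    edges = data.frame(tf = character(), peak_id = character(),
                       gene_id = character(), r = numeric()))
  qual <- links[links$peak_id %in% up_dars & links$gene_id %in% up_degs, ,
                drop = FALSE]
  if (nrow(qual) == 0L) return(empty)

  res <- lapply(tf_list, function(tf) {
    tf_peaks <- rownames(ann)[ann[, tf] != 0]
    q <- qual[qual$peak_id %in% tf_peaks, , drop = FALSE]
    if (nrow(q) == 0L) return(NULL)
    sc <- tapply(q$r^2, q$gene_id, sum)
    nl <- tapply(q$r, q$gene_id, length)
    list(targets = data.frame(tf = tf, gene_id = names(sc),
                              score = as.numeric(sc),
                              n_links = as.integer(nl),
                              stringsAsFactors = FALSE),
         edges = data.frame(tf = tf, peak_id = q$peak_id,
                            gene_id = q$gene_id, r = q$r,
                            stringsAsFactors = FALSE))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty)
  out <- list(targets = do.call(rbind, lapply(res, `[[`, "targets")),
              edges = do.call(rbind, lapply(res, `[[`, "edges")))
  rownames(out$targets) <- rownames(out$edges) <- NULL
  out
}

#' Overlap GWAS SNPs with cell-type differential peaks
#'
#' A SNP is reported for a cell type iff it falls inside one of that cell
#' type's upregulated differential peaks. Gene attribution uses the
#' containing peak's links with correlation strictly above `min_link_cor`;
#' SNPs in a differential peak without such a link are reported with an `NA`
#' gene.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (0-based).
#' @param dars_by_celltype named list of upregulated peak-id sets per cell
#'   type.
#' @param peaks peak table.
#' @param links output of [link_peaks_to_genes()].
#' @param min_link_cor correlation a link must exceed (strict) for gene
#'   attribution.
#' @return data.frame: snp_id, cell_type, peak_id, gene_id, r.
#' @export
gwas_overlap <- function(snps, dars_by_celltype, peaks, links,
                         min_link_cor = 0.2) {
  empty <- data.frame(snp_id = character(), cell_type = character(),
                      peak_id = character(), gene_id = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L) return(empty)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos + 1L, width = 1L))
  pk <- peaks_to_granges(peaks)
  out <- lapply(names(dars_by_celltype), function(ct) {
    sel <- peaks$peak_id %in% dars_by_celltype[[ct]]
    if (!any(sel)) return(NULL)
    hits <- GenomicRanges::findOverlaps(snp_gr, pk[sel])
    if (length(hits) == 0L) return(NULL)
    peak_hit <- names(pk[sel])[S4Vectors::subjectHits(hits)]
    snp_hit <- snps$snp_id[S4Vectors::queryHits(hits)]
    rows <- lapply(seq_along(snp_hit), function(i) {
      lk <- links[links$peak_id == peak_hit[i] & links$r > min_link_cor, ,
                  drop = FALSE]
      if (nrow(lk) == 0L) {
        data.frame(snp_id = snp_hit[i], cell_type = ct,
                   peak_id = peak_hit[i], gene_id = NA_character_,
                   r = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(snp_id = snp_hit[i], cell_type = ct,
                   peak_id = peak_hit[i], gene_id = lk$gene_id, r = lk$r,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}
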