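#' Filter scATAC cells on fragment count and TSS enrichment
#'
#' Retains cells with at least `min_fragments` unique fragments and TSS
#' enrichment of at least `min_tss`; both bounds are inclusive (a cell at
#' exactly 2500 fragments or TSS enrichment exactly 9 is kept). Row order is
#' preserved and the removed count is reported as a message.
#'
#' @param cells per-cell table with `n_fragments` and `tss_enrichment`.
#' @param min_fragments minimum unique fragments per cell.
#' @param min_tss minimum TSS enrichment ratio.
#' @return the filtered cell table, with attribute `removed` (count).
#' @export
filter_atac_cells <- function(cells, min_fragments = 2500, min_tss = 9) {
  assert_columns(cells, c("n_fragments", "tss_enrichment"), "cell table")
  keep <- cells$n_fragments >= min_fragments & cells$tss_enrichment >= min_tss
  out <- cells[keep, , drop = FALSE]
  message(sprintf("filter_atac_cells: removed %d of %d cells",
                  sum(!keep), nrow(cells)))
  attr(out, "removed") <- sum(!keep)
  out
}

#' Filter scRNA cells on mitochondrial fraction and detected genes
#'
#' Retains cells with mitochondrial fraction at most `max_mito` and detected
#' genes within `[min_genes, max_genes]`; all bounds inclusive (a cell at
#' exactly 11 percent mitochondrial reads, or 200 or 3000 detected genes, is
#' kept).
#'
#' @param cells per-cell table with `mito_fraction` and `n_genes_detected`.
#' @param max_mito maximum mitochondrial read fraction.
#' @param min_genes,max_genes detected-gene bounds.
#' @return the filtered cell table, with attribute `removed` (count).
#' @export
filter_rna_cells <- function(cells, max_mito = 0.11, min_genes = 200,
                             max_genes = 3000) {
  assert_columns(cells, c("mito_fraction", "n_genes_detected"), "cell table")
  keep <- cells$mito_fraction <= max_mito &
    cells$n_genes_detected >= min_genes &
    cells$n_genes_detected <= max_genes
  out <- cells[keep, , drop = FALSE]
  message(sprintf("filter_rna_cells: removed %d of %d cells",
                  sum(!keep), nrow(cells)))
  attr(out, "removed") <- sum(!keep)
  out
}

#' Per-cell TSS enrichment ratio
#'
#' Ratio of the mean per-bp insertion density in a core window around each
#' TSS (default +/- 50 bp) to the density in a distal flank window (default
#' 1901-2000 bp on both sides). Overlapping windows from nearby TSSs are
#' merged before counting, so no insertion is double counted. A zero flank
#' with a non-zero core returns `Inf`; a cell with no insertions in either
#' window scores 0.
#'
#' @param insertions data.frame with columns `barcode`, `chrom`, `pos`
#'   (0-based insertion positions).
#' @param tss data.frame with columns `chrom`, `tss` (one row per TSS).
#' @param core_halfwidth core half-width in bp.
#' @param flank two integers, the inner and outer edge of the distal flank in
#'   bp from the TSS.
#' @return named numeric vector of ratios, one per barcode present in
#'   `insertions`.
#' @export
tss_enrichment <- function(insertions, tss, core_halfwidth = 50,
                           flank = c(1901, 2000)) {
  assert_columns(insertions, c("barcode", "chrom", "pos"), "insertions")
  assert_columns(tss, c("chrom", "tss"), "tss table")
  if (nrow(tss) == 0L) stopf("tss_enrichment needs at least one TSS")
  if (flank[2] <= flank[1]) stopf("flank window is empty")

  mk <- function(starts, ends) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(start = pmax(1L, starts), end = ends)))
  }
  core <- mk(tss$tss - core_halfwidth + 1L, tss$tss + core_halfwidth + 1L)
  fl <- c(mk(tss$tss - flank[2] + 1L, tss$tss - flank[1] + 1L),
          mk(tss$tss + flank[1] + 1L, tss$tss + flank[2] + 1L))
  fl <- GenomicRanges::reduce(fl)
  core_bp <- sum(IRanges::width(core))
  flank_bp <- sum(IRanges::width(fl))

  ins <- GenomicRanges::GRanges(insertions$chrom,
                                IRanges::IRanges(insertions$pos + 1L, width = 1L))
  in_core <- IRanges::overlapsAny(ins, core)
  in_flank <- IRanges::overlapsAny(ins, fl)

  barcodes <- unique(insertions$barcode)
  core_n <- tapply(in_core, factor(insertions$barcode, barcodes), sum)
  flank_n <- tapply(in_flank, factor(insertions$barcode, barcodes), sum)
  core_d <- as.numeric(core_n) / core_bp
  flank_d <- as.numeric(flank_n) / flank_bp
  ratio <- ifelse(flank_d == 0 & core_d == 0, 0,
                  ifelse(flank_d == 0, Inf, core_d / flank_d))
  setNames(ratio, barcodes)
}

#' Gene activity scores from peak accessibility
#'
#' For each gene, nearby peak counts are combined with distance-dependent
#' weights: weight 1 for peaks overlapping the gene body or the promoter
#' window (`promoter_upstream` bp upstream of the TSS, strand-aware), and
#' `exp(-d / decay)` for distal peaks, where `d` is the distance from the
#' peak center to the nearest gene-body edge; peaks with centers beyond
#' `max_dist` of the body contribute nothing. The score is linear in the
#' count matrix.
#'
#' @param atac sparse cells x peaks count matrix (columns named by peak id).
#' @param peaks peak table (chrom, start, end, peak_id).
#' @param genes gene table (gene_id, chrom, tss, body_start, body_end,
#'   strand).
#' @param decay exponential decay length in bp.
#' @param max_dist maximum peak-center-to-body distance in bp.
#' @param promoter_upstream upstream promoter extent in bp given weight 1.
#' @return dense cells x genes score matrix.
#' @export
gene_activity_scores <- function(atac, peaks, genes, decay = 5000,
                                 max_dist = 100000, promoter_upstream = 2000) {
  if (any(genes$body_end <= genes$body_start)) {
    stopf("malformed gene body (end <= start)")
  }
  pk <- peaks_to_granges(peaks)
  ctr <- peak_centers_granges(peaks)
  body <- genes_to_body_granges(genes)
  prom <- GenomicRanges::promoters(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$tss + 1L, width = 1L),
                           strand = genes$strand),
    upstream = promoter_upstream, downstream = 0)

  ## distal candidates: peak centers within max_dist of the gene body
  hits_d <- GenomicRanges::findOverlaps(ctr, body, maxgap = max_dist)
  d <- GenomicRanges::distance(ctr[S4Vectors::queryHits(hits_d)],
                               body[S4Vectors::subjectHits(hits_d)])
  w <- exp(-as.numeric(d) / decay)

  ## proximal: weight 1 for body or promoter overlap of the full peak
  hits_b <- GenomicRanges::findOverlaps(pk, body)
  hits_p <- GenomicRanges::findOverlaps(pk, prom)
  i <- c(S4Vectors::queryHits(hits_d), S4Vectors::queryHits(hits_b),
         S4Vectors::queryHits(hits_p))
  j <- c(S4Vectors::subjectHits(hits_d), S4Vectors::subjectHits(hits_b),
         S4Vectors::subjectHits(hits_p))
  x <- c(w, rep(1, length(hits_b) + length(hits_p)))

  ## keep the maximum weight per (peak, gene) pair
  key <- paste(i, j)
  ord <- order(key, -x)
  dup <- duplicated(key[ord])
  i <- i[ord][!dup]; j <- j[ord][!dup]; x <- x[ord][!dup]

  W <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(peaks), nrow(genes)),
                            dimnames = list(peaks$peak_id, genes$gene_id))
  as.matrix(atac %*% W)
}

#' Annotate each peak with its nearest gene
#'
#' Nearest is by absolute distance from the peak center to the TSS; ties are
#' broken by lexicographically smaller gene id. The reported distance is
#' signed relative to the gene's orientation (positive downstream of the
#' TSS). A peak is a promoter peak iff the absolute distance is at most
#' `promoter_dist` (3 kb as conventionally printed); otherwise distal. Peaks
#' on a contig with no genes get an `NA` annotation with a warning.
#'
#' @param peaks peak table.
#' @param genes gene table.
#' @param promoter_dist promoter category cutoff in bp.
#' @return data.frame: peak_id, gene_id, distance, category.
#' @export
annotate_nearest_gene <- function(peaks, genes, promoter_dist = 3000) {
  if (nrow(genes) == 0L) stopf("annotate_nearest_gene needs >= 1 gene")
  ctr <- floor((peaks$start + peaks$end) / 2)
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance = NA_real_, category = NA_character_,
                    stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    ## small universes: direct distance matrix, deterministic tie-break
    dmat <- abs(outer(ctr[pi], genes$tss[gi], "-"))
    ord <- order(genes$gene_id[gi])
    dmat <- dmat[, ord, drop = FALSE]
    gsorted <- gi[ord]
    best <- max.col(-dmat, ties.method = "first")
    g <- gsorted[best]
    raw <- ctr[pi] - genes$tss[g]
    out$gene_id[pi] <- genes$gene_id[g]
    out$distance[pi] <- ifelse(genes$strand[g] == "-", -raw, raw)
  }
  if (anyNA(out$gene_id)) {
    warnf("%d peak(s) lie on contigs with no genes; annotation is NA",
          sum(is.na(out$gene_id)))
  }
  out$category <- ifelse(is.na(out$distance), NA_character_,
                         ifelse(abs(out$distance) <= promoter_dist,
                                "promoter", "distal"))
  out
}
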