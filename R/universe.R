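#' Declare a small toy genome
#'
#' The simulator places peaks and genes on a declared set of contigs rather
#' than a real reference assembly. The default is three 10-Mb contigs, large
#' enough that thousands of non-overlapping peaks and their distal regulatory
#' neighbourhoods (hundreds of kb) fit comfortably.
#'
#' @param n_chrom number of contigs.
#' @param chrom_length length of each contig in bp.
#' @return list with `chrom` (names) and `length` (bp per contig).
#' @export
toy_genome <- function(n_chrom = 3, chrom_length = 1e7) {
  if (n_chrom < 1 || chrom_length < 1e4) {
    stopf("toy genome needs >= 1 contig of >= 10 kb")
  }
  list(chrom = paste0("chr", seq_len(n_chrom)),
       length = rep(as.integer(chrom_length), n_chrom))
}

#' Generate the synthetic regulatory universe
#'
#' Lays out a non-overlapping peak set, a gene model and a binary peak-by-motif
#' annotation on a toy genome, and records the planted truth (motif
#' memberships and true peak-gene links) that downstream recovery tests are
#' scored against.
#'
#' Peaks are placed on a fixed grid of non-overlapping slots (one slot =
#' `peak_width` plus an equal gap), so non-overlap holds by construction.
#' Per-peak GC fraction is drawn from Beta(5, 5) (mean 0.5, most mass in
#' 0.2-0.8, the range where GC-matched background binning is informative).
#' Each motif annotates a `motif_density` fraction of peaks, sampled without
#' replacement. True links pair a gene with one peak within `link_max_dist`
#' of its TSS; each link carries its own latent factor in the simulator.
#'
#' @param n_peaks,n_genes,n_motifs universe sizes (all >= 1).
#' @param motif_density fraction of peaks annotated by each motif.
#' @param n_links number of planted peak-gene links.
#' @param genome output of [toy_genome()].
#' @param peak_width peak width in bp.
#' @param link_max_dist maximum peak-center-to-TSS distance for a planted
#'   link (bp); matches the default linkage search window.
#' @param seed integer seed; identical seeds give identical universes.
#' @return list with elements `peaks` (data.frame: chrom, start, end, peak_id,
#'   gc; 0-based half-open), `genes` (data.frame: gene_id, chrom, tss,
#'   body_start, body_end, strand), `motifs` (sparse binary peaks x motifs
#'   matrix), `genome`, and `truth` (list: motif_peaks, true_links,
#'   motif_effects, deg_effects, true_dars, true_degs).
#' @export
generate_universe <- function(n_peaks = 1000, n_genes = 300, n_motifs = 10,
                              motif_density = 0.1, n_links = 50,
                              genome = toy_genome(), peak_width = 500,
                              link_max_dist = 250000, seed = 1) {
  if (n_peaks < 1 || n_genes < 1 || n_motifs < 1) {
    stopf("universe sizes must all be >= 1 (got n_peaks=%d, n_genes=%d, n_motifs=%d)",
          n_peaks, n_genes, n_motifs)
  }
  if (motif_density <= 0 || motif_density > 1) {
    stopf("motif_density must be in (0, 1]")
  }
  set.seed(child_seed(seed, "universe"))

  slot <- 2L * peak_width
  slots_per_chrom <- floor(genome$length / slot)
  total_slots <- sum(slots_per_chrom)
  if (n_peaks + n_genes > total_slots) {
    stopf("genome too small: %d slots available for %d peaks + %d genes",
          total_slots, n_peaks, n_genes)
  }

  ## global slot ids -> (chrom, within-chrom slot); peaks and genes take
  ## disjoint slots so gene bodies never start inside a peak slot boundary
  picked <- sort(sample.int(total_slots, n_peaks + n_genes))
  chrom_of <- rep(seq_along(genome$chrom), slots_per_chrom)
  offset <- c(0L, cumsum(slots_per_chrom))[chrom_of]
  within <- picked - offset[picked] - 1L
  chrom_idx <- chrom_of[picked]

  take_peak <- sort(sample.int(n_peaks + n_genes, n_peaks))
  is_peak <- seq_len(n_peaks + n_genes) %in% take_peak

  start <- within * slot + as.integer(peak_width / 2)
  peaks <- data.frame(
    chrom = genome$chrom[chrom_idx[is_peak]],
    start = start[is_peak],
    end = start[is_peak] + peak_width,
    peak_id = sprintf("peak_%05d", seq_len(n_peaks)),
    gc = round(rbeta(n_peaks, 5, 5), 4),
    stringsAsFactors = FALSE
  )

  g_chrom <- genome$chrom[chrom_idx[!is_peak]]
  g_tss <- start[!is_peak]
  g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  g_len <- as.integer(round(runif(n_genes, 5000, 50000)))
  body_start <- ifelse(g_strand == "+", g_tss, pmax(0L, g_tss - g_len))
  body_end <- ifelse(g_strand == "+",
                     pmin(genome$length[chrom_idx[!is_peak]], g_tss + g_len),
                     g_tss + 1L)
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = g_chrom, tss = g_tss,
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    strand = g_strand, stringsAsFactors = FALSE
  )

  motif_ids <- sprintf("motif_%03d", seq_len(n_motifs))
  per_motif <- max(1L, as.integer(round(motif_density * n_peaks)))
  motif_peaks <- lapply(motif_ids, function(m) {
    sort(sample.int(n_peaks, per_motif))
  })
  names(motif_peaks) <- motif_ids
  motifs <- Matrix::sparseMatrix(
    i = unlist(motif_peaks),
    j = rep(seq_len(n_motifs), lengths(motif_peaks)),
    x = 1, dims = c(n_peaks, n_motifs),
    dimnames = list(peaks$peak_id, motif_ids)
  )

  ## planted links: one candidate peak within link_max_dist of a gene's TSS
  ctr <- floor((peaks$start + peaks$end) / 2)
  link_gene <- sample.int(n_genes, min(n_links, n_genes))
  links <- lapply(link_gene, function(gi) {
    ok <- which(peaks$chrom == genes$chrom[gi] &
                  abs(ctr - genes$tss[gi]) <= link_max_dist)
    if (length(ok) == 0L) return(NULL)
    data.frame(peak_id = peaks$peak_id[sample(ok, 1L)],
               gene_id = genes$gene_id[gi], stringsAsFactors = FALSE)
  })
  true_links <- do.call(rbind, links[!vapply(links, is.null, logical(1))])
  if (is.null(true_links)) {
    true_links <- data.frame(peak_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  }

  truth <- list(
    motif_peaks = lapply(motif_peaks, function(i) peaks$peak_id[i]),
    true_links = true_links,
    motif_effects = setNames(numeric(n_motifs), motif_ids),
    deg_effects = setNames(numeric(n_genes), genes$gene_id),
    true_dars = character(),
    true_degs = character(),
    hazard_beta = NA_real_
  )

  structure(list(peaks = peaks, genes = genes, motifs = motifs,
                 genome = genome, truth = truth),
            class = "reglink_universe")
}
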