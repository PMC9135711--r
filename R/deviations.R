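#' Sample GC- and accessibility-matched background peaks
#'
#' Peaks are binned on a 2-D grid over (GC fraction, log1p mean accessibility)
#' and each peak draws `n_bg` background peaks uniformly (with replacement)
#' from its own bin, so backgrounds share the technical covariates that drive
#' raw accessibility deviations. A bin containing a single peak backgrounds
#' itself; this is logged, not an error.
#'
#' @param peaks peak table with a `gc` column.
#' @param mean_accessibility per-peak mean accessibility (same order as
#'   `peaks`).
#' @param n_bg number of background draws per peak.
#' @param n_bins integer vector of length 2: bins along GC and along log1p
#'   accessibility.
#' @param seed integer seed.
#' @return integer matrix (peaks x n_bg) of background peak indices, with
#'   attribute `bin` (per-peak bin id).
#' @export
sample_background_peaks <- function(peaks, mean_accessibility, n_bg = 50,
                                    n_bins = c(10, 10), seed = 1) {
  if (length(mean_accessibility) != nrow(peaks)) {
    stopf("mean_accessibility must have one value per peak")
  }
  if (any(!is.finite(peaks$gc)) || any(!is.finite(mean_accessibility))) {
    stopf("every peak needs finite gc and mean accessibility")
  }
  set.seed(child_seed(seed, "background"))
  cut_safe <- function(x, k) {
    if (length(unique(x)) == 1L) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = k, include.lowest = TRUE))
  }
  b1 <- cut_safe(peaks$gc, n_bins[1])
  b2 <- cut_safe(log1p(mean_accessibility), n_bins[2])
  bin <- paste(b1, b2, sep = ".")
  members <- split(seq_len(nrow(peaks)), bin)
  singletons <- sum(lengths(members) == 1L)
  if (singletons > 0L) {
    message(sprintf("sample_background_peaks: %d singleton bin(s); those peaks background themselves",
                    singletons))
  }
  bg <- matrix(0L, nrow(peaks), n_bg)
  for (mem in members) {
    ## index into mem explicitly: sample(x, ...) on a scalar would sample 1:x
    bg[mem, ] <- mem[sample.int(length(mem), length(mem) * n_bg,
                                replace = TRUE)]
  }
  attr(bg, "bin") <- bin
  bg
}

#' Bias-corrected motif deviation scores
#'
#' For a cells x peaks count matrix and a binary peak x motif annotation,
#' the expected fraction of reads in peak p is `f_p` = peak total / grand
#' total; the expected motif count in a cell is its total times the summed
#' `f_p` over annotated peaks. The raw deviation is `(observed - expected) /
#' expected`. For each of the `n_bg` background draws the motif's peaks are
#' replaced by their matched background peaks (with multiplicity) and the raw
#' deviation recomputed; the bias-corrected deviation z is the raw deviation
#' standardized by the background mean and standard deviation, per cell and
#' motif. Variability is the standard deviation of z across cells per motif.
#'
#' Cells and motifs with a zero background standard deviation are flagged
#' `NA` (undefined) rather than dropped.
#'
#' @param atac sparse cells x peaks count matrix.
#' @param ann binary peaks x motifs annotation matrix (sparse or dense).
#' @param bg background index matrix from [sample_background_peaks()].
#' @return list of class `reglink_deviations` with `raw` and `z`
#'   (motifs x cells matrices) and `variability` (named per-motif sd of z).
#' @export
compute_deviations <- function(atac, ann, bg) {
  ann <- methods::as(ann, "CsparseMatrix") * 1  # force numeric sparse
  grand <- sum(atac)
  if (grand <= 0) stopf("count matrix is all zero")
  k_per_motif <- Matrix::colSums(ann != 0)
  if (any(k_per_motif == 0)) {
    stopf("motif(s) annotating no peaks: %s",
          paste(colnames(ann)[k_per_motif == 0], collapse = ", "))
  }
  if (nrow(bg) != nrow(ann)) stopf("background matrix does not match peaks")

  cell_tot <- Matrix::rowSums(atac)
  f <- Matrix::colSums(atac) / grand

  raw_dev <- function(a) {
    obs <- as.matrix(atac %*% a)
    e <- outer(cell_tot, as.numeric(Matrix::crossprod(a, f)))
    (obs - e) / e
  }
  raw <- raw_dev(ann)

  n_bg <- ncol(bg)
  summ <- matrix(0, nrow(atac), ncol(ann))
  sumsq <- matrix(0, nrow(atac), ncol(ann))
  tri <- Matrix::summary(ann)      # i = peak, j = motif
  for (b in seq_len(n_bg)) {
    a_b <- Matrix::sparseMatrix(i = bg[tri$i, b], j = tri$j, x = tri$x,
                                dims = dim(ann))
    r_b <- raw_dev(a_b)
    summ <- summ + r_b
    sumsq <- sumsq + r_b^2
  }
  mu <- summ / n_bg
  sdv <- sqrt(pmax(0, (sumsq - n_bg * mu^2) / (n_bg - 1)))
  z <- (raw - mu) / sdv
  z[sdv == 0] <- NA_real_

  raw <- t(raw); z <- t(z)
  dimnames(raw) <- dimnames(z) <- list(colnames(ann), rownames(atac))
  variability <- apply(z, 1, function(v) sd(v[is.finite(v)]))
  structure(list(raw = raw, z = z, variability = variability),
            class = "reglink_deviations")
}

#' Bias-corrected, flank-normalized TF footprint profile
#'
#' The Tn5 bias track is first scaled so its mass over the normalization
#' flank (`|offset|` in `norm_window`, default 200-250 bp) matches the
#' observed flank mass, then the observed insertion profile is corrected for
#' it. Two corrections are available: `"ratio"` (default; observed divided by
#' scaled bias, i.e. subtraction in log space) and `"subtract"` (both tracks
#' flank-normalized to mean 1, then differenced and re-centered at 1). In
#' both modes the returned normalized signal has mean exactly 1 over the
#' normalization window, so a protected core of depth d reads as a dip to
#' about 1 - d.
#'
#' @param track a `reglink_insertion_track` from [simulate_insertions()], or
#'   any list with `offsets`, `counts` (offsets x groups), `bias`.
#' @param norm_window two integers, the absolute-offset normalization window.
#' @param method `"ratio"` or `"subtract"`.
#' @return data.frame: motif_id, group, offset, observed (mean insertions per
#'   site), corrected, normalized.
#' @export
footprint_profile <- function(track, norm_window = c(200, 250),
                              method = c("ratio", "subtract")) {
  method <- match.arg(method)
  offsets <- track$offsets
  bias <- track$bias
  if (any(bias <= 0)) stopf("Tn5 bias must be positive at all offsets")
  fl <- abs(offsets) >= norm_window[1] & abs(offsets) <= norm_window[2]
  if (!any(fl)) stopf("empty normalization window")
  n_sites <- track$n_sites %||% 1

  out <- lapply(colnames(track$counts) %||% as.character(seq_len(ncol(track$counts))),
                function(grp) {
    obs <- track$counts[, grp] / n_sites
    if (mean(obs[fl]) <= 0) {
      stopf("zero flank signal for group %s: footprint profile undefined", grp)
    }
    scaled_bias <- bias * mean(obs[fl]) / mean(bias[fl])
    if (method == "ratio") {
      corrected <- obs / scaled_bias
      normalized <- corrected / mean(corrected[fl])
    } else {
      corrected <- obs - scaled_bias
      normalized <- obs / mean(obs[fl]) - bias / mean(bias[fl]) + 1
    }
    data.frame(motif_id = track$motif_id %||% "motif", group = grp,
               offset = offsets, observed = obs, corrected = corrected,
               normalized = normalized, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-cell deviation enrichment of external tissue peak sets
#'
#' Each external tissue interval is extended by `extend` bp on both sides;
#' own peaks that overlap any extended interval and have strictly more than
#' `min_connections` co-accessibility connections form that tissue's feature
#' set, which is scored like a one-motif annotation through
#' [compute_deviations()]. Tissues with an empty feature set are flagged and
#' get no scores.
#'
#' @param tissues named list of external interval tables (chrom, start, end;
#'   0-based half-open).
#' @param peaks own peak table.
#' @param connections named per-peak co-accessibility connection counts, as
#'   from [coaccessibility_connections()].
#' @param atac sparse cells x peaks count matrix.
#' @param bg background index matrix over the same peaks.
#' @param extend one-sided extension of external intervals in bp.
#' @param min_connections connection count that must be exceeded (strict).
#' @return list with `z` (tissues x cells matrix for non-empty tissues),
#'   `feature_sets` (peak ids per tissue) and `empty` (names of flagged
#'   tissues).
#' @export
tissue_peakset_enrichment <- function(tissues, peaks, connections, atac, bg,
                                      extend = 2500, min_connections = 3) {
  own <- peaks_to_granges(peaks)
  conn <- connections[peaks$peak_id]
  conn[is.na(conn)] <- 0
  sets <- lapply(tissues, function(tt) {
    ext <- GenomicRanges::GRanges(
      tt$chrom,
      IRanges::IRanges(start = pmax(1L, tt$start + 1L - extend),
                       end = tt$end + extend))
    ## tissue contigs may be disjoint from ours; that is a legitimate empty
    hit <- suppressWarnings(IRanges::overlapsAny(own, ext))
    peaks$peak_id[hit & conn > min_connections]
  })
  empty <- names(sets)[lengths(sets) == 0L]
  keep <- setdiff(names(sets), empty)
  if (length(empty)) {
    message(sprintf("tissue_peakset_enrichment: empty feature set for %s",
                    paste(empty, collapse = ", ")))
  }
  z <- NULL
  if (length(keep)) {
    ann <- Matrix::sparseMatrix(
      i = unlist(lapply(keep, function(k) match(sets[[k]], peaks$peak_id))),
      j = rep(seq_along(keep), lengths(sets[keep])),
      x = 1, dims = c(nrow(peaks), length(keep)),
      dimnames = list(peaks$peak_id, keep))
    z <- compute_deviations(atac, ann, bg)$z
  }
  list(z = z, feature_sets = sets, empty = empty)
}
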