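## Standard-format readers and writers. All genomic coordinates on disk are
## 0-based half-open (BED convention); in-memory tables use the same
## convention so files round-trip unchanged.

#' Write and read the peak table as BED3+id+gc
#'
#' Tab-separated, no header: chrom, start, end, peak_id, gc.
#'
#' @param peaks peak table.
#' @param path file path.
#' @return `read_peaks_bed` returns the peak table.
#' @export
write_peaks_bed <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end", "peak_id", "gc")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "peak_id", "gc"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric"))
  validate_bed_intervals(df, path)
  if (anyDuplicated(df$peak_id)) stopf("%s: duplicate peak ids", path)
  if (any(df$gc < 0 | df$gc > 1)) stopf("%s: gc outside [0, 1]", path)
  df
}

validate_bed_intervals <- function(df, path) {
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    stopf("%s: invalid interval at line %d (start=%s, end=%s)",
          path, bad[1], df$start[bad[1]], df$end[bad[1]])
  }
  invisible(df)
}

#' Write and read simple BED intervals with an optional name column
#'
#' Tab-separated BED3 or BED4 (chrom, start, end\[, name\]), no header.
#'
#' @param df data.frame with chrom, start, end and optionally `name`.
#' @param path file path.
#' @return `read_bed` returns a data.frame (chrom, start, end\[, name\]).
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), colnames(df))
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stopf("%s: BED needs >= 3 columns", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  validate_bed_intervals(df, path)
  df[, intersect(c("chrom", "start", "end", "name"), names(df)), drop = FALSE]
}

#' Write and read a peak-by-motif annotation as a motif-hit BED
#'
#' One row per (peak, motif) hit: chrom, start, end, peak_id, motif_id.
#'
#' @param motifs sparse binary peaks x motifs matrix with dimnames.
#' @param peaks peak table (row order defines coordinates).
#' @param path file path.
#' @return `read_motif_hits` returns the sparse annotation matrix, with rows
#'   following `peaks`.
#' @export
write_motif_hits <- function(motifs, peaks, path) {
  tri <- Matrix::summary(methods::as(motifs, "CsparseMatrix") * 1)
  df <- data.frame(chrom = peaks$chrom[tri$i], start = peaks$start[tri$i],
                   end = peaks$end[tri$i], peak_id = peaks$peak_id[tri$i],
                   motif_id = colnames(motifs)[tri$j])
  df <- df[order(df$motif_id, df$peak_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_hits
#' @export
read_motif_hits <- function(path, peaks) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "peak_id",
                                 "motif_id"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "character"))
  validate_bed_intervals(df, path)
  pi <- match(df$peak_id, peaks$peak_id)
  if (anyNA(pi)) {
    stopf("%s: line %d references unknown peak %s", path,
          which(is.na(pi))[1], df$peak_id[which(is.na(pi))[1]])
  }
  motif_ids <- sort(unique(df$motif_id))
  Matrix::sparseMatrix(i = pi, j = match(df$motif_id, motif_ids), x = 1,
                       dims = c(nrow(peaks), length(motif_ids)),
                       dimnames = list(peaks$peak_id, motif_ids))
}

#' Write and read a sparse count matrix as MatrixMarket plus index files
#'
#' Writes `<prefix>.mtx` (features x cells, the conventional orientation),
#' `<prefix>.barcodes.tsv` and `<prefix>.features.tsv`.
#'
#' @param m sparse cells x features matrix with dimnames.
#' @param prefix path prefix.
#' @return `read_counts_mtx` returns the cells x features sparse matrix.
#' @export
write_counts_mtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".barcodes.tsv"))
  writeLines(colnames(m), paste0(prefix, ".features.tsv"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  barcodes <- readLines(paste0(prefix, ".barcodes.tsv"))
  features <- readLines(paste0(prefix, ".features.tsv"))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stopf("%s.mtx dimensions (%d x %d) do not match index files (%d features, %d barcodes)",
          prefix, nrow(m), ncol(m), length(features), length(barcodes))
  }
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(barcodes, features)
  m
}

#' Read and write gene sets in GMT format
#'
#' Reading delegates to `fgsea::gmtPathways`; writing emits the standard
#' tab-separated name, description, genes... lines.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write and read the cohort (expression plus outcomes) as CSV
#'
#' One row per patient: patient, time, event, complication, then one column
#' per gene.
#'
#' @param cohort a `reglink_cohort`.
#' @param path file path.
#' @return `read_cohort_csv` returns a `reglink_cohort` (without the latent
#'   field, which is simulation-only truth).
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cbind(cohort$clinical, as.data.frame(t(cohort$expression)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  assert_columns(df, c("patient", "time", "event", "complication"),
                 basename(path))
  gene_cols <- setdiff(colnames(df), c("patient", "time", "event",
                                       "complication"))
  if (any(df$time <= 0)) stopf("%s: non-positive follow-up time", path)
  expression <- t(as.matrix(df[, gene_cols, drop = FALSE]))
  colnames(expression) <- df$patient
  structure(list(expression = expression,
                 clinical = df[, c("patient", "time", "event",
                                   "complication")]),
            class = "reglink_cohort")
}

#' Write and read aggregate insertion tracks as CSV
#'
#' Long format: motif_id, offset, group, count, bias, n_sites.
#'
#' @param tracks list of `reglink_insertion_track`.
#' @param path file path.
#' @return `read_insertions_csv` returns a named list of tracks.
#' @export
write_insertions_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    do.call(rbind, lapply(colnames(tr$counts), function(g) {
      data.frame(motif_id = tr$motif_id, offset = tr$offsets, group = g,
                 count = tr$counts[, g], bias = tr$bias,
                 n_sites = tr$n_sites, stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_insertions_csv
#' @export
read_insertions_csv <- function(path) {
  df <- read.csv(path)
  assert_columns(df, c("motif_id", "offset", "group", "count", "bias",
                       "n_sites"), basename(path))
  lapply(split(df, df$motif_id), function(d) {
    offsets <- sort(unique(d$offset))
    groups <- unique(d$group)
    counts <- vapply(groups, function(g) {
      dd <- d[d$group == g, ]
      dd$count[order(dd$offset)]
    }, numeric(length(offsets)))
    dimnames(counts) <- list(NULL, groups)
    d1 <- d[d$group == groups[1], ]
    structure(list(motif_id = d$motif_id[1], offsets = offsets,
                   counts = counts, bias = d1$bias[order(d1$offset)],
                   n_sites = d$n_sites[1]),
              class = "reglink_insertion_track")
  })
}
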