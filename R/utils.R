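#' @importFrom methods as is
#' @importFrom stats rnorm rbeta rbinom rexp rpois rmultinom rnbinom rlnorm
#'   runif quantile median sd cor p.adjust pnorm phyper pchisq qexp setNames
#' @importFrom utils read.table write.table read.csv write.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, colnames(df))
  if (length(missing) > 0L) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

## half-up rounding to `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## derive a child seed from a parent seed and a stream label; keeps values
## below 2^31 so they remain valid R integer seeds
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

## GRanges helpers -----------------------------------------------------------

peaks_to_granges <- function(peaks) {
  assert_columns(peaks, c("chrom", "start", "end", "peak_id"), "peak table")
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  names(gr) <- peaks$peak_id
  gr
}

## width-1 ranges at interval midpoints (0-based half-open input)
peak_centers_granges <- function(peaks) {
  ctr <- floor((peaks$start + peaks$end) / 2)
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = ctr + 1L, width = 1L)
  )
  names(gr) <- peaks$peak_id
  gr
}

genes_to_body_granges <- function(genes) {
  assert_columns(genes, c("gene_id", "chrom", "body_start", "body_end"),
                 "gene table")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$body_start + 1L,
                              end = genes$body_end),
    strand = genes$strand
  )
  names(gr) <- genes$gene_id
  gr
}
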