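#' Sliding-window tiling of chromosomes
#'
#' Windows start at position 1 and advance by `step` until the chromosome
#' end; a terminal window extending past the end is truncated. Coordinates
#' are 1-based inclusive.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp
#' @param window nominal window size in bp
#' @param step step size in bp
#' @return data frame with `chrom`, `start`, `end`, `span`
#' @export
tile_windows <- function(chrom_lengths, window, step) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (window < step) stop("window must be >= step")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(1L, max(1L, L - step + 1L), by = step)
    starts <- starts[starts <= L]
    ends <- pmin(starts + window - 1L, L)
    data.frame(chrom = ch, start = starts, end = ends,
               span = ends - starts + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chromosome lengths implied by a locus table
#'
#' @param loci locus data frame
#' @param chrom_lengths optional known lengths; when `NULL`, the maximum
#'   observed position per chromosome is used.
#' @return named numeric vector
#' @export
infer_chrom_lengths <- function(loci, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
    return(chrom_lengths)
  }
  tapply(loci$pos, loci$chrom, max)
}

# Index loci into windows: returns a list of integer locus-index vectors,
# one per row of the window table.
window_locus_index <- function(loci, windows) {
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$pos, loci$pos))
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  ov <- GenomicRanges::findOverlaps(wg, lg)
  split(S4Vectors::subjectHits(ov),
        factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(windows))))
}
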