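# The two window systems of the scan: genomic windows holding a fixed
# amount of non-repetitive sequence (for depth of coverage), and sliding
# windows holding a fixed number of variant sites (for the frequency scan).

#' Segment a chromosome into windows of fixed non-repetitive content
#'
#' Tiles a chromosome with non-overlapping windows of variable genomic span
#' such that each window contains exactly \code{W} bp of non-repetitive
#' (unmasked) sequence.  A window closes at the base where its running
#' unmasked total reaches \code{W}; trailing masked bases attach to the
#' next window.  A final remainder window (flagged \code{partial}) is
#' emitted iff it contains unmasked sequence; it absorbs any trailing
#' masked bases so that the emitted windows tile the chromosome.
#'
#' @param chromLen Chromosome length in bp.
#' @param mask Repeat mask for this chromosome: a \code{GRanges} or
#'   \code{IRanges} of masked intervals (1-based closed), sorted or not.
#' @param W Target non-repetitive content per window in bp (default 1e5).
#' @param chrom Chromosome name for the output ranges.
#' @return A \code{GRanges} with metadata columns \code{nonrepBp} and
#'   \code{partial}; zero-length for a fully masked chromosome.
#' @examples
#' library(GenomicRanges)
#' segmentByNonrepetitive(3e5, GRanges("chr", IRanges(1, 150000)), W = 1e5,
#'                        chrom = "chr")
#' @export
segmentByNonrepetitive <- function(chromLen, mask, W = 1e5, chrom = "chr") {
  if (W <= 0) stop("W must be positive")
  if (is(mask, "GRanges")) {
    unm <- .unmaskedRanges(mask, chrom, chromLen)
  } else {
    gr <- GenomicRanges::GRanges(chrom, mask)
    unm <- .unmaskedRanges(gr, chrom, chromLen)
  }
  if (length(unm) == 0L)
    return(GenomicRanges::GRanges(nonrepBp = numeric(0),
                                  partial = logical(0)))
  s <- GenomicRanges::start(unm)
  e <- GenomicRanges::end(unm)
  winStart <- 1
  acc <- 0
  out <- list()
  for (i in seq_along(s)) {
    si <- s[i]
    len <- e[i] - si + 1
    while (acc + len >= W) {
      need <- W - acc
      cut <- si + need - 1
      out[[length(out) + 1L]] <- c(winStart, cut, W)
      winStart <- cut + 1
      si <- cut + 1
      len <- e[i] - si + 1
      acc <- 0
      if (len <= 0) break
    }
    acc <- acc + max(len, 0)
  }
  if (acc > 0) {
    out[[length(out) + 1L]] <- c(winStart, chromLen, acc)
  } else if (length(out)) {
    # trailing fully masked tail: attach to the last emitted window
    out[[length(out)]][2] <- chromLen
  }
  m <- do.call(rbind, out)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                         nonrepBp = m[, 3], partial = m[, 3] < W)
}

#' Sliding windows of a fixed number of variant sites
#'
#' Groups sorted variant sites into overlapping windows of \code{nSites}
#' sites advancing by \code{step} sites, so consecutive windows share
#' \code{nSites - step} sites.  Windows are emitted until one reaches the
#' last site; that terminal window may hold fewer than \code{nSites} sites
#' (short chromosomes yield a single window of all sites).  The genomic
#' span of a window runs from its first to its last site.
#'
#' @param positions Sorted site positions (bp) on one chromosome.
#' @param nSites Sites per window (default 500).
#' @param step Advance in sites between window starts (default 250).
#' @return A data.frame with one row per window: \code{firstSite},
#'   \code{lastSite} (1-based site indices), \code{n}, \code{start},
#'   \code{end} (bp span).
#' @export
slidingVariantWindows <- function(positions, nSites = 500L, step = 250L) {
  if (nSites < step) stop("nSites must be >= step")
  nTot <- length(positions)
  if (nTot == 0L) {
    return(data.frame(firstSite = integer(0), lastSite = integer(0),
                      n = integer(0), start = numeric(0), end = numeric(0)))
  }
  if (is.unsorted(positions)) stop("positions must be sorted")
  first <- integer(0)
  sIdx <- 1L
  repeat {
    first <- c(first, sIdx)
    if (sIdx + nSites - 1L >= nTot) break
    sIdx <- sIdx + step
    if (sIdx > nTot) break
  }
  last <- pmin(first + nSites - 1L, nTot)
  data.frame(firstSite = first, lastSite = last, n = last - first + 1L,
             start = positions[first], end = positions[last])
}
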