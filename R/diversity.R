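# Windowed nucleotide diversity and introgression-block flagging.

#' Nucleotide diversity of a genomic window
#'
#' Unbiased per-site heterozygosity summed over the window's variant sites
#' and divided by the window's non-repetitive content: for site j with
#' n_j called allele copies and sample alternative-allele frequency p_j,
#' the contribution is (n_j / (n_j - 1)) * 2 p_j (1 - p_j).  Missing
#' genotypes reduce n_j; sites with fewer than two called copies
#' contribute nothing.  Monomorphic windows give 0; the estimator is
#' invariant under swapping reference and alternative allele labels.
#'
#' @param genotypes Sites x accessions matrix of diploid genotypes coded
#'   0/1/2 with \code{NA} for missing.
#' @param nonrepBp Non-repetitive bp of the window (the denominator).
#' @return List with \code{pi} (per-bp diversity) and \code{missing}
#'   (\code{TRUE} when no site in the window was callable).
#' @examples
#' windowPi(matrix(c(1, 1), nrow = 1), nonrepBp = 1e5)$pi  # 6.67e-06
#' @export
windowPi <- function(genotypes, nonrepBp) {
  if (nonrepBp <= 0) stop("nonrepBp must be positive")
  if (is.null(dim(genotypes)))
    genotypes <- matrix(genotypes, nrow = 1L)
  if (nrow(genotypes) == 0L) return(list(pi = 0, missing = FALSE))
  called <- !is.na(genotypes)
  nj <- 2 * rowSums(called)
  altj <- rowSums(genotypes, na.rm = TRUE)
  ok <- nj >= 2
  if (!any(ok)) return(list(pi = 0, missing = TRUE))
  p <- altj[ok] / nj[ok]
  h <- (nj[ok] / (nj[ok] - 1)) * 2 * p * (1 - p)
  list(pi = sum(h) / nonrepBp, missing = FALSE)
}

#' Per-window, per-accession SNP counts and panel diversity
#'
#' Assigns panel variant sites to genomic windows and tabulates, per
#' accession, the number of heterozygous and homozygous-alternative calls
#' per window, together with the panel nucleotide diversity of each
#' window.
#'
#' @param sites \code{GRanges} of panel variant sites (rows of
#'   \code{genotypes}).
#' @param genotypes Sites x accessions matrix, 0/1/2/\code{NA}.
#' @param windows Genomic windows (\code{GRanges} with \code{nonrepBp}).
#' @return List with \code{counts} (windows x accessions matrix of
#'   non-reference calls), \code{hetCounts}, \code{homCounts},
#'   \code{pi} (numeric per window), \code{windows}.
#' @export
diversityWindows <- function(sites, genotypes, windows) {
  nW <- length(windows)
  nA <- ncol(genotypes)
  counts <- matrix(0L, nW, nA,
                   dimnames = list(NULL, colnames(genotypes)))
  hetC <- counts
  homC <- counts
  pi <- numeric(nW)
  ov <- GenomicRanges::findOverlaps(sites, windows, ignore.strand = TRUE)
  byWin <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  nonrep <- GenomicRanges::mcols(windows)$nonrepBp
  for (w in names(byWin)) {
    wi <- as.integer(w)
    g <- genotypes[byWin[[w]], , drop = FALSE]
    hetC[wi, ] <- colSums(g == 1L, na.rm = TRUE)
    homC[wi, ] <- colSums(g == 2L, na.rm = TRUE)
    counts[wi, ] <- hetC[wi, ] + homC[wi, ]
    pi[wi] <- windowPi(g, nonrep[wi])$pi
  }
  list(counts = counts, hetCounts = hetC, homCounts = homC, pi = pi,
       windows = windows)
}

#' Flag windows with introgression-level SNP counts
#'
#' A window is flagged for an accession when its SNP count exceeds a
#' threshold derived from the baseline accessions' per-window count
#' distribution: median + k * MAD (k = 10 by default), with an absolute
#' floor of \code{floor} SNPs so that a degenerate all-zero baseline does
#' not flag singletons.  Zygosity of a flagged window is the dominant
#' genotype class among the accession's SNPs in that window.
#'
#' @param div Output of \code{\link{diversityWindows}}.
#' @param baseline Accession ids (or column indices) forming the bona fide
#'   low-diversity baseline.
#' @param k MAD multiplier (default 10).
#' @param floor Minimum threshold in SNPs (default 5).
#' @return List with \code{flags} (windows x accessions logical),
#'   \code{zygosity} (character matrix, \code{NA} where unflagged), and
#'   \code{threshold}.
#' @export
flagIntrogressedWindows <- function(div, baseline, k = 10, floor = 5) {
  counts <- div$counts
  if (is.character(baseline)) baseline <- match(baseline, colnames(counts))
  base <- as.vector(counts[, baseline, drop = FALSE])
  thr <- max(stats::median(base) + k * stats::mad(base), floor)
  flags <- counts > thr
  zyg <- matrix(NA_character_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  het <- div$hetCounts
  hom <- div$homCounts
  zyg[flags] <- ifelse(het[flags] >= hom[flags], "heterozygous",
                       "homozygous")
  list(flags = flags, zygosity = zyg, threshold = thr, counts = counts)
}

#' Merge flagged windows into introgression blocks
#'
#' Consecutive flagged windows of one accession merge into a block,
#' tolerating up to \code{gapTol} unflagged windows inside a run; the
#' block spans from the first to the last flagged window.
#'
#' @param flagged Output of \code{\link{flagIntrogressedWindows}}.
#' @param windows The genomic windows the flags refer to (\code{GRanges}).
#' @param accession Accession id (or column index) to merge.
#' @param gapTol Unflagged windows tolerated inside a block (default 1).
#' @return \code{GRanges} of blocks with \code{accession},
#'   \code{zygosity} (majority class), \code{meanCount} and
#'   \code{nWindows}; empty if nothing is flagged.
#' @export
mergeBlocks <- function(flagged, windows, accession, gapTol = 1L) {
  if (is.character(accession))
    accCol <- match(accession, colnames(flagged$flags))
  else accCol <- accession
  accId <- colnames(flagged$flags)[accCol] %||% as.character(accession)
  f <- flagged$flags[, accCol]
  empty <- GenomicRanges::GRanges()
  GenomicRanges::mcols(empty) <- S4Vectors::DataFrame(
    accession = character(0), zygosity = character(0),
    meanCount = numeric(0), nWindows = integer(0))
  idx <- which(f)
  if (!length(idx)) return(empty)
  chrom <- as.character(GenomicRanges::seqnames(windows))
  runs <- split(idx, cumsum(c(1, diff(idx) > gapTol + 1L |
                                   chrom[idx][-1] != chrom[idx][-length(idx)])))
  out <- lapply(runs, function(run) {
    data.frame(
      chrom = chrom[run[1]],
      start = min(GenomicRanges::start(windows)[run]),
      end = max(GenomicRanges::end(windows)[run]),
      zygosity = names(which.max(table(flagged$zygosity[run, accCol]))),
      meanCount = mean(flagged$counts[run, accCol]),
      nWindows = length(run), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         accession = accId, zygosity = df$zygosity,
                         meanCount = df$meanCount, nWindows = df$nWindows)
}
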