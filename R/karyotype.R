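# Karyotype scan core: homoeologous frequency and ROH_H chi-square scan
# over sliding variant windows, per-homoeolog depth-of-coverage ratios over
# genomic windows, integer copy-state fitting with mosaic mixtures, and
# event segmentation/classification.

#' Derive a homoeologous-site catalog from a euploid reference accession
#'
#' Given per-site allele depths of an accession assumed euploid (2,2),
#' retains candidate sites whose observed reference-subgenome allele
#' fraction lies in a band around the balanced expectation 0.5 at
#' sufficient depth.  This reconstructs a usable diagnostic-site catalog
#' when one is not provided with the reference.
#'
#' @param siteDepth data.frame with columns \code{chrom}, \code{pos},
#'   \code{refCount}, \code{altCount} for the reference accession.
#' @param candidates \code{GRanges} of candidate catalog sites.
#' @param band Retained fraction band (default \code{c(0.35, 0.65)}).
#' @param minDepth Minimum site depth (default 10).
#' @return The subset of \code{candidates} passing the filter.
#' @export
deriveHomoeologousCatalog <- function(siteDepth, candidates,
                                      band = c(0.35, 0.65), minDepth = 10) {
  if (nrow(siteDepth) == 0L) return(candidates[0])
  depth <- siteDepth$refCount + siteDepth$altCount
  frac <- ifelse(depth > 0, siteDepth$refCount / depth, NA_real_)
  keep <- !is.na(frac) & depth >= minDepth &
    frac >= band[1] & frac <= band[2]
  keyPass <- paste(siteDepth$chrom, siteDepth$pos)[keep]
  keyCand <- paste(as.character(GenomicRanges::seqnames(candidates)),
                   GenomicRanges::start(candidates))
  candidates[keyCand %in% keyPass]
}

#' Depth-weighted homoeologous variant frequency of a window
#'
#' The fraction of reads supporting the referenced subgenome's allele,
#' pooled over all sites of a window: sum(ref) / sum(ref + alt).  Balanced
#' 2:2 copy number gives 0.5; a 3:1 interval gives 0.75.
#'
#' @param refCount,altCount Per-site allele depths within the window.
#' @return A number in [0, 1], or \code{NA} if total depth is zero (the
#'   window is then flagged missing by the scan).
#' @export
homoeologousFrequency <- function(refCount, altCount) {
  tot <- sum(refCount) + sum(altCount)
  if (length(refCount) == 0L || tot == 0) return(NA_real_)
  sum(refCount) / tot
}

#' ROH_H chi-square scan statistic of a window
#'
#' Measures the deviation of per-site allele depths from the balanced
#' expectation (reference-subgenome allele fraction 0.5 under 2:2 copy
#' number): for each site with reads, (a - b)^2 / (a + b) is the one
#' degree-of-freedom chi-square against p = 0.5; the window statistic is
#' their sum, with degrees of freedom equal to the number of contributing
#' sites.  Significance is taken from the chi-square upper tail, Bonferroni
#' corrected over windows by the scan driver.
#'
#' @param refCount,altCount Per-site allele depths within the window.
#' @return List with \code{chi2}, \code{df} (sites with depth > 0), and
#'   \code{p} (upper-tail probability; \code{NA} for an empty window).
#' @examples
#' rohHStatistic(30, 10)  # chi2 = 10, df = 1
#' @export
rohHStatistic <- function(refCount, altCount) {
  depth <- refCount + altCount
  use <- depth > 0
  if (!any(use)) return(list(chi2 = NA_real_, df = 0L, p = NA_real_))
  a <- refCount[use]
  b <- altCount[use]
  chi2 <- sum((a - b)^2 / (a + b))
  df <- sum(use)
  list(chi2 = chi2, df = as.integer(df),
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Per-window depth-of-coverage ratio relative to a reference accession
#'
#' For each subgenome, the window coverage of the test accession divided
#' by its genome-wide median, over the same quantity in the euploid
#' reference accession (a double ratio).  The median normalization makes
#' the statistic robust to the aberrations being detected and to library
#' size.  A balanced window has doc = 1; a trisomic homoeolog 1.5; a lost
#' homoeolog 0.  Windows with zero reference coverage are flagged missing.
#'
#' @param coverage,refCoverage data.frames with columns \code{chrom},
#'   \code{start}, \code{end}, \code{covA}, \code{covB} over the same
#'   window set (matched by chrom/start/end).
#' @return \code{coverage} with added columns \code{docA}, \code{docB}.
#' @export
docRatio <- function(coverage, refCoverage) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  idx <- match(key(coverage), key(refCoverage))
  if (anyNA(idx)) stop("accessions must share the window set")
  rc <- refCoverage[idx, , drop = FALSE]
  medA <- stats::median(coverage$covA)
  medB <- stats::median(coverage$covB)
  medAr <- stats::median(rc$covA)
  medBr <- stats::median(rc$covB)
  if (medA <= 0 || medB <= 0 || medAr <= 0 || medBr <= 0)
    stop("zero genome-wide median coverage")
  docA <- (coverage$covA / medA) / (rc$covA / medAr)
  docB <- (coverage$covB / medB) / (rc$covB / medBr)
  docA[rc$covA <= 0] <- NA_real_
  docB[rc$covB <= 0] <- NA_real_
  out <- coverage
  out$docA <- docA
  out$docB <- docB
  out
}

# Residual of observations against a (possibly mosaic) state.
.stateResidual <- function(fBar, docA, docB, cA, cB, m = 1,
                           weights = c(f = 1, d = 1)) {
  effA <- m * cA + (1 - m) * 2
  effB <- m * cB + (1 - m) * 2
  tot <- effA + effB
  r <- 0
  if (!is.na(fBar) && tot > 0)
    r <- r + weights[["f"]] * (fBar - effA / tot)^2
  if (!is.na(docA)) r <- r + weights[["d"]] * (docA - effA / 2)^2
  if (!is.na(docB)) r <- r + weights[["d"]] * (docB - effB / 2)^2
  r
}

#' Fit an integer homoeolog copy state to window observables
#'
#' Exhaustive search over the integer copy-state grid (per-homoeolog
#' copies 0..4, total 0..5) minimizing the weighted squared residual
#' between the observed (frequency, docA, docB) triple and each state's
#' expectations; ties break toward the state closest to balanced (2,2) in
#' L1 copy distance (parsimony).  A one-dimensional mosaic fit then mixes
#' each non-euploid state with (2,2); the mosaic is reported instead of
#' the pure state when it reduces the residual by more than
#' \code{mosaicImprovement}, the estimated mixture fraction lies strictly
#' inside \code{mosaicRange}, and the best pure residual exceeds
#' \code{mosaicMinResidual} (pure states fit nearly exactly, so without
#' the floor, sampling noise alone could promote them to equivalent
#' mosaic mixtures).
#'
#' @param fBar Depth-weighted reference-subgenome allele fraction
#'   (\code{NA} if missing).
#' @param docA,docB Normalized depth ratios of the two homoeologs.
#' @param weights Named weights \code{c(f = , d = )} on the frequency and
#'   depth terms (default 1:1 on their natural scales).
#' @param mosaicImprovement Residual-reduction factor required to report a
#'   mosaic (default 0.25).
#' @param mosaicRange Open interval for an admissible mixture fraction.
#' @param mosaicMinResidual Absolute pure-residual floor below which the
#'   mosaic fit is not attempted.
#' @return List with \code{state} (a \code{\link{copyState}}; \code{m < 1}
#'   iff mosaic), \code{residual}, and \code{mosaic} (logical).  All
#'   observations missing yields \code{NULL}.
#' @examples
#' fitCopyState(0.75, 1.5, 0.5)$state    # (3,1) heterozygous exchange
#' fitCopyState(0.625, 1.25, 0.75)       # mosaic (3,1), m = 0.5
#' @export
fitCopyState <- function(fBar, docA, docB, weights = c(f = 1, d = 1),
                         mosaicImprovement = 0.25,
                         mosaicRange = c(0.15, 0.85),
                         mosaicMinResidual = 0.01) {
  if (is.na(fBar) && is.na(docA) && is.na(docB)) return(NULL)
  grid <- .stateGrid()
  res <- vapply(seq_len(nrow(grid)), function(i) {
    .stateResidual(fBar, docA, docB, grid$cRef[i], grid$cOther[i],
                   weights = weights)
  }, numeric(1))
  l1 <- abs(grid$cRef - 2L) + abs(grid$cOther - 2L)
  o <- order(res, l1)
  best <- o[1]
  bestRes <- res[best]
  out <- list(state = copyState(grid$cRef[best], grid$cOther[best], m = 1),
              residual = bestRes, mosaic = FALSE)
  if (bestRes <= mosaicMinResidual) return(out)
  aberrant <- grid[!(grid$cRef == 2L & grid$cOther == 2L), , drop = FALSE]
  mixBest <- NULL
  for (i in seq_len(nrow(aberrant))) {
    cA <- aberrant$cRef[i]
    cB <- aberrant$cOther[i]
    opt <- stats::optimize(function(m) {
      .stateResidual(fBar, docA, docB, cA, cB, m = m, weights = weights)
    }, interval = c(0, 1), tol = 1e-6)
    l1i <- abs(cA - 2L) + abs(cB - 2L)
    # mixture families can coincide exactly (a (4,0) mixture at m/2 equals
    # a (3,1) mixture at m), so ties break toward the aberrant state
    # closest to balanced
    tol <- 1e-6 * (1 + abs(opt$objective))
    if (is.null(mixBest) || opt$objective < mixBest$residual - tol ||
        (opt$objective < mixBest$residual + tol && l1i < mixBest$l1)) {
      mixBest <- list(cA = cA, cB = cB, m = opt$minimum,
                      residual = opt$objective, l1 = l1i)
    }
  }
  if (!is.null(mixBest) &&
      mixBest$residual < mosaicImprovement * bestRes &&
      mixBest$m > mosaicRange[1] && mixBest$m < mosaicRange[2]) {
    out <- list(state = copyState(mixBest$cA, mixBest$cB, m = mixBest$m),
                residual = mixBest$residual, mosaic = TRUE)
  }
  out
}

# Overlap-weighted mean doc over a genomic interval, from per-genomic-
# window doc values.
.intervalDoc <- function(doc, chrom, start, end) {
  sel <- doc$chrom == chrom & doc$end >= start & doc$start <= end
  if (!any(sel)) return(c(NA_real_, NA_real_))
  d <- doc[sel, , drop = FALSE]
  w <- pmin(d$end, end) - pmax(d$start, start) + 1
  c(stats::weighted.mean(d$docA, w, na.rm = TRUE),
    stats::weighted.mean(d$docB, w, na.rm = TRUE))
}

#' Compute per-window karyotype observations for one accession
#'
#' Runs the sliding-variant-window scan: for each window of
#' \code{nSites} homoeologous sites (step \code{step}), computes the
#' depth-weighted homoeologous variant frequency, the ROH_H chi-square
#' statistic, and the overlap-weighted depth-of-coverage ratios of the two
#' homoeologs interpolated from the genomic-window doc table.
#'
#' @param siteDepth Accession site-depth data.frame (\code{chrom},
#'   \code{pos}, \code{refCount}, \code{altCount}) at catalog sites.
#' @param doc Output of \code{\link{docRatio}} for this accession.
#' @param nSites,step Sliding-window geometry (defaults 500/250).
#' @return data.frame of per-window observations: \code{chrom},
#'   \code{start}, \code{end}, \code{nSites}, \code{fBar}, \code{chi2},
#'   \code{df}, \code{p}, \code{docA}, \code{docB}.
#' @export
windowObservations <- function(siteDepth, doc, nSites = 500L, step = 250L) {
  out <- list()
  for (chrom in unique(siteDepth$chrom)) {
    sd <- siteDepth[siteDepth$chrom == chrom, , drop = FALSE]
    sd <- sd[order(sd$pos), , drop = FALSE]
    win <- slidingVariantWindows(sd$pos, nSites = nSites, step = step)
    if (nrow(win) == 0L) next
    for (i in seq_len(nrow(win))) {
      idx <- win$firstSite[i]:win$lastSite[i]
      a <- sd$refCount[idx]
      b <- sd$altCount[idx]
      st <- rohHStatistic(a, b)
      dv <- .intervalDoc(doc, chrom, win$start[i], win$end[i])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = win$start[i], end = win$end[i],
        nSites = win$n[i], fBar = homoeologousFrequency(a, b),
        chi2 = st$chi2, df = st$df, p = st$p, docA = dv[1], docB = dv[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), nSites = integer(0),
                      fBar = numeric(0), chi2 = numeric(0), df = integer(0),
                      p = numeric(0), docA = numeric(0), docB = numeric(0)))
  }
  do.call(rbind, out)
}

.eventType <- function(cRef, cOther, wholeChrom) {
  tot <- cRef + cOther
  if (wholeChrom && tot != 4L) {
    if (tot > 4L) return("aneuploidy_gain") else return("aneuploidy_loss")
  }
  if (tot == 4L) return("homoeologous_exchange")
  if (tot < 4L) return("deletion")
  "duplication"
}

#' Segment flagged windows into classified karyotype events
#'
#' Flags windows whose ROH_H statistic is significant after Bonferroni
#' correction over all windows of the genome (at \code{alpha}) or whose
#' doc departs from 1 by more than \code{docTol}; fits a copy state to
#' every flagged window; merges consecutive flagged windows sharing the
#' same fitted state (allowing \code{gapTol} unflagged windows in
#' between); drops events shorter than \code{minEventSize}; reclassifies
#' events spanning at least \code{aneuploidySpan} of the chromosome's
#' scannable extent as whole-chromosome aneuploidy.  Zygosity follows the
#' fitted state (one copy away from balanced: heterozygous; two or more:
#' homozygous; mosaic fits propagate as mosaic with the mean fitted m).
#'
#' @param obs Per-window observations from \code{\link{windowObservations}}.
#' @param accession Accession id stored on the events.
#' @param alpha Genome-wide significance level for the chi-square flag.
#' @param docTol Flagging tolerance for |doc - 1|.
#' @param minEventSize Minimum event span in bp (default 2e5).
#' @param gapTol Unflagged windows tolerated inside a run (default 1).
#' @param aneuploidySpan Fraction of the chromosome's scanned extent above
#'   which an event is a whole-chromosome aneuploidy (default 0.95).
#' @param weights,mosaicImprovement,mosaicRange,mosaicMinResidual Passed
#'   to \code{\link{fitCopyState}}.
#' @return \code{GRanges} of events with metadata columns
#'   \code{accession}, \code{type}, \code{zygosity}, \code{cRef},
#'   \code{cOther}, \code{m}, \code{residual}, \code{nWindows},
#'   \code{meanChi2PerSite}.
#' @export
segmentEvents <- function(obs, accession = "accession", alpha = 0.05,
                          docTol = 0.25, minEventSize = 2e5, gapTol = 1L,
                          aneuploidySpan = 0.95,
                          weights = c(f = 1, d = 1),
                          mosaicImprovement = 0.25,
                          mosaicRange = c(0.15, 0.85),
                          mosaicMinResidual = 0.01) {
  empty <- GenomicRanges::GRanges()
  GenomicRanges::mcols(empty) <- S4Vectors::DataFrame(
    accession = character(0), type = character(0), zygosity = character(0),
    cRef = integer(0), cOther = integer(0), m = numeric(0),
    residual = numeric(0), nWindows = integer(0),
    meanChi2PerSite = numeric(0))
  if (nrow(obs) == 0L) return(empty)
  nWin <- sum(!is.na(obs$p))
  flagChi <- !is.na(obs$p) & obs$p < alpha / max(nWin, 1L)
  flagDoc <- (!is.na(obs$docA) & abs(obs$docA - 1) > docTol) |
    (!is.na(obs$docB) & abs(obs$docB - 1) > docTol)
  obs$flagged <- flagChi | flagDoc
  fits <- vector("list", nrow(obs))
  key <- rep(NA_character_, nrow(obs))
  for (i in which(obs$flagged)) {
    ft <- fitCopyState(obs$fBar[i], obs$docA[i], obs$docB[i],
                       weights = weights,
                       mosaicImprovement = mosaicImprovement,
                       mosaicRange = mosaicRange,
                       mosaicMinResidual = mosaicMinResidual)
    if (is.null(ft)) next
    st <- ft$state
    if (st@cRef == 2L && st@cOther == 2L && !ft$mosaic) next  # euploid fit
    fits[[i]] <- ft
    # runs merge on the fitted copy state; the mosaic flag is zygosity,
    # not state (event-boundary windows fit partial mixtures of the same
    # state and must not split the run)
    key[i] <- sprintf("%d:%d", st@cRef, st@cOther)
  }
  events <- list()
  for (chrom in unique(obs$chrom)) {
    ci <- which(obs$chrom == chrom)
    scanStart <- min(obs$start[ci])
    scanEnd <- max(obs$end[ci])
    usable <- ci[!is.na(key[ci])]
    if (!length(usable)) next
    # group consecutive usable windows with the same state key, tolerating
    # up to gapTol intervening windows
    runs <- split(usable,
                  cumsum(c(1, diff(usable) > gapTol + 1L |
                               key[usable][-1] != key[usable][-length(usable)])))
    # windows straddling an event edge see a diluted signal and can fit a
    # different (intermediate) state, producing a short run hugging the
    # true event; such runs are absorbed by (dropped in favor of) an
    # adjacent longer run
    if (length(runs) > 1L) {
      ord <- order(-vapply(runs, length, integer(1)),
                   vapply(runs, min, integer(1)))
      accepted <- list()
      for (ri in ord) {
        run <- runs[[ri]]
        adjacent <- any(vapply(accepted, function(a) {
          min(abs(min(run) - max(a)), abs(min(a) - max(run))) <= gapTol + 1L
        }, logical(1)))
        if (!adjacent) accepted[[length(accepted) + 1L]] <- run
      }
      runs <- accepted[order(vapply(accepted, min, integer(1)))]
    }
    for (run in runs) {
      start <- min(obs$start[run])
      end <- max(obs$end[run])
      if (end - start + 1 < minEventSize) next
      ft1 <- fits[[run[1]]]
      cA <- ft1$state@cRef
      cB <- ft1$state@cOther
      isMosaic <- vapply(fits[run], `[[`, logical(1), "mosaic")
      mosaic <- mean(isMosaic) > 0.5
      mHat <- if (mosaic)
        mean(vapply(fits[run][isMosaic], function(f) f$state@m, numeric(1)))
      else 1
      whole <- (end - start + 1) >= aneuploidySpan * (scanEnd - scanStart + 1)
      type <- .eventType(cA, cB, whole)
      zyg <- if (mosaic) "mosaic" else .zygosityOf(cA, cB)
      events[[length(events) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end,
        accession = accession, type = type, zygosity = zyg,
        cRef = cA, cOther = cB, m = mHat,
        residual = mean(vapply(fits[run], `[[`, numeric(1), "residual")),
        nWindows = length(run),
        meanChi2PerSite = mean(obs$chi2[run] / pmax(obs$df[run], 1L)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(empty)
  ev <- do.call(rbind, events)
  GenomicRanges::GRanges(
    ev$chrom, IRanges::IRanges(ev$start, ev$end),
    accession = ev$accession, type = ev$type, zygosity = ev$zygosity,
    cRef = ev$cRef, cOther = ev$cOther, m = ev$m, residual = ev$residual,
    nWindows = ev$nWindows, meanChi2PerSite = ev$meanChi2PerSite)
}

#' Run the full karyotype scan for one accession
#'
#' Convenience driver chaining \code{\link{docRatio}},
#' \code{\link{windowObservations}} and \code{\link{segmentEvents}}.
#'
#' @param siteDepth,coverage Accession observables (site-depth and
#'   per-window coverage tables).
#' @param refCoverage Per-window coverage of the euploid reference
#'   accession.
#' @param nSites,step Sliding-window geometry.
#' @param ... Passed to \code{\link{segmentEvents}}.
#' @return List with \code{observations} (data.frame) and \code{events}
#'   (\code{GRanges}).
#' @export
karyotypeScan <- function(siteDepth, coverage, refCoverage,
                          nSites = 500L, step = 250L, ...) {
  doc <- docRatio(coverage, refCoverage)
  obs <- windowObservations(siteDepth, doc, nSites = nSites, step = step)
  events <- segmentEvents(obs, ...)
  list(observations = obs, events = events, doc = doc)
}
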