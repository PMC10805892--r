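# Synthetic allotetraploid generator.
#
# Emulates the observables of a resequenced allotetraploid panel: two
# homoeologous subgenomes with diagnostic sites at ~divergence density on
# the unmasked genome, injected karyotype aberrations with ground-truth
# bookkeeping, Poisson/binomial read-depth sampling at homoeologous sites,
# per-window unique-mapping coverage per subgenome, and a low-diversity
# variant panel with optional high-diversity introgressed blocks.

# Alternating-run repeat mask for one chromosome region profile.  Runs are
# exponential with a 10 kb masked+unmasked cycle, giving interval sizes in
# the range of plant TE clusters.
.simulateMask <- function(chromLen, fracProfile, cycle = 1e4) {
  k <- length(fracProfile)
  bounds <- round(seq(0, chromLen, length.out = k + 1))
  ivs <- list()
  for (r in seq_len(k)) {
    frac <- fracProfile[r]
    lo <- bounds[r] + 1
    hi <- bounds[r + 1]
    if (hi < lo) next
    if (frac >= 1) {
      ivs[[length(ivs) + 1L]] <- c(lo, hi)
      next
    }
    if (frac <= 0) next
    pos <- lo
    repeat {
      gap <- ceiling(stats::rexp(1, rate = 1 / ((1 - frac) * cycle)))
      pos <- pos + gap
      if (pos > hi) break
      len <- ceiling(stats::rexp(1, rate = 1 / (frac * cycle)))
      ivs[[length(ivs) + 1L]] <- c(pos, min(pos + len - 1, hi))
      pos <- pos + len
      if (pos > hi) break
    }
  }
  if (!length(ivs)) return(IRanges::IRanges())
  m <- do.call(rbind, ivs)
  IRanges::reduce(IRanges::IRanges(m[, 1], m[, 2]))
}

#' Simulate a two-subgenome reference model
#'
#' Builds the coordinate universe of a synthetic allotetraploid: paired
#' homoeologous chromosomes of equal length, a random repeat mask following
#' the configured per-region masked-fraction profile, and a catalog of
#' homoeologous sites placed only at unmasked positions, each site present
#' independently with probability \code{siteDensity} (so the per-chromosome
#' site count is binomial).  Homoeologs of a pair share coordinates; the
#' two alleles at each site are distinct bases.
#'
#' @param params A \code{\link{simulationParams}} object.  Its seed fully
#'   determines the output.
#' @return A \code{\link{ReferenceModel-class}} object.
#' @examples
#' ref <- simulateReference(simulationParams(1, 1e6, seed = 3))
#' length(siteCatalog(ref))
#' @export
simulateReference <- function(params) {
  validObject(params)
  set.seed(params@seed)
  nP <- params@nChromosomePairs
  lens <- params@chromosomeLength
  chromA <- sprintf("chr%d_A", seq_len(nP))
  chromB <- sprintf("chr%d_B", seq_len(nP))
  pairs <- S4Vectors::DataFrame(pair = seq_len(nP), chromA = chromA,
                                chromB = chromB, length = lens)
  maskL <- list()
  catL <- list()
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(nP)) {
    ir <- .simulateMask(lens[p], params@repeatFraction)
    maskL[[p]] <- GenomicRanges::GRanges(rep(chromA[p], length(ir)), ir)
    unm <- .unmaskedRanges(maskL[[p]], chromA[p], lens[p])
    U <- sum(as.numeric(GenomicRanges::width(unm)))
    if (params@siteDensity > 0 && U >= 1) {
      n <- stats::rbinom(1L, size = as.integer(min(U, .Machine$integer.max)),
                         prob = params@siteDensity)
      if (n < 1L)
        stop("site density too low: fewer than one site on chromosome ",
             chromA[p])
      pos <- .samplePositions(unm, n)
      aA <- sample(bases, n, replace = TRUE)
      shift <- sample.int(3L, n, replace = TRUE)
      aB <- bases[((match(aA, bases) - 1L + shift) %% 4L) + 1L]
      catL[[p]] <- GenomicRanges::GRanges(
        chromA[p], IRanges::IRanges(pos, pos),
        pair = p, chromB = chromB[p], posB = pos, alleleA = aA, alleleB = aB)
    }
  }
  mask <- .combineGR(maskL)
  catalog <- .combineGR(catL)
  if (length(catalog) == 0L)
    GenomicRanges::mcols(catalog) <- S4Vectors::DataFrame(
      pair = integer(0), chromB = character(0), posB = integer(0),
      alleleA = character(0), alleleB = character(0))
  new("ReferenceModel", pairs = pairs, mask = mask, catalog = catalog)
}

.classifyTruthEvent <- function(cRef, cOther, whole) {
  tot <- cRef + cOther
  if (whole) {
    if (tot > 4) return("aneuploidy_gain")
    if (tot < 4) return("aneuploidy_loss")
    return("homoeologous_exchange")
  }
  if (tot == 4) return("homoeologous_exchange")
  if (tot < 4) return("deletion")
  "duplication"
}

.zygosityOf <- function(cRef, cOther) {
  if (cRef + cOther == 4L) {
    if (abs(cRef - 2L) == 1L) "heterozygous" else "homozygous"
  } else {
    if (abs(cRef - 2L) + abs(cOther - 2L) == 1L) "heterozygous"
    else "homozygous"
  }
}

#' Inject karyotype aberrations into a simulated panel
#'
#' Records requested copy-number events (homoeologous exchanges, segmental
#' deletions and duplications, whole-chromosome aneuploidies, optionally in
#' mosaic state) as ground truth for downstream recovery scoring.  Events
#' for the same accession on the same chromosome pair must not overlap;
#' copy numbers must lie in 0..4 per homoeolog with total at most 5.
#' Exchanges conserve total copy number 4; deletions and duplications
#' change it.  Events spanning a whole chromosome are typed as aneuploidy.
#'
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param events A data.frame with columns \code{accession}, \code{pair},
#'   \code{start}, \code{end} (1-based closed, bp), \code{cRef},
#'   \code{cOther} and optionally \code{m} (mosaic fraction, default 1).
#'   An empty or \code{NULL} request yields an all-euploid truth.
#' @param accessions Accession identifiers covered by the truth; defaults
#'   to those present in \code{events}.
#' @return A \code{\link{SyntheticTruth-class}} object.
#' @examples
#' ref <- simulateReference(simulationParams(1, 1e6, seed = 3))
#' injectKaryotype(ref, data.frame(accession = "acc1", pair = 1,
#'   start = 1, end = 5e5, cRef = 3, cOther = 1))
#' @export
injectKaryotype <- function(ref, events = NULL, accessions = NULL) {
  pairs <- chromosomePairs(ref)
  if (is.null(events) || nrow(events) == 0L) {
    return(new("SyntheticTruth",
               events = GenomicRanges::GRanges(
                 accession = character(0), pair = integer(0),
                 cRef = integer(0), cOther = integer(0), m = numeric(0),
                 type = character(0), zygosity = character(0)),
               accessions = as.character(accessions %||% character(0))))
  }
  if (is.null(events$m)) events$m <- 1
  idx <- match(events$pair, pairs$pair)
  if (anyNA(idx)) stop("unknown chromosome pair in event request")
  lens <- pairs$length[idx]
  if (any(events$start < 1 | events$end > lens | events$start > events$end))
    stop("event interval outside chromosome bounds")
  if (any(events$cRef < 0 | events$cRef > 4 |
          events$cOther < 0 | events$cOther > 4))
    stop("per-homoeolog copy number outside 0..4")
  if (any(events$cRef + events$cOther > 5))
    stop("total copy number above 5")
  whole <- events$start == 1 & events$end == lens
  type <- mapply(.classifyTruthEvent, events$cRef, events$cOther, whole)
  zyg <- mapply(.zygosityOf, as.integer(events$cRef),
                as.integer(events$cOther))
  zyg[events$m < 1] <- "mosaic"
  gr <- GenomicRanges::GRanges(
    pairs$chromA[idx], IRanges::IRanges(events$start, events$end),
    accession = as.character(events$accession), pair = events$pair,
    cRef = as.integer(events$cRef), cOther = as.integer(events$cOther),
    m = events$m, type = type, zygosity = zyg)
  acc <- unique(c(as.character(accessions %||% character(0)),
                  as.character(events$accession)))
  new("SyntheticTruth", events = gr, accessions = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effective per-homoeolog copy numbers at each catalog site for one
# accession, given the truth (mosaic mixing with the balanced state).
.siteCopies <- function(catalog, truth, accession) {
  n <- length(catalog)
  cA <- rep(2, n)
  cB <- rep(2, n)
  ev <- truthEvents(truth)
  ev <- ev[ev$accession == accession]
  if (length(ev)) {
    ov <- GenomicRanges::findOverlaps(catalog, ev, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    m <- ev$m[s]
    cA[q] <- m * ev$cRef[s] + (1 - m) * 2
    cB[q] <- m * ev$cOther[s] + (1 - m) * 2
  }
  list(cA = cA, cB = cB)
}

# Length-weighted effective copies over each genomic window.
.windowCopies <- function(windows, truth, accession) {
  n <- length(windows)
  cA <- rep(2, n)
  cB <- rep(2, n)
  ev <- truthEvents(truth)
  ev <- ev[ev$accession == accession]
  if (length(ev)) {
    ov <- GenomicRanges::findOverlaps(windows, ev, ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      inter <- GenomicRanges::pintersect(windows[q], ev[s],
                                         ignore.strand = TRUE)
      wfrac <- GenomicRanges::width(inter) / GenomicRanges::width(windows[q])
      m <- ev$m[s]
      dA <- (m * ev$cRef[s] + (1 - m) * 2 - 2) * wfrac
      dB <- (m * ev$cOther[s] + (1 - m) * 2 - 2) * wfrac
      for (k in seq_along(q)) {
        cA[q[k]] <- cA[q[k]] + dA[k]
        cB[q[k]] <- cB[q[k]] + dB[k]
      }
    }
  }
  list(cA = cA, cB = cB)
}

#' Simulate resequencing observables for a panel of accessions
#'
#' Draws, for each accession, the two observables of the karyotype scan:
#' per-site allele depths at homoeologous sites and per-window
#' unique-mapping coverage of each subgenome.  Total site depth is
#' Poisson with mean \code{coveragePerCopy} times the (effective) total
#' copy number; reads supporting the reference-subgenome allele are
#' binomial at the copy-ratio expectation perturbed by the symmetric
#' sequencing error (observed fraction f(1-e) + (1-f)e).  Window coverage
#' of subgenome s is Poisson with mean \code{coveragePerCopy * c_s} per
#' unmasked base, reported as x-fold depth over the window's unmasked
#' content.
#'
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param truth A \code{\link{SyntheticTruth-class}}; accessions not
#'   listed in any event are euploid.
#' @param params A \code{\link{simulationParams}} object.
#' @param accessions Accessions to simulate (default: those in
#'   \code{truth}, or \code{"acc1"} if none).
#' @param windows Genomic windows (\code{GRanges} with \code{nonrepBp}),
#'   default: \code{\link{segmentByNonrepetitive}} at 100 kb on each
#'   chromosome.
#' @param seed Seed for this draw; defaults to \code{params@seed + 1}.
#' @return A list with one element per accession, each a list of
#'   \code{siteDepth} (data.frame: chrom, pos, refCount, altCount) and
#'   \code{coverage} (data.frame: chrom, start, end, nonrepBp, covA, covB),
#'   plus attribute \code{windows}.
#' @export
simulateObservables <- function(ref, truth, params, accessions = NULL,
                                windows = NULL, seed = NULL) {
  validObject(params)
  set.seed(seed %||% (params@seed + 1L))
  pairs <- chromosomePairs(ref)
  catalog <- siteCatalog(ref)
  if (is.null(windows)) windows <- referenceWindows(ref)
  if (is.null(accessions)) {
    accessions <- truth@accessions
    if (!length(accessions)) accessions <- "acc1"
  }
  cov <- params@coveragePerCopy
  eps <- params@sequencingError
  unmBp <- GenomicRanges::mcols(windows)$nonrepBp
  out <- list()
  for (acc in accessions) {
    sc <- .siteCopies(catalog, truth, acc)
    tot <- sc$cA + sc$cB
    depth <- stats::rpois(length(tot), cov * tot)
    fexp <- ifelse(tot > 0, sc$cA / pmax(tot, 1e-12), 0)
    fobs <- fexp * (1 - eps) + (1 - fexp) * eps
    refCount <- stats::rbinom(length(depth), depth, fobs)
    siteDepth <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(catalog)),
      pos = GenomicRanges::start(catalog),
      refCount = refCount, altCount = depth - refCount,
      stringsAsFactors = FALSE)
    wc <- .windowCopies(windows, truth, acc)
    readsA <- stats::rpois(length(unmBp), cov * wc$cA * unmBp)
    readsB <- stats::rpois(length(unmBp), cov * wc$cB * unmBp)
    coverage <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(windows)),
      start = GenomicRanges::start(windows),
      end = GenomicRanges::end(windows),
      nonrepBp = unmBp,
      covA = readsA / pmax(unmBp, 1),
      covB = readsB / pmax(unmBp, 1),
      stringsAsFactors = FALSE)
    out[[acc]] <- list(siteDepth = siteDepth, coverage = coverage)
  }
  attr(out, "windows") <- windows
  out
}

#' Default genomic windows of a reference model
#'
#' Segments every chromosome pair of the model into windows of fixed
#' non-repetitive content (100 kb by default).
#'
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param W Non-repetitive bp per window.
#' @return A \code{GRanges} with \code{nonrepBp} and \code{partial} columns.
#' @export
referenceWindows <- function(ref, W = 1e5) {
  pairs <- chromosomePairs(ref)
  wl <- lapply(seq_len(nrow(pairs)), function(p) {
    segmentByNonrepetitive(pairs$length[p], repeatMask(ref), W = W,
                           chrom = pairs$chromA[p])
  })
  wl <- wl[vapply(wl, length, 1L) > 0L]
  if (!length(wl))
    return(GenomicRanges::GRanges(nonrepBp = numeric(0),
                                  partial = logical(0)))
  .combineGR(wl)
}

#' Simulate a low-diversity resequencing panel with introgressed blocks
#'
#' Generates biallelic variant sites on the unmasked genome so the panel's
#' realized nucleotide diversity matches \code{panelPi}: segregating sites
#' arise at density panelPi * a_n per unmasked bp (a_n the harmonic number
#' over 2n-1 allele copies) with derived-allele counts drawn from the
#' neutral frequency spectrum (probability proportional to 1/i), then
#' distributed at random over the 2n chromosome copies of the n diploid
#' accessions.  Designated accessions additionally carry contiguous
#' introgressed blocks where carrier-private alleles are added at the
#' density that raises local diversity to
#' panelPi * introgressionPiMultiplier; block truth is recorded.  Read
#' depths per site and accession are Poisson at 4 * coveragePerCopy with
#' binomial allele sampling, so the panel can be genotyped with
#' \code{\link{callGenotypes}}.
#'
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param nAccessions Panel size (>= 2).
#' @param params A \code{\link{simulationParams}} object.
#' @param introgression Optional data.frame of blocks with columns
#'   \code{accession} (index or id), \code{pair}, \code{start}, \code{end}
#'   and optional \code{zygosity} ("heterozygous"/"homozygous").
#' @param seed Seed for this draw; default \code{params@seed + 2}.
#' @return A list: \code{sites} (\code{GRanges} with \code{refAllele},
#'   \code{altAllele}), \code{genotypes} (sites x accessions matrix of
#'   0/1/2 true genotypes), \code{refDepth}/\code{altDepth} (matching
#'   matrices of simulated allele depths), \code{blocks} (truth
#'   \code{GRanges}, empty when no distinguishable block exists).
#' @export
simulatePanel <- function(ref, nAccessions, params, introgression = NULL,
                          seed = NULL) {
  stopifnot(nAccessions >= 2)
  validObject(params)
  set.seed(seed %||% (params@seed + 2L))
  pairs <- chromosomePairs(ref)
  n <- as.integer(nAccessions)
  accIds <- sprintf("acc%d", seq_len(n))
  twoN <- 2L * n
  aN <- sum(1 / seq_len(twoN - 1L))
  siteL <- list()
  gtL <- list()
  for (p in seq_len(nrow(pairs))) {
    unm <- .unmaskedRanges(repeatMask(ref), pairs$chromA[p], pairs$length[p])
    U <- sum(as.numeric(GenomicRanges::width(unm)))
    S <- stats::rpois(1L, params@panelPi * aN * U)
    if (S == 0L) next
    S <- min(S, U)
    pos <- .samplePositions(unm, S)
    iFreq <- sample.int(twoN - 1L, S, replace = TRUE,
                        prob = 1 / seq_len(twoN - 1L))
    g <- matrix(0L, nrow = S, ncol = n)
    for (j in seq_len(S)) {
      copies <- sample.int(twoN, iFreq[j])
      accIdx <- ((copies - 1L) %/% 2L) + 1L
      tab <- tabulate(accIdx, nbins = n)
      g[j, ] <- as.integer(tab)
    }
    siteL[[p]] <- GenomicRanges::GRanges(pairs$chromA[p],
                                         IRanges::IRanges(pos, pos))
    gtL[[p]] <- g
  }
  sites <- .combineGR(siteL)
  gt <- if (length(gtL)) do.call(rbind, gtL) else
    matrix(0L, nrow = 0, ncol = n)

  blockL <- GenomicRanges::GRanges(accession = character(0),
                                   zygosity = character(0))
  mult <- params@introgressionPiMultiplier
  if (!is.null(introgression) && nrow(introgression) > 0 && mult > 1) {
    if (is.null(introgression$zygosity))
      introgression$zygosity <- "heterozygous"
    exL <- list()
    exG <- list()
    for (b in seq_len(nrow(introgression))) {
      p <- introgression$pair[b]
      chrom <- pairs$chromA[match(p, pairs$pair)]
      accRaw <- introgression$accession[b]
      acc <- if (is.numeric(accRaw)) as.integer(accRaw)
             else match(as.character(accRaw), accIds)
      z <- if (identical(introgression$zygosity[b], "homozygous")) 2L else 1L
      blockGr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(introgression$start[b], introgression$end[b]))
      unmB <- GenomicRanges::intersect(
        blockGr, .unmaskedRanges(repeatMask(ref), chrom,
                                 pairs$length[match(p, pairs$pair)]),
        ignore.strand = TRUE)
      uB <- sum(as.numeric(GenomicRanges::width(unmB)))
      pHat <- z / twoN
      hSite <- (twoN / (twoN - 1)) * 2 * pHat * (1 - pHat)
      dens <- params@panelPi * (mult - 1) / hSite
      nExtra <- stats::rpois(1L, dens * uB)
      nExtra <- min(nExtra, uB)
      if (nExtra > 0L) {
        posX <- .samplePositions(unmB, nExtra)
        gX <- matrix(0L, nrow = nExtra, ncol = n)
        gX[, acc] <- z
        exL[[length(exL) + 1L]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(posX, posX))
        exG[[length(exG) + 1L]] <- gX
      }
      GenomicRanges::mcols(blockGr) <-
        S4Vectors::DataFrame(accession = accIds[acc],
                             zygosity = introgression$zygosity[b])
      blockL <- .combineGR(list(blockL, blockGr))
    }
    if (length(exL)) {
      sites <- .combineGR(c(list(sites), exL))
      gt <- rbind(gt, do.call(rbind, exG))
      o <- order(match(as.character(GenomicRanges::seqnames(sites)),
                       GenomeInfoDb::seqlevels(sites)),
                 GenomicRanges::start(sites))
      sites <- sites[o]
      gt <- gt[o, , drop = FALSE]
    }
  }
  # assign distinct ref/alt alleles and simulate allele depths
  nS <- length(sites)
  bases <- c("A", "C", "G", "T")
  refA <- sample(bases, nS, replace = TRUE)
  altA <- bases[((match(refA, bases) - 1L +
                  sample.int(3L, max(nS, 1L), replace = TRUE)[seq_len(nS)])
                 %% 4L) + 1L]
  GenomicRanges::mcols(sites) <- S4Vectors::DataFrame(refAllele = refA,
                                                      altAllele = altA)
  covAcc <- 4 * params@coveragePerCopy
  depth <- matrix(stats::rpois(nS * n, covAcc), nrow = nS)
  altDepth <- matrix(stats::rbinom(nS * n, as.vector(depth),
                                   as.vector(gt[seq_len(nS), , drop = FALSE])
                                   / 2),
                     nrow = nS)
  colnames(gt) <- accIds
  colnames(depth) <- accIds
  colnames(altDepth) <- accIds
  list(sites = sites, genotypes = gt, refDepth = depth - altDepth,
       altDepth = altDepth, blocks = blockL, accessions = accIds)
}
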