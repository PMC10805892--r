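#' @import methods
NULL

#' Parameters of the synthetic allotetraploid generator
#'
#' Holds every tunable of the synthetic-data module.  A single seed fully
#' determines all generator outputs; all rates are probabilities in [0, 1].
#'
#' @slot nChromosomePairs Number of homoeologous chromosome pairs.
#' @slot chromosomeLength Length of each chromosome in bp (recycled to
#'   \code{nChromosomePairs}).
#' @slot siteDensity Expected homoeologous-site density per unmasked bp.
#'   The default 0.005 reflects roughly 5\% sequence divergence between
#'   subgenomes after repeat masking, thinned to usable diagnostic sites.
#' @slot repeatFraction Per-region masked fraction in [0, 1]; a vector is
#'   interpreted as a profile over equally sized chromosome regions.
#' @slot coveragePerCopy Mean mapped depth contributed by a single
#'   chromosome copy (x-fold).  The default 2 corresponds to roughly 8x
#'   per euploid accession.
#' @slot sequencingError Symmetric per-read substitution probability.
#' @slot seed Integer seed; fixing it reproduces byte-identical outputs.
#' @slot panelPi Target within-panel nucleotide diversity per bp.
#' @slot introgressionPiMultiplier Fold increase of local diversity inside
#'   introgressed blocks (dimensionless, default 10).
#' @export
setClass("SimulationParams",
  representation(
    nChromosomePairs = "integer",
    chromosomeLength = "numeric",
    siteDensity = "numeric",
    repeatFraction = "numeric",
    coveragePerCopy = "numeric",
    sequencingError = "numeric",
    seed = "integer",
    panelPi = "numeric",
    introgressionPiMultiplier = "numeric"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  if (object@nChromosomePairs < 1L)
    msg <- c(msg, "nChromosomePairs must be >= 1")
  if (any(object@chromosomeLength <= 0))
    msg <- c(msg, "chromosomeLength must be positive")
  if (object@siteDensity < 0 || object@siteDensity > 1)
    msg <- c(msg, "siteDensity must be in [0, 1]")
  if (any(object@repeatFraction < 0) || any(object@repeatFraction > 1))
    msg <- c(msg, "repeatFraction must be in [0, 1]")
  if (object@coveragePerCopy < 0)
    msg <- c(msg, "coveragePerCopy must be non-negative")
  if (object@sequencingError < 0 || object@sequencingError > 1)
    msg <- c(msg, "sequencingError must be in [0, 1]")
  if (object@panelPi < 0 || object@panelPi > 1)
    msg <- c(msg, "panelPi must be in [0, 1]")
  if (object@introgressionPiMultiplier <= 0)
    msg <- c(msg, "introgressionPiMultiplier must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationParams-class Constructor.
#' @param nChromosomePairs,chromosomeLength,siteDensity,repeatFraction
#'   See slots.
#' @param coveragePerCopy,sequencingError,seed,panelPi,introgressionPiMultiplier
#'   See slots.
#' @return A validated \code{SimulationParams} object.
#' @examples
#' simulationParams(nChromosomePairs = 1, chromosomeLength = 2e6, seed = 7)
#' @export
simulationParams <- function(nChromosomePairs = 2L,
                             chromosomeLength = 5e6,
                             siteDensity = 0.005,
                             repeatFraction = 0.5,
                             coveragePerCopy = 2,
                             sequencingError = 0.001,
                             seed = 1L,
                             panelPi = 3e-4,
                             introgressionPiMultiplier = 10) {
  new("SimulationParams",
    nChromosomePairs = as.integer(nChromosomePairs),
    chromosomeLength = rep_len(as.numeric(chromosomeLength),
                               as.integer(nChromosomePairs)),
    siteDensity = siteDensity,
    repeatFraction = repeatFraction,
    coveragePerCopy = coveragePerCopy,
    sequencingError = sequencingError,
    seed = as.integer(seed),
    panelPi = panelPi,
    introgressionPiMultiplier = introgressionPiMultiplier
  )
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nChromosomePairs, "chromosome pair(s) of",
      paste(format(object@chromosomeLength, big.mark = ","), collapse = "/"),
      "bp\n")
  cat("  site density", object@siteDensity, "| repeat fraction",
      paste(object@repeatFraction, collapse = ","),
      "| coverage/copy", object@coveragePerCopy, "x\n")
  cat("  error", object@sequencingError, "| panel pi", object@panelPi,
      "| introgression x", object@introgressionPiMultiplier,
      "| seed", object@seed, "\n")
})

#' Two-subgenome reference model
#'
#' The coordinate universe of an allotetraploid analysis: homoeologous
#' chromosome pairs, the repeat mask, and the catalog of homoeologous sites
#' (positions where the two subgenomes carry different alleles, diagnostic
#' of subgenome origin of reads).  Coordinates are 1-based closed
#' (\code{GRanges} convention); BED export converts to 0-based half-open.
#'
#' The mask and catalog are kept in subgenome-A coordinates; in the
#' simulated references the two homoeologs of a pair share coordinates, so
#' \code{posB == posA} for every catalog entry.
#'
#' @slot pairs \code{DataFrame} with columns \code{pair}, \code{chromA},
#'   \code{chromB}, \code{length}.
#' @slot mask \code{GRanges} of repeat-masked intervals.
#' @slot catalog \code{GRanges} of homoeologous sites with metadata columns
#'   \code{pair}, \code{chromB}, \code{posB}, \code{alleleA}, \code{alleleB}.
#' @export
setClass("ReferenceModel",
  representation(pairs = "DataFrame", mask = "GRanges", catalog = "GRanges"))

setValidity("ReferenceModel", function(object) {
  msg <- character(0)
  need <- c("pair", "chromA", "chromB", "length")
  if (!all(need %in% colnames(object@pairs)))
    msg <- c(msg, paste("pairs must have columns",
                        paste(need, collapse = ", ")))
  if (length(object@catalog)) {
    mc <- GenomicRanges::mcols(object@catalog)
    needc <- c("pair", "chromB", "posB", "alleleA", "alleleB")
    if (!all(needc %in% colnames(mc))) {
      msg <- c(msg, paste("catalog must have metadata columns",
                          paste(needc, collapse = ", ")))
    } else {
      if (any(as.character(mc$alleleA) == as.character(mc$alleleB)))
        msg <- c(msg, "catalog alleles must differ between subgenomes")
      if (!all(as.character(GenomicRanges::seqnames(object@catalog)) %in%
               object@pairs$chromA))
        msg <- c(msg, "catalog sites must map to a known chromosome pair")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceModel", function(object) {
  cat("ReferenceModel:", nrow(object@pairs), "homoeologous chromosome",
      "pair(s),", length(object@catalog), "catalog sites,",
      length(object@mask), "mask intervals\n")
  tot <- sum(as.numeric(object@pairs$length))
  msk <- sum(as.numeric(GenomicRanges::width(object@mask)))
  cat(sprintf("  %s bp per subgenome, %.1f%% masked\n",
              format(tot, big.mark = ","), 100 * msk / tot))
})

#' @describeIn ReferenceModel-class Chromosome-pair table accessor.
#' @param object,x A \code{ReferenceModel}.
#' @export
setGeneric("chromosomePairs", function(x) standardGeneric("chromosomePairs"))
#' @describeIn ReferenceModel-class Chromosome-pair table.
#' @export
setMethod("chromosomePairs", "ReferenceModel", function(x) x@pairs)

#' @describeIn ReferenceModel-class Repeat-mask accessor.
#' @export
setGeneric("repeatMask", function(x) standardGeneric("repeatMask"))
#' @describeIn ReferenceModel-class Repeat mask as \code{GRanges}.
#' @export
setMethod("repeatMask", "ReferenceModel", function(x) x@mask)

#' @describeIn ReferenceModel-class Homoeologous-site catalog accessor.
#' @export
setGeneric("siteCatalog", function(x) standardGeneric("siteCatalog"))
#' @describeIn ReferenceModel-class Site catalog as \code{GRanges}.
#' @export
setMethod("siteCatalog", "ReferenceModel", function(x) x@catalog)

#' Ground truth of an injected synthetic karyotype
#'
#' Records the aberration events injected into a simulated panel: interval,
#' per-homoeolog copy numbers, mosaic mixture fraction and derived type and
#' zygosity, per accession.  Recovery tests score the scan against this.
#'
#' @slot events \code{GRanges} (subgenome-A coordinates) with metadata
#'   columns \code{accession}, \code{pair}, \code{cRef}, \code{cOther},
#'   \code{m}, \code{type}, \code{zygosity}.
#' @slot accessions Character vector of accession identifiers covered by
#'   the truth (accessions without events are euploid).
#' @export
setClass("SyntheticTruth",
  representation(events = "GRanges", accessions = "character"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  ev <- object@events
  if (length(ev)) {
    mc <- GenomicRanges::mcols(ev)
    need <- c("accession", "pair", "cRef", "cOther", "m", "type", "zygosity")
    if (!all(need %in% colnames(mc)))
      return(paste("events must have metadata columns",
                   paste(need, collapse = ", ")))
    if (any(mc$cRef < 0 | mc$cRef > 4 | mc$cOther < 0 | mc$cOther > 4))
      msg <- c(msg, "per-homoeolog copy numbers must be integers in 0..4")
    if (any(mc$cRef + mc$cOther > 5))
      msg <- c(msg, "total copy number must be at most 5")
    if (any(mc$m < 0 | mc$m > 1))
      msg <- c(msg, "mosaic fraction m must be in [0, 1]")
    key <- paste(mc$accession, as.character(GenomicRanges::seqnames(ev)))
    for (k in unique(key)) {
      sub <- ev[key == k]
      if (length(GenomicRanges::reduce(sub, ignore.strand = TRUE)) <
          length(sub))
        msg <- c(msg, paste("overlapping events for", k))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@events), "event(s) across",
      length(object@accessions), "accession(s)\n")
  if (length(object@events)) {
    mc <- GenomicRanges::mcols(object@events)
    print(table(type = mc$type, zygosity = mc$zygosity))
  }
})

#' @describeIn SyntheticTruth-class Event accessor.
#' @param x A \code{SyntheticTruth}.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @describeIn SyntheticTruth-class Injected events as \code{GRanges}.
#' @export
setMethod("truthEvents", "SyntheticTruth", function(x) x@events)

#' Integer homoeolog copy state with optional mosaic mixture
#'
#' A copy state (cRef, cOther) gives the number of chromosome copies of the
#' referenced subgenome and of its homoeologous partner over an interval.
#' The balanced allotetraploid state is (2, 2).  A mosaic fraction m < 1
#' models somatic mosaicism: a fraction m of cells carry the aberrant state
#' and the remainder are balanced (2, 2); m = 1 is a pure state.
#'
#' The state implies the two observables of the scan: the expected
#' reference-subgenome allele fraction at homoeologous sites
#' (\code{\link{expectedFrequency}}) and the expected per-homoeolog
#' depth-of-coverage ratio relative to a euploid reference accession
#' (\code{\link{expectedDoc}}).
#'
#' @slot cRef Copies of the referenced subgenome, integer 0..4.
#' @slot cOther Copies of the other subgenome, integer 0..4.
#' @slot m Mosaic mixture fraction in [0, 1] (1 = pure state).
#' @export
setClass("CopyState",
  representation(cRef = "integer", cOther = "integer", m = "numeric"))

setValidity("CopyState", function(object) {
  msg <- character(0)
  if (object@cRef < 0L || object@cRef > 4L ||
      object@cOther < 0L || object@cOther > 4L)
    msg <- c(msg, "copy numbers must be integers in 0..4")
  if (object@cRef + object@cOther > 5L)
    msg <- c(msg, "total copy number must be at most 5")
  if (object@m < 0 || object@m > 1)
    msg <- c(msg, "m must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CopyState-class Constructor.
#' @param cRef,cOther,m See slots.
#' @return A validated \code{CopyState}.
#' @examples
#' expectedFrequency(copyState(3, 1))  # heterozygous exchange, 0.75
#' expectedDoc(copyState(3, 2))        # trisomy, c(1.5, 1.0)
#' @export
copyState <- function(cRef, cOther, m = 1) {
  new("CopyState", cRef = as.integer(cRef), cOther = as.integer(cOther),
      m = as.numeric(m))
}

setMethod("show", "CopyState", function(object) {
  cat(sprintf("CopyState %d:%d", object@cRef, object@cOther))
  if (object@m < 1) cat(sprintf(" (mosaic, m = %.2f)", object@m))
  f <- expectedFrequency(object)
  d <- expectedDoc(object)
  cat(sprintf("  [f = %s, DOC = %.2f/%.2f]\n",
              ifelse(is.na(f), "NA", sprintf("%.3f", f)), d[1], d[2]))
})

#' Depth-ratio genotype calling rule set
#'
#' Thresholds of the deterministic genotype caller: minimum read depth and
#' the partition of the alternative-allele fraction r = alt/(ref+alt) into
#' homozygous-reference (r <= homRefMax), heterozygous (r inside
#' \code{hetInterval}, endpoints inclusive), homozygous-alternative
#' (r >= homAltMin) and missing (everything else, including low depth).
#'
#' @slot minDepth Minimum total read depth for a call.
#' @slot hetInterval Heterozygous interval \code{c(lo, hi)}.
#' @slot homRefMax Upper bound of the homozygous-reference fraction.
#' @slot homAltMin Lower bound of the homozygous-alternative fraction.
#' @slot informativenessMin Minimum fraction of individuals with a
#'   non-missing call for a site to be retained (strict inequality).
#' @export
setClass("GenotypeRuleset",
  representation(minDepth = "integer", hetInterval = "numeric",
                 homRefMax = "numeric", homAltMin = "numeric",
                 informativenessMin = "numeric"))

setValidity("GenotypeRuleset", function(object) {
  h <- object@hetInterval
  if (length(h) != 2L) return("hetInterval must have length 2")
  if (!(object@homRefMax < h[1] && h[1] <= h[2] && h[2] < object@homAltMin))
    return("need homRefMax < het lo <= het hi < homAltMin")
  TRUE
})

#' @describeIn GenotypeRuleset-class General constructor.
#' @param minDepth,hetInterval,homRefMax,homAltMin,informativenessMin
#'   See slots.
#' @export
genotypeRuleset <- function(minDepth = 10L, hetInterval = c(0.15, 0.85),
                            homRefMax = 0.1, homAltMin = 0.9,
                            informativenessMin = 0.5) {
  new("GenotypeRuleset", minDepth = as.integer(minDepth),
      hetInterval = as.numeric(hetInterval), homRefMax = homRefMax,
      homAltMin = homAltMin, informativenessMin = informativenessMin)
}

#' @describeIn GenotypeRuleset-class Whole-genome sequencing rules:
#'   depth >= 10, het fraction in [0.15, 0.85].
#' @export
wgsRuleset <- function() genotypeRuleset()

#' @describeIn GenotypeRuleset-class Low-coverage WGS rules: depth >= 5.
#' @export
lowCoverageRuleset <- function() genotypeRuleset(minDepth = 5L)

#' @describeIn GenotypeRuleset-class Genotyping-by-sequencing rules:
#'   depth >= 10, het fraction in [0.25, 0.75].
#' @export
gbsRuleset <- function() genotypeRuleset(hetInterval = c(0.25, 0.75))

setMethod("show", "GenotypeRuleset", function(object) {
  cat(sprintf(
    "GenotypeRuleset: depth >= %d; hom_ref r <= %.2f; het r in [%.2f, %.2f]; hom_alt r >= %.2f\n",
    object@minDepth, object@homRefMax, object@hetInterval[1],
    object@hetInterval[2], object@homAltMin))
})
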