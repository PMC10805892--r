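# Deterministic depth-ratio genotype calling and site filters.

#' Call genotypes from allele depths
#'
#' Deterministic depth-ratio calling: with r = alt / (ref + alt), a sample
#' is homozygous reference when r <= homRefMax, heterozygous when r lies
#' inside the het interval (endpoints inclusive), homozygous alternative
#' when r >= homAltMin, and missing otherwise -- including when total depth
#' is below the ruleset minimum, when both counts are zero, and when r
#' falls in the uncovered gaps between the intervals.  Calls depend only on
#' the fraction, so they are invariant under scaling both counts by a
#' common positive factor (at equal depth sufficiency).
#'
#' @param refCount,altCount Non-negative integer vectors of reads
#'   supporting the reference and alternative allele.
#' @param ruleset A \code{\link{genotypeRuleset}} (default
#'   \code{\link{wgsRuleset}()}).
#' @return Character vector of calls among \code{"hom_ref"}, \code{"het"},
#'   \code{"hom_alt"}, \code{"missing"}.
#' @examples
#' callGenotypes(c(5, 10, 88), c(5, 0, 12))  # het, hom_ref, missing
#' @export
callGenotypes <- function(refCount, altCount, ruleset = wgsRuleset()) {
  stopifnot(length(refCount) == length(altCount),
            all(refCount >= 0), all(altCount >= 0))
  depth <- refCount + altCount
  r <- ifelse(depth > 0, altCount / depth, NA_real_)
  call <- rep("missing", length(depth))
  ok <- depth >= ruleset@minDepth & !is.na(r)
  call[ok & r <= ruleset@homRefMax] <- "hom_ref"
  call[ok & r >= ruleset@hetInterval[1] & r <= ruleset@hetInterval[2]] <-
    "het"
  call[ok & r >= ruleset@homAltMin] <- "hom_alt"
  call
}

#' Remove variant sites also called in the reference self-alignment
#'
#' Variant calls obtained by aligning the reference accession's own reads
#' back to the assembly mark positions where misalignment or consensus
#' inaccuracy produces false variants; any panel site that matches such a
#' self-alignment call (same chromosome, position and allele pair) is
#' discarded.
#'
#' @param panelSites,selfSites \code{GRanges} of variant sites; if a
#'   \code{refAllele}/\code{altAllele} metadata pair is present on both,
#'   alleles take part in the match, otherwise position alone is used.
#' @return The filtered subset of \code{panelSites}.
#' @export
filterReferenceArtifacts <- function(panelSites, selfSites) {
  if (length(selfSites) == 0L) return(panelSites)
  kp <- paste(as.character(GenomicRanges::seqnames(panelSites)),
              GenomicRanges::start(panelSites))
  ks <- paste(as.character(GenomicRanges::seqnames(selfSites)),
              GenomicRanges::start(selfSites))
  mcp <- GenomicRanges::mcols(panelSites)
  mcs <- GenomicRanges::mcols(selfSites)
  withAlleles <- all(c("refAllele", "altAllele") %in% colnames(mcp)) &&
    all(c("refAllele", "altAllele") %in% colnames(mcs))
  if (withAlleles) {
    kp <- paste(kp, mcp$refAllele, mcp$altAllele)
    ks <- paste(ks, mcs$refAllele, mcs$altAllele)
  }
  panelSites[!(kp %in% ks)]
}

#' Retain sites informative in more than a minimum fraction of individuals
#'
#' A site is retained iff the fraction of individuals with a non-missing
#' genotype call strictly exceeds the threshold (default > 0.5, so a site
#' called in exactly half of the panel is dropped).
#'
#' @param calls Matrix of genotype calls (sites x individuals); missing
#'   entries are \code{"missing"} or \code{NA}.
#' @param minFraction Informativeness threshold (strict), default 0.5.
#' @return Logical vector of retained sites.
#' @export
informativeSites <- function(calls, minFraction = 0.5) {
  called <- !(is.na(calls) | calls == "missing")
  rowMeans(called) > minFraction
}

#' Tabulate genotype-call categories per site
#'
#' Audit table of the caller's behavior: per-category counts over a call
#' matrix, written alongside genotype output by the pipeline.
#'
#' @param calls Matrix or vector of calls.
#' @return Named integer vector over the four categories.
#' @export
genotypeAudit <- function(calls) {
  lv <- c("hom_ref", "het", "hom_alt", "missing")
  tab <- table(factor(as.vector(calls), levels = lv))
  out <- as.integer(tab)
  names(out) <- lv
  out
}
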