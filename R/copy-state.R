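# Copy-state expectation model.
#
# A pure state (cRef, cOther) produces reads from cRef + cOther chromosome
# copies; at a homoeologous site the reference-subgenome allele fraction is
# cRef / (cRef + cOther) and each homoeolog's depth, normalized to a euploid
# (2-copy) reference accession, is c/2.  Under somatic mosaicism a fraction
# m of cells carries the aberrant state and the rest are balanced (2, 2);
# observed read pools mix in proportion to cell fraction times copy number,
# so effective copy numbers are m*c + (1-m)*2 per homoeolog and the
# frequency expectation is their ratio (linear in m only when the aberrant
# state conserves total copy number, as homoeologous exchanges do).

.effectiveCopies <- function(state) {
  m <- state@m
  c(ref = m * state@cRef + (1 - m) * 2,
    other = m * state@cOther + (1 - m) * 2)
}

#' Expected homoeologous variant frequency of a copy state
#'
#' The expected fraction of reads carrying the referenced subgenome's
#' allele at homoeologous sites, given a (possibly mosaic) copy state.
#' Balanced (2,2) gives 0.5; a heterozygous exchange (3,1) gives 0.75; a
#' homozygous replacement (4,0) gives 1.
#'
#' @param state A \code{\link{copyState}} object.
#' @return A single number in [0, 1], or \code{NA} when the total
#'   effective copy number is zero (no reads expected).
#' @examples
#' expectedFrequency(copyState(1, 3))          # 0.25
#' expectedFrequency(copyState(4, 0, m = 0.5)) # mosaic, 0.75
#' @export
setGeneric("expectedFrequency", function(state)
  standardGeneric("expectedFrequency"))

#' @rdname expectedFrequency
#' @export
setMethod("expectedFrequency", "CopyState", function(state) {
  eff <- .effectiveCopies(state)
  tot <- sum(eff)
  if (tot == 0) return(NA_real_)
  unname(eff["ref"] / tot)
})

#' Expected depth-of-coverage ratio of a copy state
#'
#' The expected per-homoeolog depth of coverage of an accession, relative
#' to a euploid reference accession carrying two copies of each homoeolog.
#' A trisomic homoeolog (3 copies) gives 1.5; a homozygous replacement
#' (4 copies) gives 2; a lost homoeolog gives 0.
#'
#' @param state A \code{\link{copyState}} object.
#' @return Named numeric vector \code{c(ref = , other = )} of fold ratios.
#' @examples
#' expectedDoc(copyState(3, 2))  # c(ref = 1.5, other = 1)
#' @export
setGeneric("expectedDoc", function(state) standardGeneric("expectedDoc"))

#' @rdname expectedDoc
#' @export
setMethod("expectedDoc", "CopyState", function(state) {
  .effectiveCopies(state) / 2
})

# The full pure-state grid searched by the fitter: per-homoeolog copies in
# 0..4 with total in 0..5 (monosomy through trisomy; tetrasomy and higher
# are outside the grid and surface as high residuals).
.stateGrid <- function() {
  g <- expand.grid(cRef = 0:4, cOther = 0:4)
  g[g$cRef + g$cOther <= 5L, , drop = FALSE]
}
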