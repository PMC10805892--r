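# Readers and writers for the standard interchange formats.  FASTA goes
# through Biostrings, BED through rtracklayer (which converts between the
# package's 1-based closed ranges and BED's 0-based half-open intervals),
# VCF through VariantAnnotation, and the tabular observables through plain
# TSV with a provenance comment header.

#' Write the simulated subgenome sequences as FASTA
#'
#' Generates random nucleotide sequences for both homoeologs of every
#' chromosome pair, identical between homoeologs except at catalog sites
#' where each subgenome carries its own diagnostic allele, and writes them
#' as a single FASTA file.  Sequence content outside catalog sites is
#' random background; only the catalog alleles matter downstream.
#'
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param file Output FASTA path.
#' @param seed Seed for the background sequence draw.
#' @return The file path, invisibly.
#' @export
writeReferenceFasta <- function(ref, file, seed = 1L) {
  set.seed(seed)
  pairs <- chromosomePairs(ref)
  cat <- siteCatalog(ref)
  seqs <- character(0)
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(nrow(pairs))) {
    len <- pairs$length[p]
    bg <- sample(bases, len, replace = TRUE)
    sA <- bg
    sB <- bg
    ci <- as.character(GenomicRanges::seqnames(cat)) == pairs$chromA[p]
    if (any(ci)) {
      pos <- GenomicRanges::start(cat)[ci]
      sA[pos] <- GenomicRanges::mcols(cat)$alleleA[ci]
      sB[pos] <- GenomicRanges::mcols(cat)$alleleB[ci]
    }
    seqs[[pairs$chromA[p]]] <- paste(sA, collapse = "")
    seqs[[pairs$chromB[p]]] <- paste(sB, collapse = "")
  }
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(dss, file)
  invisible(file)
}

#' Write the repeat mask as BED
#' @param ref A \code{\link{ReferenceModel-class}}.
#' @param file Output BED path.
#' @return The file path, invisibly.
#' @export
writeMaskBed <- function(ref, file) {
  rtracklayer::export(repeatMask(ref), file, format = "BED")
  invisible(file)
}

#' Write karyotype events (or truth events) as BED
#'
#' The BED name field packs accession, type, zygosity and fitted copy
#' state; coordinates follow BED convention (0-based half-open).
#'
#' @param events \code{GRanges} with \code{accession}, \code{type},
#'   \code{zygosity}, \code{cRef}, \code{cOther} metadata.
#' @param file Output BED path.
#' @return The file path, invisibly.
#' @export
writeEventsBed <- function(events, file) {
  gr <- events
  mc <- GenomicRanges::mcols(gr)
  nm <- paste(mc$accession, mc$type, mc$zygosity,
              paste0(mc$cRef, ":", mc$cOther), sep = "|")
  out <- GenomicRanges::granges(gr)
  GenomicRanges::mcols(out)$name <- nm
  rtracklayer::export(out, file, format = "BED")
  invisible(file)
}

#' Read karyotype events from BED
#' @param file BED path written by \code{\link{writeEventsBed}}.
#' @return \code{GRanges} with unpacked metadata columns.
#' @export
readEventsBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  parts <- strsplit(as.character(GenomicRanges::mcols(gr)$name), "|",
                    fixed = TRUE)
  cs <- strsplit(vapply(parts, `[`, "", 4L), ":", fixed = TRUE)
  out <- GenomicRanges::granges(gr)
  GenomicRanges::mcols(out) <- S4Vectors::DataFrame(
    accession = vapply(parts, `[`, "", 1L),
    type = vapply(parts, `[`, "", 2L),
    zygosity = vapply(parts, `[`, "", 3L),
    cRef = as.integer(vapply(cs, `[`, "", 1L)),
    cOther = as.integer(vapply(cs, `[`, "", 2L)))
  out
}

#' Write / read a site-depth table
#'
#' TSV with columns chrom, pos (1-based), refCount, altCount and a
#' provenance comment header.
#'
#' @param siteDepth data.frame as produced by
#'   \code{\link{simulateObservables}}.
#' @param file TSV path.
#' @param seed,config Optional provenance fields for the header.
#' @return The file path (writer) or the data.frame (reader).
#' @export
writeSiteDepth <- function(siteDepth, file, seed = NULL, config = NULL) {
  .writeTsv(siteDepth, file, .provenanceHeader(seed, config))
}

#' @rdname writeSiteDepth
#' @export
readSiteDepth <- function(file) .readTsv(file)

#' Write / read a per-window coverage table
#' @param coverage data.frame with chrom, start, end, nonrepBp, covA, covB.
#' @param file TSV path.
#' @param seed,config Optional provenance fields.
#' @return The file path (writer) or the data.frame (reader).
#' @export
writeCoverageTable <- function(coverage, file, seed = NULL, config = NULL) {
  .writeTsv(coverage, file, .provenanceHeader(seed, config))
}

#' @rdname writeCoverageTable
#' @export
readCoverageTable <- function(file) .readTsv(file)

#' Write / read the homoeologous-site catalog as TSV
#'
#' Columns: chromA, posA (1-based), alleleA, chromB, posB, alleleB, pair.
#'
#' @param ref A \code{\link{ReferenceModel-class}} (writer).
#' @param file TSV path.
#' @return The file path (writer); a catalog \code{GRanges} (reader).
#' @export
writeCatalogTsv <- function(ref, file) {
  cat <- siteCatalog(ref)
  mc <- GenomicRanges::mcols(cat)
  df <- data.frame(
    chromA = as.character(GenomicRanges::seqnames(cat)),
    posA = GenomicRanges::start(cat),
    alleleA = mc$alleleA, chromB = mc$chromB, posB = mc$posB,
    alleleB = mc$alleleB, pair = mc$pair, stringsAsFactors = FALSE)
  .writeTsv(df, file, .provenanceHeader())
}

#' @rdname writeCatalogTsv
#' @export
readCatalogTsv <- function(file) {
  df <- .readTsv(file)
  GenomicRanges::GRanges(df$chromA, IRanges::IRanges(df$posA, df$posA),
                         pair = df$pair, chromB = df$chromB,
                         posB = df$posB, alleleA = df$alleleA,
                         alleleB = df$alleleB)
}

#' Write a panel with allele depths as VCF
#'
#' Emits the simulated panel as a VCF with per-sample GT and AD fields
#' (positions 1-based, as VCF requires).
#'
#' @param panel List from \code{\link{simulatePanel}}.
#' @param file Output VCF path (plain text).
#' @param genome Genome label for the VCF header.
#' @return The file path, invisibly.
#' @export
writePanelVcf <- function(panel, file, genome = "synthetic") {
  sites <- panel$sites
  n <- length(panel$accessions)
  nS <- length(sites)
  gtCode <- matrix("./.", nS, n)
  gtCode[panel$genotypes == 0L] <- "0/0"
  gtCode[panel$genotypes == 1L] <- "0/1"
  gtCode[panel$genotypes == 2L] <- "1/1"
  ad <- matrix(paste0(panel$refDepth, ",", panel$altDepth), nS, n)
  body <- cbind(
    CHROM = as.character(GenomicRanges::seqnames(sites)),
    POS = GenomicRanges::start(sites),
    ID = ".", REF = GenomicRanges::mcols(sites)$refAllele,
    ALT = GenomicRanges::mcols(sites)$altAllele,
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT:AD",
    matrix(paste(gtCode, ad, sep = ":"), nS, n,
           dimnames = list(NULL, panel$accessions)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=homoeoScan %s",
            utils::packageVersion("homoeoScan")),
    sprintf("##reference=%s", genome),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$accessions), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a panel VCF with AD fields
#'
#' Reads a VCF (via VariantAnnotation) and returns sites plus per-sample
#' allele-depth matrices, from which genotypes can be called with
#' \code{\link{callGenotypes}}.
#'
#' @param file VCF path.
#' @return List with \code{sites} (\code{GRanges} with refAllele /
#'   altAllele), \code{refDepth}, \code{altDepth}, \code{accessions}.
#' @export
readPanelVcf <- function(file) {
  vcf <- VariantAnnotation::readVcf(file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- GenomicRanges::granges(rr)
  GenomicRanges::mcols(sites) <- S4Vectors::DataFrame(
    refAllele = as.character(rr$REF),
    altAllele = vapply(rr$ALT, function(a) as.character(a)[1], ""))
  ad <- VariantAnnotation::geno(vcf)$AD
  nS <- nrow(ad)
  nA <- ncol(ad)
  refD <- matrix(NA_integer_, nS, nA, dimnames = dimnames(ad))
  altD <- refD
  for (j in seq_len(nA)) {
    refD[, j] <- vapply(ad[, j], function(x) as.integer(x[1]), 1L)
    altD[, j] <- vapply(ad[, j], function(x) as.integer(x[2]), 1L)
  }
  list(sites = sites, refDepth = refD, altDepth = altD,
       accessions = colnames(ad))
}

#' Write windows as BED plus TSV with non-repetitive content
#'
#' @param windows \code{GRanges} with \code{nonrepBp}.
#' @param bedFile,tsvFile Output paths (either may be \code{NULL}).
#' @return Invisibly, the written paths.
#' @export
writeWindows <- function(windows, bedFile = NULL, tsvFile = NULL) {
  if (!is.null(bedFile))
    rtracklayer::export(GenomicRanges::granges(windows), bedFile,
                        format = "BED")
  if (!is.null(tsvFile)) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(windows)),
      start = GenomicRanges::start(windows),
      end = GenomicRanges::end(windows),
      nonrepBp = GenomicRanges::mcols(windows)$nonrepBp,
      partial = GenomicRanges::mcols(windows)$partial,
      stringsAsFactors = FALSE)
    .writeTsv(df, tsvFile, .provenanceHeader())
  }
  invisible(c(bedFile, tsvFile))
}
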