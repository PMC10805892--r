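# Internal helpers shared across modules.

#' @importFrom GenomicRanges GRanges seqnames start end width reduce setdiff
#'   findOverlaps pintersect mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

# Complement of the repeat mask on one chromosome, as a GRanges of
# 1-based closed unmasked intervals.
.unmaskedRanges <- function(mask, chrom, chromLen) {
  whole <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, chromLen))
  m <- mask[as.character(GenomicRanges::seqnames(mask)) == chrom]
  if (length(m) == 0L) return(whole)
  GenomicRanges::setdiff(whole, m, ignore.strand = TRUE)
}

# Sample n distinct positions uniformly from the unmasked space described by
# a GRanges of disjoint intervals.  Returns sorted 1-based positions.
.samplePositions <- function(unmasked, n) {
  w <- GenomicRanges::width(unmasked)
  total <- sum(as.numeric(w))
  if (n == 0L || total == 0) return(integer(0))
  stopifnot(n <= total)
  offs <- sort(sample.int(total, n))
  cw <- cumsum(as.numeric(w))
  idx <- findInterval(offs - 1, cw) + 1L
  prev <- c(0, cw[-length(cw)])
  pos <- GenomicRanges::start(unmasked)[idx] + (offs - prev[idx]) - 1
  as.integer(pos)
}

# Total unmasked bp of a chromosome.
.unmaskedLength <- function(mask, chrom, chromLen) {
  sum(as.numeric(GenomicRanges::width(.unmaskedRanges(mask, chrom, chromLen))))
}

# Concatenate GRanges objects after unifying their seqlevels (plain c()
# warns when levels differ between chromosomes).
.combineGR <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  lst <- lst[vapply(lst, length, integer(1)) > 0L]
  if (!length(lst)) return(GenomicRanges::GRanges())
  lv <- unique(unlist(lapply(lst, GenomeInfoDb::seqlevels)))
  lst <- lapply(lst, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  do.call(c, lst)
}

# Tiny stable FNV-1a string hash, used to stamp configs in provenance lines.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply, split to stay inside double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

.provenanceHeader <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("homoeoScan"))
  parts <- c(sprintf("homoeoScan %s", ver))
  if (!is.null(seed)) parts <- c(parts, sprintf("seed=%s", seed))
  if (!is.null(config)) parts <- c(parts, sprintf("config=%s", .fnv1a(config)))
  paste0("# ", paste(parts, collapse = "; "))
}

# Write a data.frame as TSV with an optional provenance comment header.
.writeTsv <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.readTsv <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}
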