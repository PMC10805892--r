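# Pipeline orchestration: YAML config validation, staged execution with
# provenance-stamped outputs, and karyotype report rendering.

.configSchema <- function() {
  list(
    seed = "integer", out = "character", stages = "character",
    simulate = list(
      nChromosomePairs = "integer", chromosomeLength = "numeric",
      siteDensity = "numeric", repeatFraction = "numeric",
      coveragePerCopy = "numeric", sequencingError = "numeric",
      panelPi = "numeric", introgressionPiMultiplier = "numeric",
      nAccessions = "integer", referenceAccession = "character",
      events = "list", introgression = "list"),
    windows = list(W = "numeric"),
    genotype = list(ruleset = "character"),
    karyotype = list(
      nSites = "integer", step = "integer", alpha = "numeric",
      docTol = "numeric", minEventSize = "numeric", gapTol = "integer",
      aneuploidySpan = "numeric", mosaicImprovement = "numeric",
      mosaicMinResidual = "numeric"),
    diversity = list(k = "numeric", floor = "numeric", gapTol = "integer",
                     baseline = "character"))
}

.validateConfig <- function(config, schema = .configSchema(),
                            path = "config") {
  if (!is.list(config)) stop(path, " must be a mapping")
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste0(path, "$", unknown), collapse = ", "))
  for (k in names(config)) {
    if (is.list(schema[[k]]) && !identical(schema[[k]], "list") &&
        is.list(config[[k]]))
      .validateConfig(config[[k]], schema[[k]], paste0(path, "$", k))
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and fills defaults.
#'
#' @param file YAML path, or a list already in memory.
#' @return Validated config list with class \code{"homoeoScanConfig"}.
#' @export
loadConfig <- function(file) {
  config <- if (is.character(file)) yaml::read_yaml(file) else file
  .validateConfig(config)
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||%
    c("simulate", "windows", "genotype", "karyotype", "diversity", "report")
  structure(config, class = "homoeoScanConfig")
}

.cfg <- function(config, group, key, default) {
  v <- config[[group]][[key]]
  if (is.null(v)) default else v
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order
#' simulate -> windows -> genotype -> karyotype -> diversity -> report,
#' writing every artifact under the output directory with a provenance
#' header (tool version, seed, config hash).  All randomness flows from
#' the single configured seed.  On failure, partially written outputs are
#' removed.
#'
#' @param config Path to a YAML config, or a list (see
#'   \code{\link{loadConfig}}).
#' @param outDir Output directory (overrides \code{config$out}).
#' @param seed Seed override.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list of in-memory results per stage.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL, quiet = FALSE) {
  config <- loadConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outDir <- outDir %||% config$out %||% stop("no output directory configured")
  cfgText <- yaml::as.yaml(unclass(config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(...) if (!quiet) message("[homoeoScan] ", ...)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit({
    if (!ok) unlink(written)
  })
  seedBase <- config$seed
  res <- list(config = config)

  stages <- config$stages
  # --- simulate -----------------------------------------------------------
  params <- simulationParams(
    nChromosomePairs = .cfg(config, "simulate", "nChromosomePairs", 2L),
    chromosomeLength = .cfg(config, "simulate", "chromosomeLength", 3e6),
    siteDensity = .cfg(config, "simulate", "siteDensity", 0.005),
    repeatFraction = .cfg(config, "simulate", "repeatFraction", 0.5),
    coveragePerCopy = .cfg(config, "simulate", "coveragePerCopy", 2),
    sequencingError = .cfg(config, "simulate", "sequencingError", 0.001),
    seed = seedBase,
    panelPi = .cfg(config, "simulate", "panelPi", 3e-4),
    introgressionPiMultiplier =
      .cfg(config, "simulate", "introgressionPiMultiplier", 10))
  refAcc <- .cfg(config, "simulate", "referenceAccession", "reference")
  if ("simulate" %in% stages) {
    note("simulate: reference + observables (seed ", seedBase, ")")
    ref <- simulateReference(params)
    evCfg <- config$simulate$events
    evDf <- if (is.null(evCfg)) NULL else
      do.call(rbind, lapply(evCfg, as.data.frame))
    truth <- injectKaryotype(ref, evDf)
    accs <- unique(c(refAcc, truth@accessions))
    obs <- simulateObservables(ref, truth, params, accessions = accs)
    res$ref <- ref
    res$truth <- truth
    res$observables <- obs
    writeCatalogTsv(ref, emit(file.path(outDir, "catalog.tsv")))
    writeMaskBed(ref, emit(file.path(outDir, "mask.bed")))
    if (length(truthEvents(truth)))
      writeEventsBed(truthEvents(truth),
                     emit(file.path(outDir, "truth-events.bed")))
    for (acc in accs) {
      writeSiteDepth(obs[[acc]]$siteDepth,
                     emit(file.path(outDir, paste0(acc, ".sitedepth.tsv"))),
                     seed = seedBase, config = cfgText)
      writeCoverageTable(obs[[acc]]$coverage,
                         emit(file.path(outDir,
                                        paste0(acc, ".coverage.tsv"))),
                         seed = seedBase, config = cfgText)
    }
    nAcc <- .cfg(config, "simulate", "nAccessions", 0L)
    if (nAcc >= 2L) {
      intCfg <- config$simulate$introgression
      intDf <- if (is.null(intCfg)) NULL else
        do.call(rbind, lapply(intCfg, as.data.frame))
      res$panel <- simulatePanel(ref, nAcc, params, introgression = intDf)
      writePanelVcf(res$panel, emit(file.path(outDir, "panel.vcf")))
    }
  }
  # --- windows ------------------------------------------------------------
  if ("windows" %in% stages && !is.null(res$ref)) {
    W <- .cfg(config, "windows", "W", 1e5)
    res$windows <- referenceWindows(res$ref, W = W)
    note("windows: ", length(res$windows), " genomic windows of ", W,
         " unmasked bp")
    writeWindows(res$windows,
                 bedFile = emit(file.path(outDir, "windows.bed")),
                 tsvFile = emit(file.path(outDir, "windows.tsv")))
  }
  # --- genotype -----------------------------------------------------------
  if ("genotype" %in% stages && !is.null(res$panel)) {
    rsName <- .cfg(config, "genotype", "ruleset", "wgs")
    rs <- switch(rsName, wgs = wgsRuleset(), gbs = gbsRuleset(),
                 lowCoverage = lowCoverageRuleset(),
                 stop("unknown ruleset: ", rsName))
    calls <- matrix(
      callGenotypes(as.vector(res$panel$refDepth),
                    as.vector(res$panel$altDepth), rs),
      nrow = nrow(res$panel$refDepth),
      dimnames = dimnames(res$panel$refDepth))
    keep <- informativeSites(calls, rs@informativenessMin)
    res$calls <- calls
    res$informative <- keep
    note("genotype: ", sum(keep), "/", length(keep), " informative sites")
    audit <- as.data.frame(t(genotypeAudit(calls)))
    .writeTsv(audit, emit(file.path(outDir, "genotype-audit.tsv")),
              .provenanceHeader(seedBase, cfgText))
  }
  # --- karyotype ----------------------------------------------------------
  if ("karyotype" %in% stages && !is.null(res$observables)) {
    refCov <- res$observables[[refAcc]]$coverage
    scans <- list()
    for (acc in setdiff(names(res$observables), refAcc)) {
      scans[[acc]] <- karyotypeScan(
        res$observables[[acc]]$siteDepth,
        res$observables[[acc]]$coverage, refCov,
        nSites = .cfg(config, "karyotype", "nSites", 500L),
        step = .cfg(config, "karyotype", "step", 250L),
        accession = acc,
        alpha = .cfg(config, "karyotype", "alpha", 0.05),
        docTol = .cfg(config, "karyotype", "docTol", 0.25),
        minEventSize = .cfg(config, "karyotype", "minEventSize", 2e5),
        gapTol = .cfg(config, "karyotype", "gapTol", 1L),
        aneuploidySpan = .cfg(config, "karyotype", "aneuploidySpan", 0.95))
      note("karyotype: ", acc, ": ", length(scans[[acc]]$events),
           " event(s)")
      .writeTsv(scans[[acc]]$observations,
                emit(file.path(outDir, paste0(acc, ".windows.tsv"))),
                .provenanceHeader(seedBase, cfgText))
      if (length(scans[[acc]]$events))
        writeEventsBed(scans[[acc]]$events,
                       emit(file.path(outDir, paste0(acc, ".events.bed"))))
    }
    res$scans <- scans
  }
  # --- diversity ----------------------------------------------------------
  if ("diversity" %in% stages && !is.null(res$panel) &&
      !is.null(res$windows)) {
    gt <- res$panel$genotypes
    if (!is.null(res$calls)) {
      gt <- matrix(c(hom_ref = 0L, het = 1L, hom_alt = 2L,
                     missing = NA_integer_)[res$calls],
                   nrow = nrow(res$calls), dimnames = dimnames(res$calls))
    }
    div <- diversityWindows(res$panel$sites, gt, res$windows)
    baseline <- .cfg(config, "diversity", "baseline",
                     res$panel$accessions)
    flagged <- flagIntrogressedWindows(
      div, baseline, k = .cfg(config, "diversity", "k", 10),
      floor = .cfg(config, "diversity", "floor", 5))
    blocks <- GenomicRanges::GRanges()
    for (acc in res$panel$accessions) {
      b <- mergeBlocks(flagged, res$windows, acc,
                       gapTol = .cfg(config, "diversity", "gapTol", 1L))
      if (length(b)) blocks <- .combineGR(list(blocks, b))
    }
    res$diversity <- div
    res$flagged <- flagged
    res$blocks <- blocks
    note("diversity: median window pi = ",
         signif(stats::median(div$pi), 3), "; ", length(blocks),
         " introgression block(s)")
    dfPi <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(res$windows)),
      start = GenomicRanges::start(res$windows),
      end = GenomicRanges::end(res$windows),
      nonrepBp = GenomicRanges::mcols(res$windows)$nonrepBp,
      pi = div$pi)
    .writeTsv(cbind(dfPi, div$counts),
              emit(file.path(outDir, "diversity-windows.tsv")),
              .provenanceHeader(seedBase, cfgText))
    if (length(blocks))
      rtracklayer::export(blocks,
                          emit(file.path(outDir, "introgression.bed")),
                          format = "BED")
  }
  # --- report -------------------------------------------------------------
  if ("report" %in% stages && !is.null(res$scans)) {
    report <- renderKaryotypeReport(
      res$scans, chromosomePairs(res$ref), seed = seedBase,
      config = cfgText,
      file = emit(file.path(outDir, "karyotype-report.json")),
      textFile = emit(file.path(outDir, "karyotype-report.txt")))
    res$report <- report
  }
  ok <- TRUE
  invisible(res)
}

.textIdeogram <- function(chromLen, events, width = 50L) {
  bar <- rep(".", width)
  if (length(events)) {
    for (i in seq_along(events)) {
      a <- max(1L, ceiling(GenomicRanges::start(events)[i] / chromLen *
                             width))
      b <- min(width, ceiling(GenomicRanges::end(events)[i] / chromLen *
                                width))
      ch <- switch(GenomicRanges::mcols(events)$type[i],
                   homoeologous_exchange = "X", deletion = "D",
                   duplication = "U", aneuploidy_gain = "G",
                   aneuploidy_loss = "L", "?")
      bar[a:b] <- ch
    }
  }
  paste(bar, collapse = "")
}

#' Render the karyotype report
#'
#' Produces a machine-readable JSON report and a human-readable text
#' ideogram per accession: one chromosome row per pair with the fitted
#' copy state (all 2:2 when euploid), plus the event list with 1-based
#' inclusive coordinates, type, zygosity, mosaic fraction and residuals.
#'
#' @param scans Named list of \code{\link{karyotypeScan}} results (one
#'   per accession).
#' @param pairs Chromosome-pair table of the reference model.
#' @param seed,config Provenance fields.
#' @param file Optional JSON output path.
#' @param textFile Optional text output path.
#' @return The report as a list, invisibly when written to file.
#' @export
renderKaryotypeReport <- function(scans, pairs, seed = NULL, config = NULL,
                                  file = NULL, textFile = NULL) {
  report <- list(
    tool = sprintf("homoeoScan %s", utils::packageVersion("homoeoScan")),
    seed = seed,
    configHash = if (!is.null(config)) .fnv1a(config) else NULL,
    accessions = list())
  textLines <- c(report$tool,
                 if (!is.null(seed)) sprintf("seed: %s", seed))
  for (acc in names(scans)) {
    ev <- scans[[acc]]$events
    chromTab <- list()
    textLines <- c(textLines, "", sprintf("accession %s", acc))
    for (p in seq_len(nrow(pairs))) {
      chrom <- pairs$chromA[p]
      evp <- ev[as.character(GenomicRanges::seqnames(ev)) == chrom]
      state <- if (length(evp) == 0L) "2:2" else
        paste0(GenomicRanges::mcols(evp)$cRef[1], ":",
               GenomicRanges::mcols(evp)$cOther[1])
      chromTab[[chrom]] <- list(pair = pairs$pair[p], state = state,
                                nEvents = length(evp))
      textLines <- c(textLines, sprintf(
        "  %-10s [%s] %s", chrom,
        .textIdeogram(pairs$length[p], evp), state))
    }
    evList <- lapply(seq_along(ev), function(i) {
      mc <- GenomicRanges::mcols(ev)
      list(chrom = as.character(GenomicRanges::seqnames(ev))[i],
           start = GenomicRanges::start(ev)[i],
           end = GenomicRanges::end(ev)[i],
           type = mc$type[i], zygosity = mc$zygosity[i],
           state = paste0(mc$cRef[i], ":", mc$cOther[i]),
           m = round(mc$m[i], 3), residual = signif(mc$residual[i], 4),
           nWindows = mc$nWindows[i])
    })
    for (e in evList) {
      textLines <- c(textLines, sprintf(
        "    %s:%d-%d %s (%s%s) state %s",
        e$chrom, e$start, e$end, e$type, e$zygosity,
        if (e$zygosity == "mosaic") sprintf(", m = %.2f", e$m) else "",
        e$state))
    }
    report$accessions[[acc]] <- list(chromosomes = chromTab,
                                     events = evList)
  }
  if (!is.null(file))
    jsonlite::write_json(report, file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (!is.null(textFile)) writeLines(textLines, textFile)
  if (is.null(file) && is.null(textFile)) report else invisible(report)
}

#' Path of the bundled demo configuration
#' @return Path to a YAML config that simulates a small panel with one
#'   injected heterozygous exchange and runs every stage.
#' @export
demoConfig <- function() {
  system.file("extdata", "demo-config.yaml", package = "homoeoScan",
              mustWork = TRUE)
}
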