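library(GenomicRanges)

test_that("catalog site counts are binomial in the unmasked length", {
  p <- simulationParams(1, 1e6, siteDensity = 0.05, repeatFraction = 0.3,
                        seed = 21)
  ref <- simulateReference(p)
  U <- sum(width(GenomicRanges::setdiff(
    GRanges("chr1_A", IRanges(1, 1e6)), repeatMask(ref))))
  n <- length(siteCatalog(ref))
  mu <- U * 0.05
  sigma <- sqrt(U * 0.05 * 0.95)
  expect_lt(abs(n - mu), 4 * sigma)
  # sites fall only on unmasked positions
  hits <- findOverlaps(siteCatalog(ref), repeatMask(ref))
  expect_length(hits, 0L)
  # alleles always differ between subgenomes
  expect_true(all(siteCatalog(ref)$alleleA != siteCatalog(ref)$alleleB))
})

test_that("degenerate densities behave as specified", {
  p0 <- simulationParams(1, 1e5, siteDensity = 0, seed = 2)
  expect_length(siteCatalog(simulateReference(p0)), 0L)
  pm <- simulationParams(1, 1e5, siteDensity = 0.05, repeatFraction = 1,
                         seed = 2)
  refm <- simulateReference(pm)
  expect_length(siteCatalog(refm), 0L)
  expect_equal(sum(width(repeatMask(refm))), 1e5)
  # density so low that a chromosome draws no site is refused
  plow <- simulationParams(1, 1e5, siteDensity = 1e-9, seed = 2)
  expect_error(simulateReference(plow), "density")
})

test_that("a fixed seed reproduces identical outputs", {
  p <- smallParams(seed = 77L)
  r1 <- simulateReference(p)
  r2 <- simulateReference(p)
  expect_identical(as.data.frame(siteCatalog(r1)),
                   as.data.frame(siteCatalog(r2)))
  expect_identical(as.data.frame(repeatMask(r1)),
                   as.data.frame(repeatMask(r2)))
  ev <- data.frame(accession = "a", pair = 1, start = 1, end = 1e6,
                   cRef = 3, cOther = 1)
  o1 <- simulateObservables(r1, injectKaryotype(r1, ev), p)
  o2 <- simulateObservables(r2, injectKaryotype(r2, ev), p)
  expect_identical(o1$a$siteDepth, o2$a$siteDepth)
  expect_identical(o1$a$coverage, o2$a$coverage)
})

test_that("simulated observables match copy-state expectations", {
  # >= 1e5 site draws per state; empirical mean frequency within 3 sigma
  # of the expectation, window doc close to c/2
  p <- simulationParams(1, 1e6, siteDensity = 0.12, repeatFraction = 0,
                        coveragePerCopy = 2, sequencingError = 0,
                        seed = 31)
  ref <- simulateReference(p)
  expect_gte(length(siteCatalog(ref)), 1e5)
  states <- list(c(4, 0, 1), c(3, 1, 1), c(2, 2, 1), c(1, 3, 1),
                 c(0, 2, 1), c(3, 2, 1), c(1, 2, 1), c(4, 0, 0.5))
  for (st in states) {
    ev <- if (st[1] == 2 && st[2] == 2) NULL else
      data.frame(accession = "a", pair = 1, start = 1, end = 1e6,
                 cRef = st[1], cOther = st[2], m = st[3])
    truth <- injectKaryotype(ref, ev, accessions = "a")
    obs <- simulateObservables(ref, truth, p, accessions = "a")$a
    cs <- copyState(st[1], st[2], m = st[3])
    fExp <- expectedFrequency(cs)
    totRef <- sum(obs$siteDepth$refCount)
    totDepth <- totRef + sum(obs$siteDepth$altCount)
    fHat <- totRef / totDepth
    sigma <- sqrt(fExp * (1 - fExp) / totDepth)
    expect_lt(abs(fHat - fExp), max(3 * sigma, 1e-6),
              label = sprintf("state %d:%d m=%.1f fHat=%.4f", st[1], st[2],
                              st[3], fHat))
    # mean site depth tracks coverage per copy times effective total copies
    totCopies <- 2 * sum(expectedDoc(cs))
    depthMean <- mean(obs$siteDepth$refCount + obs$siteDepth$altCount)
    expect_lt(abs(depthMean - 2 * totCopies),
              4 * sqrt(2 * totCopies / nrow(obs$siteDepth)) + 0.01)
    # raw window coverage tracks coveragePerCopy * effective copies
    # (effective copies = 2 * doc expectation)
    expect_lt(abs(mean(obs$coverage$covA) -
                    2 * 2 * expectedDoc(cs)[["ref"]]), 0.05)
    expect_lt(abs(mean(obs$coverage$covB) -
                    2 * 2 * expectedDoc(cs)[["other"]]), 0.05)
  }
})

test_that("sequencing error shifts observed frequency symmetrically", {
  p <- simulationParams(1, 1e6, siteDensity = 0.1, repeatFraction = 0,
                        coveragePerCopy = 5, sequencingError = 0.1,
                        seed = 13)
  ref <- simulateReference(p)
  truth <- injectKaryotype(ref, data.frame(
    accession = "a", pair = 1, start = 1, end = 1e6, cRef = 4, cOther = 0))
  obs <- simulateObservables(ref, truth, p, accessions = "a")$a
  fHat <- sum(obs$siteDepth$refCount) /
    sum(obs$siteDepth$refCount + obs$siteDepth$altCount)
  # f(1-e) + (1-f)e with f = 1, e = 0.1 -> 0.9
  expect_lt(abs(fHat - 0.9), 0.005)
})

test_that("event requests are validated", {
  ref <- simulateReference(smallParams(seed = 3L))
  expect_error(injectKaryotype(ref, data.frame(
    accession = "a", pair = 1, start = 1, end = 9e9, cRef = 3, cOther = 1)),
    "bounds")
  expect_error(injectKaryotype(ref, data.frame(
    accession = "a", pair = 1, start = 1, end = 1e6, cRef = 5, cOther = 0)),
    "0..4")
  expect_error(injectKaryotype(ref, data.frame(
    accession = "a", pair = 1, start = c(1, 5e5), end = c(1e6, 8e5),
    cRef = 3, cOther = 1)), "overlap")
  tr <- injectKaryotype(ref, NULL, accessions = "a")
  expect_length(truthEvents(tr), 0L)
  # whole-chromosome gain is aneuploidy; terminal segment is an exchange
  tr2 <- injectKaryotype(ref, data.frame(
    accession = "a", pair = 1:2, start = 1, end = c(3e6, 1e6),
    cRef = c(3, 3), cOther = c(2, 1)))
  expect_equal(truthEvents(tr2)$type,
               c("aneuploidy_gain", "homoeologous_exchange"))
  expect_equal(truthEvents(tr2)$zygosity, rep("heterozygous", 2))
})

test_that("panel diversity matches the target and blocks are recorded", {
  p <- simulationParams(1, 5e6, siteDensity = 0.005, repeatFraction = 0.4,
                        panelPi = 3e-4, seed = 41)
  ref <- simulateReference(p)
  panel <- simulatePanel(ref, 20, p)
  U <- 5e6 - sum(width(repeatMask(ref)))
  g <- panel$genotypes
  called <- 2 * ncol(g)
  pHat <- rowSums(g) / called
  h <- (called / (called - 1)) * 2 * pHat * (1 - pHat)
  piHat <- sum(h) / U
  expect_lt(abs(piHat - 3e-4) / 3e-4, 0.2)
  expect_length(panel$blocks, 0L)
  # one block for one accession: truth lists exactly that interval
  blk <- data.frame(accession = 3, pair = 1, start = 1e6, end = 3e6)
  panelB <- simulatePanel(ref, 20, p, introgression = blk)
  expect_length(panelB$blocks, 1L)
  expect_equal(start(panelB$blocks), 1e6)
  expect_equal(end(panelB$blocks), 3e6)
  expect_equal(panelB$blocks$accession, "acc3")
  # multiplier 1: no distinguishable block, truth stays empty
  p1 <- simulationParams(1, 5e6, siteDensity = 0.005, repeatFraction = 0.4,
                         panelPi = 3e-4, introgressionPiMultiplier = 1,
                         seed = 41)
  panel1 <- simulatePanel(simulateReference(p1), 20, p1,
                          introgression = blk)
  expect_length(panel1$blocks, 0L)
})
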