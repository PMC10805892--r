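library(GenomicRanges)

test_that("window frequency is the depth-weighted pooled fraction", {
  expect_equal(homoeologousFrequency(rep(10, 5), rep(10, 5)), 0.5)
  expect_equal(homoeologousFrequency(rep(30, 5), rep(10, 5)), 0.75)
  expect_equal(homoeologousFrequency(7, 3), 0.7)
  expect_true(is.na(homoeologousFrequency(integer(0), integer(0))))
  expect_true(is.na(homoeologousFrequency(c(0, 0), c(0, 0))))
})

test_that("ROH_H statistic equals the per-site chi-square oracle", {
  expect_equal(rohHStatistic(rep(5, 4), rep(5, 4))$chi2, 0)
  expect_equal(rohHStatistic(30, 10)$chi2, 10)
  # exhaustive small-instance equivalence: random windows of <= 10 sites
  # with depths <= 20, against an independently written Pearson oracle
  set.seed(9)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    a <- sample(0:20, n, replace = TRUE)
    b <- sample(0:20, n, replace = TRUE)
    if (all(a + b == 0)) next
    got <- rohHStatistic(a, b)
    want <- chisqOracle(a, b)
    expect_equal(got$chi2, want$chi2)
    expect_equal(got$df, want$df)
  }
  expect_true(is.na(rohHStatistic(integer(0), integer(0))$chi2))
})

test_that("balanced windows give chi2 close to its degrees of freedom", {
  set.seed(10)
  depth <- rpois(500, 40)
  a <- rbinom(500, depth, 0.5)
  st <- rohHStatistic(a, depth - a)
  # mean of a chi-square equals df; allow 4 sd = 4 * sqrt(2 df)
  expect_lt(abs(st$chi2 - st$df), 4 * sqrt(2 * st$df))
})

test_that("doc ratio is 1 for self-comparison and scales with copies", {
  cov <- data.frame(chrom = "c", start = seq(1, 1e6, 1e5),
                    end = seq(1e5, 1e6, 1e5), nonrepBp = 1e5,
                    covA = runif(10, 5, 15), covB = runif(10, 5, 15))
  doc <- docRatio(cov, cov)
  expect_equal(doc$docA, rep(1, 10))
  expect_equal(doc$docB, rep(1, 10))
  # median normalization cancels library-size differences
  cov2 <- cov
  cov2$covA <- cov$covA * 3.7
  cov2$covB <- cov$covB * 3.7
  doc2 <- docRatio(cov2, cov)
  expect_equal(doc2$docA, rep(1, 10))
  expect_error(docRatio(cov[1:5, ], cov[6:10, ]), "window set")
})

test_that("catalog derivation keeps balanced sites at depth", {
  cand <- GRanges("c", IRanges(1:4, 1:4))
  sd <- data.frame(chrom = "c", pos = 1:4,
                   refCount = c(20, 39, 5, 12),
                   altCount = c(20, 1, 4, 12))
  kept <- deriveHomoeologousCatalog(sd, cand)
  # 20/20 balanced: kept; 39/1 off-band: dropped; 5/4 below depth:
  # dropped; 12/12 balanced: kept
  expect_equal(start(kept), c(1, 4))
  # recovery on a simulated euploid accession at high depth
  p <- simulationParams(1, 1e6, siteDensity = 0.01, repeatFraction = 0,
                        coveragePerCopy = 20, sequencingError = 0,
                        seed = 51)
  ref <- simulateReference(p)
  obs <- simulateObservables(ref, injectKaryotype(ref, NULL), p,
                             accessions = "ref")$ref
  kept2 <- deriveHomoeologousCatalog(obs$siteDepth, siteCatalog(ref))
  expect_gte(length(kept2) / length(siteCatalog(ref)), 0.95)
})

test_that("copy-state fitting reproduces the expectation grid exactly", {
  for (st in list(c(4, 0), c(3, 1), c(2, 2), c(1, 3), c(0, 2), c(3, 2),
                  c(1, 2), c(0, 4))) {
    cs <- copyState(st[1], st[2])
    ft <- fitCopyState(expectedFrequency(cs),
                       expectedDoc(cs)[["ref"]],
                       expectedDoc(cs)[["other"]])
    expect_equal(ft$state@cRef, st[1])
    expect_equal(ft$state@cOther, st[2])
    expect_false(ft$mosaic)
    expect_equal(ft$residual, 0)
  }
})

test_that("mosaic mixtures are fitted with the parsimonious state", {
  # dense-enumeration oracle over states and m for the spec observation
  grid <- expand.grid(cA = 0:4, cB = 0:4, m = seq(0, 1, 5e-4))
  grid <- grid[grid$cA + grid$cB <= 5 & !(grid$cA == 2 & grid$cB == 2), ]
  effA <- grid$m * grid$cA + (1 - grid$m) * 2
  effB <- grid$m * grid$cB + (1 - grid$m) * 2
  res <- (0.625 - effA / (effA + effB))^2 + (1.25 - effA / 2)^2 +
    (0.75 - effB / 2)^2
  best <- grid[!is.na(res) & res < min(res, na.rm = TRUE) + 1e-9, ]
  # the oracle confirms (3,1) at m = 0.5 attains the optimum
  expect_true(any(best$cA == 3 & best$cB == 1 & abs(best$m - 0.5) < 1e-3))
  ft <- fitCopyState(0.625, 1.25, 0.75)
  expect_true(ft$mosaic)
  expect_equal(ft$state@cRef, 3L)
  expect_equal(ft$state@cOther, 1L)
  expect_equal(ft$state@m, 0.5, tolerance = 1e-3)
  # a pure-state observation is never degraded to a mosaic
  ftPure <- fitCopyState(0.751, 1.497, 0.502)
  expect_false(ftPure$mosaic)
  expect_equal(ftPure$state@cRef, 3L)
  # all-missing observations yield no fit
  expect_null(fitCopyState(NA, NA, NA))
})

test_that("an injected heterozygous exchange is recovered as one event", {
  inp <- simScanInput(data.frame(accession = "test", pair = 1,
                                 start = 1e6, end = 2e6,
                                 cRef = 3, cOther = 1),
                      params = smallParams(seed = 61L))
  sc <- karyotypeScan(inp$siteDepth, inp$coverage, inp$refCoverage,
                      accession = "test")
  ev <- sc$events
  expect_length(ev, 1L)
  expect_equal(ev$type, "homoeologous_exchange")
  expect_equal(ev$zygosity, "heterozygous")
  expect_equal(ev$cRef, 3L)
  expect_equal(ev$cOther, 1L)
  # exchanges conserve total doc: docA + docB ~ 2 over the event
  obs <- sc$observations
  inEv <- obs$chrom == "chr1_A" & obs$start >= start(ev) &
    obs$end <= end(ev)
  expect_lt(abs(mean(obs$docA[inEv] + obs$docB[inEv]) - 2), 0.1)
})

test_that("a whole-chromosome trisomy is classified as aneuploidy gain", {
  # three pairs so the genome-wide median coverage stays anchored by the
  # euploid chromosomes
  p3 <- simulationParams(nChromosomePairs = 3L, chromosomeLength = 3e6,
                         siteDensity = 0.005, repeatFraction = 0.4,
                         coveragePerCopy = 2, seed = 62L)
  inp <- simScanInput(data.frame(accession = "test", pair = 2,
                                 start = 1, end = 3e6,
                                 cRef = 3, cOther = 2),
                      params = p3)
  sc <- karyotypeScan(inp$siteDepth, inp$coverage, inp$refCoverage,
                      accession = "test")
  ev <- sc$events[sc$events$type == "aneuploidy_gain"]
  expect_length(ev, 1L)
  expect_equal(as.character(seqnames(ev)), "chr2_A")
  expect_equal(ev$cRef, 3L)
  expect_equal(ev$cOther, 2L)
})

test_that("a euploid accession yields no events", {
  inp <- simScanInput(NULL, params = smallParams(seed = 63L))
  sc <- karyotypeScan(inp$siteDepth, inp$coverage, inp$refCoverage,
                      accession = "test")
  expect_length(sc$events, 0L)
})

test_that("deletions violate total-doc conservation in the fitted direction", {
  inp <- simScanInput(data.frame(accession = "test", pair = 1,
                                 start = 1, end = 1.2e6,
                                 cRef = 1, cOther = 2),
                      params = smallParams(seed = 64L))
  sc <- karyotypeScan(inp$siteDepth, inp$coverage, inp$refCoverage,
                      accession = "test")
  ev <- sc$events
  expect_length(ev, 1L)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$zygosity, "heterozygous")
  obs <- sc$observations
  inEv <- obs$chrom == "chr1_A" & obs$end <= end(ev)
  expect_lt(mean(obs$docA[inEv] + obs$docB[inEv]), 2 - 0.25)
})
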