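library(GenomicRanges)

test_that("window pi follows the unbiased heterozygosity estimator", {
  # one site, 2 of 4 called allele copies alternative, 100 kb window:
  # (4/3) * 2 * 0.5 * 0.5 / 1e5
  got <- windowPi(matrix(c(1, 1), nrow = 1), nonrepBp = 1e5)
  expect_equal(got$pi, (4 / 3) * 0.5 / 1e5)
  # monomorphic window
  expect_equal(windowPi(matrix(0L, 3, 4), 1e5)$pi, 0)
  # empty window
  z <- windowPi(matrix(integer(0), 0, 4), 1e5)
  expect_equal(z$pi, 0)
  # no callable sites: pi = 0 with the missingness flag
  miss <- windowPi(matrix(NA_integer_, 2, 4), 1e5)
  expect_equal(miss$pi, 0)
  expect_true(miss$missing)
  # missing genotypes reduce the called allele count n_j
  g <- matrix(c(1L, 1L, NA, NA), nrow = 1)
  expect_equal(windowPi(g, 1e5)$pi, (4 / 3) * 2 * 0.5 * 0.5 / 1e5)
})

test_that("pi is invariant under allele relabeling", {
  set.seed(17)
  g <- matrix(sample(0:2, 50 * 8, replace = TRUE), 50, 8)
  expect_equal(windowPi(g, 1e5)$pi, windowPi(2L - g, 1e5)$pi)
})

test_that("introgressed windows are flagged and merged into blocks", {
  p <- simulationParams(1, 8e6, siteDensity = 0.005, repeatFraction = 0.4,
                        panelPi = 3e-4, introgressionPiMultiplier = 10,
                        seed = 71)
  ref <- simulateReference(p)
  blk <- data.frame(accession = 2, pair = 1, start = 2e6, end = 4e6)
  panel <- simulatePanel(ref, 20, p, introgression = blk)
  windows <- referenceWindows(ref)
  div <- diversityWindows(panel$sites, panel$genotypes, windows)
  # baseline excludes the carrier
  flagged <- flagIntrogressedWindows(div, setdiff(panel$accessions, "acc2"))
  inBlock <- overlapsAny(windows, panel$blocks, minoverlap = 50000L)
  # >= 90% of the block's windows flagged for the carrier
  expect_gte(mean(flagged$flags[inBlock, "acc2"]), 0.9)
  # baseline accessions essentially unflagged
  expect_lt(mean(flagged$flags[, "acc1"]), 0.05)
  # heterozygous block -> flagged windows labeled heterozygous
  expect_true(all(flagged$zygosity[inBlock, "acc2"][
    flagged$flags[inBlock, "acc2"]] == "heterozygous"))
  # merged block recovers the injected interval within one window
  blocks <- mergeBlocks(flagged, windows, "acc2")
  expect_length(blocks, 1L)
  wWidth <- median(width(windows))
  expect_lt(abs(start(blocks) - 2e6), 2 * wWidth)
  expect_lt(abs(end(blocks) - 4e6), 2 * wWidth)
  expect_equal(blocks$zygosity, "heterozygous")
  # window pi inside the block recovers the multiplier within +/-30%
  ratio <- median(div$pi[inBlock]) / median(div$pi[!inBlock])
  expect_lt(abs(ratio - 10) / 10, 0.3)
  # simulated panel median window pi within +/-20% of the target
  expect_lt(abs(median(div$pi[!inBlock]) - 3e-4) / 3e-4, 0.2)
})

test_that("accessions at the baseline median are not flagged", {
  counts <- matrix(rpois(200, 40), 50, 4,
                   dimnames = list(NULL, paste0("acc", 1:4)))
  div <- list(counts = counts, hetCounts = counts,
              homCounts = counts * 0L)
  flagged <- flagIntrogressedWindows(div, paste0("acc", 1:4))
  expect_false(any(flagged$flags))
  # degenerate all-zero baseline floors the threshold at 5 SNPs
  div0 <- list(counts = matrix(0L, 10, 2,
                               dimnames = list(NULL, c("a", "b"))),
               hetCounts = matrix(0L, 10, 2), homCounts = matrix(0L, 10, 2))
  flagged0 <- flagIntrogressedWindows(div0, c("a", "b"))
  expect_equal(flagged0$threshold, 5)
})

test_that("block merging respects the gap tolerance", {
  win <- GRanges("c", IRanges(seq(1, 1e6, 1e5), width = 1e5),
                 nonrepBp = 1e5)
  mk <- function(idx) {
    f <- matrix(FALSE, 10, 1, dimnames = list(NULL, "a"))
    f[idx, 1] <- TRUE
    z <- matrix(NA_character_, 10, 1, dimnames = list(NULL, "a"))
    z[idx, 1] <- "heterozygous"
    list(flags = f, zygosity = z, counts = f * 100)
  }
  one <- mergeBlocks(mk(3:7), win, "a")
  expect_length(one, 1L)
  expect_equal(start(one), start(win)[3])
  expect_equal(end(one), end(win)[7])
  expect_equal(one$nWindows, 5L)
  # flags on 3-5 and 8-9 with gap tolerance 1 -> two blocks
  two <- mergeBlocks(mk(c(3:5, 8:9)), win, "a", gapTol = 1L)
  expect_length(two, 2L)
  # gap tolerance 2 merges them
  merged <- mergeBlocks(mk(c(3:5, 8:9)), win, "a", gapTol = 2L)
  expect_length(merged, 1L)
  # no flags -> empty
  expect_length(mergeBlocks(mk(integer(0)), win, "a"), 0L)
})
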