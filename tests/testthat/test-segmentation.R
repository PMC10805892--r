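library(GenomicRanges)

test_that("unmasked genome tiles into equal windows", {
  w <- segmentByNonrepetitive(3e5, GRanges(), W = 1e5, chrom = "c")
  expect_equal(length(w), 3L)
  expect_equal(start(w), c(1, 100001, 200001))
  expect_equal(end(w), c(100000, 200000, 300000))
  expect_equal(w$nonrepBp, rep(1e5, 3))
  expect_false(any(w$partial))
})

test_that("masked prefix stretches the first window", {
  mask <- GRanges("c", IRanges(1, 150000))  # 0-based [0, 150kb)
  w <- segmentByNonrepetitive(3e5, mask, W = 1e5, chrom = "c")
  # prefix-sum oracle: unmasked positions start at 150001, so 100 kb of
  # unmasked content is reached at base 250000
  expect_equal(start(w)[1], 1)
  expect_equal(end(w)[1], 250000)
  expect_equal(w$nonrepBp[1], 1e5)
  expect_equal(w$nonrepBp[2], 5e4)
  expect_true(w$partial[2])
})

test_that("fully masked chromosome yields zero windows", {
  w <- segmentByNonrepetitive(1e5, GRanges("c", IRanges(1, 1e5)),
                              W = 1e4, chrom = "c")
  expect_equal(length(w), 0L)
})

test_that("window content sums to the unmasked length and windows tile", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    s <- sort(sample.int(9e5, n))
    mask <- reduce(GRanges("c", IRanges(s, s + sample.int(5e4, n))))
    mask <- restrict(mask, start = 1L, end = 1e6L)
    w <- segmentByNonrepetitive(1e6, mask, W = 5e4, chrom = "c")
    unmasked <- 1e6 - sum(width(mask))
    expect_equal(sum(w$nonrepBp), unmasked)
    # tiling: sorted, non-overlapping, contiguous, covering the chromosome
    expect_equal(start(w)[1], 1)
    expect_equal(end(w)[length(w)], 1e6)
    if (length(w) > 1)
      expect_equal(start(w)[-1], end(w)[-length(w)] + 1)
    # every non-terminal window holds exactly W unmasked bp
    expect_equal(w$nonrepBp[-length(w)], rep(5e4, length(w) - 1L))
  }
})

test_that("segmentation is idempotent on concatenated unmasked content", {
  mask <- GRanges("c", IRanges(c(1, 250001, 700001),
                               c(120000, 400000, 730000)))
  w <- segmentByNonrepetitive(1e6, mask, W = 1e5, chrom = "c")
  unmaskedTotal <- sum(w$nonrepBp)
  # concatenating the unmasked content gives a mask-free chromosome whose
  # re-segmentation has boundaries at multiples of W
  w2 <- segmentByNonrepetitive(unmaskedTotal, GRanges(), W = 1e5,
                               chrom = "c")
  expect_equal(w2$nonrepBp, w$nonrepBp)
  expect_equal(length(w2), length(w))
  # and cumulative unmasked content at the right boundary agrees
  expect_equal(end(w2), cumsum(w$nonrepBp))
})

test_that("non-positive window content is refused", {
  expect_error(segmentByNonrepetitive(1e5, GRanges(), W = 0))
})

test_that("sliding windows advance by step and stop at the last site", {
  pos <- seq_len(1000) * 100
  w <- slidingVariantWindows(pos, nSites = 500, step = 250)
  expect_equal(w$firstSite, c(1, 251, 501))
  expect_equal(w$lastSite, c(500, 750, 1000))
  expect_equal(w$n, c(500, 500, 500))
  # consecutive windows share nSites - step sites
  expect_equal(w$firstSite[-1] + (500 - 250) - 1,
               w$lastSite[-length(w$lastSite)])
  expect_equal(w$start, pos[w$firstSite])
  expect_equal(w$end, pos[w$lastSite])
})

test_that("short chromosomes give a single window of all sites", {
  expect_equal(nrow(slidingVariantWindows(seq_len(400), 500, 250)), 1L)
  expect_equal(slidingVariantWindows(seq_len(400), 500, 250)$n, 400L)
  w <- slidingVariantWindows(seq_len(500), 500, 250)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n, 500L)
})

test_that("step larger than window size is refused", {
  expect_error(slidingVariantWindows(1:10, nSites = 5, step = 6))
})
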