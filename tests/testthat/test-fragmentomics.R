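fragGr <- function(start0, len, chrom = "chr1") {
  GRanges(chrom, IRanges(start0 + 1L, start0 + len))
}

test_that("length histograms count and normalize correctly", {
  fr <- fragGr(c(0, 100, 200, 300), c(166, 167, 167, 168))
  h <- lengthHistogram(fr, binWidth = 1L)
  expect_identical(h$count[h$length == 167], 2L)
  hd <- lengthHistogram(fr, binWidth = 4L, density = TRUE)
  expect_equal(sum(hd$density), 1)
  expect_error(lengthHistogram(GRanges()), "empty")
})

test_that("genome binning drops terminal tiles, blacklist bins and attaches GC", {
  expect_length(binGenome(c(chr1 = 1e6), binWidth = 1e5), 10L)
  expect_length(binGenome(c(chr1 = 1.05e6), binWidth = 1e5), 10L)
  bl <- GRanges("chr1", IRanges(250000L, 250100L))  # hits bin 3
  expect_length(binGenome(c(chr1 = 1e6), binWidth = 1e5, blacklist = bl),
                9L)
  expect_length(binGenome(c(chr1 = 1e6, chrX = 1e6), binWidth = 1e5), 10L)
  expect_error(binGenome(c(chr1 = 5e4), binWidth = 1e5), "no bins")

  # length-weighted GC: a bin covered half by gc 0.3 and half by gc 0.5
  track <- GRanges("chr1", IRanges(c(1L, 50001L), c(50000L, 100000L)))
  S4Vectors::mcols(track)$gc <- c(0.3, 0.5)
  b <- binGenome(c(chr1 = 1e5), binWidth = 1e5, gcTrack = track)
  expect_equal(as.numeric(S4Vectors::mcols(b)$gc), 0.4)
})

test_that("short/long classification uses the inclusive boundary lengths", {
  bins <- binGenome(c(chr1 = 1e6), binWidth = 1e5)
  fr <- fragGr(rep(1000L, 5), c(79L, 80L, 150L, 151L, 251L))
  p <- countShortLong(fr, bins)
  m <- S4Vectors::mcols(p)
  expect_identical(sum(m$short), 2L)   # 80 and 150
  expect_identical(sum(m$long), 1L)    # 151
  expect_identical(sum(m$total), 3L)   # 80, 150, 151; 79 and 251 excluded

  # midpoint assignment: fragment [99950, 100050) has midpoint 100000,
  # the first base of bin 2
  edge <- fragGr(99950L, 100L)
  pe <- countShortLong(edge, bins)
  expect_identical(S4Vectors::mcols(pe)$short[2], 1L)
  expect_identical(S4Vectors::mcols(pe)$short[1], 0L)
})

test_that("bin counting agrees with a per-fragment brute-force scan", {
  set.seed(31)
  bins <- binGenome(c(chr1 = 1e6, chr2 = 5e5), binWidth = 1e5)
  n <- 10000
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE, prob = c(2, 1))
  maxPos <- c(chr1 = 1e6, chr2 = 5e5)[chrom] - 400
  start0 <- floor(runif(n) * maxPos)
  len <- sample(60:300, n, replace = TRUE)
  fr <- GRanges(chrom, IRanges(start0 + 1L, start0 + len))
  p <- countShortLong(fr, bins)

  # oracle: arithmetic bin index from the midpoint, per fragment
  binKey <- paste0(as.character(seqnames(bins)), ":",
                   (start(bins) - 1L) %/% 1e5)
  oShort <- oLong <- oTotal <- stats::setNames(integer(length(bins)),
                                               binKey)
  for (i in seq_len(n)) {
    mid <- (start0[i] + start0[i] + len[i]) %/% 2
    key <- paste0(chrom[i], ":", mid %/% 1e5)
    if (!key %in% binKey) next
    if (len[i] >= 80 && len[i] <= 150) oShort[key] <- oShort[key] + 1L
    if (len[i] >= 151 && len[i] <= 250) oLong[key] <- oLong[key] + 1L
    if (len[i] >= 80 && len[i] <= 250) oTotal[key] <- oTotal[key] + 1L
  }
  expect_identical(S4Vectors::mcols(p)$short, unname(oShort))
  expect_identical(S4Vectors::mcols(p)$long, unname(oLong))
  expect_identical(S4Vectors::mcols(p)$total, unname(oTotal))
})

test_that("LOWESS GC correction removes monotone bias and preserves the mean", {
  set.seed(41)
  gc <- runif(400, 0.3, 0.6)
  flat <- rep(50, 400)
  expect_equal(gcCorrect(flat, gc), flat, tolerance = 1e-9)

  biased <- 100 + 120 * gc + rnorm(400, sd = 3)
  corrected <- gcCorrect(biased, gc)
  expect_lt(abs(cor(corrected, gc)), 0.1)
  expect_gt(abs(cor(biased, gc)), 0.9)
  expect_equal(mean(corrected), mean(biased), tolerance = 1e-6)

  # constant GC: correction degenerates to the identity
  expect_identical(gcCorrect(biased, rep(0.5, 400)), biased)
  expect_error(gcCorrect(1:5, runif(5)), "10 bins")
})

test_that("window aggregation sums bins, computes RoSL and flags missing", {
  bins <- binGenome(c(chr1 = 1e7), binWidth = 1e5)  # 100 bins
  S4Vectors::mcols(bins)$short <- rep(2L, 100)
  S4Vectors::mcols(bins)$long <- rep(1L, 100)
  S4Vectors::mcols(bins)$total <- rep(3L, 100)
  S4Vectors::mcols(bins)$corrected_short <- rep(2, 100)
  S4Vectors::mcols(bins)$corrected_long <- rep(1, 100)
  S4Vectors::mcols(bins)$corrected_total <- rep(3, 100)
  w <- aggregateWindows(bins, windowWidth = 5e6)  # 50 bins per window
  expect_identical(nrow(w), 2L)
  expect_equal(w$short, c(100, 100))
  expect_equal(w$rosl, c(2, 2))

  # a window with no long fragments has missing RoSL
  S4Vectors::mcols(bins)$long[1:50] <- 0L
  w2 <- aggregateWindows(bins, windowWidth = 5e6)
  expect_true(is.na(w2$rosl[1]))
  expect_false(is.na(w2$rosl[2]))

  expect_error(aggregateWindows(bins, windowWidth = 2.5e5), "multiple")
})

test_that("median healthy profile follows the stated median conventions", {
  mk <- function(rosl) data.frame(window_id = paste0("w", seq_along(rosl)),
                                  rosl = rosl)
  one <- medianHealthyProfile(list(mk(c(1.5, 2.5))))
  expect_equal(unname(one), c(1.5, 2.5))
  expect_equal(unname(medianHealthyProfile(list(mk(1), mk(2), mk(9)))), 2)
  expect_equal(unname(medianHealthyProfile(list(mk(1), mk(3)))), 2)
  # missing values fall back to the median of the non-missing ones
  expect_equal(unname(medianHealthyProfile(list(mk(NA), mk(4), mk(6)))), 5)
})

test_that("profile correlation matches the textbook formula and flags degeneracy", {
  set.seed(51)
  x <- stats::setNames(runif(100), paste0("w", 1:100))
  y <- stats::setNames(runif(100), paste0("w", 1:100))
  expect_equal(profileCorrelation(x, y), oraclePearson(x, y),
               tolerance = 1e-12)
  expect_equal(profileCorrelation(x, x), 1)
  expect_equal(profileCorrelation(x, -x + 3), -1)
  expect_error(profileCorrelation(x[1:2], y[1:2]), "3 shared")
  expect_error(profileCorrelation(stats::setNames(rep(1, 5), names(x)[1:5]),
                                  y[1:5]), "zero variance")
})

test_that("fragmentation features are per-sample standardized and affine-invariant", {
  mk <- function(short, total) {
    data.frame(window_id = paste0("w", seq_along(short)),
               short = short, total = total)
  }
  set.seed(61)
  p1 <- mk(runif(10), runif(10))
  p2 <- mk(runif(10), runif(10))
  fm <- fragmentationFeatures(list(a = p1, b = p2),
                              group = c("cancer", "healthy"))
  vals <- featureValues(fm)
  expect_identical(ncol(vals), 20L)
  shortBlock <- vals[, startsWith(colnames(vals), "short@")]
  expect_equal(unname(rowMeans(shortBlock)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(shortBlock, 1, sd)), c(1, 1), tolerance = 1e-9)

  # affine transform of the raw coverages leaves z-scores unchanged
  p1b <- mk(3 * p1$short + 7, 3 * p1$total + 7)
  fmB <- fragmentationFeatures(list(a = p1b, b = p2),
                               group = c("cancer", "healthy"))
  expect_equal(featureValues(fmB), vals, tolerance = 1e-9)

  expect_error(fragmentationFeatures(list(a = mk(rep(1, 10), runif(10)))),
               "zero within-sample variance")
})
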