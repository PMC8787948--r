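summitGr <- function(pos1, score, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(pos1, pos1))
  S4Vectors::mcols(gr)$score <- score
  gr
}

test_that("summits extend to 201-bp fixed-width peaks with scores carried over", {
  # BED summit chr1:5000-5001 reads as 1-based position 5001
  s <- summitGr(5001L, score = 10)
  p <- fixedWidthPeaks(s)
  expect_identical(start(p), 4901L)  # BED start 4900
  expect_identical(end(p), 5101L)
  expect_identical(width(p), 201L)
  expect_identical(S4Vectors::mcols(p)$score, 10)

  s3 <- summitGr(c(1000L, 2000L, 3000L), score = c(1, 2, 3))
  p3 <- fixedWidthPeaks(s3)
  expect_length(p3, 3L)
  expect_identical(S4Vectors::mcols(p3)$score, c(1, 2, 3))

  # a summit near the chromosome start extends to negative coordinates,
  # and filterPeaks removes it
  pEdge <- fixedWidthPeaks(summitGr(51L, score = 5))
  expect_lt(start(pEdge), 1L)
  kept <- filterPeaks(scorePerMillion(pEdge), c(chr1 = 1e6L))
  expect_length(kept, 0L)
})

test_that("score-per-million normalizes to a one-million total", {
  p <- makePeaks(c(1000L, 5000L), score = c(5, 15))
  sp <- scorePerMillion(p)
  expect_equal(S4Vectors::mcols(sp)$spm, c(250000, 750000))

  single <- scorePerMillion(makePeaks(100L, score = 7))
  expect_equal(S4Vectors::mcols(single)$spm, 1e6)

  set.seed(11)
  rnd <- scorePerMillion(makePeaks(seq(1000L, 100000L, by = 1000L),
                                   score = runif(100, 0, 50)))
  expect_equal(sum(S4Vectors::mcols(rnd)$spm), 1e6, tolerance = 1e-6)

  expect_error(scorePerMillion(makePeaks(1L, score = 0)), "zero")
})

test_that("overlap removal keeps the greedy spm-ranked non-overlapping set", {
  # A chr1:100-301 spm 10 beats overlapping B chr1:200-401 spm 5
  ab <- makePeaks(c(101L, 201L), spm = c(10, 5))
  kept <- removeOverlaps(ab)
  expect_identical(start(kept), 101L)

  # abutting half-open intervals do not overlap
  abut <- makePeaks(c(101L, 302L), spm = c(10, 5))
  expect_length(removeOverlaps(abut), 2L)

  # equal spm: the peak with the smaller start wins
  tie <- makePeaks(c(201L, 101L), spm = c(7, 7))
  expect_identical(start(removeOverlaps(tie)), 101L)
})

test_that("overlap removal matches a brute-force interval oracle and is idempotent", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    start0 <- sample.int(5000, n, replace = TRUE)
    w <- sample(50:300, n, replace = TRUE)
    spm <- round(runif(n, 0, 100), 3)
    gr <- GRanges("chr1", IRanges(start0 + 1L, start0 + w))
    S4Vectors::mcols(gr)$spm <- spm

    kept <- removeOverlaps(gr)

    # oracle: same greedy rule, but overlap decided by exhaustive pairwise
    # arithmetic on half-open intervals
    ord <- order(-spm, start0)
    keep <- logical(n)
    for (i in ord) {
      ok <- TRUE
      for (j in which(keep)) {
        if (oracleOverlaps(start0[i], start0[i] + w[i],
                           start0[j], start0[j] + w[j])) {
          ok <- FALSE
          break
        }
      }
      keep[i] <- ok
    }
    expected <- sort(paste0(start0[keep], "-", start0[keep] + w[keep]))
    got <- sort(paste0(start(kept) - 1L, "-", end(kept)))
    expect_identical(got, expected)

    # idempotence
    expect_identical(start(removeOverlaps(kept)), start(kept))
  }
})

test_that("reproducible peaks honour the support-fraction and spm thresholds", {
  mk <- function(start1, spm) makePeaks(start1, spm = spm)
  # 10 samples; locus A present in 1 sample with spm >= 5: ceil(0.1*10)=1
  # supporting sample suffices
  sets <- c(list(mk(1001L, 8)), replicate(9, mk(90001L, 9),
                                          simplify = FALSE))
  names(sets) <- paste0("s", 1:10)
  rp <- reproduciblePeaks(sets, minFraction = 0.10, minSpm = 5)
  expect_true(any(start(rp) == 1001L))

  # a peak seen only below the spm threshold is dropped
  sets2 <- c(list(mk(1001L, 4.9)), replicate(9, mk(90001L, 9),
                                             simplify = FALSE))
  names(sets2) <- paste0("s", 1:10)
  rp2 <- reproduciblePeaks(sets2, minFraction = 0.10, minSpm = 5)
  expect_false(any(start(rp2) == 1001L))

  # degenerate single sample: all of its spm >= 5 non-overlapping peaks kept
  solo <- list(s1 = mk(c(1001L, 5001L, 9001L), spm = c(6, 5, 4)))
  rp3 <- reproduciblePeaks(solo)
  expect_identical(start(rp3), c(1001L, 5001L))
})

test_that("consensus merging unions group lists and resolves cross-group overlaps", {
  a <- makePeaks(c(1001L, 3001L, 5001L), spm = c(5, 6, 7))
  b <- makePeaks(c(10001L, 12001L, 14001L, 16001L), spm = 1:4)
  cons <- consensusPeaks(a, b)
  expect_length(cons, 7L)
  expect_identical(names(cons)[1L], "chr1:1000-1201")

  # idempotence on identical inputs
  same <- consensusPeaks(a, a)
  expect_identical(start(same), sort(start(a)))

  # one overlapping pair across groups: the higher-spm peak survives
  x <- makePeaks(1001L, spm = 9)
  y <- makePeaks(1101L, spm = 3)
  expect_identical(start(consensusPeaks(x, y)), 1001L)
  expect_identical(start(consensusPeaks(y, x)), 1001L)
})

test_that("peak filtering removes blacklist, out-of-bounds and excluded chromosomes", {
  sizes <- c(chr1 = 100000L, chr2 = 100000L)
  bl <- GRanges("chr1", IRanges(50001L, 52000L))
  gr <- suppressWarnings(
    c(makePeaks(50101L, spm = 1),            # inside blacklist
      makePeaks(1001L, spm = 1),             # clean
      makePeaks(99950L, spm = 1),            # runs off chr1 end
      makePeaks(1001L, spm = 1, chrom = "chrX")))
  out <- filterPeaks(gr, sizes, blacklist = bl)
  expect_length(out, 1L)
  expect_identical(start(out), 1001L)
  # idempotent
  expect_identical(filterPeaks(out, sizes, blacklist = bl), out)
  expect_error(filterPeaks(makePeaks(1L, spm = 1, chrom = "chr9"), sizes),
               "chr9")
})

test_that("FPKM follows the counting formula and its scaling laws", {
  peak <- makePeaks(10001L)
  names(peak) <- "chr1:10000-10201"
  frag10 <- GRanges("chr1", IRanges(rep(10050L, 10), rep(10150L, 10)))
  fm <- quantifyFpkm(list(s1 = frag10), peak,
                     librarySizes = c(s1 = 1e6))
  expect_equal(unname(featureValues(fm)[1, 1]), 10 / 0.201,
               tolerance = 1e-12)

  # no overlap -> 0; doubling the library halves FPKM
  farAway <- GRanges("chr1", IRanges(500000L, 500100L))
  fm0 <- quantifyFpkm(list(s1 = farAway), peak, librarySizes = c(s1 = 1e6))
  expect_identical(unname(featureValues(fm0)[1, 1]), 0)
  fm2 <- quantifyFpkm(list(s1 = frag10), peak,
                      librarySizes = c(s1 = 2e6))
  expect_equal(featureValues(fm2)[1, 1], featureValues(fm)[1, 1] / 2)

  expect_error(quantifyFpkm(list(s1 = frag10), peak,
                            librarySizes = c(s1 = 0)), "positive")
})

test_that("fragment-in-peak counting agrees with the brute-force oracle", {
  set.seed(13)
  nP <- 40
  pStart0 <- sort(sample.int(200000, nP)) * 1L
  peaks <- GRanges("chr1", IRanges(pStart0 + 1L, pStart0 + 201L))
  names(peaks) <- sprintf("chr1:%d-%d", pStart0, pStart0 + 201L)
  nF <- 2000
  fStart0 <- sample.int(210000, nF, replace = TRUE) * 1L
  fLen <- sample(80:250, nF, replace = TRUE)
  frags <- GRanges("chr1", IRanges(fStart0 + 1L, fStart0 + fLen))
  fm <- quantifyFpkm(list(s = frags), peaks, librarySizes = c(s = nF))
  got <- featureValues(fm)[1, ] * (0.201 * nF / 1e6)
  exp <- oracleCountOverlaps(pStart0, pStart0 + 201L, fStart0,
                             fStart0 + fLen)
  expect_equal(unname(got), as.numeric(exp), tolerance = 1e-9)
})

test_that("spike-in capture efficiency returns fractions summing to one", {
  eff <- spikeInEfficiency(c(hmC = 97, mC = 2, C = 1))
  expect_equal(unname(eff), c(0.97, 0.02, 0.01))
  expect_equal(unname(spikeInEfficiency(c(only = 12))), 1)
  set.seed(3)
  rnd <- spikeInEfficiency(stats::setNames(rpois(5, 50), letters[1:5]))
  expect_equal(sum(rnd), 1)
  expect_error(spikeInEfficiency(c(a = 0, b = 0)), "positive")
})
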