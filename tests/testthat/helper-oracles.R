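# Independent brute-force oracles used to cross-check the package's
# interval, counting and statistics code. These deliberately share no code
# with the implementation: plain arithmetic and exhaustive loops only.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

options(hmcfrag.quiet = TRUE)

# Half-open integer intervals [s1, e1) and [s2, e2) overlap by >= 1 bp.
oracleOverlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# O(n * m) overlap counting on BED-style half-open intervals.
oracleCountOverlaps <- function(qStart, qEnd, sStart, sEnd) {
  vapply(seq_along(qStart), function(i) {
    sum(vapply(seq_along(sStart), function(j) {
      oracleOverlaps(qStart[i], qEnd[i], sStart[j], sEnd[j])
    }, logical(1L)))
  }, integer(1L))
}

# Concordant-pair AUC: mean over all (positive, negative) pairs of
# 1[s_p > s_n] + 0.5 * 1[s_p == s_n].
oracleAuc <- function(scores, labels) {
  sp <- scores[labels == "cancer"]
  sn <- scores[labels == "healthy"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Textbook Pearson product-moment formula.
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Benjamini-Hochberg step-up, written out: sort ascending, p * n / rank,
# enforce monotonicity from the largest down, restore the input order.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided permutation p value of the rank-sum statistic by full
# enumeration of group assignments (feasible for n1 + n2 <= 16).
oraclePermWilcoxon <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  wObs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all), n1)
  w <- apply(combos, 2L, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(w <= wObs), mean(w >= wObs)))
}

# A small simulated cohort shared across tests (built once per run).
.fixtureEnv <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.fixtureEnv$cohort)) {
    dir <- file.path(tempdir(), "hmcfrag_small_cohort")
    genome <- simulateGenome(nChrom = 2L, chromLength = 1e7,
                             gcWindow = 1e5, seed = 42L)
    design <- CohortDesign(nCancer = 6L, nHealthy = 6L,
                           fragmentsPerSample = 5000L, nPeakLoci = 60L,
                           nDifferentialLoci = 10L, seed = 42L)
    truth <- simulateCohort(genome, design, dir)
    .fixtureEnv$cohort <- list(dir = dir, genome = genome, design = design,
                               truth = truth)
  }
  .fixtureEnv$cohort
}

# Quick constructor for peak GRanges used throughout the peak tests.
makePeaks <- function(starts, width = 201L, spm = NULL, score = NULL,
                      chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(starts, starts + width - 1L))
  if (!is.null(score)) mcols(gr)$score <- score
  if (!is.null(spm)) mcols(gr)$spm <- spm
  gr
}
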