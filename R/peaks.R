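#' Peak-based 5hmC feature extraction
#'
#' Peak sets are plain [GenomicRanges::GRanges] objects carrying the
#' metadata columns `summit` (1-based summit position), `score` (raw peak
#' score) and, after [scorePerMillion()], `spm`. All operations follow the
#' fixed-width peak convention: each summit is extended 100 bp on either
#' side, giving 201-bp peaks, overlapping peaks are removed greedily by
#' descending score-per-million, and the consensus set is the overlap-free
#' union of group-level reproducible peaks.
#'
#' @name peak-features
NULL

.checkPeaks <- function(peaks, needSpm = FALSE) {
  if (!is(peaks, "GRanges")) stop("peaks must be a GRanges")
  if (needSpm && is.null(mcols(peaks)$spm))
    stop("peaks must carry a 'spm' column; run scorePerMillion() first")
  invisible(peaks)
}

#' Extend peak summits to fixed-width peaks
#'
#' Each 1-bp summit becomes a 201-bp peak covering 100 bp on either side of
#' the summit (BED half-open `[summit - 100, summit + 101)`). Peaks whose
#' extension runs off the chromosome start are retained here and flagged for
#' removal by [filterPeaks()].
#'
#' @param summits GRanges of 1-bp summits (e.g. from [readBed()] on a MACS2
#'   `summits.bed`), with a `score` metadata column.
#' @param halfWidth Extension on either side of the summit, in bp.
#' @return GRanges of fixed-width peaks with `summit` and `score` columns.
#' @examples
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5001),
#'                             score = 10)
#' fixedWidthPeaks(s)  # chr1:4901-5101 (1-based), width 201
#' @export
fixedWidthPeaks <- function(summits, halfWidth = 100L) {
  .checkPeaks(summits)
  if (any(width(summits) != 1L))
    stop("summits must be 1-bp intervals")
  if (is.null(mcols(summits)$score))
    stop("summits must carry a 'score' column")
  pos <- start(summits)
  gr <- GRanges(seqnames(summits),
                IRanges(pos - as.integer(halfWidth),
                        pos + as.integer(halfWidth)))
  mcols(gr)$summit <- pos
  mcols(gr)$score <- mcols(summits)$score
  if (!is.null(mcols(summits)$name)) mcols(gr)$name <- mcols(summits)$name
  gr
}

#' Normalize peak scores to score-per-million
#'
#' `spm_i = score_i * 1e6 / sum(score)`, so a sample's scores sum to one
#' million and peak strength is comparable across sequencing depths.
#'
#' @param peaks GRanges with a `score` column; at least one score must be
#'   positive.
#' @return The input with an `spm` column added.
#' @export
scorePerMillion <- function(peaks) {
  .checkPeaks(peaks)
  sc <- mcols(peaks)$score
  if (is.null(sc)) stop("peaks must carry a 'score' column")
  if (any(sc < 0)) stop("peak scores must be non-negative")
  total <- sum(sc)
  if (total == 0) stop("cannot normalize: all peak scores are zero")
  mcols(peaks)$spm <- sc * 1e6 / total
  peaks
}

# Greedy overlap-free selection: visit peaks in the order `ord`; keep a peak
# iff it overlaps (>= 1 bp) no already-kept peak. Returns a logical keep mask.
.greedySelect <- function(gr, ord) {
  hits <- findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keepPairs <- q != s
  adj <- split(s[keepPairs], q[keepPairs])
  state <- integer(length(gr))  # 0 undecided, 1 kept, -1 excluded
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    nb <- adj[[as.character(i)]]
    if (!is.null(nb)) state[nb[state[nb] == 0L]] <- -1L
  }
  state == 1L
}

#' Remove overlapping peaks greedily by descending score-per-million
#'
#' Peaks are visited in order of decreasing `spm` (ties broken by
#' chromosome, then start, ascending); a peak is kept iff it overlaps no
#' already-kept peak by at least 1 bp. The operation is deterministic and
#' idempotent. Abutting half-open intervals do not overlap.
#'
#' @param peaks GRanges with an `spm` column.
#' @return Overlap-free GRanges, sorted by position.
#' @export
removeOverlaps <- function(peaks) {
  .checkPeaks(peaks, needSpm = TRUE)
  if (length(peaks) == 0L) return(peaks)
  ord <- order(-mcols(peaks)$spm, as.integer(seqnames(peaks)), start(peaks))
  kept <- peaks[.greedySelect(peaks, ord)]
  GenomicRanges::sort(kept)
}

#' Group-level reproducible peaks
#'
#' Pools the peaks of all samples in one group as candidates. A candidate is
#' supported in a sample if any of that sample's peaks with
#' `spm >= minSpm` overlaps it (per-sample summits at the same locus jitter,
#' so support is defined by overlap, not identity). Candidates supported in
#' at least `ceiling(minFraction * n_samples)` samples are kept; overlaps
#' among survivors are then removed greedily, preferring higher support and
#' breaking ties by higher mean spm.
#'
#' @param samplePeaks Named list of per-sample GRanges (overlap-free, with
#'   `spm`), all from the same group.
#' @param minFraction Minimum supporting fraction of samples (default 10%).
#' @param minSpm Minimum score-per-million for a peak to count as support.
#' @return GRanges of reproducible peaks with `support` (number of
#'   supporting samples), `spm` (mean spm of supporting peaks) columns.
#' @export
reproduciblePeaks <- function(samplePeaks, minFraction = 0.10, minSpm = 5) {
  if (!length(samplePeaks)) stop("at least one sample peak set is required")
  lapply(samplePeaks, .checkPeaks, needSpm = TRUE)
  n <- length(samplePeaks)
  minSamples <- ceiling(minFraction * n)

  pooled <- suppressWarnings(do.call(c, unname(samplePeaks)))
  if (length(pooled) == 0L) return(pooled)
  qualifying <- lapply(samplePeaks,
                       function(p) p[mcols(p)$spm >= minSpm])

  support <- integer(length(pooled))
  spmSum <- numeric(length(pooled))
  spmN <- integer(length(pooled))
  for (p in qualifying) {
    if (length(p) == 0L) next
    hits <- findOverlaps(pooled, p)
    q <- S4Vectors::queryHits(hits)
    support <- support + as.integer(tabulate(q, length(pooled)) > 0L)
    spmSum <- spmSum + unname(tapply(mcols(p)$spm[S4Vectors::subjectHits(hits)],
                                     factor(q, levels = seq_along(pooled)),
                                     sum, default = 0))
    spmN <- spmN + tabulate(q, length(pooled))
  }
  keep <- support >= minSamples
  cand <- pooled[keep]
  if (length(cand) == 0L) {
    out <- GRanges()
    mcols(out)$support <- integer()
    mcols(out)$spm <- numeric()
    return(out)
  }
  meanSpm <- (spmSum / pmax(1L, spmN))[keep]
  mcols(cand) <- DataFrame(support = support[keep], spm = meanSpm)
  ord <- order(-mcols(cand)$support, -mcols(cand)$spm,
               as.integer(seqnames(cand)), start(cand))
  GenomicRanges::sort(cand[.greedySelect(cand, ord)])
}

#' Merge group-specific peak lists into the final consensus set
#'
#' The union of the (individually overlap-free) cancer-specific and
#' healthy-specific peak lists, with cross-group overlaps removed greedily
#' by descending spm. Each consensus peak receives a stable feature id
#' `chrom:start-end` (BED coordinates).
#'
#' @param cancerPeaks,healthyPeaks Overlap-free GRanges with `spm`.
#' @return Consensus GRanges named by feature id.
#' @export
consensusPeaks <- function(cancerPeaks, healthyPeaks) {
  .checkPeaks(cancerPeaks, needSpm = TRUE)
  .checkPeaks(healthyPeaks, needSpm = TRUE)
  cols <- intersect(colnames(mcols(cancerPeaks)),
                    colnames(mcols(healthyPeaks)))
  mcols(cancerPeaks) <- mcols(cancerPeaks)[, cols, drop = FALSE]
  mcols(healthyPeaks) <- mcols(healthyPeaks)[, cols, drop = FALSE]
  merged <- removeOverlaps(suppressWarnings(c(cancerPeaks, healthyPeaks)))
  names(merged) <- sprintf("%s:%d-%d", as.character(seqnames(merged)),
                           start(merged) - 1L, end(merged))
  merged
}

#' Filter consensus peaks by blacklist, chromosome bounds and excluded
#' chromosomes
#'
#' Removes peaks overlapping a blacklist interval by at least 1 bp, peaks
#' extending beyond either end of their chromosome, and peaks on excluded
#' chromosomes (sex chromosomes and the mitochondrial genome by default).
#' Idempotent.
#'
#' @param peaks GRanges.
#' @param chromSizes Named integer vector of chromosome lengths; must cover
#'   every chromosome present (unknown chromosomes are an error).
#' @param blacklist Optional GRanges of excluded regions.
#' @param excludeChroms Chromosome names to drop entirely.
#' @return The filtered GRanges.
#' @export
filterPeaks <- function(peaks, chromSizes, blacklist = NULL,
                        excludeChroms = c("chrX", "chrY", "chrM")) {
  .checkPeaks(peaks)
  chrom <- as.character(seqnames(peaks))
  unknown <- setdiff(unique(chrom), c(names(chromSizes), excludeChroms))
  if (length(unknown))
    stop("unknown chromosome(s) in peak set: ",
         paste(unknown, collapse = ", "))
  keep <- !(chrom %in% excludeChroms)
  sizeOf <- unname(chromSizes[chrom])
  inBounds <- !is.na(sizeOf) & start(peaks) >= 1L & end(peaks) <= sizeOf
  keep <- keep & inBounds
  if (!is.null(blacklist) && length(blacklist))
    keep <- keep & !overlapsAny(peaks, blacklist)
  out <- peaks[keep]
  .logMsg("filterPeaks: kept %d / %d peaks", length(out), length(peaks))
  out
}

#' Quantify 5hmC peak signal as FPKM
#'
#' `FPKM(s, k) = C(s, k) / (width_kb(k) * librarySize(s) / 1e6)` where
#' `C(s, k)` is the number of fragments of sample `s` overlapping peak `k`
#' by at least 1 bp (or whose midpoint falls in the peak, with
#' `countMethod = "midpoint"`).
#'
#' @param fragments Named list of per-sample fragment GRanges.
#' @param consensus Consensus peak GRanges named by feature id.
#' @param librarySizes Optional named total fragment counts per sample;
#'   defaults to `lengths(fragments)`. Must be positive.
#' @param group Optional per-sample group labels ("cancer"/"healthy").
#' @param countMethod Fragment-to-peak assignment rule.
#' @return A feature matrix (see [FeatureMatrix()]), peaks x samples.
#' @export
quantifyFpkm <- function(fragments, consensus, librarySizes = NULL,
                         group = NULL, countMethod = c("any", "midpoint")) {
  countMethod <- match.arg(countMethod)
  .checkPeaks(consensus)
  if (is.null(names(consensus)))
    stop("consensus peaks must be named by feature id")
  if (is.null(names(fragments)))
    stop("'fragments' must be a named list of GRanges")
  if (is.null(librarySizes)) {
    librarySizes <- vapply(fragments, length, integer(1L))
  }
  librarySizes <- librarySizes[names(fragments)]
  if (any(is.na(librarySizes)) || any(librarySizes <= 0))
    stop("library sizes must be positive for every sample")

  widthKb <- width(consensus) / 1000
  counts <- vapply(names(fragments), function(sid) {
    fr <- fragments[[sid]]
    if (countMethod == "midpoint") {
      mid0 <- (start(fr) - 1L + end(fr)) %/% 2L
      fr <- GRanges(seqnames(fr), IRanges(mid0 + 1L, mid0 + 1L))
    }
    countOverlaps(consensus, fr)
  }, integer(length(consensus)))
  counts <- matrix(counts, nrow = length(consensus),
                   dimnames = list(names(consensus), names(fragments)))
  fpkm <- counts / (widthKb * rep(librarySizes / 1e6,
                                  each = nrow(counts)))
  FeatureMatrix(fpkm, group = group, rowRanges = consensus)
}

#' Spike-in capture efficiency
#'
#' The fraction of reads aligned to each type-specific spike-in reference
#' out of all reads aligned to spike-in DNA; a library-quality measure of
#' the 5hmC pulldown.
#'
#' @param counts Named non-negative read counts per spike-in class; total
#'   must be positive.
#' @return Named fractions summing to 1.
#' @examples
#' spikeInEfficiency(c(hmC = 97, mC = 2, C = 1))
#' @export
spikeInEfficiency <- function(counts) {
  if (any(counts < 0)) stop("spike-in counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total spike-in count must be positive")
  counts / total
}
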