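#' Fragment-length histogram
#'
#' Counts fragment lengths (`end - start` in BED coordinates, equal to the
#' GRanges width) in bins of `binWidth` bp over `range` (inclusive).
#'
#' @param fragments GRanges of fragments.
#' @param binWidth Length-bin width in bp (1 for single-bp resolution, 4 for
#'   the conventional display).
#' @param range Inclusive length range kept.
#' @param density If `TRUE`, add a `density` column normalized to sum to 1
#'   over the kept range.
#' @return data.frame with columns `length` (bin start), `count` and
#'   optionally `density`.
#' @export
lengthHistogram <- function(fragments, binWidth = 1L, range = c(30L, 400L),
                            density = FALSE) {
  if (length(fragments) == 0L) stop("empty fragment set")
  len <- width(fragments)
  if (any(len <= 0L)) stop("fragments must have positive length")
  binWidth <- .assertCount(binWidth, "binWidth", 1L)
  inRange <- len >= range[1L] & len <= range[2L]
  len <- len[inRange]
  idx <- (len - range[1L]) %/% binWidth
  nBins <- (range[2L] - range[1L]) %/% binWidth + 1L
  counts <- tabulate(idx + 1L, nBins)
  out <- data.frame(length = range[1L] + (seq_len(nBins) - 1L) * binWidth,
                    count = counts)
  if (density) out$density <- if (sum(counts) > 0) counts / sum(counts) else 0
  out
}

#' Tile the genome into fixed-width bins
#'
#' Tiles each included chromosome left to right with `binWidth` bins,
#' dropping the incomplete terminal tile, bins overlapping the blacklist by
#' at least 1 bp, and excluded chromosomes. When a GC track is supplied the
#' length-weighted mean GC fraction over each bin is attached.
#'
#' @param chromSizes Named positive chromosome lengths.
#' @param binWidth Bin width in bp (default 100 kb).
#' @param blacklist Optional exclusion GRanges.
#' @param excludeChroms Chromosomes dropped entirely.
#' @param gcTrack Optional GRanges with a `gc` metadata column.
#' @return GRanges of bins, sorted, with a `gc` column (NA when no track).
#' @export
binGenome <- function(chromSizes, binWidth = 1e5, blacklist = NULL,
                      excludeChroms = c("chrX", "chrY", "chrM"),
                      gcTrack = NULL) {
  if (any(chromSizes <= 0)) stop("chromosome sizes must be positive")
  binWidth <- as.integer(binWidth)
  use <- chromSizes[setdiff(names(chromSizes), excludeChroms)]
  grl <- lapply(names(use), function(chr) {
    nBins <- use[[chr]] %/% binWidth
    if (nBins == 0L) return(GRanges())
    starts <- (seq_len(nBins) - 1L) * binWidth + 1L
    GRanges(chr, IRanges(starts, starts + binWidth - 1L))
  })
  bins <- suppressWarnings(do.call(c, grl))
  if (!is.null(blacklist) && length(blacklist))
    bins <- bins[!overlapsAny(bins, blacklist)]
  if (length(bins) == 0L)
    stop("no bins remain; bin width larger than every chromosome?")
  gc <- rep(NA_real_, length(bins))
  if (!is.null(gcTrack)) {
    hits <- findOverlaps(bins, gcTrack)
    ov <- width(GenomicRanges::pintersect(
      bins[S4Vectors::queryHits(hits)], gcTrack[S4Vectors::subjectHits(hits)]))
    gcv <- mcols(gcTrack)$gc[S4Vectors::subjectHits(hits)]
    q <- factor(S4Vectors::queryHits(hits), levels = seq_along(bins))
    gc <- unname(tapply(gcv * ov, q, sum, default = NA_real_) /
                 tapply(ov, q, sum, default = NA_real_))
  }
  mcols(bins)$gc <- gc
  GenomicRanges::sort(bins)
}

#' Count short, long and total fragments per bin
#'
#' A fragment is assigned to the bin containing its midpoint
#' (`(start + end) %/% 2` in BED coordinates; even-length fragments round
#' down, i.e. ties go to the lower coordinate). Fragments are classified by
#' length: short when within `shortRange`, long when within `longRange`
#' (both inclusive), and counted in `total` when within
#' `[shortRange[1], longRange[2]]`. Fragments whose midpoint falls in no bin
#' are ignored (their count is logged).
#'
#' @param fragments GRanges of one sample's fragments.
#' @param bins GRanges from [binGenome()].
#' @param shortRange,longRange Inclusive length ranges; must not overlap.
#' @return The bins with metadata columns `short`, `long`, `total` added;
#'   the sample can be recorded by the caller via `metadata()`.
#' @export
countShortLong <- function(fragments, bins, shortRange = c(80L, 150L),
                           longRange = c(151L, 250L)) {
  if (shortRange[2L] >= longRange[1L])
    stop("short and long ranges must not overlap")
  len <- width(fragments)
  mid0 <- (start(fragments) - 1L + end(fragments)) %/% 2L
  mids <- GRanges(seqnames(fragments), IRanges(mid0 + 1L, mid0 + 1L))
  hit <- findOverlaps(mids, bins, select = "first")
  dropped <- sum(is.na(hit))
  if (dropped > 0L)
    .logMsg("countShortLong: %d fragments outside all bins ignored", dropped)
  ok <- !is.na(hit)
  binIdx <- hit[ok]
  len <- len[ok]
  isShort <- len >= shortRange[1L] & len <= shortRange[2L]
  isLong <- len >= longRange[1L] & len <= longRange[2L]
  isTotal <- len >= shortRange[1L] & len <= longRange[2L]
  out <- bins
  mcols(out)$short <- tabulate(binIdx[isShort], length(bins))
  mcols(out)$long <- tabulate(binIdx[isLong], length(bins))
  mcols(out)$total <- tabulate(binIdx[isTotal], length(bins))
  out
}

#' LOWESS GC-bias correction
#'
#' Fits a LOWESS curve of counts against per-bin GC fraction and returns the
#' residuals re-centred so the raw mean is preserved exactly:
#' `corrected_i = count_i - fitted(gc_i) + mean(fitted)`. Re-centring by the
#' mean of the fitted values (rather than the raw mean, which differs from
#' it by a vanishing constant) makes mean conservation exact; downstream
#' features are z-scored per sample, so the constant is immaterial. With
#' constant GC the correction is the identity.
#'
#' @param counts Numeric per-bin counts of one fragment class of one sample.
#' @param gc Per-bin GC fractions in `[0, 1]`; at least 10 bins.
#' @param frac LOWESS smoother span.
#' @return Corrected counts (real-valued).
#' @export
gcCorrect <- function(counts, gc, frac = 0.75) {
  if (length(counts) != length(gc)) stop("counts and gc must be parallel")
  if (length(counts) < 10L) stop("at least 10 bins are required")
  if (any(is.na(gc)) || any(gc < 0 | gc > 1))
    stop("gc fractions must lie in [0, 1]")
  if (stats::var(gc) == 0) return(counts)
  lw <- stats::lowess(gc, counts, f = frac, iter = 3L)
  fitted <- stats::approx(lw$x, lw$y, xout = gc, rule = 2L,
                          ties = mean)$y
  counts - fitted + mean(fitted)
}

#' @describeIn gcCorrect Apply the correction to the `short`, `long` and
#'   `total` columns of a bin profile, adding `corrected_*` columns.
#' @param profile Bins with count columns, from [countShortLong()].
#' @export
gcCorrectProfile <- function(profile, frac = 0.75) {
  gc <- mcols(profile)$gc
  noGc <- all(is.na(gc))
  if (noGc)
    .logMsg("gcCorrectProfile: no GC track attached; counts passed through")
  for (cls in c("short", "long", "total")) {
    mcols(profile)[[paste0("corrected_", cls)]] <-
      if (noGc) as.numeric(mcols(profile)[[cls]])
      else gcCorrect(mcols(profile)[[cls]], gc, frac = frac)
  }
  profile
}

#' Aggregate bin profiles into wide windows
#'
#' Groups the consecutive bins of each chromosome (in positional order) into
#' windows of `windowWidth / binWidth` bins, dropping an incomplete trailing
#' group, and sums corrected short/total coverage over member bins. The
#' short-to-long ratio (RoSL) per window is computed from the raw counts and
#' flagged missing (NA) when the window has no long fragments.
#'
#' @param profile Bins with corrected counts, from [gcCorrectProfile()].
#' @param windowWidth Window width in bp; must be an integer multiple of the
#'   bin width.
#' @return data.frame with one row per window: `window_id`, `chrom`,
#'   `start`, `end` (BED coordinates), `short`, `total` (corrected sums),
#'   `short_raw`, `long_raw`, `rosl`.
#' @export
aggregateWindows <- function(profile, windowWidth = 5e6) {
  binWidth <- width(profile)[1L]
  if (windowWidth %% binWidth != 0)
    stop("windowWidth must be an integer multiple of the bin width")
  k <- as.integer(windowWidth %/% binWidth)
  need <- c("corrected_short", "corrected_total", "short", "long")
  if (!all(need %in% colnames(mcols(profile))))
    stop("profile must carry corrected counts; run gcCorrectProfile() first")
  profile <- GenomicRanges::sort(profile)
  chrom <- as.character(seqnames(profile))
  out <- lapply(unique(chrom), function(chr) {
    p <- profile[chrom == chr]
    nWin <- length(p) %/% k
    if (nWin == 0L) return(NULL)
    grpIdx <- rep(seq_len(nWin), each = k)
    p <- p[seq_len(nWin * k)]
    sumBy <- function(v) as.numeric(tapply(v, grpIdx, sum))
    stS <- sumBy(mcols(p)$short)
    loS <- sumBy(mcols(p)$long)
    data.frame(chrom = chr,
               start = as.integer(tapply(start(p), grpIdx, min)) - 1L,
               end = as.integer(tapply(end(p), grpIdx, max)),
               short = sumBy(mcols(p)$corrected_short),
               total = sumBy(mcols(p)$corrected_total),
               short_raw = stS, long_raw = loS,
               rosl = ifelse(loS == 0, NA_real_, stS / loS),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$window_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out[, c("window_id", "chrom", "start", "end", "short", "total",
          "short_raw", "long_raw", "rosl")]
}

#' Median healthy RoSL profile
#'
#' Per-window median of the short-to-long ratio across healthy samples;
#' windows where a sample's ratio is missing use the median of the
#' non-missing values. The even-count median is the mean of the two middle
#' values.
#'
#' @param profiles List of window profiles ([aggregateWindows()]) of healthy
#'   samples; all must share the same window set.
#' @return Named numeric vector of reference RoSL values by window id.
#' @export
medianHealthyProfile <- function(profiles) {
  if (!length(profiles)) stop("at least one healthy profile is required")
  ids <- profiles[[1L]]$window_id
  m <- vapply(profiles, function(p) {
    if (!identical(p$window_id, ids))
      stop("window profiles must share the same window set")
    p$rosl
  }, numeric(length(ids)))
  m <- matrix(m, nrow = length(ids))
  stats::setNames(apply(m, 1L, stats::median, na.rm = TRUE), ids)
}

#' Pearson correlation between a sample profile and the reference
#'
#' Computed over windows that are non-missing in both vectors; at least
#' three shared windows are required and either vector being constant is an
#' error (the correlation is undefined).
#'
#' @param sampleRosl Named RoSL vector of one sample.
#' @param referenceRosl Named reference vector (e.g. from
#'   [medianHealthyProfile()]).
#' @return Pearson product-moment correlation.
#' @export
profileCorrelation <- function(sampleRosl, referenceRosl) {
  shared <- intersect(names(sampleRosl), names(referenceRosl))
  x <- sampleRosl[shared]
  y <- referenceRosl[shared]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-missing windows")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a profile")
  stats::cor(x, y)
}

#' Standardized fragmentation feature matrix
#'
#' For each sample, the vectors of GC-corrected short and total window
#' coverages are each centred to mean 0 and scaled to unit standard
#' deviation within the sample, then stacked as features named
#' `short@window` and `total@window` (2 x n_windows features).
#'
#' @param profiles Named list of window profiles, one per sample, sharing
#'   the same window set.
#' @param group Optional per-sample group labels.
#' @return A feature matrix (see [FeatureMatrix()]).
#' @export
fragmentationFeatures <- function(profiles, group = NULL) {
  if (!length(profiles)) stop("at least one sample profile is required")
  if (is.null(names(profiles))) stop("'profiles' must be named by sample id")
  ids <- profiles[[1L]]$window_id
  zscore <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop("zero within-sample variance")
    (v - mean(v)) / s
  }
  vals <- vapply(profiles, function(p) {
    if (!identical(p$window_id, ids))
      stop("window profiles must share the same window set")
    c(zscore(p$short), zscore(p$total))
  }, numeric(2L * length(ids)))
  vals <- matrix(vals, nrow = 2L * length(ids),
                 dimnames = list(c(paste0("short@", ids),
                                   paste0("total@", ids)),
                                 names(profiles)))
  FeatureMatrix(vals, group = group)
}
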