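#' Simulate a small reference genome with smooth GC and chromatin tracks
#'
#' Generates a stand-in genome for cohort simulation. Chromosomes are tiled
#' into windows of `gcWindow` bp; each window carries three smooth AR(1)
#' tracks: `gc` (GC fraction, drives coverage bias), `shortness` (regional
#' propensity for short fragments shared by all samples, giving healthy
#' fragmentation profiles genuine genome-wide structure) and `aberration`
#' (regions where the cancer-specific excess of short fragments
#' concentrates). Autoregressive smoothing makes neighbouring windows
#' correlated, as real genomic covariates are.
#'
#' @param nChrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chromLength Length of each chromosome in bp; must be at least ten
#'   track windows.
#' @param gcWindow Track window width in bp.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#'
#' @return A [SyntheticGenome-class] object.
#' @examples
#' g <- simulateGenome(nChrom = 2, chromLength = 2e6, gcWindow = 1e5, seed = 1)
#' range(S4Vectors::mcols(gcTrack(g))$gc)
#' @export
simulateGenome <- function(nChrom = 2L, chromLength = 2e7, gcWindow = 1e5,
                           seed = 1L) {
  nChrom <- .assertCount(nChrom, "nChrom", 1L)
  .assertScalarNumber(chromLength, "chromLength", lower = 1)
  .assertScalarNumber(gcWindow, "gcWindow", lower = 1)
  if (chromLength < 10 * gcWindow)
    stop("chromLength must be at least 10 gc windows")
  chromLength <- as.integer(chromLength)
  gcWindow <- as.integer(gcWindow)
  seed <- .assertCount(seed, "seed")

  ar1 <- function(n, phi, sdStat) {
    innov <- stats::rnorm(n, sd = sdStat * sqrt(1 - phi^2))
    x <- numeric(n)
    x[1L] <- stats::rnorm(1L, sd = sdStat)
    for (t in seq_len(n)[-1L]) x[t] <- phi * x[t - 1L] + innov[t]
    x
  }

  chromNames <- paste0("chr", seq_len(nChrom))
  lengths <- stats::setNames(rep(chromLength, nChrom), chromNames)

  tracks <- .withSeed(seed, {
    grl <- lapply(chromNames, function(chr) {
      starts <- seq(1L, chromLength, by = gcWindow)
      ends <- pmin(starts + gcWindow - 1L, chromLength)
      n <- length(starts)
      gc <- pmin(0.65, pmax(0.25, 0.41 + ar1(n, phi = 0.9, sdStat = 0.07)))
      gr <- GRanges(chr, IRanges(starts, ends))
      mcols(gr)$gc <- gc
      mcols(gr)$shortness <- ar1(n, phi = 0.98, sdStat = 1)
      mcols(gr)$aberration <- ar1(n, phi = 0.98, sdStat = 1)
      gr
    })
    suppressWarnings(do.call(c, grl))
  })
  seqlevels(tracks) <- chromNames
  new("SyntheticGenome", chromLengths = lengths, gcWindow = gcWindow,
      tracks = tracks)
}

#' Simulate a cfDNA 5hmC cohort with known ground truth
#'
#' Writes one BED3 fragment file and one BED5 summit file per sample plus a
#' sample sheet and a ground-truth JSON, and returns the ground truth. The
#' generative model emulates the statistical structure the downstream
#' analysis assumes:
#'
#' * fragment lengths follow a mixture of a discretized normal
#'   (mode `lengthModeHealthy`, sd `lengthSd`) for the mono-nucleosomal peak
#'   and a uniform short component on 80-150 bp; the short-component
#'   probability varies regionally with the genome's `shortness` track, and
#'   in cancer samples an extra `shortExcessCancer` of mass is moved into the
#'   short range, concentrated in high-`aberration` regions;
#' * fragment placement is GC-biased with weight
#'   `max(0.05, 1 + gcBiasStrength * (gc - mean(gc)))` per window, so the
#'   LOWESS correction downstream has a monotone bias to remove;
#' * a `peakFraction` share of fragments is drawn from `nPeakLoci` fixed
#'   5hmC peak loci; in cancer samples the draw weight of the
#'   `nDifferentialLoci` differential loci is scaled by `2^effectLog2fc`,
#'   and summit scores at those loci are scaled likewise;
#' * each summit file additionally carries `noisePeaksPerSample`
#'   sample-private low-score summits that the reproducibility filter is
#'   expected to remove.
#'
#' All randomness derives from `design@seed`; identical inputs give
#' byte-identical output files.
#'
#' @param genome A [SyntheticGenome-class].
#' @param design A [CohortDesign-class].
#' @param outDir Output directory (created if missing); fragment files go to
#'   `<outDir>/fragments/`, summit files to `<outDir>/summits/`.
#'
#' @return A [GroundTruth-class] object.
#' @export
simulateCohort <- function(genome, design, outDir) {
  stopifnot(is(genome, "SyntheticGenome"), is(design, "CohortDesign"))
  validObject(design)
  dir.create(file.path(outDir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "summits"), recursive = TRUE,
             showWarnings = FALSE)

  tracks <- gcTrack(genome)
  sizes <- chromSizes(genome)
  seed <- design@seed

  ## ---- fixed cohort-level structure (loci, window weights) ----
  loci <- .withSeed(.deriveSeed(seed, 1L), {
    cand <- do.call(rbind, lapply(names(sizes), function(chr) {
      pos <- seq(5000L, sizes[[chr]] - 5000L, by = 2000L)
      data.frame(chrom = chr, pos0 = pos)
    }))
    if (nrow(cand) < design@nPeakLoci)
      stop("genome too small for the requested number of peak loci")
    pick <- sort(sample.int(nrow(cand), design@nPeakLoci))
    loci <- cand[pick, ]
    loci$id <- sprintf("locus_%03d", seq_len(nrow(loci)))
    loci$base_weight <- stats::rlnorm(nrow(loci), 0, 0.5)
    loci$base_score <- pmax(10, round(200 * loci$base_weight))
    loci$differential <- FALSE
    loci$differential[sample.int(nrow(loci), design@nDifferentialLoci)] <- TRUE
    loci$log2fc <- ifelse(loci$differential, design@effectLog2fc, 0)
    loci
  })
  lociGr <- GRanges(loci$chrom, IRanges(loci$pos0 + 1L, loci$pos0 + 1L))
  names(lociGr) <- loci$id
  mcols(lociGr)$base_score <- loci$base_score
  mcols(lociGr)$differential <- loci$differential
  mcols(lociGr)$log2fc <- loci$log2fc

  gc <- mcols(tracks)$gc
  winW <- width(tracks)
  # placement weight per window: GC bias times window width
  wGC <- pmax(0.05, 1 + design@gcBiasStrength * (gc - mean(gc))) *
    (winW / genome@gcWindow)
  pWin <- wGC / sum(wGC)
  pShortHealthy <- pmin(0.4, pmax(0.002,
    design@baseShortProb * exp(0.8 * mcols(tracks)$shortness)))
  # aberration-weighted excess, normalized so the expected extra short mass
  # over the placement distribution equals shortExcessCancer
  ew <- exp(mcols(tracks)$aberration)
  excessWin <- design@shortExcessCancer * ew / sum(pWin * ew)
  pShortCancer <- pmin(0.95, pShortHealthy + excessWin)

  lociWin <- findOverlaps(lociGr, tracks, select = "first")
  winStart0 <- start(tracks) - 1L
  chromOfWin <- as.character(seqnames(tracks))

  ids <- c(sprintf("cancer_%02d", seq_len(design@nCancer)),
           sprintf("healthy_%02d", seq_len(design@nHealthy)))
  groups <- rep(c("cancer", "healthy"), c(design@nCancer, design@nHealthy))

  # per-group locus draw weights: differential loci up-weighted in cancer
  lociMassH <- loci$base_weight / sum(loci$base_weight) * design@peakFraction
  lociMassC <- lociMassH * 2^loci$log2fc
  bgMass <- 1 - design@peakFraction

  fragFiles <- summitFiles <- stats::setNames(character(length(ids)), ids)
  meanLen <- stats::setNames(numeric(length(ids)), ids)

  for (i in seq_along(ids)) {
    sid <- ids[i]
    isCancer <- groups[i] == "cancer"
    res <- .withSeed(.deriveSeed(seed, 100L + i), {
      n <- design@fragmentsPerSample
      lociMass <- if (isCancer) lociMassC else lociMassH
      probPeak <- sum(lociMass) / (sum(lociMass) + bgMass)
      isPeak <- stats::runif(n) < probPeak
      nPk <- sum(isPeak)
      locusIdx <- sample.int(nrow(loci), nPk, replace = TRUE, prob = lociMass)
      bgWin <- sample.int(length(tracks), n - nPk, replace = TRUE, prob = pWin)
      winIdx <- integer(n)
      winIdx[isPeak] <- lociWin[locusIdx]
      winIdx[!isPeak] <- bgWin

      pShort <- if (isCancer) pShortCancer[winIdx] else pShortHealthy[winIdx]
      isShort <- stats::runif(n) < pShort
      len <- integer(n)
      len[isShort] <- sample(80:150, sum(isShort), replace = TRUE)
      len[!isShort] <- pmin(400L, pmax(30L, as.integer(round(
        stats::rnorm(sum(!isShort), design@lengthModeHealthy,
                     design@lengthSd)))))

      start0 <- integer(n)
      # background fragments: uniform within their window
      bgIdx <- which(!isPeak)
      start0[bgIdx] <- winStart0[winIdx[bgIdx]] +
        as.integer(floor(stats::runif(length(bgIdx)) *
                         pmax(1L, winW[winIdx[bgIdx]] - len[bgIdx])))
      # peak fragments: centred on the locus with jitter
      pkIdx <- which(isPeak)
      center0 <- loci$pos0[locusIdx] +
        as.integer(round(stats::runif(length(pkIdx), -50, 50)))
      start0[pkIdx] <- center0 - len[pkIdx] %/% 2L

      chrom <- character(n)
      chrom[bgIdx] <- chromOfWin[winIdx[bgIdx]]
      chrom[pkIdx] <- loci$chrom[locusIdx]
      maxStart <- sizes[chrom] - len
      start0 <- pmax(0L, pmin(start0, as.integer(maxStart)))
      frag <- data.table::data.table(chrom = chrom, start = start0,
                                     end = start0 + len)
      data.table::setorder(frag, chrom, start, end)

      # summit file: jittered ground-truth loci plus sample-private noise
      jitter <- sample(-20:20, nrow(loci), replace = TRUE)
      spos0 <- loci$pos0 + jitter
      scale <- if (isCancer) 2^loci$log2fc else 1
      score <- pmax(1, round(loci$base_score *
                             stats::rlnorm(nrow(loci), 0, 0.3) * scale))
      sm <- data.table::data.table(chrom = loci$chrom, start = spos0,
                                   end = spos0 + 1L,
                                   name = paste0(sid, "_", loci$id),
                                   score = as.integer(score))
      if (design@noisePeaksPerSample > 0L) {
        nchr <- sample(names(sizes), design@noisePeaksPerSample,
                       replace = TRUE)
        npos <- as.integer(floor(stats::runif(design@noisePeaksPerSample,
                                              300, sizes[nchr] - 300)))
        noise <- data.table::data.table(chrom = nchr, start = npos,
                                        end = npos + 1L,
                                        name = paste0(sid, "_noise_",
                                          seq_len(design@noisePeaksPerSample)),
                                        score = sample(1:5,
                                          design@noisePeaksPerSample,
                                          replace = TRUE))
        sm <- rbind(sm, noise)
      }
      data.table::setorder(sm, chrom, start)
      list(frag = frag, summits = sm, meanLen = mean(frag$end - frag$start))
    })
    fragFiles[sid] <- file.path(outDir, "fragments", paste0(sid, ".bed"))
    summitFiles[sid] <- file.path(outDir, "summits",
                                  paste0(sid, "_summits.bed"))
    data.table::fwrite(res$frag, fragFiles[sid], sep = "\t",
                       col.names = FALSE, quote = FALSE)
    data.table::fwrite(res$summits, summitFiles[sid], sep = "\t",
                       col.names = FALSE, quote = FALSE)
    meanLen[sid] <- res$meanLen
  }

  sheet <- data.frame(sample_id = ids, group = groups,
                      stringsAsFactors = FALSE)
  truth <- new("GroundTruth", sampleSheet = sheet, peakLoci = lociGr,
               differentialLocusIds = loci$id[loci$differential],
               meanFragmentLength = meanLen,
               fragmentFiles = fragFiles, summitFiles = summitFiles,
               seed = seed)
  writeSampleSheet(truth, file.path(outDir, "sample_sheet.tsv"))
  writeChromSizes(sizes, file.path(outDir, "chrom.sizes"))
  .writeGroundTruthJson(truth, file.path(outDir, "ground_truth.json"))
  .logMsg("simulated cohort: %d samples, %d fragments each, %d peak loci (%d differential)",
          length(ids), design@fragmentsPerSample, nrow(loci),
          sum(loci$differential))
  truth
}

#' Write the sample sheet of a simulated cohort
#'
#' @param truth A [GroundTruth-class].
#' @param out Output TSV path.
#' @return The path, invisibly usable in pipelines.
#' @export
writeSampleSheet <- function(truth, out) {
  stopifnot(is(truth, "GroundTruth"))
  data.table::fwrite(truth@sampleSheet, out, sep = "\t", quote = FALSE)
  out
}

.writeGroundTruthJson <- function(truth, path) {
  loci <- truth@peakLoci
  obj <- list(
    seed = truth@seed,
    samples = data.frame(sample_id = truth@sampleSheet$sample_id,
                         group = truth@sampleSheet$group,
                         mean_fragment_length =
                           unname(truth@meanFragmentLength)),
    loci = data.frame(id = names(loci),
                      chrom = as.character(seqnames(loci)),
                      pos0 = start(loci) - 1L,
                      base_score = mcols(loci)$base_score,
                      differential = mcols(loci)$differential,
                      log2fc = mcols(loci)$log2fc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON back as a GroundTruth object
#'
#' File paths are reconstructed from the directory layout used by
#' [simulateCohort()].
#' @param dir Cohort directory written by [simulateCohort()].
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  loci <- GRanges(obj$loci$chrom,
                  IRanges(obj$loci$pos0 + 1L, obj$loci$pos0 + 1L))
  names(loci) <- obj$loci$id
  mcols(loci)$base_score <- obj$loci$base_score
  mcols(loci)$differential <- obj$loci$differential
  mcols(loci)$log2fc <- obj$loci$log2fc
  ids <- obj$samples$sample_id
  new("GroundTruth",
      sampleSheet = data.frame(sample_id = ids, group = obj$samples$group,
                               stringsAsFactors = FALSE),
      peakLoci = loci,
      differentialLocusIds = obj$loci$id[obj$loci$differential],
      meanFragmentLength = stats::setNames(
        obj$samples$mean_fragment_length, ids),
      fragmentFiles = stats::setNames(
        file.path(dir, "fragments", paste0(ids, ".bed")), ids),
      summitFiles = stats::setNames(
        file.path(dir, "summits", paste0(ids, "_summits.bed")), ids),
      seed = as.integer(obj$seed))
}
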