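#' Default pipeline configuration
#'
#' A single flat, human-editable configuration object (YAML on disk) holds
#' every stage parameter of the pipeline; [readRunConfig()] merges a user
#' file over these defaults and rejects unknown keys. Defaults mirror the
#' conventional analysis settings: 201-bp fixed-width peaks, score-per-
#' million >= 5 in at least 10% of a group, differential thresholds
#' p < 0.001 / adjusted p < 0.05 / |log2FC| >= 0.5, 100-kb bins with 80-150
#' bp short and 151-250 bp long fragments aggregated to 5-Mb windows, a 4:1
#' stratified split, fivefold cross-validated stability selection with 100
#' repeats at 95% frequency, and an integrated model tuned by tenfold CV
#' over an alpha grid including 0.
#'
#' @return Nested named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    out_dir = "hmcfrag_run",
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      n_chrom = 2L, chrom_length = 2e7, gc_window = 1e5,
      n_cancer = 40L, n_healthy = 40L, fragments_per_sample = 20000L,
      length_mode_healthy = 167, length_sd = 10,
      short_excess_cancer = 0.1, gc_bias_strength = 1,
      n_peak_loci = 120L, n_differential_loci = 20L, effect_log2fc = 2,
      peak_fraction = 0.3, base_short_prob = 0.05,
      noise_peaks_per_sample = 20L),
    paths = list(sample_sheet = NULL, fragment_dir = NULL,
                 summit_dir = NULL, chrom_sizes = NULL, blacklist = NULL),
    peaks = list(half_width = 100L, min_spm = 5, min_fraction = 0.10,
                 exclude_chroms = c("chrX", "chrY", "chrM")),
    differential = list(p_raw_max = 0.001, p_adj_max = 0.05,
                        min_abs_log2fc = 0.5, pseudocount = 1),
    fragmentomics = list(bin_width = 1e5, window_width = 5e6,
                         short_min = 80L, short_max = 150L,
                         long_min = 151L, long_max = 250L,
                         lowess_frac = 0.75),
    model = list(proportion = 0.8, n_folds = 5L, n_repeats = 100L,
                 min_freq = 0.95, min_crosses_hmc = 4L,
                 min_crosses_frag = 5L, subsample = 0.8,
                 select_alpha = 0.5, integrated_folds = 10L)
  )
}

.mergeConfig <- function(user, defaults, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .mergeConfig(user[[k]], defaults[[k]],
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' @describeIn defaultRunConfig Read a YAML configuration file, merge it
#'   over the defaults and reject unknown keys.
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  .mergeConfig(yaml::read_yaml(path), defaultRunConfig())
}

.parseFeatureIds <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("malformed feature id: ", ids[which(bad)[1L]])
  GRanges(vapply(m, `[`, "", 2L),
          IRanges(as.integer(vapply(m, `[`, "", 3L)) + 1L,
                  as.integer(vapply(m, `[`, "", 4L))))
}

#' Run the full diagnostic pipeline
#'
#' Executes, in order: cohort simulation (optional), per-sample peak
#' processing and consensus building, FPKM quantification, the stratified
#' train/validation split, differential-locus testing on the training set,
#' fragmentation profiling (GC-corrected short/total coverage, RoSL
#' profiles and correlations to the median healthy profile), training of
#' the 5hmC, fragmentation and integrated stability-selection elastic-net
#' models, and wd-score evaluation. Intermediate artifacts are written
#' under `out_dir`; with `resume = TRUE` stages whose outputs already exist
#' are reloaded instead of recomputed. A run manifest (config snapshot,
#' package version, output checksums, wall-clock per stage) is written
#' atomically at the end.
#'
#' The run is single-threaded and fully deterministic given the
#' configuration and seed: re-running with an unchanged config reproduces
#' every model JSON and matrix byte for byte.
#'
#' @param config Path to a YAML config, or a config list (merged over
#'   [defaultRunConfig()]).
#' @param resume Reuse existing stage outputs instead of recomputing them.
#' @return Invisibly, a list with the consensus peaks, feature matrices,
#'   split, differential table, models, evaluations and the manifest.
#' @export
runPipeline <- function(config, resume = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else .mergeConfig(config, defaultRunConfig())
  seed <- .assertCount(cfg$seed, "seed")
  outDir <- cfg$out_dir
  for (d in c("", "peaks", "fpkm", "differential", "frag", "models",
              "scores", "eval"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)

  timings <- list()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    v
  }

  ## ---- stage: input / simulation ----
  gcT <- NULL
  inp <- timed("simulate", {
    if (isTRUE(cfg$simulate$enabled)) {
      dataDir <- file.path(outDir, "data")
      s <- cfg$simulate
      genome <- simulateGenome(nChrom = s$n_chrom,
                               chromLength = s$chrom_length,
                               gcWindow = s$gc_window, seed = seed)
      gcT <- gcTrack(genome)
      if (resume && file.exists(file.path(dataDir, "ground_truth.json"))) {
        truth <- readGroundTruth(dataDir)
      } else {
        design <- CohortDesign(
          nCancer = s$n_cancer, nHealthy = s$n_healthy,
          fragmentsPerSample = s$fragments_per_sample,
          lengthModeHealthy = s$length_mode_healthy,
          lengthSd = s$length_sd,
          shortExcessCancer = s$short_excess_cancer,
          gcBiasStrength = s$gc_bias_strength,
          nPeakLoci = s$n_peak_loci,
          nDifferentialLoci = s$n_differential_loci,
          effectLog2fc = s$effect_log2fc, peakFraction = s$peak_fraction,
          baseShortProb = s$base_short_prob,
          noisePeaksPerSample = s$noise_peaks_per_sample, seed = seed)
        truth <- simulateCohort(genome, design, dataDir)
      }
      list(sheet = sampleSheet(truth),
           chromSizes = chromSizes(genome),
           fragmentFiles = truth@fragmentFiles,
           summitFiles = truth@summitFiles,
           truth = truth)
    } else {
      p <- cfg$paths
      for (k in c("sample_sheet", "fragment_dir", "summit_dir",
                  "chrom_sizes"))
        if (is.null(p[[k]]) || !file.exists(p[[k]]))
          stop("config paths.", k, " must exist when simulation is disabled")
      sheet <- readSampleSheet(p$sample_sheet)
      list(sheet = sheet,
           chromSizes = readChromSizes(p$chrom_sizes),
           fragmentFiles = stats::setNames(
             file.path(p$fragment_dir, paste0(sheet$sample_id, ".bed")),
             sheet$sample_id),
           summitFiles = stats::setNames(
             file.path(p$summit_dir,
                       paste0(sheet$sample_id, "_summits.bed")),
             sheet$sample_id),
           truth = NULL)
    }
  })
  sheet <- inp$sheet
  blacklist <- if (!is.null(cfg$paths$blacklist))
    readBed(cfg$paths$blacklist) else NULL

  ## ---- stage: peaks ----
  consensusFile <- file.path(outDir, "peaks", "consensus_peaks.bed")
  consensus <- timed("peaks", {
    if (resume && file.exists(consensusFile)) {
      gr <- readBed(consensusFile, minCols = 5L)
      names(gr) <- mcols(gr)$name
      mcols(gr)$spm <- mcols(gr)$score
      gr
    } else {
      pk <- cfg$peaks
      perSample <- lapply(inp$summitFiles, function(f)
        removeOverlaps(scorePerMillion(
          fixedWidthPeaks(readBed(f, minCols = 5L),
                          halfWidth = pk$half_width))))
      repC <- reproduciblePeaks(perSample[sheet$group == "cancer"],
                                minFraction = pk$min_fraction,
                                minSpm = pk$min_spm)
      repH <- reproduciblePeaks(perSample[sheet$group == "healthy"],
                                minFraction = pk$min_fraction,
                                minSpm = pk$min_spm)
      cons <- filterPeaks(consensusPeaks(repC, repH), inp$chromSizes,
                          blacklist = blacklist,
                          excludeChroms = pk$exclude_chroms)
      writeBed(cons, consensusFile, format = "bed6")
      cons
    }
  })

  ## ---- stage: fragments + FPKM ----
  frags <- timed("read_fragments",
                 lapply(inp$fragmentFiles, readBed, minCols = 3L))
  fpkmFile <- file.path(outDir, "fpkm", "fpkm_matrix.tsv")
  fm <- timed("quantify", {
    if (resume && file.exists(fpkmFile)) {
      m <- readTsvMatrix(fpkmFile)
      FeatureMatrix(t(m), group = sheet$group[match(rownames(m),
                                                    sheet$sample_id)])
    } else {
      fm <- quantifyFpkm(frags, consensus, group = sheet$group)
      writeTsvMatrix(featureValues(fm), fpkmFile)
      fm
    }
  })

  ## ---- stage: split ----
  split <- timed("split", splitCohort(sheet, proportion =
                                        cfg$model$proportion, seed = seed))
  jsonlite::write_json(list(train = trainIds(split),
                            validation = validationIds(split)),
                       file.path(outDir, "split.json"))

  ## ---- stage: differential (training samples only) ----
  diffTab <- timed("differential", {
    d <- cfg$differential
    res <- differentialLoci(fm[, trainIds(split)],
                            pRawMax = d$p_raw_max, pAdjMax = d$p_adj_max,
                            minAbsLog2fc = d$min_abs_log2fc,
                            pseudocount = d$pseudocount)
    data.table::fwrite(res, file.path(outDir, "differential",
                                      "differential_loci.tsv"), sep = "\t")
    if (any(res$passes)) {
      gr <- .parseFeatureIds(res$feature_id[res$passes])
      mcols(gr)$name <- res$feature_id[res$passes]
      mcols(gr)$score <- 0
      writeBed(gr, file.path(outDir, "differential", "passing_loci.bed"),
               format = "bed5")
    }
    res
  })

  ## ---- stage: fragmentation profiles ----
  fr <- cfg$fragmentomics
  fragRes <- timed("fragmentomics", {
    bins <- binGenome(inp$chromSizes, binWidth = fr$bin_width,
                      blacklist = blacklist,
                      excludeChroms = cfg$peaks$exclude_chroms,
                      gcTrack = gcT)
    profiles <- lapply(frags, function(f)
      aggregateWindows(gcCorrectProfile(
        countShortLong(f, bins,
                       shortRange = c(fr$short_min, fr$short_max),
                       longRange = c(fr$long_min, fr$long_max)),
        frac = fr$lowess_frac), windowWidth = fr$window_width))
    fmFrag <- fragmentationFeatures(profiles, group = sheet$group)
    writeTsvMatrix(featureValues(fmFrag),
                   file.path(outDir, "frag", "window_features.tsv"))
    rosl <- vapply(profiles, function(p) p$rosl,
                   numeric(nrow(profiles[[1L]])))
    rosl <- matrix(rosl, ncol = length(profiles),
                   dimnames = list(profiles[[1L]]$window_id,
                                   names(profiles)))
    writeTsvMatrix(t(rosl), file.path(outDir, "frag", "rosl_profiles.tsv"))
    healthyTrain <- intersect(trainIds(split),
                              sheet$sample_id[sheet$group == "healthy"])
    reference <- medianHealthyProfile(profiles[healthyTrain])
    refTab <- profiles[[1L]][, c("chrom", "start", "end")]
    refTab$rosl <- unname(reference)
    data.table::fwrite(refTab, file.path(outDir, "frag",
                                         "median_healthy_rosl.tsv"),
                       sep = "\t")
    cors <- vapply(names(profiles), function(sid)
      profileCorrelation(stats::setNames(profiles[[sid]]$rosl,
                                         profiles[[sid]]$window_id),
                         reference), numeric(1L))
    data.table::fwrite(data.frame(sample_id = names(cors),
                                  group = sheet$group[match(names(cors),
                                                            sheet$sample_id)],
                                  correlation = unname(cors)),
                       file.path(outDir, "frag", "profile_correlations.tsv"),
                       sep = "\t")
    list(fmFrag = fmFrag, correlations = cors, reference = reference,
         profiles = profiles)
  })
  fmFrag <- fragRes$fmFrag

  ## ---- stage: model training ----
  md <- cfg$model
  xH <- featureValues(fm)
  xF <- featureValues(fmFrag)
  yAll <- stats::setNames(sheet$group, sheet$sample_id)
  tr <- trainIds(split)
  modelFiles <- file.path(outDir, "models",
                          c(hmc = "model_hmc.json",
                            frag = "model_frag.json",
                            integrated = "model_integrated.json"))
  names(modelFiles) <- c("hmc", "frag", "integrated")
  models <- timed("train", {
    if (resume && all(file.exists(modelFiles))) {
      lapply(modelFiles, readStabilityModel)
    } else {
      mH <- trainDiagnosticModel(xH[tr, , drop = FALSE], yAll[tr],
                                 nFolds = md$n_folds,
                                 nRepeats = md$n_repeats,
                                 minFreq = md$min_freq,
                                 minCrosses = md$min_crosses_hmc,
                                 subsample = md$subsample,
                                 selectAlpha = md$select_alpha,
                                 seed = .deriveSeed(seed, 31L))
      mF <- trainDiagnosticModel(xF[tr, , drop = FALSE], yAll[tr],
                                 nFolds = md$n_folds,
                                 nRepeats = md$n_repeats,
                                 minFreq = md$min_freq,
                                 minCrosses = md$min_crosses_frag,
                                 subsample = md$subsample,
                                 selectAlpha = md$select_alpha,
                                 seed = .deriveSeed(seed, 37L))
      mI <- if (length(markers(mH)) || length(markers(mF))) {
        integrateModels(markers(mH), markers(mF),
                        xH[tr, , drop = FALSE], xF[tr, , drop = FALSE],
                        yAll[tr], nFolds = md$integrated_folds,
                        seed = .deriveSeed(seed, 41L))
      } else mH  # both empty: integrated model is empty too
      out <- list(hmc = mH, frag = mF, integrated = mI)
      for (k in names(out)) writeStabilityModel(out[[k]], modelFiles[[k]])
      out
    }
  })

  ## ---- stage: scoring and evaluation ----
  evals <- timed("evaluate", {
    designs <- list(hmc = xH, frag = xF, integrated = cbind(xH, xF))
    scoreRows <- list()
    evalRows <- list()
    testRows <- list()
    va <- validationIds(split)
    res <- list()
    for (k in names(models)) {
      sc <- wdScore(models[[k]], designs[[k]])
      evTrain <- evaluateModel(sc[tr], yAll[tr])
      evVal <- evaluateModel(sc[va], yAll[va],
                             threshold = evTrain@threshold)
      res[[k]] <- list(train = evTrain, validation = evVal)
      for (set in c("train", "validation")) {
        ids <- if (set == "train") tr else va
        scoreRows[[paste(k, set)]] <-
          data.frame(model = k, set = set, sample_id = ids,
                     group = unname(yAll[ids]), wd_score = unname(sc[ids]))
        ev <- res[[k]][[if (set == "train") "train" else "validation"]]
        evalRows[[paste(k, set)]] <-
          data.frame(model = k, set = set, auc = ev@auc,
                     sensitivity = ev@sensitivity,
                     specificity = ev@specificity,
                     threshold = ev@threshold)
        wt <- compareGroupsWilcoxon(sc[ids], yAll[ids])
        testRows[[paste(k, set)]] <- cbind(model = k, set = set, wt)
      }
    }
    data.table::fwrite(do.call(rbind, scoreRows),
                       file.path(outDir, "scores", "wd_scores.tsv"),
                       sep = "\t")
    data.table::fwrite(do.call(rbind, evalRows),
                       file.path(outDir, "eval", "evaluation.tsv"),
                       sep = "\t")
    data.table::fwrite(do.call(rbind, testRows),
                       file.path(outDir, "eval", "wd_score_tests.tsv"),
                       sep = "\t")
    res
  })

  ## ---- manifest, written atomically ----
  keyOutputs <- c(consensusFile, fpkmFile,
                  file.path(outDir, "frag", "window_features.tsv"),
                  modelFiles,
                  file.path(outDir, "eval", "evaluation.tsv"))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("hmcfrag")),
                   config = cfg,
                   checksums = as.list(tools::md5sum(keyOutputs)),
                   timings_sec = timings)
  tmp <- file.path(outDir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(outDir, "manifest.json"))

  invisible(list(consensus = consensus, fpkm = fm, fragFeatures = fmFrag,
                 split = split, differential = diffTab,
                 correlations = fragRes$correlations, models = models,
                 evaluations = evals, truth = inp$truth,
                 manifest = manifest))
}
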