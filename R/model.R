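#' Stratified train/validation split
#'
#' Randomly assigns a `proportion` share of each class to the training set
#' (4:1 by default), deterministically given the seed.
#'
#' @param sheet Sample sheet data.frame with `sample_id` and `group`.
#' @param proportion Training fraction, strictly inside (0, 1); both sets
#'   must end up non-empty in every class.
#' @param seed Integer seed.
#' @return A [SplitPlan-class].
#' @export
splitCohort <- function(sheet, proportion = 0.8, seed = 1L) {
  .assertScalarNumber(proportion, "proportion", 1e-9, 1 - 1e-9)
  seed <- .assertCount(seed, "seed")
  train <- character()
  .withSeed(.deriveSeed(seed, 7L), {
    for (g in sort(unique(sheet$group))) {
      ids <- sheet$sample_id[sheet$group == g]
      if (length(ids) < 2L)
        stop("class '", g, "' has fewer than 2 samples")
      nTrain <- round(proportion * length(ids))
      if (nTrain < 1L || nTrain >= length(ids))
        stop("proportion leaves an empty training or validation set for '",
             g, "'")
      train <- c(train, sample(ids, nTrain))
    }
  })
  new("SplitPlan", trainIds = sort(train),
      validationIds = sort(setdiff(sheet$sample_id, train)),
      proportion = proportion, seed = seed)
}

# Stratified fold assignment: samples of each class are dealt round-robin
# into shuffled folds, so every fold keeps the class balance within one.
.stratifiedFolds <- function(yBin, nFolds) {
  fold <- integer(length(yBin))
  for (cls in unique(yBin)) {
    idx <- which(yBin == cls)
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

.checkXy <- function(x, y) {
  if (!is.matrix(x) || is.null(colnames(x)) || is.null(rownames(x)))
    stop("'x' must be a samples x features matrix with dimnames")
  if (length(y) != nrow(x)) stop("'y' must have one label per sample")
  yBin <- as.integer(as.character(y) == "cancer")
  if (!all(as.character(y) %in% c("cancer", "healthy")))
    stop("labels must be 'cancer' or 'healthy'")
  yBin
}

#' Marker selection by cross-validated stability selection
#'
#' The training cohort is split into `nFolds` stratified crosses. In each
#' cross, the other `nFolds - 1` folds form the cross-training set, on which
#' `nRepeats` elastic-net logistic fits are run, each on a fresh stratified
#' random subsample of `subsample` of the cross-training samples, with the
#' penalty strength chosen per fit by internal cross-validated deviance. A
#' feature is selected in a cross when its coefficient is nonzero in at
#' least `minFreq` of the repeats; the marker panel is the set of features
#' selected in at least `minCrosses` crosses. Fully deterministic given the
#' seed.
#'
#' @param x Samples x features numeric matrix with dimnames.
#' @param y Group labels ("cancer"/"healthy") parallel to rows of `x`.
#' @param nFolds Number of crosses (default fivefold).
#' @param nRepeats Elastic-net fits per cross.
#' @param minFreq Minimum selection frequency within a cross.
#' @param minCrosses Minimum number of crosses a marker must appear in
#'   (4 for the 5hmC model, 5 for the fragmentation model by convention).
#' @param subsample Subsampled fraction of the cross-training set per repeat.
#' @param alpha Elastic-net mixing parameter used during selection.
#' @param innerFolds Folds of the internal lambda-selection CV.
#' @param nLambda Length of the per-fit lambda path.
#' @param seed Integer seed.
#' @return List with elements `markers` (character), `frequencies`
#'   (features x crosses selection-frequency matrix) and `crosses` (named
#'   list: marker -> crosses where its frequency reached `minFreq`). An
#'   empty marker set is returned with a warning when nothing is stable.
#' @export
#' @importFrom glmnet cv.glmnet glmnet
stabilitySelect <- function(x, y, nFolds = 5L, nRepeats = 100L,
                            minFreq = 0.95, minCrosses = 4L,
                            subsample = 0.8, alpha = 0.5, innerFolds = 3L,
                            nLambda = 30L, seed = 1L) {
  yBin <- .checkXy(x, y)
  if (min(table(yBin)) < nFolds)
    stop("each class needs at least nFolds samples")
  seed <- .assertCount(seed, "seed")
  p <- ncol(x)
  freq <- matrix(0, p, nFolds, dimnames = list(colnames(x), NULL))

  fold <- .withSeed(.deriveSeed(seed, 11L), .stratifiedFolds(yBin, nFolds))
  for (cross in seq_len(nFolds)) {
    inCross <- fold != cross
    xs <- x[inCross, , drop = FALSE]
    ys <- yBin[inCross]
    if (min(table(ys)) < 3L)
      stop("stability selection needs at least 3 cross-training samples ",
           "per class; reduce nFolds or enlarge the cohort")
    selCount <- numeric(p)
    .withSeed(.deriveSeed(seed, 1000L + cross), {
      for (r in seq_len(nRepeats)) {
        # subsample floor of 3 per class: the internal CV needs two
        # observations of each class in every fold's training portion
        idx <- unlist(lapply(unique(ys), function(cls) {
          cand <- which(ys == cls)
          sample(cand, min(length(cand),
                           max(3L, floor(subsample * length(cand)))))
        }), use.names = FALSE)
        foldid <- .stratifiedFolds(ys[idx], innerFolds)
        # cv.glmnet needs >= 3 folds; tiny subsamples can produce fewer, so
        # deal samples round-robin in class order, which keeps every fold's
        # training complement populated with both classes
        if (length(unique(foldid)) < 3L)
          foldid[order(ys[idx])] <- rep_len(seq_len(3L), length(idx))
        cvfit <- suppressWarnings(
          cv.glmnet(xs[idx, , drop = FALSE], ys[idx],
                    family = "binomial", alpha = alpha,
                    foldid = foldid, nlambda = nLambda,
                    lambda.min.ratio = 1e-5,
                    type.measure = "deviance"))
        cf <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1L]
        selCount <- selCount + (cf != 0)
      }
    })
    freq[, cross] <- selCount / nRepeats
  }
  selectedIn <- freq >= minFreq
  markers <- colnames(x)[rowSums(selectedIn) >= minCrosses]
  if (!length(markers))
    warning("stability selection returned an empty marker set")
  crosses <- lapply(stats::setNames(markers, markers),
                    function(m) which(selectedIn[m, ]))
  .logMsg("stabilitySelect: %d markers (>= %d / %d crosses at freq >= %.2f)",
          length(markers), minCrosses, nFolds, minFreq)
  list(markers = markers, frequencies = freq, crosses = crosses)
}

# Rank (Mann-Whitney) AUC with 0.5 credit for ties; positive class "cancer".
.aucRank <- function(scores, labels) {
  pos <- labels == "cancer"
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

# Threshold maximizing Youden's J (sens + spec - 1) for the rule
# score >= threshold => cancer; ties in J resolved toward the larger
# threshold (higher specificity).
.youdenThreshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  pos <- labels == "cancer"
  j <- vapply(cand, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, numeric(1L))
  cand[max(which(j == max(j)))]
}

#' Fit the final elastic-net model on the selected markers
#'
#' Grid search over `(alpha, lambda)` maximizing the mean cross-validated
#' AUC on the training set, then a refit on the full training set at the
#' winning point. Grid ties prefer the larger lambda, then the smaller
#' alpha (sparser, smoother models). Coefficients are reported on the
#' original feature scale (standardization is internal to the fit), so
#' wd-scores are plain weighted sums of raw feature values.
#'
#' @inheritParams stabilitySelect
#' @param markers Feature ids to restrict the design to; must be non-empty.
#' @param alphaGrid Candidate mixing values (0.05-1 in 0.05 steps by
#'   default; include 0 for the integrated model).
#' @param lambdaGrid Candidate penalty strengths (50 log-spaced points on
#'   `[1e-5, 1]` by default).
#' @param nFolds CV folds of the grid search (fivefold; tenfold for the
#'   integrated model).
#' @param selectionRecord,featureBlocks Provenance stored in the model.
#' @return A [StabilityModel-class].
#' @export
fitFinal <- function(x, y, markers, alphaGrid = seq(0.05, 1, by = 0.05),
                     lambdaGrid = 10^seq(0, -5, length.out = 50L),
                     nFolds = 5L, seed = 1L, selectionRecord = list(),
                     featureBlocks = NULL) {
  yBin <- .checkXy(x, y)
  if (!length(markers)) stop("empty marker set")
  if (!all(markers %in% colnames(x)))
    stop("markers missing from the feature matrix")
  seed <- .assertCount(seed, "seed")
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  # every CV fold must hold out both classes
  nFolds <- min(nFolds, min(table(yBin)))
  xm <- x[, markers, drop = FALSE]
  # glmnet requires >= 2 columns; pad single-marker designs with a zero
  # dummy whose coefficient is necessarily 0
  padded <- ncol(xm) == 1L
  if (padded) xm <- cbind(xm, .dummy = 0)

  fold <- .withSeed(.deriveSeed(seed, 23L), .stratifiedFolds(yBin, nFolds))
  cvAuc <- matrix(NA_real_, length(alphaGrid), length(lambdaGrid))
  for (a in seq_along(alphaGrid)) {
    aucSum <- numeric(length(lambdaGrid))
    for (f in seq_len(nFolds)) {
      inTrain <- fold != f
      fit <- suppressWarnings(
        glmnet(xm[inTrain, , drop = FALSE], yBin[inTrain],
               family = "binomial", alpha = alphaGrid[a],
               lambda = lambdaGrid))
      pred <- stats::predict(fit, xm[!inTrain, , drop = FALSE],
                             s = lambdaGrid, type = "link")
      lab <- ifelse(yBin[!inTrain] == 1L, "cancer", "healthy")
      aucSum <- aucSum + vapply(seq_along(lambdaGrid),
                                function(l) .aucRank(pred[, l], lab),
                                numeric(1L))
    }
    cvAuc[a, ] <- aucSum / nFolds
  }
  best <- which(cvAuc == max(cvAuc), arr.ind = TRUE)
  # larger lambda = smaller column index (grid is decreasing); then smaller
  # alpha = smaller row index
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1L, ]
  alphaStar <- alphaGrid[best["row"]]
  lambdaStar <- lambdaGrid[best["col"]]

  fit <- suppressWarnings(glmnet(xm, yBin, family = "binomial",
                                 alpha = alphaStar, lambda = lambdaGrid))
  cf <- as.numeric(stats::coef(fit, s = lambdaStar))
  names(cf) <- c("(Intercept)", colnames(xm))
  coefs <- cf[markers]
  if (is.null(featureBlocks))
    featureBlocks <- stats::setNames(rep("default", length(markers)), markers)
  new("StabilityModel", markers = markers, coefficients = coefs,
      intercept = unname(cf[1L]), alpha = alphaStar, lambda = lambdaStar,
      selectionRecord = selectionRecord, featureBlocks = featureBlocks,
      seed = seed)
}

#' Weighted diagnosis score
#'
#' `wd = sum_k coef(k) * feature(k)` over the model's markers; the intercept
#' is excluded, so the score is linear in the features. Models with an
#' empty marker panel score every sample 0.
#'
#' @param model A [StabilityModel-class].
#' @param features Named numeric vector (one sample) or samples x features
#'   matrix; every marker must be present.
#' @return Numeric score(s), named by sample for matrix input.
#' @export
wdScore <- function(model, features) {
  stopifnot(is(model, "StabilityModel"))
  if (is.vector(features)) features <- t(as.matrix(features))
  if (!length(markers(model)))
    return(stats::setNames(rep(0, nrow(features)), rownames(features)))
  missing <- setdiff(markers(model), colnames(features))
  if (length(missing))
    stop("marker feature(s) missing: ", paste(missing, collapse = ", "))
  drop(features[, markers(model), drop = FALSE] %*% coef(model))
}

#' Integrate the 5hmC and fragmentation models
#'
#' Horizontally concatenates the marker-restricted 5hmC FPKM block and the
#' fragmentation-feature block (each retaining its own normalization) and
#' refits an elastic net with tenfold cross-validation over an alpha grid
#' that includes 0.
#'
#' @param markersHmc,markersFrag Marker panels of the two single-modality
#'   models; at least one must be non-empty.
#' @param xHmc,xFrag Samples x features matrices sharing the same sample
#'   ids in the same order.
#' @param y Group labels.
#' @param alphaGrid,lambdaGrid,nFolds,seed Passed to [fitFinal()].
#' @return A [StabilityModel-class] whose `featureBlocks` records each
#'   marker's origin.
#' @export
integrateModels <- function(markersHmc, markersFrag, xHmc, xFrag, y,
                            alphaGrid = seq(0, 1, by = 0.05),
                            lambdaGrid = 10^seq(0, -5, length.out = 50L),
                            nFolds = 10L, seed = 1L) {
  if (!identical(rownames(xHmc), rownames(xFrag)))
    stop("sample ids of the two feature blocks do not match")
  if (!length(markersHmc) && !length(markersFrag))
    stop("both marker sets are empty")
  blocks <- c(stats::setNames(rep("hmc", length(markersHmc)), markersHmc),
              stats::setNames(rep("frag", length(markersFrag)), markersFrag))
  if (anyDuplicated(names(blocks)))
    stop("feature ids collide across blocks")
  design <- cbind(xHmc[, markersHmc, drop = FALSE],
                  xFrag[, markersFrag, drop = FALSE])
  fitFinal(design, y, markers = names(blocks), alphaGrid = alphaGrid,
           lambdaGrid = lambdaGrid, nFolds = nFolds, seed = seed,
           featureBlocks = blocks)
}

#' Evaluate classifier scores
#'
#' AUC by the Mann-Whitney rank formulation (ties credited 0.5).
#' Sensitivity and specificity are computed at `threshold` (score >=
#' threshold calls cancer); when no threshold is given it is chosen by
#' Youden's J on the supplied scores — standard practice is to derive it
#' from training scores and apply it unchanged to validation data.
#'
#' @param scores Named numeric scores.
#' @param labels Group labels parallel to `scores`; both classes required.
#' @param threshold Optional fixed decision threshold.
#' @return An [EvalResult-class].
#' @export
evaluateModel <- function(scores, labels, threshold = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  if (is.null(threshold)) threshold <- .youdenThreshold(scores, labels)
  pos <- labels == "cancer"
  new("EvalResult",
      auc = .aucRank(scores, labels),
      sensitivity = mean(scores[pos] >= threshold),
      specificity = mean(scores[!pos] < threshold),
      threshold = threshold,
      scores = if (is.null(names(scores)))
        stats::setNames(scores, seq_along(scores)) else scores,
      labels = labels)
}

#' Pairwise Wilcoxon comparison of scores between groups
#'
#' Two-sided rank-sum test for every pair of groups (e.g. wd-scores of
#' cancer vs healthy, or across stage strata). Exact p values are used
#' where [stats::wilcox.test()] supports them (small groups without ties).
#'
#' @param scores Numeric scores.
#' @param grouping Group assignment parallel to `scores`.
#' @return data.frame with columns `group1`, `group2`, `p_value`.
#' @export
compareGroupsWilcoxon <- function(scores, grouping) {
  grouping <- as.character(grouping)
  groups <- sort(unique(grouping))
  if (any(table(grouping) < 1L)) stop("empty group")
  pairs <- utils::combn(groups, 2L)
  res <- apply(pairs, 2L, function(gp) {
    suppressWarnings(stats::wilcox.test(scores[grouping == gp[1L]],
                                        scores[grouping == gp[2L]],
                                        alternative = "two.sided")$p.value)
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_value = res,
             stringsAsFactors = FALSE)
}

#' Train a diagnostic model end to end
#'
#' Stability selection followed by the final grid-search fit. When no
#' feature is stable (e.g. under a null cohort), an intercept-only model is
#' returned with a warning: it scores every sample identically, giving
#' chance-level AUC.
#'
#' @inheritParams stabilitySelect
#' @inheritParams fitFinal
#' @param selectAlpha Mixing parameter used during stability selection.
#' @return A [StabilityModel-class].
#' @export
trainDiagnosticModel <- function(x, y, nFolds = 5L, nRepeats = 100L,
                                 minFreq = 0.95, minCrosses = 4L,
                                 subsample = 0.8, selectAlpha = 0.5,
                                 alphaGrid = seq(0.05, 1, by = 0.05),
                                 lambdaGrid = 10^seq(0, -5,
                                                     length.out = 50L),
                                 seed = 1L) {
  sel <- stabilitySelect(x, y, nFolds = nFolds, nRepeats = nRepeats,
                         minFreq = minFreq, minCrosses = minCrosses,
                         subsample = subsample, alpha = selectAlpha,
                         seed = seed)
  if (!length(sel$markers)) {
    return(new("StabilityModel", markers = character(),
               coefficients = stats::setNames(numeric(), character()),
               intercept = 0, alpha = NA_real_, lambda = NA_real_,
               selectionRecord = list(),
               featureBlocks = stats::setNames(character(), character()),
               seed = .assertCount(seed, "seed")))
  }
  fitFinal(x, y, markers = sel$markers, alphaGrid = alphaGrid,
           lambdaGrid = lambdaGrid, nFolds = nFolds, seed = seed,
           selectionRecord = sel$crosses)
}

#' Serialize a fitted model to JSON
#'
#' @param model A [StabilityModel-class].
#' @param path Output path.
#' @export
writeStabilityModel <- function(model, path) {
  obj <- list(markers = model@markers,
              coefficients = as.list(model@coefficients),
              intercept = model@intercept,
              alpha = model@alpha, lambda = model@lambda,
              selection_record = model@selectionRecord,
              feature_blocks = as.list(model@featureBlocks),
              seed = model@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeStabilityModel
#' @export
readStabilityModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- as.character(obj$markers)
  num1 <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("StabilityModel", markers = markers,
      coefficients = stats::setNames(
        as.numeric(unlist(obj$coefficients)[markers]), markers),
      intercept = num1(obj$intercept),
      alpha = num1(obj$alpha), lambda = num1(obj$lambda),
      selectionRecord = lapply(obj$selection_record, as.integer),
      featureBlocks = stats::setNames(
        as.character(unlist(obj$feature_blocks)[markers]), markers),
      seed = as.integer(obj$seed))
}
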