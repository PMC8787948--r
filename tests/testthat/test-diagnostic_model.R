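sheetOf <- function(nCancer, nHealthy) {
  data.frame(sample_id = c(sprintf("c%02d", seq_len(nCancer)),
                           sprintf("h%02d", seq_len(nHealthy))),
             group = rep(c("cancer", "healthy"), c(nCancer, nHealthy)))
}

# cohort with one perfectly separating feature among noise
separableXy <- function(n = 60, p = 50, seed = 1) {
  set.seed(seed)
  y <- rep(c("cancer", "healthy"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("f%02d", 1:p)))
  x[, "f01"] <- ifelse(y == "cancer", 1, 0) + rnorm(n, sd = 0.1)
  list(x = x, y = y)
}

test_that("cohort splitting is stratified, deterministic and guarded", {
  sheet <- sheetOf(50, 50)
  sp <- splitCohort(sheet, proportion = 0.8, seed = 3L)
  expect_length(trainIds(sp), 80L)
  expect_length(validationIds(sp), 20L)
  grp <- stats::setNames(sheet$group, sheet$sample_id)
  expect_identical(as.integer(table(grp[trainIds(sp)])), c(40L, 40L))
  expect_identical(as.integer(table(grp[validationIds(sp)])), c(10L, 10L))
  expect_length(intersect(trainIds(sp), validationIds(sp)), 0L)

  expect_identical(trainIds(splitCohort(sheet, seed = 3L)), trainIds(sp))
  expect_false(identical(trainIds(splitCohort(sheet, seed = 4L)),
                         trainIds(sp)))
  expect_error(splitCohort(sheet, proportion = 1.0), "proportion")
  expect_error(splitCohort(sheetOf(1, 5), seed = 1L), "fewer than 2")
})

test_that("stability selection finds a separating feature in every cross", {
  for (seed in c(1L, 2L, 3L)) {
    d <- separableXy(seed = seed)
    sel <- stabilitySelect(d$x, d$y, nRepeats = 30L, minCrosses = 5L,
                           seed = seed)
    expect_true("f01" %in% sel$markers)
    expect_identical(unname(sel$crosses[["f01"]]), 1:5)
  }
})

test_that("stability selection under permuted labels returns almost nothing", {
  d <- separableXy(seed = 5)
  set.seed(99)
  yNull <- sample(d$y)
  sel <- suppressWarnings(stabilitySelect(d$x, yNull, nRepeats = 30L,
                                          minCrosses = 4L, seed = 5L))
  expect_lte(length(sel$markers), 2L)
})

test_that("marker sets shrink monotonically in the cross threshold", {
  d <- separableXy(seed = 7)
  sel <- suppressWarnings(stabilitySelect(d$x, d$y, nRepeats = 30L,
                                          minCrosses = 1L, seed = 7L))
  atLeast <- function(k) {
    names(which(rowSums(sel$frequencies >= 0.95) >= k))
  }
  expect_true(all(atLeast(5) %in% atLeast(1)))
})

test_that("the final fit maximizes training AUC and is reproducible", {
  d <- separableXy(seed = 9)
  m <- fitFinal(d$x, d$y, markers = c("f01", "f02", "f03"), seed = 9L)
  expect_s4_class(m, "StabilityModel")
  sc <- wdScore(m, d$x)
  expect_equal(auc(evaluateModel(sc, d$y)), 1)

  m2 <- fitFinal(d$x, d$y, markers = c("f01", "f02", "f03"), seed = 9L)
  expect_identical(coef(m), coef(m2))
  expect_identical(c(m@alpha, m@lambda), c(m2@alpha, m2@lambda))

  # single-marker designs are supported
  m1 <- fitFinal(d$x, d$y, markers = "f01", seed = 9L)
  expect_identical(markers(m1), "f01")
  expect_error(fitFinal(d$x, d$y, markers = character()), "empty")
})

test_that("wd-scores are the plain coefficient-weighted feature sums", {
  m <- new("StabilityModel", markers = c("a", "b"),
           coefficients = c(a = 2, b = -1), intercept = 5,
           alpha = 0.5, lambda = 0.1, selectionRecord = list(),
           featureBlocks = c(a = "hmc", b = "hmc"), seed = 1L)
  expect_equal(wdScore(m, c(a = 3, b = 4)), 2)
  expect_equal(wdScore(m, c(a = 0, b = 0)), 0)
  # linearity
  x <- matrix(runif(10), 5, 2, dimnames = list(paste0("s", 1:5),
                                               c("a", "b")))
  expect_equal(wdScore(m, 2 * x), 2 * wdScore(m, x))
  expect_error(wdScore(m, c(a = 1)), "missing")
  # intercept only shifts the linear predictor: wd-score ranks match it
  lp <- wdScore(m, x) + m@intercept
  expect_identical(rank(wdScore(m, x)), rank(lp))
})

test_that("model integration concatenates the marker blocks", {
  set.seed(77)
  n <- 60
  y <- rep(c("cancer", "healthy"), each = n / 2)
  ids <- sprintf("s%02d", 1:n)
  xH <- matrix(rnorm(n * 40), n, 40,
               dimnames = list(ids, sprintf("peak%02d", 1:40)))
  xF <- matrix(rnorm(n * 50), n, 50,
               dimnames = list(ids, sprintf("frag%02d", 1:50)))
  xH[, 1] <- xH[, 1] + ifelse(y == "cancer", 2, 0)
  xF[, 1] <- xF[, 1] + ifelse(y == "cancer", 2, 0)
  mI <- integrateModels(sprintf("peak%02d", 1:37), sprintf("frag%02d", 1:48),
                        xH, xF, y, seed = 77L)
  expect_length(markers(mI), 85L)
  expect_identical(as.integer(table(mI@featureBlocks)[c("frag", "hmc")]),
                   c(48L, 37L))
  # an empty block reduces to the other design
  mH <- integrateModels(sprintf("peak%02d", 1:5), character(), xH, xF, y,
                        seed = 77L)
  expect_identical(unname(mH@featureBlocks), rep("hmc", 5L))
  expect_error(integrateModels(character(), character(), xH, xF, y),
               "empty")
  expect_error(integrateModels("peak01", "frag01", xH[1:10, ], xF, y),
               "sample ids")
})

test_that("AUC agrees with the concordant-pair oracle and is calibrated", {
  # perfect separation
  ev <- evaluateModel(c(1, 2, 3, 10, 11, 12),
                      rep(c("healthy", "cancer"), each = 3))
  expect_equal(auc(ev), 1)
  expect_equal(c(ev@sensitivity, ev@specificity), c(1, 1))

  # random scores, large n: AUC near 1/2
  set.seed(100)
  scores <- rnorm(2000)
  labels <- rep(c("cancer", "healthy"), 1000)
  expect_gt(auc(evaluateModel(scores, labels)), 0.47)
  expect_lt(auc(evaluateModel(scores, labels)), 0.53)

  # oracle equivalence on small instances, including ties
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:100, 1)
    s <- sample(round(rnorm(n), 1))  # rounding induces ties
    l <- sample(rep(c("cancer", "healthy"), length.out = n))
    expect_equal(auc(evaluateModel(s, l)), oracleAuc(s, l),
                 tolerance = 1e-12)
  }
  expect_error(evaluateModel(1:3, rep("cancer", 3)), "both classes")
})

test_that("AUC matches the reference ROC implementation", {
  set.seed(111)
  s <- rnorm(80)
  l <- rep(c("cancer", "healthy"), 40)
  s[l == "cancer"] <- s[l == "cancer"] + 1
  ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                        levels = c("healthy", "cancer"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(evaluateModel(s, l)), ref, tolerance = 1e-12)
})

test_that("a fixed training threshold carries over to validation scoring", {
  trainScores <- c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0)
  trainLabels <- rep(c("healthy", "cancer"), each = 3)
  evT <- evaluateModel(trainScores, trainLabels)
  evV <- evaluateModel(c(0.05, 0.95, 0.4, 0.85),
                       c("healthy", "cancer", "cancer", "cancer"),
                       threshold = evT@threshold)
  expect_identical(evV@threshold, evT@threshold)
  expect_equal(evV@specificity, 1)
  expect_equal(evV@sensitivity, 2 / 3)
})

test_that("group score comparisons follow the rank-sum distribution", {
  expect_gte(compareGroupsWilcoxon(rep(c(1, 2, 3), 2),
                                   rep(c("a", "b"), each = 3))$p_value,
             0.9)
  sep <- compareGroupsWilcoxon(c(rnorm(20), rnorm(20) + 100),
                               rep(c("a", "b"), each = 20))
  expect_lt(sep$p_value, 1e-6)

  # exact permutation oracle for small groups
  set.seed(121)
  for (i in 1:5) {
    x <- rnorm(sample(4:8, 1))
    y <- rnorm(sample(4:8, 1))
    got <- compareGroupsWilcoxon(c(x, y),
                                 rep(c("a", "b"),
                                     c(length(x), length(y))))$p_value
    expect_lt(abs(got - oraclePermWilcoxon(x, y)), 0.01)
  }
})

test_that("models survive a JSON round trip and empty models score zero", {
  d <- separableXy(seed = 13)
  m <- fitFinal(d$x, d$y, markers = c("f01", "f05"), seed = 13L,
                selectionRecord = list(f01 = 1:5, f05 = c(1L, 3L)))
  path <- tempfile(fileext = ".json")
  writeStabilityModel(m, path)
  m2 <- readStabilityModel(path)
  expect_identical(markers(m2), markers(m))
  expect_equal(coef(m2), coef(m))
  expect_equal(m2@intercept, m@intercept)
  expect_identical(selectionRecord(m2), selectionRecord(m))

  empty <- new("StabilityModel", markers = character(),
               coefficients = stats::setNames(numeric(), character()),
               intercept = 0, alpha = NA_real_, lambda = NA_real_,
               selectionRecord = list(),
               featureBlocks = stats::setNames(character(), character()),
               seed = 1L)
  expect_equal(unname(wdScore(empty, d$x)), rep(0, nrow(d$x)))
  expect_equal(auc(evaluateModel(wdScore(empty, d$x), d$y)), 0.5)
  p2 <- tempfile(fileext = ".json")
  writeStabilityModel(empty, p2)
  expect_length(markers(readStabilityModel(p2)), 0L)
})
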