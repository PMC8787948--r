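#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around [stats::p.adjust()] (step-up with monotonicity
#' enforcement) that validates its input; kept as a named operation so the
#' adjustment procedure used by [differentialLoci()] is explicit and
#' testable.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, order-preserving.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differentially hydroxymethylated loci
#'
#' Per-feature two-sided Wilcoxon rank-sum test (tie-corrected normal
#' approximation) of cancer versus healthy FPKM, with a pseudocounted
#' log2 fold change of group means and Benjamini-Hochberg adjustment across
#' all tested features. A locus passes when all three thresholds hold:
#' `p_raw < pRawMax`, `p_adj < pAdjMax` and `|log2fc| >= minAbsLog2fc`
#' (defaults 0.001 / 0.05 / 0.5).
#'
#' Features that are constant across all samples get `p = 1` and
#' `log2fc = 0`.
#'
#' @param fm Feature matrix (see [FeatureMatrix()]) with group labels; both
#'   groups need at least two samples.
#' @param pRawMax,pAdjMax,minAbsLog2fc The three pass thresholds.
#' @param pseudocount Added to both group means before the fold change
#'   (`log2((mean_cancer + eps) / (mean_healthy + eps))`), avoiding division
#'   by zero for unobserved loci.
#' @return data.frame with columns `feature_id`, `log2fc`, `p_raw`, `p_adj`,
#'   `passes`, in feature order.
#' @export
differentialLoci <- function(fm, pRawMax = 0.001, pAdjMax = 0.05,
                             minAbsLog2fc = 0.5, pseudocount = 1) {
  vals <- SummarizedExperiment::assay(fm, "values")
  group <- groupLabels(fm)
  if (is.null(group)) stop("feature matrix must carry group labels")
  isC <- group == "cancer"
  if (sum(isC) < 2L || sum(!isC) < 2L)
    stop("each group needs at least two samples")
  for (th in c(pRawMax, pAdjMax))
    .assertScalarNumber(th, "threshold", lower = 1e-300, upper = 1)

  nFeat <- nrow(vals)
  pRaw <- numeric(nFeat)
  log2fc <- numeric(nFeat)
  for (k in seq_len(nFeat)) {
    x <- vals[k, isC]
    y <- vals[k, !isC]
    if (stats::var(c(x, y)) == 0) {
      pRaw[k] <- 1
      log2fc[k] <- 0
    } else {
      pRaw[k] <- stats::wilcox.test(x, y, alternative = "two.sided",
                                    exact = FALSE, correct = TRUE)$p.value
      log2fc[k] <- log2((mean(x) + pseudocount) / (mean(y) + pseudocount))
    }
  }
  pAdj <- bhAdjust(pRaw)
  res <- data.frame(feature_id = rownames(vals), log2fc = log2fc,
                    p_raw = pRaw, p_adj = pAdj,
                    passes = pRaw < pRawMax & pAdj < pAdjMax &
                      abs(log2fc) >= minAbsLog2fc,
                    stringsAsFactors = FALSE)
  .logMsg("differentialLoci: %d / %d loci pass (p < %g, adj p < %g, |log2FC| >= %g)",
          sum(res$passes), nFeat, pRawMax, pAdjMax, minAbsLog2fc)
  res
}
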