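#' Samples-by-features container
#'
#' Feature matrices (FPKM over consensus peaks, or standardized
#' fragmentation coverages) are stored as a
#' [SummarizedExperiment::SummarizedExperiment] with features as rows and
#' samples as columns (the Bioconductor convention), a single assay
#' `"values"`, and the binary group label in `colData(fm)$group`.
#'
#' @param values Numeric matrix, features x samples, with complete dimnames
#'   and no missing values.
#' @param group Optional character vector of per-sample labels, a subset of
#'   `{"cancer", "healthy"}`, parallel to the columns of `values`.
#' @param rowRanges Optional [GenomicRanges::GRanges] describing the features.
#'
#' @return A `SummarizedExperiment`.
#' @examples
#' m <- matrix(1:6, 2, 3,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' fm <- FeatureMatrix(m, group = c("cancer", "cancer", "healthy"))
#' featureValues(fm)
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
FeatureMatrix <- function(values, group = NULL, rowRanges = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (anyNA(values))
    stop("feature matrix must not contain missing values")
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != ncol(values))
      stop("'group' must have one label per sample")
    if (!all(group %in% c("cancer", "healthy")))
      stop("group labels must be 'cancer' or 'healthy'")
    cd$group <- group
  }
  if (is.null(rowRanges)) {
    SummarizedExperiment(assays = list(values = values), colData = cd)
  } else {
    names(rowRanges) <- rownames(values)
    SummarizedExperiment(assays = list(values = values), colData = cd,
                         rowRanges = rowRanges)
  }
}

#' @describeIn FeatureMatrix Feature values as a samples x features base
#'   matrix (the layout model-fitting code consumes).
#' @param fm A feature matrix as returned by `FeatureMatrix()`.
#' @export
featureValues <- function(fm) {
  t(SummarizedExperiment::assay(fm, "values"))
}

#' @describeIn FeatureMatrix Per-sample group labels (or `NULL` if unset).
#' @export
groupLabels <- function(fm) {
  cd <- SummarizedExperiment::colData(fm)
  if ("group" %in% colnames(cd)) as.character(cd$group) else NULL
}
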