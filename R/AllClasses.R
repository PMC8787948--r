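#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqnames<-
NULL

#' Synthetic reference genome for cohort simulation
#'
#' A minimal stand-in for a real genome assembly: a set of chromosomes with
#' per-window GC-fraction, "shortness" and "aberration" tracks. The GC track
#' drives coverage bias; the shortness track gives healthy samples a
#' regionally structured fragment-length profile (as real cfDNA has); the
#' aberration track localizes the cancer-specific excess of short fragments.
#' All tracks are smooth (AR(1)) so that neighbouring windows are correlated.
#'
#' @slot chromLengths Named integer vector of chromosome lengths in bp.
#' @slot gcWindow Window width in bp at which the tracks are defined.
#' @slot tracks A [GenomicRanges::GRanges] tiling of the genome with metadata
#'   columns `gc`, `shortness` and `aberration`.
#'
#' @seealso [simulateGenome()]
#' @export
setClass("SyntheticGenome",
  slots = c(chromLengths = "integer", gcWindow = "integer", tracks = "GRanges"))

setValidity("SyntheticGenome", function(object) {
  msg <- character()
  if (length(object@chromLengths) == 0L)
    msg <- c(msg, "at least one chromosome is required")
  if (is.null(names(object@chromLengths)) ||
      anyDuplicated(names(object@chromLengths)))
    msg <- c(msg, "chromosome names must be present and unique")
  if (any(object@chromLengths <= 0L))
    msg <- c(msg, "chromosome lengths must be positive")
  gc <- mcols(object@tracks)$gc
  if (is.null(gc) || any(gc < 0 | gc > 1))
    msg <- c(msg, "GC fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic cfDNA cohort
#'
#' Captures the study conditions a simulated cohort should reproduce: cohort
#' sizes, sequencing depth (fragments per sample), the mono-nucleosomal
#' fragment-length law (mode near 167 bp), the cancer-specific excess of
#' short (80-150 bp) fragments, GC-dependent coverage bias, and the number
#' and effect size of differentially hydroxymethylated peak loci.
#'
#' @slot nCancer,nHealthy Samples per arm.
#' @slot fragmentsPerSample Sequenced cfDNA fragments per sample.
#' @slot lengthModeHealthy Mode of the healthy fragment-length distribution (bp).
#' @slot lengthSd Standard deviation of the mono-nucleosomal length component (bp).
#' @slot shortExcessCancer Probability mass moved into the 80-150 bp range in
#'   cancer samples (0 disables the fragmentation signal).
#' @slot gcBiasStrength Linear coefficient of the per-window coverage weight
#'   `1 + gcBiasStrength * (gc - mean(gc))`; 0 disables GC bias.
#' @slot nPeakLoci Number of ground-truth 5hmC peak loci.
#' @slot nDifferentialLoci Number of loci whose 5hmC signal differs between
#'   groups; must not exceed `nPeakLoci`.
#' @slot effectLog2fc log2 fold change of 5hmC signal at differential loci in
#'   cancer (0 disables the 5hmC signal).
#' @slot peakFraction Fraction of a healthy sample's fragments drawn from the
#'   5hmC peak loci rather than genomic background.
#' @slot baseShortProb Baseline probability that a background fragment is a
#'   short (80-150 bp) fragment in healthy samples, modulated regionally by
#'   the genome's shortness track.
#' @slot noisePeaksPerSample Sample-private low-score summits added to each
#'   summit file; these are expected to be removed by the reproducibility
#'   filter downstream.
#' @slot seed Root seed fixing all randomness of the cohort.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("CohortDesign",
  slots = c(nCancer = "integer", nHealthy = "integer",
            fragmentsPerSample = "integer",
            lengthModeHealthy = "numeric", lengthSd = "numeric",
            shortExcessCancer = "numeric", gcBiasStrength = "numeric",
            nPeakLoci = "integer", nDifferentialLoci = "integer",
            effectLog2fc = "numeric", peakFraction = "numeric",
            baseShortProb = "numeric", noisePeaksPerSample = "integer",
            seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@nDifferentialLoci > object@nPeakLoci)
    msg <- c(msg, "nDifferentialLoci must not exceed nPeakLoci")
  for (p in c("shortExcessCancer", "peakFraction", "baseShortProb")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  if (object@fragmentsPerSample < 1L)
    msg <- c(msg, "fragmentsPerSample must be positive")
  if (any(c(object@nCancer, object@nHealthy) < 0L))
    msg <- c(msg, "cohort sizes must be non-negative")
  if (object@lengthSd <= 0) msg <- c(msg, "lengthSd must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortDesign-class Constructor with the default study conditions.
#' @param nCancer,nHealthy,fragmentsPerSample,lengthModeHealthy,lengthSd,shortExcessCancer,gcBiasStrength,nPeakLoci,nDifferentialLoci,effectLog2fc,peakFraction,baseShortProb,noisePeaksPerSample,seed
#'   See the slot documentation.
#' @export
CohortDesign <- function(nCancer = 40L, nHealthy = 40L,
                         fragmentsPerSample = 20000L,
                         lengthModeHealthy = 167, lengthSd = 10,
                         shortExcessCancer = 0.1, gcBiasStrength = 1,
                         nPeakLoci = 120L, nDifferentialLoci = 20L,
                         effectLog2fc = 2, peakFraction = 0.3,
                         baseShortProb = 0.05, noisePeaksPerSample = 20L,
                         seed = 1L) {
  new("CohortDesign",
      nCancer = .assertCount(nCancer, "nCancer"),
      nHealthy = .assertCount(nHealthy, "nHealthy"),
      fragmentsPerSample = .assertCount(fragmentsPerSample,
                                        "fragmentsPerSample", 1L),
      lengthModeHealthy = lengthModeHealthy, lengthSd = lengthSd,
      shortExcessCancer = shortExcessCancer, gcBiasStrength = gcBiasStrength,
      nPeakLoci = .assertCount(nPeakLoci, "nPeakLoci", 1L),
      nDifferentialLoci = .assertCount(nDifferentialLoci, "nDifferentialLoci"),
      effectLog2fc = effectLog2fc, peakFraction = peakFraction,
      baseShortProb = baseShortProb,
      noisePeaksPerSample = .assertCount(noisePeaksPerSample,
                                         "noisePeaksPerSample"),
      seed = .assertCount(seed, "seed"))
}

#' Ground truth of a simulated cohort
#'
#' Returned by [simulateCohort()]; records everything the generator knows and
#' downstream recovery tests need: sample labels, the peak-locus universe,
#' which loci are truly differential (and their log2 fold change), per-sample
#' mean fragment lengths, and the paths of the files written.
#'
#' @slot sampleSheet data.frame with columns `sample_id` and `group`.
#' @slot peakLoci GRanges of ground-truth summit positions (1-bp), named by
#'   locus id, with metadata columns `base_score`, `differential`, `log2fc`.
#' @slot differentialLocusIds Ids of the truly differential loci.
#' @slot meanFragmentLength Named per-sample mean fragment length (bp).
#' @slot fragmentFiles,summitFiles Named paths of the per-sample BED files.
#' @slot seed Root seed used.
#' @export
setClass("GroundTruth",
  slots = c(sampleSheet = "data.frame", peakLoci = "GRanges",
            differentialLocusIds = "character",
            meanFragmentLength = "numeric",
            fragmentFiles = "character", summitFiles = "character",
            seed = "integer"))

setValidity("GroundTruth", function(object) {
  if (!all(object@differentialLocusIds %in% names(object@peakLoci)))
    return("every differential locus id must exist in the peak-locus universe")
  TRUE
})

#' Stratified train/validation split
#'
#' @slot trainIds,validationIds Disjoint sample-id sets whose union is the
#'   cohort; class balance is preserved within one sample per class.
#' @slot proportion Training fraction (default 0.8, i.e. a 4:1 split).
#' @slot seed Seed that fixed the assignment.
#' @seealso [splitCohort()]
#' @export
setClass("SplitPlan",
  slots = c(trainIds = "character", validationIds = "character",
            proportion = "numeric", seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainIds, object@validationIds)))
    return("training and validation sets must be disjoint")
  TRUE
})

#' Stability-selection elastic-net classifier
#'
#' A fitted diagnostic model: the marker panel retained by stability
#' selection, the elastic-net coefficients refit on the full training set at
#' the cross-validated `(alpha, lambda)` optimum, and the provenance of each
#' marker (the crosses in which its selection frequency reached the cutoff).
#' Coefficients are reported on the original feature scale so that the
#' weighted diagnosis score is simply `sum(coef[k] * feature[k])`.
#'
#' @slot markers Character vector of selected feature ids.
#' @slot coefficients Named numeric coefficients, one per marker (zero
#'   allowed). Features outside `markers` implicitly carry coefficient 0.
#' @slot intercept Model intercept (excluded from wd-scores).
#' @slot alpha,lambda Chosen elastic-net mixing and penalty strength.
#' @slot selectionRecord Named list mapping each marker to the integer
#'   cross-validation crosses in which it was selected.
#' @slot featureBlocks Named character mapping each marker to its feature
#'   block ("hmc", "frag", ...); used by the integrated model.
#' @slot seed Root seed of the fit.
#' @seealso [stabilitySelect()], [fitFinal()], [wdScore()]
#' @export
setClass("StabilityModel",
  slots = c(markers = "character", coefficients = "numeric",
            intercept = "numeric", alpha = "numeric", lambda = "numeric",
            selectionRecord = "list", featureBlocks = "character",
            seed = "integer"))

setValidity("StabilityModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@markers) ||
      !identical(names(object@coefficients), object@markers))
    msg <- c(msg, "coefficients must be named exactly by the markers")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation result
#'
#' @slot auc Area under the ROC curve (Mann-Whitney rank formulation,
#'   ties credited 0.5).
#' @slot sensitivity,specificity Operating characteristics at `threshold`.
#' @slot threshold Decision threshold (score >= threshold calls cancer);
#'   chosen by Youden's J on training scores and applied unchanged to
#'   validation data.
#' @slot scores Named per-sample scores.
#' @slot labels Per-sample group labels, parallel to `scores`.
#' @seealso [evaluateModel()]
#' @export
setClass("EvalResult",
  slots = c(auc = "numeric", sensitivity = "numeric", specificity = "numeric",
            threshold = "numeric", scores = "numeric", labels = "character"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome with", length(object@chromLengths), "chromosomes,",
      sprintf("%.1f Mb total,", sum(object@chromLengths) / 1e6),
      sprintf("%d bp track windows\n", object@gcWindow))
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", object@nCancer, "cancer /", object@nHealthy,
      "healthy samples,", object@fragmentsPerSample, "fragments each\n")
  cat("  length mode", object@lengthModeHealthy, "bp; short excess",
      object@shortExcessCancer, "; GC bias", object@gcBiasStrength, "\n")
  cat("  peak loci:", object@nPeakLoci, "(", object@nDifferentialLoci,
      "differential, log2FC", object@effectLog2fc, "); seed",
      object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@sampleSheet$group)
  cat("GroundTruth:", paste(sprintf("%d %s", tab, names(tab)),
                            collapse = ", "), "\n")
  cat("  ", length(object@peakLoci), "peak loci,",
      length(object@differentialLocusIds), "differential\n")
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan:", length(object@trainIds), "training /",
      length(object@validationIds), "validation samples (proportion",
      object@proportion, ")\n")
})

setMethod("show", "StabilityModel", function(object) {
  cat("StabilityModel with", length(object@markers), "markers;",
      sprintf("alpha = %.2f, lambda = %.3g\n", object@alpha, object@lambda))
  nz <- sum(object@coefficients != 0)
  cat("  ", nz, "nonzero coefficients; intercept",
      sprintf("%.4g\n", object@intercept))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: AUC = %.4f, sensitivity = %.4f, specificity = %.4f (threshold %.4g)\n",
              object@auc, object@sensitivity, object@specificity,
              object@threshold))
})

## ---- accessors -------------------------------------------------------------

#' @rdname StabilityModel-class
#' @param object,x A fitted object.
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname StabilityModel-class
#' @export
setMethod("markers", "StabilityModel", function(object) object@markers)

#' @rdname StabilityModel-class
#' @export
setGeneric("selectionRecord",
           function(object) standardGeneric("selectionRecord"))

#' @rdname StabilityModel-class
#' @export
setMethod("selectionRecord", "StabilityModel",
          function(object) object@selectionRecord)

#' @rdname StabilityModel-class
#' @param ... Ignored.
#' @export
setMethod("coef", "StabilityModel", function(object, ...) object@coefficients)

#' @rdname SyntheticGenome-class
#' @export
setGeneric("chromSizes", function(object) standardGeneric("chromSizes"))

#' @rdname SyntheticGenome-class
#' @export
setMethod("chromSizes", "SyntheticGenome", function(object) object@chromLengths)

#' @rdname SyntheticGenome-class
#' @export
setGeneric("gcTrack", function(object) standardGeneric("gcTrack"))

#' @rdname SyntheticGenome-class
#' @export
setMethod("gcTrack", "SyntheticGenome", function(object) object@tracks)

#' @rdname GroundTruth-class
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname GroundTruth-class
#' @export
setMethod("sampleSheet", "GroundTruth", function(object) object@sampleSheet)

#' @rdname GroundTruth-class
#' @export
setGeneric("differentialLocusIds",
           function(object) standardGeneric("differentialLocusIds"))

#' @rdname GroundTruth-class
#' @export
setMethod("differentialLocusIds", "GroundTruth",
          function(object) object@differentialLocusIds)

#' @rdname GroundTruth-class
#' @export
setGeneric("peakLoci", function(object) standardGeneric("peakLoci"))

#' @rdname GroundTruth-class
#' @export
setMethod("peakLoci", "GroundTruth", function(object) object@peakLoci)

#' @rdname SplitPlan-class
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))

#' @rdname SplitPlan-class
#' @export
setMethod("trainIds", "SplitPlan", function(object) object@trainIds)

#' @rdname SplitPlan-class
#' @export
setGeneric("validationIds", function(object) standardGeneric("validationIds"))

#' @rdname SplitPlan-class
#' @export
setMethod("validationIds", "SplitPlan", function(object) object@validationIds)

#' @rdname EvalResult-class
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname EvalResult-class
#' @export
setMethod("auc", "EvalResult", function(object) object@auc)
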