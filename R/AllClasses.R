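#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif sd var
#' @importFrom utils head read.csv write.csv combn
NULL

#' RawSpectrum: one centroided measurement of one sample
#'
#' A single MALDI-TOF measurement: paired m/z (Thomson) and intensity
#' vectors, tagged with the sample id and the replicate index of the
#' measurement. m/z values are strictly ascending and intensities are
#' non-negative.
#'
#' @slot sampleId character(1) sample identifier.
#' @slot replicate integer(1) replicate (measurement) index, >= 1.
#' @slot mz numeric, strictly ascending m/z values.
#' @slot intensity numeric, same length as `mz`, all >= 0.
#'
#' @exportClass RawSpectrum
setClass("RawSpectrum",
  slots = c(
    sampleId = "character",
    replicate = "integer",
    mz = "numeric",
    intensity = "numeric"
  )
)

setValidity("RawSpectrum", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (length(object@replicate) != 1L || is.na(object@replicate) ||
      object@replicate < 1L)
    msg <- c(msg, "replicate must be a single integer >= 1")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 0) {
    if (any(!is.finite(object@mz)) || any(object@mz <= 0))
      msg <- c(msg, "mz values must be finite and positive")
    if (any(diff(object@mz) <= 0))
      msg <- c(msg, "mz values must be strictly ascending")
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' PeakTable: aligned intensity matrix on a reference m/z axis
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. Rows are reference
#' ions (rowData column `mz`, strictly ascending), columns are
#' sample-measurements with colData columns `sample_id`, `class`, `set`
#' (one of `"A1"`, `"A2"`, `"B"`, `"none"`) and `replicate`. The single
#' assay is named `"intensity"`.
#'
#' @exportClass PeakTable
setClass("PeakTable", contains = "SummarizedExperiment")

.VALID_SETS <- c("A1", "A2", "B", "none")

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"mz" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain an 'mz' column")
  } else {
    mz <- rd$mz
    if (length(mz) > 1 && any(diff(mz) <= 0))
      msg <- c(msg, "axis m/z must be strictly ascending")
    if (length(mz) > 0 && (any(!is.finite(mz)) || any(mz <= 0)))
      msg <- c(msg, "axis m/z must be finite and positive")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "class", "set", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  if ("set" %in% colnames(cd) && nrow(cd) > 0 &&
      !all(cd$set %in% .VALID_SETS))
    msg <- c(msg, "set labels must be one of A1, A2, B, none")
  if (length(msg)) msg else TRUE
})

#' LoadingVector: per-ion weighting factors from PCA-DA
#'
#' The discriminant direction of the PCA-based discriminant analysis,
#' back-projected to ion space, so that the discriminant score of a column
#' is exactly the weighted sum of its (Pareto-scaled) intensities. Scaled
#' to unit Euclidean norm and signed so that the target class scores
#' positive.
#'
#' @slot mz numeric, the reference axis.
#' @slot weight numeric, one finite weight per reference ion, not all zero.
#' @slot targetClass character(1) the class whose mean score is positive.
#'
#' @exportClass LoadingVector
setClass("LoadingVector",
  slots = c(mz = "numeric", weight = "numeric", targetClass = "character")
)

setValidity("LoadingVector", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@weight))
    msg <- c(msg, "mz and weight must have equal length")
  if (any(!is.finite(object@weight)))
    msg <- c(msg, "weights must be finite")
  if (length(object@weight) > 0 && all(object@weight == 0))
    msg <- c(msg, "weights must not all be zero")
  if (length(msg)) msg else TRUE
})

#' ScalingStats: frozen preprocessing statistics
#'
#' Per-ion mean and standard deviation used by Pareto scaling, plus the
#' total-area normalization target. Fitted once on training columns and
#' then frozen, so validation columns are transformed without refitting.
#'
#' @slot ionMean numeric per-ion mean of the normalized intensities.
#' @slot ionSd numeric per-ion sample standard deviation (>= 0).
#' @slot targetArea numeric(1) the common column sum after normalization.
#'
#' @exportClass ScalingStats
setClass("ScalingStats",
  slots = c(ionMean = "numeric", ionSd = "numeric", targetArea = "numeric")
)

setValidity("ScalingStats", function(object) {
  msg <- character()
  if (length(object@ionMean) != length(object@ionSd))
    msg <- c(msg, "ionMean and ionSd must have equal length")
  if (any(object@ionSd < 0, na.rm = TRUE))
    msg <- c(msg, "ionSd must be >= 0")
  if (length(object@targetArea) != 1L)
    msg <- c(msg, "targetArea must be a single value")
  if (!is.na(object@targetArea) && object@targetArea <= 0)
    msg <- c(msg, "targetArea must be positive")
  if (length(msg)) msg else TRUE
})

#' LOMEModel: a frozen low-mass-ion discriminant equation
#'
#' Everything needed to score a new sample: the reference m/z axis, the
#' discriminative ion panel (indices into that axis), the full weighting
#' factor vector, the frozen scaling statistics, and the decision
#' threshold (0 for the sign rule, or a trained cut-point).
#'
#' @slot axisMz numeric reference axis.
#' @slot panel integer indices of discriminative ions (sorted, unique).
#' @slot loading LoadingVector with weights on the full axis.
#' @slot scaling ScalingStats frozen on the training columns.
#' @slot threshold numeric(1) decision threshold; score > threshold is
#'   screen-positive.
#' @slot targetClass character(1) the screened-for class.
#' @slot referenceReplicate integer(1) index of the replicate whose
#'   measurement served as the reference mass spectrum.
#' @slot configHash character(1) md5 of the run configuration.
#'
#' @exportClass LOMEModel
setClass("LOMEModel",
  slots = c(
    axisMz = "numeric",
    panel = "integer",
    loading = "LoadingVector",
    scaling = "ScalingStats",
    threshold = "numeric",
    targetClass = "character",
    referenceReplicate = "integer",
    configHash = "character"
  )
)

setValidity("LOMEModel", function(object) {
  msg <- character()
  if (length(object@panel) == 0)
    msg <- c(msg, "panel must contain at least one ion")
  if (any(object@panel < 1L) || any(object@panel > length(object@axisMz)))
    msg <- c(msg, "panel indices must lie on the reference axis")
  if (anyDuplicated(object@panel))
    msg <- c(msg, "panel indices must be unique")
  if (is.unsorted(object@panel))
    msg <- c(msg, "panel indices must be sorted")
  if (length(object@loading@weight) != length(object@axisMz))
    msg <- c(msg, "loading length must equal the axis length")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite value")
  if (length(msg)) msg else TRUE
})
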