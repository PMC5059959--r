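#' Construct a RawSpectrum
#'
#' Peaks are sorted by m/z and exact duplicate m/z entries are merged by
#' summing their intensities, so the result always satisfies the class
#' invariants.
#'
#' @param sampleId sample identifier.
#' @param replicate replicate (measurement) index.
#' @param mz numeric m/z values.
#' @param intensity numeric intensities, same length as `mz`.
#' @return A [RawSpectrum-class] object.
#' @export
RawSpectrum <- function(sampleId, replicate, mz, intensity) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(rowsum(intensity, group = mz))
      mz <- sort(unique(mz))
    }
  }
  new("RawSpectrum",
    sampleId = as.character(sampleId),
    replicate = as.integer(replicate),
    mz = mz, intensity = intensity)
}

#' @describeIn RawSpectrum-class number of peaks
#' @param x,object a `RawSpectrum`.
#' @export
setMethod("length", "RawSpectrum", function(x) length(x@mz))

#' Peak m/z values
#' @param x a [RawSpectrum-class].
#' @return numeric vector of m/z values.
#' @export
peakMz <- function(x) x@mz

#' Peak intensities
#' @param x a [RawSpectrum-class].
#' @return numeric vector of intensities.
#' @export
peakIntensity <- function(x) x@intensity

#' Sample id of a spectrum
#' @param x a [RawSpectrum-class].
#' @export
sampleId <- function(x) x@sampleId

#' Replicate index of a spectrum
#' @param x a [RawSpectrum-class].
#' @export
replicateIndex <- function(x) x@replicate

setMethod("show", "RawSpectrum", function(object) {
  cat("RawSpectrum '", object@sampleId, "' replicate ", object@replicate,
      ": ", length(object@mz), " peaks", sep = "")
  if (length(object@mz))
    cat(", m/z ", format(min(object@mz), digits = 6), "-",
        format(max(object@mz), digits = 6), sep = "")
  cat("\n")
})

#' Construct a PeakTable
#'
#' @param mz strictly ascending reference m/z axis.
#' @param intensity matrix of intensities, `length(mz)` rows.
#' @param sample_id,class,set,replicate per-column metadata; `set`
#'   defaults to `"none"` and `replicate` to 1.
#' @return A [PeakTable-class].
#' @export
PeakTable <- function(mz, intensity,
                      sample_id = colnames(intensity),
                      class = rep(NA_character_, ncol(intensity)),
                      set = rep("none", ncol(intensity)),
                      replicate = rep(1L, ncol(intensity))) {
  intensity <- as.matrix(intensity)
  if (is.null(sample_id))
    sample_id <- paste0("col", seq_len(ncol(intensity)))
  colnames(intensity) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(mz = as.numeric(mz)),
    colData = S4Vectors::DataFrame(
      sample_id = as.character(sample_id),
      class = as.character(class),
      set = as.character(set),
      replicate = as.integer(replicate)
    )
  )
  new("PeakTable", se)
}

#' Reference m/z axis of a PeakTable
#' @param x a [PeakTable-class].
#' @return numeric vector.
#' @export
axisMz <- function(x) SummarizedExperiment::rowData(x)$mz

#' Intensity matrix of a PeakTable
#' @param x a [PeakTable-class].
#' @return numeric matrix, ions x columns.
#' @export
peakIntensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' Column metadata of a PeakTable as a data.frame
#' @param x a [PeakTable-class].
#' @export
columnMeta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' Replace the intensity assay, keeping all metadata
#' @param x a [PeakTable-class].
#' @param value replacement matrix of identical dimensions.
#' @export
setIntensities <- function(x, value) {
  stopifnot(all(dim(value) == dim(x)))
  SummarizedExperiment::assay(x, "intensity") <- as.matrix(value)
  x
}

setMethod("show", "PeakTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PeakTable: ", nrow(object), " ions x ", ncol(object), " columns (",
      length(unique(cd$sample_id)), " samples)\n", sep = "")
  if (nrow(object))
    cat("  axis m/z: ", format(min(axisMz(object)), digits = 6), " - ",
        format(max(axisMz(object)), digits = 6), "\n", sep = "")
  if (ncol(object)) {
    tab <- table(cd$set)
    cat("  sets: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
})

#' Construct a LoadingVector
#' @param mz reference axis.
#' @param weight per-ion weights.
#' @param targetClass class whose mean discriminant score is positive.
#' @export
LoadingVector <- function(mz, weight, targetClass = NA_character_) {
  new("LoadingVector", mz = as.numeric(mz), weight = as.numeric(weight),
      targetClass = as.character(targetClass))
}

#' Weights of a LoadingVector (or of a LOMEModel's loading)
#' @param x a [LoadingVector-class] or [LOMEModel-class].
#' @export
loadingWeights <- function(x) {
  if (is(x, "LOMEModel")) x@loading@weight else x@weight
}

setMethod("show", "LoadingVector", function(object) {
  cat("LoadingVector: ", length(object@weight), " weights, |w| = ",
      format(sqrt(sum(object@weight^2)), digits = 6),
      ", target class '", object@targetClass, "'\n", sep = "")
})

#' Construct ScalingStats
#' @param ionMean per-ion mean.
#' @param ionSd per-ion sample standard deviation.
#' @param targetArea normalization target column sum.
#' @export
ScalingStats <- function(ionMean, ionSd, targetArea = NA_real_) {
  new("ScalingStats", ionMean = as.numeric(ionMean),
      ionSd = as.numeric(ionSd), targetArea = as.numeric(targetArea))
}

setMethod("show", "ScalingStats", function(object) {
  cat("ScalingStats: ", length(object@ionMean), " ions, target area ",
      format(object@targetArea, digits = 6), "\n", sep = "")
})

#' Panel m/z values of a LOMEModel
#' @param x a [LOMEModel-class].
#' @export
panelMz <- function(x) x@axisMz[x@panel]

#' Panel indices of a LOMEModel
#' @param x a [LOMEModel-class].
#' @export
panelIndices <- function(x) x@panel

#' Decision threshold of a LOMEModel
#' @param x a [LOMEModel-class].
#' @export
decisionThreshold <- function(x) x@threshold

#' Frozen scaling statistics of a LOMEModel
#' @param x a [LOMEModel-class].
#' @export
scalingStats <- function(x) x@scaling

setMethod("show", "LOMEModel", function(object) {
  cat("LOMEModel: ", length(object@panel), "-ion panel on a ",
      length(object@axisMz), "-ion axis\n", sep = "")
  cat("  target class: ", object@targetClass,
      "; threshold: ", format(object@threshold, digits = 6),
      "; reference replicate: ", object@referenceReplicate, "\n", sep = "")
  cat("  panel m/z:", paste(format(panelMz(object), digits = 7),
                            collapse = ", "), "\n")
})
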