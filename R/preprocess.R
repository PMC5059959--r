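#' Build a reference m/z axis from a set of spectra
#'
#' Emulates importing several centroided spectra into one peak table:
#' pooled peaks are greedily clustered in ascending m/z order (a new
#' cluster starts when a peak lies more than `tolerancePpm` above the
#' first peak of the current cluster) and each cluster contributes its
#' mean m/z as one axis point.
#'
#' @param spectra list of [RawSpectrum-class].
#' @param tolerancePpm clustering tolerance in ppm (default 300).
#' @return strictly ascending numeric axis.
#' @export
buildReferenceAxis <- function(spectra, tolerancePpm = 300) {
  mz <- sort(unlist(lapply(spectra, peakMz), use.names = FALSE))
  if (!length(mz)) stop("no peaks to build an axis from")
  tol <- tolerancePpm * 1e-6
  # cluster id grows where the relative gap to the cluster anchor exceeds tol
  cl <- integer(length(mz))
  id <- 1L
  anchor <- mz[1]
  cl[1] <- 1L
  for (i in seq_along(mz)[-1]) {
    if (mz[i] > anchor * (1 + tol)) {
      id <- id + 1L
      anchor <- mz[i]
    }
    cl[i] <- id
  }
  as.numeric(rowsum(mz, cl) / tabulate(cl))
}

# Assign each peak to its nearest reference ion in ppm distance
# (|mz_peak - mz_ref| / mz_ref), inclusive tolerance, ties toward the
# lower-m/z reference ion. Returns index into axis, NA if unmatched.
.assignPeaks <- function(mz, axisMz, tolerancePpm) {
  tol <- tolerancePpm * 1e-6
  lo <- findInterval(mz, axisMz)
  hi <- pmin(lo + 1L, length(axisMz))
  lo <- pmax(lo, 1L)
  dLo <- abs(mz - axisMz[lo]) / axisMz[lo]
  dHi <- abs(mz - axisMz[hi]) / axisMz[hi]
  pick <- ifelse(dHi < dLo, hi, lo)  # tie -> lower m/z (lo)
  dist <- pmin(dLo, dHi)
  ifelse(dist <= tol, pick, NA_integer_)
}

#' Align one spectrum onto a reference axis
#'
#' Each sample peak is assigned to at most one reference ion: the nearest
#' in ppm distance, provided the distance is within the (inclusive)
#' tolerance; ties break toward the lower m/z. Multiple peaks assigned to
#' one ion are summed; unassigned reference ions get intensity 0.
#'
#' @param spectrum a [RawSpectrum-class].
#' @param axisMz ascending reference axis.
#' @param tolerancePpm matching tolerance in ppm (default 300).
#' @return numeric intensity vector, one value per reference ion.
#' @export
alignToReference <- function(spectrum, axisMz, tolerancePpm = 300) {
  if (!length(axisMz)) stop("reference axis is empty")
  stopifnot(tolerancePpm > 0)
  out <- numeric(length(axisMz))
  if (!length(spectrum@mz)) return(out)
  idx <- .assignPeaks(spectrum@mz, axisMz, tolerancePpm)
  ok <- !is.na(idx)
  if (any(ok)) {
    sums <- rowsum(spectrum@intensity[ok], group = idx[ok])
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

#' Build an aligned PeakTable from spectra
#'
#' @param spectra list of [RawSpectrum-class].
#' @param axisMz reference axis.
#' @param meta data.frame with one row per spectrum (sample_id, class,
#'   set, replicate); defaults are taken from the spectra themselves.
#' @param tolerancePpm matching tolerance in ppm.
#' @return A [PeakTable-class].
#' @export
buildPeakTable <- function(spectra, axisMz, meta = NULL,
                           tolerancePpm = 300) {
  x <- vapply(spectra, alignToReference, numeric(length(axisMz)),
              axisMz = axisMz, tolerancePpm = tolerancePpm)
  x <- matrix(x, nrow = length(axisMz))
  if (is.null(meta))
    meta <- data.frame(
      sample_id = vapply(spectra, sampleId, character(1)),
      class = NA_character_,
      set = "none",
      replicate = vapply(spectra, replicateIndex, integer(1))
    )
  PeakTable(axisMz, x, sample_id = meta$sample_id, class = meta$class,
            set = meta$set, replicate = meta$replicate)
}

#' Realign a peak table onto a reference axis
#'
#' Every column is treated as a peak list on the table's current axis and
#' re-matched against the reference axis at the given tolerance. Ions
#' that collide on the reference axis are merged by sum; ions farther
#' than the tolerance from every reference ion are dropped. The
#' operation is idempotent: realigning a table already on the reference
#' axis is the identity.
#'
#' @param table a [PeakTable-class].
#' @param axisMz the reference axis.
#' @param tolerancePpm matching tolerance in ppm.
#' @return A [PeakTable-class] on `axisMz`.
#' @export
realign <- function(table, axisMz, tolerancePpm = 300) {
  if (ncol(table) == 0) stop("cannot realign an empty table")
  old <- axisMz(table)
  idx <- .assignPeaks(old, axisMz, tolerancePpm)
  x <- peakIntensities(table)
  out <- matrix(0, nrow = length(axisMz), ncol = ncol(x))
  ok <- !is.na(idx)
  if (any(ok)) {
    sums <- rowsum(x[ok, , drop = FALSE], group = idx[ok])
    out[as.integer(rownames(sums)), ] <- sums
  }
  cd <- columnMeta(table)
  PeakTable(axisMz, out, sample_id = cd$sample_id, class = cd$class,
            set = cd$set, replicate = cd$replicate)
}

#' Total-area-sum normalization
#'
#' Scales every column so its intensity sum equals a common target area.
#' When fitting (`targetArea = NULL`) the target is the mean of the input
#' columns' sums, so the average column is unchanged; a frozen target can
#' be supplied to normalize validation columns without refitting.
#'
#' @param table a [PeakTable-class]; every column must have a positive
#'   intensity sum.
#' @param targetArea optional frozen target area.
#' @return list with `table` (normalized) and `targetArea`.
#' @export
normalizeTotalArea <- function(table, targetArea = NULL) {
  x <- peakIntensities(table)
  sums <- colSums(x)
  if (any(sums <= 0)) {
    bad <- which(sums <= 0)[1]
    cd <- columnMeta(table)
    stop("column ", bad, " (sample ", cd$sample_id[bad], ", replicate ",
         cd$replicate[bad], ") has non-positive total area")
  }
  if (is.null(targetArea)) targetArea <- mean(sums)
  out <- sweep(x, 2, targetArea / sums, `*`)
  list(table = setIntensities(table, out), targetArea = targetArea)
}

#' Pareto scaling
#'
#' Per ion i and column j the scaled value is
#' (x_ij - mean_i) / sqrt(sd_i), with the per-ion mean and sample
#' (n-1) standard deviation computed across the fitting columns. Ions
#' with zero standard deviation map to 0 in every column.
#' `paretoScale` fits and applies; `applyPareto` applies frozen
#' statistics to new columns.
#'
#' @param table a [PeakTable-class]; fitting needs >= 2 columns.
#' @return `paretoScale`: list with `table` (scaled) and `stats`
#'   ([ScalingStats-class], `targetArea` left `NA`).
#' @export
paretoScale <- function(table) {
  x <- peakIntensities(table)
  if (ncol(x) < 2) stop("Pareto scaling needs >= 2 columns to fit")
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  stats <- ScalingStats(ionMean = m, ionSd = s)
  list(table = applyPareto(table, stats), stats = stats)
}

#' @rdname paretoScale
#' @param stats frozen [ScalingStats-class].
#' @export
applyPareto <- function(table, stats) {
  x <- peakIntensities(table)
  if (nrow(x) != length(stats@ionMean))
    stop("scaling statistics length (", length(stats@ionMean),
         ") does not match ion count (", nrow(x), ")")
  denom <- sqrt(stats@ionSd)
  out <- (x - stats@ionMean) / denom
  out[stats@ionSd == 0, ] <- 0
  setIntensities(table, out)
}

#' Multiply a table by per-ion weighting factors
#'
#' @param table a [PeakTable-class].
#' @param loading a [LoadingVector-class] (or bare numeric) whose length
#'   equals the ion count.
#' @return the weighted [PeakTable-class].
#' @export
applyWeights <- function(table, loading) {
  w <- if (is(loading, "LoadingVector")) loading@weight else as.numeric(loading)
  if (length(w) != nrow(table))
    stop("weight length (", length(w), ") does not match ion count (",
         nrow(table), ")")
  setIntensities(table, peakIntensities(table) * w)
}

#' Average replicate columns per sample
#'
#' Collapses the table to one column per sample: each cell is the
#' arithmetic mean across that sample's replicate columns. Column
#' metadata collapses to (sample_id, class, set); the replicate index is
#' set to NA.
#'
#' @param table a [PeakTable-class] with >= 1 column per sample.
#' @return the averaged [PeakTable-class], columns in first-appearance
#'   order of the sample ids.
#' @export
averageReplicates <- function(table) {
  if (ncol(table) == 0) stop("cannot average an empty table")
  cd <- columnMeta(table)
  ids <- unique(cd$sample_id)
  grp <- match(cd$sample_id, ids)
  x <- peakIntensities(table)
  cnt <- tabulate(grp, nbins = length(ids))
  out <- matrix(0, nrow = nrow(x), ncol = length(ids))
  for (j in seq_len(ncol(x))) out[, grp[j]] <- out[, grp[j]] + x[, j]
  out <- sweep(out, 2, cnt, `/`)
  first <- match(ids, cd$sample_id)
  PeakTable(axisMz(table), out, sample_id = ids,
            class = cd$class[first], set = cd$set[first],
            replicate = rep(NA_integer_, length(ids)))
}
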