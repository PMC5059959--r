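#' Run configuration for the LOME pipeline
#'
#' Defaults reproduce the published import and search settings: 300 ppm
#' mass tolerance, minimum response 10.0, at most 10000 peaks, weighted
#' magnitude threshold 0.1 in more than half of the columns.
#'
#' @param targetClass the screened-for class label.
#' @param tolerancePpm alignment tolerance in ppm.
#' @param minResponse minimum retained intensity.
#' @param maxPeaks maximum retained peaks per spectrum.
#' @param magnitudeThreshold Search Algorithm 1 magnitude cut-off.
#' @param columnFraction Search Algorithm 1 column fraction.
#' @param varianceRule PCA variance rule (fraction of explained
#'   variance).
#' @param maxComponents optional cap on retained components.
#' @param candidateCap cap on candidates entering Search Algorithm 2.
#' @param thresholdMode `"sign"` (threshold 0) or `"trained"`.
#' @param includeReferenceReplicate keep the reference-defining
#'   replicate among the downstream columns (default FALSE).
#' @param holdoutClasses classes excluded from training; their samples
#'   are assigned to the validation set and reported separately.
#' @param rngSeed seed for the trisection.
#' @return a validated `run_config` list.
#' @export
runConfig <- function(targetClass,
                      tolerancePpm = 300,
                      minResponse = 10.0,
                      maxPeaks = 10000L,
                      magnitudeThreshold = 0.1,
                      columnFraction = 0.5,
                      varianceRule = 0.95,
                      maxComponents = NULL,
                      candidateCap = 64L,
                      thresholdMode = c("sign", "trained"),
                      includeReferenceReplicate = FALSE,
                      holdoutClasses = character(),
                      rngSeed = 1L) {
  stopifnot(tolerancePpm > 0, minResponse >= 0, maxPeaks >= 1,
            magnitudeThreshold >= 0, columnFraction >= 0,
            columnFraction < 1, varianceRule > 0, varianceRule <= 1,
            candidateCap >= 1)
  cfg <- list(
    targetClass = as.character(targetClass),
    tolerancePpm = as.numeric(tolerancePpm),
    minResponse = as.numeric(minResponse),
    maxPeaks = as.integer(maxPeaks),
    magnitudeThreshold = as.numeric(magnitudeThreshold),
    columnFraction = as.numeric(columnFraction),
    varianceRule = as.numeric(varianceRule),
    maxComponents = if (is.null(maxComponents)) NULL
                    else as.integer(maxComponents),
    candidateCap = as.integer(candidateCap),
    thresholdMode = match.arg(thresholdMode),
    includeReferenceReplicate = isTRUE(includeReferenceReplicate),
    holdoutClasses = as.character(holdoutClasses),
    rngSeed = as.integer(rngSeed)
  )
  class(cfg) <- "run_config"
  cfg
}

# Named atomic vectors would lose their names in JSON; listify them.
.jsonify <- function(x) {
  if (is.list(x)) lapply(x, .jsonify)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config[order(names(config))], f, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(f))
}

#' Trisect samples into training and validation sets
#'
#' Within every stratum (class, or class x stage when a stage column is
#' present) the samples are divided almost evenly among Sets A1, A2 and
#' B: set sizes differ by at most one, and which sets receive the
#' remainder is decided by the seeded RNG, as is the sample shuffling.
#' Classes listed in `holdoutClasses` are excluded from training and
#' assigned wholly to Set B.
#'
#' @param manifest data.frame with sample_id and class columns (one or
#'   more rows per sample); an optional `stage` column refines the
#'   strata.
#' @param rngSeed integer seed.
#' @param holdoutClasses classes assigned wholly to the validation set.
#' @return data.frame with columns sample_id, set.
#' @export
trisect <- function(manifest, rngSeed = 1L, holdoutClasses = character()) {
  if (!nrow(manifest)) stop("empty manifest")
  cols <- c("sample_id", "class", intersect("stage", colnames(manifest)))
  samples <- unique(manifest[, cols, drop = FALSE])
  if (anyDuplicated(samples$sample_id))
    stop("inconsistent class/stage metadata within a sample")
  strata <- if ("stage" %in% colnames(samples))
    paste(samples$class, samples$stage, sep = "|") else samples$class

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rngSeed)

  sets <- c("A1", "A2", "B")
  out <- character(nrow(samples))
  for (st in sort(unique(strata))) {
    idx <- which(strata == st)
    if (samples$class[idx[1]] %in% holdoutClasses) {
      out[idx] <- "B"
      next
    }
    n <- length(idx)
    base <- n %/% 3L
    rem <- n %% 3L
    extras <- sample(sets)[seq_len(rem)]
    sizes <- base + as.integer(sets %in% extras)
    assignment <- rep(sets, times = sizes)
    out[idx] <- assignment[sample.int(n)]
  }
  data.frame(sample_id = samples$sample_id, set = out,
             stringsAsFactors = FALSE)
}

#' Mean discriminant score of each sample
#'
#' The mean DS of a sample is the sum, over the model's discriminative
#' ions, of the sample's averaged weighted intensities. The table must
#' be on the model's reference axis.
#'
#' @param table the replicate-averaged, weighted [PeakTable-class].
#' @param model a [LOMEModel-class].
#' @return named numeric vector of scores, one per column.
#' @export
meanDS <- function(table, model) {
  if (nrow(table) != length(model@axisMz) ||
      !isTRUE(all.equal(axisMz(table), model@axisMz)))
    stop("table axis does not match the model's reference axis")
  x <- peakIntensities(table)
  ds <- colSums(x[model@panel, , drop = FALSE])
  names(ds) <- columnMeta(table)$sample_id
  ds
}

#' Screening decision from a discriminant score
#'
#' Screen-positive iff the score strictly exceeds the threshold; a score
#' exactly at the threshold (including the sign rule's DS = 0) is
#' negative, favoring specificity.
#'
#' @param ds numeric discriminant score(s).
#' @param threshold decision threshold (default 0, the sign rule).
#' @return logical vector, TRUE = screen-positive.
#' @export
classifyDS <- function(ds, threshold = 0) ds > threshold

#' Train a decision threshold on labelled scores
#'
#' Scans all cut-points (midpoints of consecutive distinct sorted
#' scores, plus one below and one above the observed range) and returns
#' the threshold maximizing sensitivity + specificity; ties break toward
#' the larger specificity, then the smaller threshold.
#'
#' @param ds numeric training scores.
#' @param classes per-score class labels.
#' @param targetClass the positive class.
#' @return numeric threshold.
#' @export
trainThreshold <- function(ds, classes, targetClass) {
  pos <- classes == targetClass
  if (all(pos) || !any(pos))
    stop("both classes must be present to train a threshold")
  u <- sort(unique(ds))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cuts, function(t) sum(ds > t & pos) / sum(pos), numeric(1))
  spec <- vapply(cuts, function(t) sum(ds <= t & !pos) / sum(!pos),
                 numeric(1))
  ss <- sens + spec
  best <- which(ss == max(ss))
  if (length(best) > 1) best <- best[spec[best] == max(spec[best])]
  cuts[best[1]]
}

.roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification metrics of screening decisions
#'
#' Computes the confusion counts and sensitivity, specificity, PPV and
#' NPV as percentages (full precision, plus half-up rounding to two
#' decimals for reporting; undefined ratios are NA, never 0). When group
#' labels are supplied, a per-group specificity is reported for every
#' non-target group; groups listed in `excludeGroups` (e.g. classes the
#' model was never trained on) are kept out of the overall counts and
#' appear only in the per-group table.
#'
#' @param predicted logical screen decisions.
#' @param actual logical, TRUE for the target class.
#' @param groups optional per-sample group labels.
#' @param excludeGroups groups excluded from the overall metrics.
#' @return list with `counts` (TP, FP, TN, FN), `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent, full precision), `reported`
#'   (the same, rounded half-up to 2 decimals), and
#'   `groupSpecificity` / `reportedGroupSpecificity`.
#' @export
evaluateMetrics <- function(predicted, actual, groups = NULL,
                            excludeGroups = character()) {
  if (length(predicted) != length(actual))
    stop("prediction and label lengths differ")
  inc <- if (is.null(groups)) rep(TRUE, length(actual))
         else !(groups %in% excludeGroups)
  p <- predicted[inc]
  a <- actual[inc]
  tp <- sum(p & a); fn <- sum(!p & a)
  tn <- sum(!p & !a); fp <- sum(p & !a)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp)
  npv <- pct(tn, tn + fn)
  gspec <- NULL
  if (!is.null(groups)) {
    gl <- setdiff(unique(groups[!actual]), character(0))
    gspec <- vapply(gl, function(g) {
      i <- groups == g & !actual
      pct(sum(!predicted[i]), sum(i))
    }, numeric(1))
    names(gspec) <- gl
  }
  list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    reported = c(sensitivity = .roundHalfUp(sens),
                 specificity = .roundHalfUp(spec),
                 ppv = .roundHalfUp(ppv),
                 npv = .roundHalfUp(npv)),
    groupSpecificity = gspec,
    reportedGroupSpecificity = if (is.null(gspec)) NULL
                               else .roundHalfUp(gspec)
  )
}

# Preprocess aligned tables for model building/scoring: normalization ->
# Pareto -> weights -> replicate averaging. Frozen stats when supplied.
.preprocessColumns <- function(table, loading, stats = NULL) {
  if (is.null(stats)) {
    norm <- normalizeTotalArea(table)
    par <- paretoScale(norm$table)
    stats <- par$stats
    stats@targetArea <- norm$targetArea
    scaled <- par$table
  } else {
    norm <- normalizeTotalArea(table, targetArea = stats@targetArea)
    scaled <- applyPareto(norm$table, stats)
  }
  weighted <- applyWeights(scaled, loading)
  list(averaged = averageReplicates(weighted), stats = stats)
}

#' Build a LOME model under the two-stage training scheme
#'
#' Pipeline: (1) trisect the samples (unless the manifest already
#' assigns sets); (2) apply the import filters; (3) for each replicate,
#' align the Set A1 spectra of that measurement on their own merged
#' axis, preprocess, and fit PCA-DA; the replicate with the best
#' separation becomes the reference mass spectrum and supplies the
#' reference axis and the weighting factors; (4) run Search Algorithm 1
#' on the weighted reference table; (5) align all remaining measurements
#' of every sample on the reference axis, normalize and Pareto-scale
#' with statistics fitted on the Set A columns and frozen, weight, and
#' average replicates per sample; (6) run Search Algorithm 2 on the
#' averaged Set A table; (7) freeze the model (threshold 0 under the
#' sign rule, or trained on Set A) and evaluate Sets A1, A2 and B
#' separately.
#'
#' @param spectra list of [RawSpectrum-class], parallel to the manifest
#'   rows.
#' @param manifest data.frame with sample_id, class, replicate and
#'   optionally set columns.
#' @param config a [runConfig()].
#' @return list with `model` ([LOMEModel-class]), `report` (per-set
#'   metrics, candidate count, search trace, per-replicate separation)
#'   and `tables` (the averaged weighted Set A and Set B tables).
#' @export
buildLome <- function(spectra, manifest, config) {
  stopifnot(length(spectra) == nrow(manifest))
  tol <- config$tolerancePpm

  spectra <- lapply(spectra, applyImportFilters,
                    minResponse = config$minResponse,
                    maxPeaks = config$maxPeaks)

  if (!"set" %in% colnames(manifest) || all(manifest$set == "none")) {
    tri <- trisect(manifest, rngSeed = config$rngSeed,
                   holdoutClasses = config$holdoutClasses)
    manifest$set <- tri$set[match(manifest$sample_id, tri$sample_id)]
  }

  a1 <- manifest$set == "A1"
  if (!any(a1)) stop("stage reference-selection: no Set A1 samples")
  replicates <- sort(unique(manifest$replicate))
  repTables <- lapply(replicates, function(r) {
    rows <- which(a1 & manifest$replicate == r)
    if (!length(rows))
      stop("stage reference-selection: replicate ", r,
           " has no Set A1 measurements")
    axis <- buildReferenceAxis(spectra[rows], tol)
    buildPeakTable(spectra[rows], axis, manifest[rows, ], tol)
  })
  sel <- selectReferenceMeasurement(repTables, config$targetClass,
                                    varianceRule = config$varianceRule,
                                    maxComponents = config$maxComponents)
  refReplicate <- replicates[sel$replicateIndex]
  loading <- sel$fit$pcada$loading
  referenceAxis <- axisMz(sel$fit$table)

  weightedRef <- applyWeights(sel$fit$table, loading)
  candidates <- searchPreliminary(weightedRef,
                                  config$magnitudeThreshold,
                                  config$columnFraction)
  if (!length(candidates$index))
    stop("stage candidate-search: no preliminary candidates selected")

  keepRows <- if (config$includeReferenceReplicate) seq_len(nrow(manifest))
              else which(manifest$replicate != refReplicate)
  man <- manifest[keepRows, ]
  aligned <- buildPeakTable(spectra[keepRows], referenceAxis, man, tol)
  aligned <- realign(aligned, referenceAxis, tol)

  inA <- columnMeta(aligned)$set %in% c("A1", "A2")
  if (!any(inA)) stop("stage preprocessing: no Set A columns")
  prepA <- .preprocessColumns(aligned[, inA], loading)
  stats <- prepA$stats
  avgA <- prepA$averaged
  avgB <- if (any(!inA))
    .preprocessColumns(aligned[, !inA], loading, stats)$averaged
  else NULL

  found <- searchDiscriminative(candidates, avgA,
                                targetClass = config$targetClass,
                                candidateCap = config$candidateCap)
  panel <- as.integer(found$panel)

  dsA <- colSums(peakIntensities(avgA)[panel, , drop = FALSE])
  threshold <- if (config$thresholdMode == "trained")
    trainThreshold(dsA, columnMeta(avgA)$class, config$targetClass)
  else 0

  model <- new("LOMEModel",
    axisMz = referenceAxis,
    panel = panel,
    loading = loading,
    scaling = stats,
    threshold = threshold,
    targetClass = config$targetClass,
    referenceReplicate = as.integer(refReplicate),
    configHash = .configHash(config))

  evalSet <- function(avg, setLabel) {
    cd <- columnMeta(avg)
    keep <- cd$set == setLabel
    if (!any(keep)) return(NULL)
    ds <- meanDS(avg[, keep], model)
    cls <- cd$class[keep]
    m <- evaluateMetrics(classifyDS(ds, model@threshold),
                         cls == config$targetClass,
                         groups = cls,
                         excludeGroups = config$holdoutClasses)
    m$ds <- ds
    m
  }
  report <- list(
    sets = Filter(Negate(is.null), list(
      A1 = evalSet(avgA, "A1"),
      A2 = evalSet(avgA, "A2"),
      B = if (!is.null(avgB)) evalSet(avgB, "B") else NULL
    )),
    nCandidates = length(candidates$index),
    candidateMz = candidates$mz,
    panelMz = referenceAxis[panel],
    referenceReplicate = refReplicate,
    replicateSeparation = sel$separation,
    searchTrace = found$trace
  )
  list(model = model, report = report,
       tables = list(avgA = avgA, avgB = avgB),
       manifest = manifest)
}

#' Score new samples with a frozen LOME model
#'
#' Applies the import filters, aligns every measurement on the model's
#' reference axis, normalizes to the frozen target area, applies the
#' frozen Pareto statistics and the weighting factors, averages the
#' replicates per sample, and returns the mean discriminant score and
#' the screening decision.
#'
#' @param model a [LOMEModel-class].
#' @param spectra list of [RawSpectrum-class].
#' @param manifest data.frame parallel to `spectra` (sample_id, class,
#'   replicate, set); constructed from the spectra when omitted.
#' @param tolerancePpm,minResponse,maxPeaks import settings (defaults:
#'   300 ppm, 10.0, 10000).
#' @param includeReferenceReplicate also average the measurements of the
#'   replicate that defined the reference spectrum (default FALSE,
#'   matching the training pipeline, which averages the other
#'   measurements of each sample).
#' @return data.frame with sample_id, ds, decision.
#' @export
scoreSamples <- function(model, spectra, manifest = NULL,
                         tolerancePpm = 300, minResponse = 10.0,
                         maxPeaks = 10000L,
                         includeReferenceReplicate = FALSE) {
  if (!length(spectra)) {
    return(data.frame(sample_id = character(0), ds = numeric(0),
                      decision = character(0)))
  }
  spectra <- lapply(spectra, applyImportFilters,
                    minResponse = minResponse, maxPeaks = maxPeaks)
  if (is.null(manifest))
    manifest <- data.frame(
      sample_id = vapply(spectra, sampleId, character(1)),
      class = NA_character_,
      set = "none",
      replicate = vapply(spectra, replicateIndex, integer(1)))
  if (!includeReferenceReplicate) {
    keep <- manifest$replicate != model@referenceReplicate
    # a sample measured only on the reference replicate keeps its rows
    lost <- setdiff(manifest$sample_id, manifest$sample_id[keep])
    keep <- keep | manifest$sample_id %in% lost
    spectra <- spectra[keep]
    manifest <- manifest[keep, , drop = FALSE]
  }
  aligned <- buildPeakTable(spectra, model@axisMz, manifest, tolerancePpm)
  avg <- .preprocessColumns(aligned, model@loading, model@scaling)$averaged
  ds <- meanDS(avg, model)
  data.frame(
    sample_id = columnMeta(avg)$sample_id,
    ds = as.numeric(ds),
    decision = ifelse(classifyDS(ds, model@threshold),
                      "positive", "negative"),
    stringsAsFactors = FALSE)
}

#' Augment a model's panel with extra ions and retrain the threshold
#'
#' The extra m/z values are matched to the model's reference axis within
#' 300 ppm (error if absent); the panel becomes the union of the
#' existing and extra ions with weights taken from the stored loading
#' vector, and the decision threshold is retrained on the supplied
#' training table.
#'
#' @param model a [LOMEModel-class].
#' @param extraMz numeric m/z values to add (may be empty).
#' @param trainingTable the averaged weighted training
#'   [PeakTable-class] (Set A).
#' @param targetClass positive class (default: the model's).
#' @param tolerancePpm matching tolerance for the extra ions.
#' @return the augmented [LOMEModel-class].
#' @export
augmentModel <- function(model, extraMz, trainingTable,
                         targetClass = model@targetClass,
                         tolerancePpm = 300) {
  extra <- integer(0)
  if (length(extraMz)) {
    idx <- .assignPeaks(sort(as.numeric(extraMz)), model@axisMz,
                        tolerancePpm)
    if (anyNA(idx)) {
      bad <- sort(as.numeric(extraMz))[which(is.na(idx))[1]]
      stop("extra m/z ", format(bad, digits = 9),
           " is not on the reference axis within ", tolerancePpm, " ppm")
    }
    extra <- as.integer(idx)
  }
  panel <- sort(union(model@panel, extra))
  ds <- colSums(peakIntensities(trainingTable)[panel, , drop = FALSE])
  thr <- trainThreshold(ds, columnMeta(trainingTable)$class, targetClass)
  initialize(model, panel = as.integer(panel), threshold = thr)
}

#' Write / read a LOME model bundle
#'
#' The bundle is a directory of plain-text artifacts: `loading.csv`
#' (m/z, weight on the full axis), `panel.csv` (the discriminative
#' ions), `scaling.json` (frozen statistics), `model.json` (threshold,
#' target class, reference replicate, config hash) and, when supplied,
#' `report.json`.
#'
#' @param model a [LOMEModel-class].
#' @param dir bundle directory.
#' @param report optional report list from [buildLome()].
#' @return `readModelBundle` returns a list with `model` and (if
#'   present) `report`.
#' @export
writeModelBundle <- function(model, dir, report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f)
    utils::write.table(format(df, digits = 17, trim = TRUE),
                       file.path(dir, f), sep = ",", quote = FALSE,
                       row.names = FALSE)
  wcsv(data.frame(mz = model@axisMz, weight = model@loading@weight),
       "loading.csv")
  wcsv(data.frame(index = model@panel, mz = panelMz(model),
                  weight = model@loading@weight[model@panel]),
       "panel.csv")
  jsonlite::write_json(
    list(targetArea = model@scaling@targetArea,
         ionMean = model@scaling@ionMean,
         ionSd = model@scaling@ionSd),
    file.path(dir, "scaling.json"), digits = NA)
  jsonlite::write_json(
    list(threshold = model@threshold,
         targetClass = model@targetClass,
         referenceReplicate = model@referenceReplicate,
         configHash = model@configHash),
    file.path(dir, "model.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(report))
    jsonlite::write_json(.jsonify(report), file.path(dir, "report.json"),
                         digits = NA, force = TRUE, na = "null")
  invisible(dir)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(dir) {
  loading <- utils::read.csv(file.path(dir, "loading.csv"))
  panel <- utils::read.csv(file.path(dir, "panel.csv"))
  sc <- jsonlite::read_json(file.path(dir, "scaling.json"),
                            simplifyVector = TRUE)
  mj <- jsonlite::read_json(file.path(dir, "model.json"),
                            simplifyVector = TRUE)
  model <- new("LOMEModel",
    axisMz = loading$mz,
    panel = as.integer(panel$index),
    loading = LoadingVector(loading$mz, loading$weight, mj$targetClass),
    scaling = ScalingStats(sc$ionMean, sc$ionSd, sc$targetArea),
    threshold = as.numeric(mj$threshold),
    targetClass = mj$targetClass,
    referenceReplicate = as.integer(mj$referenceReplicate),
    configHash = as.character(mj$configHash))
  rep <- NULL
  rf <- file.path(dir, "report.json")
  if (file.exists(rf)) rep <- jsonlite::read_json(rf, simplifyVector = TRUE)
  list(model = model, report = rep)
}
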