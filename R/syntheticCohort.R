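#' Configuration for a synthetic MALDI-like cohort
#'
#' Describes a multi-class serum-profiling cohort: several disease classes
#' with one designated target (screened-for) class, a few thousand
#' detectable low-mass ions on m/z 50-2500, a handful of planted
#' class-discriminative ions, multiplicative replicate noise, a
#' per-measurement global intensity factor, and mass-axis jitter.
#'
#' @param classLabels character vector of class labels.
#' @param targetClass the one label carrying the planted signal.
#' @param nPerClass samples per class.
#' @param nIons number of baseline ions (2000 at desk scale).
#' @param nPlanted number of planted discriminative ions.
#' @param effectSize mean log-intensity shift of planted ions in the
#'   target class (dimensionless, natural-log scale).
#' @param noiseCv coefficient of variation of the multiplicative
#'   replicate noise.
#' @param massJitterPpm standard deviation of the per-measurement m/z
#'   perturbation, in ppm.
#' @param nReplicates measurements per sample (>= 2).
#' @param rngSeed integer seed; identical configurations reproduce the
#'   cohort exactly.
#' @param baseLogMean,baseLogSd mean and sd of the per-ion baseline
#'   natural-log intensity.
#' @param sampleScaleSd sd (log scale) of the per-measurement global
#'   intensity factor that total-area normalization is meant to remove.
#' @param minSpacing enforce a minimum spacing of 600 ppm between nominal
#'   ion m/z so alignment at 300 ppm is unambiguous; disable to
#'   stress-test alignment.
#' @return A validated `cohort_config` list.
#' @export
cohortConfig <- function(classLabels = c("TARGET", "CTRL", "OTHER"),
                         targetClass = classLabels[1],
                         nPerClass = 30L,
                         nIons = 2000L,
                         nPlanted = 3L,
                         effectSize = 3,
                         noiseCv = 0.2,
                         massJitterPpm = 60,
                         nReplicates = 6L,
                         rngSeed = 1L,
                         baseLogMean = log(500),
                         baseLogSd = 1,
                         sampleScaleSd = 0.3,
                         minSpacing = TRUE) {
  cfg <- list(
    classLabels = as.character(classLabels),
    targetClass = as.character(targetClass),
    nPerClass = as.integer(nPerClass),
    nIons = as.integer(nIons),
    nPlanted = as.integer(nPlanted),
    effectSize = as.numeric(effectSize),
    noiseCv = as.numeric(noiseCv),
    massJitterPpm = as.numeric(massJitterPpm),
    nReplicates = as.integer(nReplicates),
    rngSeed = as.integer(rngSeed),
    baseLogMean = as.numeric(baseLogMean),
    baseLogSd = as.numeric(baseLogSd),
    sampleScaleSd = as.numeric(sampleScaleSd),
    minSpacing = isTRUE(minSpacing)
  )
  .checkCohortConfig(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

.cfgFail <- function(field, why) {
  stop("invalid cohort configuration: field '", field, "' ", why,
       call. = FALSE)
}

.checkCohortConfig <- function(cfg) {
  if (length(cfg$classLabels) < 2 || anyDuplicated(cfg$classLabels))
    .cfgFail("classLabels", "needs >= 2 distinct labels")
  if (length(cfg$targetClass) != 1 ||
      sum(cfg$classLabels == cfg$targetClass) != 1)
    .cfgFail("targetClass", "must match exactly one class label")
  if (is.na(cfg$nPerClass) || cfg$nPerClass < 1)
    .cfgFail("nPerClass", "must be >= 1")
  if (is.na(cfg$nIons) || cfg$nIons < 2)
    .cfgFail("nIons", "must be >= 2")
  if (is.na(cfg$nPlanted) || cfg$nPlanted < 0 || cfg$nPlanted >= cfg$nIons)
    .cfgFail("nPlanted", "must satisfy 0 <= nPlanted < nIons")
  if (is.na(cfg$effectSize) || cfg$effectSize < 0)
    .cfgFail("effectSize", "must be >= 0")
  if (is.na(cfg$noiseCv) || cfg$noiseCv < 0)
    .cfgFail("noiseCv", "must be >= 0")
  if (is.na(cfg$massJitterPpm) || cfg$massJitterPpm < 0)
    .cfgFail("massJitterPpm", "must be >= 0")
  if (is.na(cfg$nReplicates) || cfg$nReplicates < 2)
    .cfgFail("nReplicates", "must be >= 2")
  if (is.na(cfg$rngSeed))
    .cfgFail("rngSeed", "must be an integer")
  invisible(TRUE)
}

# Nominal axis: uniform on [50, 2500], optionally thinned so consecutive
# ions are > 600 ppm apart (relative gap), topping up until nIons remain.
.drawAxis <- function(n, minSpacing) {
  gap <- 600e-6
  mz <- sort(runif(if (minSpacing) 2L * n else n, 50, 2500))
  if (!minSpacing) return(mz[seq_len(n)])
  keep <- function(x) {
    out <- numeric(0)
    last <- -Inf
    for (v in x) {
      if (v > last * (1 + gap)) {
        out <- c(out, v)
        last <- v
      }
    }
    out
  }
  mz <- keep(mz)
  tries <- 0
  while (length(mz) < n && tries < 50) {
    mz <- keep(sort(c(mz, runif(n, 50, 2500))))
    tries <- tries + 1
  }
  if (length(mz) < n)
    stop("could not place ", n, " ions with the minimum-spacing constraint")
  sort(sample(mz, n))
}

#' Generate a synthetic cohort with known planted discriminative ions
#'
#' Intensities are log-normal: each ion has a baseline log-mean; planted
#' ions are shifted additively on the log scale (up or down, per a random
#' direction) in every target-class sample. Each measurement applies a
#' global log-normal intensity factor (emulating spot-to-spot variation)
#' and multiplicative per-ion replicate noise with the configured CV, and
#' jitters every observed m/z with the configured ppm standard deviation.
#' One RNG stream is seeded once per cohort; per-sample sub-seeds are
#' drawn from it, so identical configurations reproduce byte-identical
#' cohorts.
#'
#' @param config a [cohortConfig()] object.
#' @return A list with elements `spectra` (list of [RawSpectrum-class],
#'   one per measurement), `manifest` (data.frame with sample_id, class,
#'   replicate, set = "none"), and `truth` (list with `plantedMz`,
#'   `plantedIndex`, `plantedDirection`, `axisMz`).
#' @export
generateCohort <- function(config) {
  .checkCohortConfig(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$rngSeed)

  axis <- .drawAxis(config$nIons, config$minSpacing)
  ionLogMean <- rnorm(config$nIons, config$baseLogMean, config$baseLogSd)
  plantedIdx <- sort(sample.int(config$nIons, config$nPlanted))
  plantedDir <- sample(c(-1, 1), config$nPlanted, replace = TRUE)

  classes <- rep(config$classLabels, each = config$nPerClass)
  nSamples <- length(classes)
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  subSeeds <- sample.int(.Machine$integer.max, nSamples)

  effect <- numeric(config$nIons)
  effect[plantedIdx] <- plantedDir * config$effectSize
  sdlog <- sqrt(log1p(config$noiseCv^2))
  jit <- config$massJitterPpm * 1e-6

  spectra <- vector("list", nSamples * config$nReplicates)
  manifest <- data.frame(
    sample_id = rep(sampleIds, each = config$nReplicates),
    class = rep(classes, each = config$nReplicates),
    replicate = rep(seq_len(config$nReplicates), nSamples),
    set = "none",
    stringsAsFactors = FALSE
  )
  k <- 0L
  for (s in seq_len(nSamples)) {
    set.seed(subSeeds[s])
    mu <- ionLogMean +
      if (classes[s] == config$targetClass) effect else 0
    for (r in seq_len(config$nReplicates)) {
      scale <- rnorm(1, 0, config$sampleScaleSd)
      inten <- exp(mu + scale + rnorm(config$nIons, 0, sdlog))
      mzObs <- axis * (1 + rnorm(config$nIons, 0, jit))
      k <- k + 1L
      spectra[[k]] <- RawSpectrum(sampleIds[s], r, mzObs, inten)
    }
  }
  list(
    spectra = spectra,
    manifest = manifest,
    truth = list(
      plantedMz = axis[plantedIdx],
      plantedIndex = plantedIdx,
      plantedDirection = plantedDir,
      axisMz = axis
    )
  )
}
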