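#' Search Algorithm 1: preliminary low-mass-ion candidates
#'
#' On the weighted reference table (Pareto-scaled intensities multiplied
#' by the weighting factors), an ion is a preliminary candidate iff its
#' weighted intensity has magnitude strictly greater than
#' `magnitudeThreshold` in strictly more than `columnFraction` of the
#' intensity columns.
#'
#' @param weightedTable the weighted reference [PeakTable-class].
#' @param magnitudeThreshold magnitude cut-off (default 0.1, strict).
#' @param columnFraction required fraction of columns (default 1/2,
#'   strict: "more than half").
#' @return list with `index` (ion indices, sorted) and `mz`.
#' @export
searchPreliminary <- function(weightedTable, magnitudeThreshold = 0.1,
                              columnFraction = 0.5) {
  x <- peakIntensities(weightedTable)
  if (ncol(x) == 0 || nrow(x) == 0)
    stop("cannot search an empty table")
  counts <- rowSums(abs(x) > magnitudeThreshold)
  sel <- which(counts > columnFraction * ncol(x))
  list(index = sel, mz = axisMz(weightedTable)[sel])
}

# Vectorized confusion metrics for a combos x samples DS matrix at a
# threshold: positive iff DS > threshold.
.scoreDsMatrix <- function(dsMat, pos, threshold = 0) {
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  pred <- dsMat > threshold
  sens <- rowSums(pred[, pos, drop = FALSE]) / nPos
  spec <- rowSums(!pred[, !pos, drop = FALSE]) / nNeg
  mP <- rowMeans(dsMat[, pos, drop = FALSE])
  mN <- rowMeans(dsMat[, !pos, drop = FALSE])
  vP <- if (nPos > 1)
    (rowSums(dsMat[, pos, drop = FALSE]^2) - nPos * mP^2) / (nPos - 1)
  else rep(0, nrow(dsMat))
  vN <- if (nNeg > 1)
    (rowSums(dsMat[, !pos, drop = FALSE]^2) - nNeg * mN^2) / (nNeg - 1)
  else rep(0, nrow(dsMat))
  vP <- pmax(vP, 0)
  vN <- pmax(vN, 0)
  denom <- vP + vN
  dm2 <- (mP - mN)^2
  fisher <- ifelse(denom == 0, ifelse(dm2 > 0, Inf, 0), dm2 / denom)
  list(sensitivity = sens, specificity = spec, sumSS = sens + spec,
       fisherRatio = fisher)
}

#' Score an ion combination
#'
#' The combination's discriminant score of a sample is the sum of the
#' subset's (weighted) intensities; the sample is predicted positive iff
#' the score exceeds the threshold. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP); the Fisher discriminant ratio is
#' (mean_pos - mean_neg)^2 / (var_pos + var_neg) of the scores (sample
#' variances; a zero denominator scores +Inf if the means differ, else
#' 0).
#'
#' @param subset ion indices (rows of `table`), nonempty.
#' @param table the weighted, replicate-averaged [PeakTable-class].
#' @param classes per-column class labels (default: colData classes).
#' @param targetClass the positive class.
#' @param threshold decision threshold (default 0).
#' @return list with `ions` (sorted), `sensitivity`, `specificity`,
#'   `sumSS` and `fisherRatio`.
#' @export
comboScore <- function(subset, table, classes = NULL, targetClass,
                       threshold = 0) {
  if (!length(subset)) stop("subset must be nonempty")
  subset <- as.integer(subset)
  if (any(subset < 1) || any(subset > nrow(table)))
    stop("subset index out of range")
  if (is.null(classes)) classes <- columnMeta(table)$class
  pos <- classes == targetClass
  x <- peakIntensities(table)
  ds <- colSums(x[subset, , drop = FALSE])
  s <- .scoreDsMatrix(matrix(ds, nrow = 1), pos, threshold)
  list(ions = sort(subset), sensitivity = s$sensitivity,
       specificity = s$specificity, sumSS = s$sumSS,
       fisherRatio = s$fisherRatio)
}

# TRUE iff integer vector a precedes b lexicographically.
.lexLess <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Break ties between equally performing combinations
#'
#' All supplied combinations share the same sensitivity + specificity
#' sum. Priority 1: the combination with the fewest ions wins.
#' Priority 2: among equal sizes, the largest Fisher discriminant ratio
#' wins. Residual ties break toward the lexicographically smallest
#' sorted ion-index sequence, making the choice deterministic.
#'
#' @param combos list of combination scores as returned by
#'   [comboScore()].
#' @return the selected element of `combos`.
#' @export
tieBreak <- function(combos) {
  if (!length(combos)) stop("no combinations to choose from")
  sizes <- lengths(lapply(combos, `[[`, "ions"))
  keep <- which(sizes == min(sizes))
  if (length(keep) > 1) {
    fr <- vapply(combos[keep], `[[`, numeric(1), "fisherRatio")
    keep <- keep[fr == max(fr)]
  }
  if (length(keep) > 1) {
    best <- keep[1]
    for (i in keep[-1])
      if (.lexLess(sort(combos[[i]]$ions), sort(combos[[best]]$ions)))
        best <- i
    keep <- best
  }
  combos[[keep[1]]]
}

# Index of the winning combo among parallel score vectors, applying the
# tie-break priorities. ionSets: list of sorted merged ion vectors.
.pickBest <- function(score, ionSets) {
  cand <- which(score$sumSS == max(score$sumSS))
  if (length(cand) > 1) {
    sz <- lengths(ionSets[cand])
    cand <- cand[sz == min(sz)]
  }
  if (length(cand) > 1) {
    fr <- score$fisherRatio[cand]
    cand <- cand[fr == max(fr)]
  }
  if (length(cand) > 1) {
    best <- cand[1]
    for (i in cand[-1])
      if (.lexLess(ionSets[[i]], ionSets[[best]])) best <- i
    cand <- best
  }
  cand[1]
}

# Best 2- or 3-subset grouping over the current units.
# units: list of integer ion vectors. dsU: units x samples DS matrix.
.bestGrouping <- function(units, dsU, pos, threshold) {
  m <- length(units)
  combos <- list()
  dsRows <- list()
  for (s in 2:min(3, m)) {
    cm <- combn(m, s)
    ds <- dsU[cm[1, ], , drop = FALSE]
    for (r in 2:s) ds <- ds + dsU[cm[r, ], , drop = FALSE]
    combos <- c(combos, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
    dsRows <- c(dsRows, list(ds))
  }
  dsMat <- do.call(rbind, dsRows)
  score <- .scoreDsMatrix(dsMat, pos, threshold)
  ionSets <- lapply(combos, function(ix) sort(unlist(units[ix])))
  b <- .pickBest(score, ionSets)
  list(unitIdx = combos[[b]], ions = ionSets[[b]],
       sumSS = score$sumSS[b],
       sensitivity = score$sensitivity[b],
       specificity = score$specificity[b],
       fisherRatio = score$fisherRatio[b])
}

.unitDs <- function(x, units) {
  t(vapply(units, function(ions)
    colSums(x[ions, , drop = FALSE]), numeric(ncol(x))))
}

#' Search Algorithm 2: germination and growth of the discriminative panel
#'
#' Germination: if a single candidate separates the training classes
#' perfectly (sensitivity = specificity = 1 at threshold 0) it is
#' returned at once. Otherwise all 2- and 3-subsets of the candidates
#' are scored and the best combination is repeatedly set aside until at
#' most one candidate remains; the set-aside combinations are then
#' treated as atomic units and the 2-/3-grouping repeats hierarchically
#' until a single unit remains or a round fails to improve the best
#' sensitivity + specificity sum seen so far. The best-scoring unit
#' formed at any level (singletons included) becomes the seed set.
#' Growth: 1-, 2- and 3-subsets of the remaining candidates are added to
#' the seed; the best enlargement replaces the seed while it strictly
#' improves the sum, and the last seed is returned as the discriminative
#' panel. Ties at every decision follow [tieBreak()]'s priorities.
#'
#' Leftover single candidates of the first set-aside round are not
#' grouped further but stay available to the growth phase, which draws
#' from all candidates outside the seed.
#'
#' @param candidates integer ion indices, or the list returned by
#'   [searchPreliminary()].
#' @param table the weighted, replicate-averaged training
#'   [PeakTable-class].
#' @param classes per-column class labels (default: colData classes).
#' @param targetClass the positive class.
#' @param threshold decision threshold used throughout the search
#'   (default 0, the sign rule).
#' @param candidateCap cap on the number of candidates entering the
#'   combinatorial search (default 64); above it the candidates with the
#'   best singleton scores are kept, with a warning.
#' @return list with `panel` (sorted ion indices), `score` (the panel's
#'   [comboScore()]), `seed` (the germination seed), and `trace`
#'   (data.frame of accepted sets: phase, ions, sumSS, fisherRatio).
#' @export
searchDiscriminative <- function(candidates, table, classes = NULL,
                                 targetClass, threshold = 0,
                                 candidateCap = 64L) {
  if (is.list(candidates)) candidates <- candidates$index
  cand <- sort(unique(as.integer(candidates)))
  if (!length(cand)) stop("candidate set is empty")
  if (is.null(classes)) classes <- columnMeta(table)$class
  pos <- classes == targetClass
  x <- peakIntensities(table)

  singleDs <- x[cand, , drop = FALSE]
  singleScore <- .scoreDsMatrix(singleDs, pos, threshold)

  if (length(cand) > candidateCap) {
    warning("candidate set of size ", length(cand), " capped at ",
            candidateCap, " by singleton performance")
    o <- order(-singleScore$sumSS, -singleScore$fisherRatio, cand)
    keep <- sort(o[seq_len(candidateCap)])
    cand <- cand[keep]
    singleDs <- singleDs[keep, , drop = FALSE]
    singleScore <- lapply(singleScore, `[`, keep)
  }

  trace <- list()
  note <- function(phase, ions, ss, fr)
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, ions = paste(ions, collapse = "+"),
      sumSS = ss, fisherRatio = fr, stringsAsFactors = FALSE)

  scoreOf <- function(ions) comboScore(ions, table, classes, targetClass,
                                       threshold)

  # Step 1: perfect single candidate.
  perfect <- which(singleScore$sensitivity == 1 &
                   singleScore$specificity == 1)
  if (length(perfect)) {
    combos <- lapply(perfect, function(i) {
      s <- scoreOf(cand[i])
      s
    })
    best <- tieBreak(combos)
    note("germination", best$ions, best$sumSS, best$fisherRatio)
    return(list(panel = best$ions, score = best, seed = best$ions,
                trace = do.call(rbind, trace)))
  }

  # All units formed at any level, singletons included.
  allUnits <- lapply(seq_along(cand), function(i) list(
    ions = cand[i], sumSS = singleScore$sumSS[i],
    fisherRatio = singleScore$fisherRatio[i]))
  bestSS <- max(singleScore$sumSS)

  units <- as.list(cand)
  round <- 0L
  while (length(units) >= 2) {
    round <- round + 1L
    pool <- units
    aside <- list()
    roundBest <- -Inf
    while (length(pool) >= 2) {
      dsU <- .unitDs(x, pool)
      g <- .bestGrouping(pool, dsU, pos, threshold)
      aside[[length(aside) + 1L]] <- g$ions
      allUnits[[length(allUnits) + 1L]] <- list(
        ions = g$ions, sumSS = g$sumSS, fisherRatio = g$fisherRatio)
      note("germination", g$ions, g$sumSS, g$fisherRatio)
      roundBest <- max(roundBest, g$sumSS)
      pool <- pool[-g$unitIdx]
    }
    units <- if (round == 1L) aside else c(aside, pool)
    if (roundBest <= bestSS) break
    bestSS <- roundBest
  }

  # Step 6: the best unit formed at any level is the seed.
  seedCombos <- list()
  maxSS <- max(vapply(allUnits, `[[`, numeric(1), "sumSS"))
  for (u in allUnits)
    if (u$sumSS == maxSS)
      seedCombos[[length(seedCombos) + 1L]] <- list(
        ions = u$ions, sumSS = u$sumSS, fisherRatio = u$fisherRatio)
  seedPick <- tieBreak(seedCombos)
  seed <- sort(seedPick$ions)
  seedScore <- scoreOf(seed)
  note("seed", seed, seedScore$sumSS, seedScore$fisherRatio)

  # Growth: add the best 1-/2-/3-subset of the remaining candidates
  # while it strictly improves the sum of sensitivity and specificity.
  repeat {
    poolIons <- setdiff(cand, seed)
    if (!length(poolIons)) break
    dsSeed <- colSums(x[seed, , drop = FALSE])
    combos <- list()
    dsRows <- list()
    for (s in 1:min(3, length(poolIons))) {
      cm <- combn(length(poolIons), s)
      ds <- x[poolIons[cm[1, ]], , drop = FALSE]
      if (s > 1)
        for (r in 2:s) ds <- ds + x[poolIons[cm[r, ]], , drop = FALSE]
      ds <- sweep(ds, 2, dsSeed, `+`)
      combos <- c(combos, lapply(seq_len(ncol(cm)),
                                 function(j) poolIons[cm[, j]]))
      dsRows <- c(dsRows, list(ds))
    }
    dsMat <- do.call(rbind, dsRows)
    sc <- .scoreDsMatrix(dsMat, pos, threshold)
    ionSets <- lapply(combos, function(add) sort(c(seed, add)))
    b <- .pickBest(sc, ionSets)
    if (sc$sumSS[b] > seedScore$sumSS) {
      seed <- ionSets[[b]]
      seedScore <- scoreOf(seed)
      note("growth", seed, seedScore$sumSS, seedScore$fisherRatio)
    } else break
  }

  list(panel = seed, score = seedScore, seed = seedPick$ions,
       trace = do.call(rbind, trace))
}
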