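# Shared fixtures: tiny in-code tables, small cohorts, and independent
# oracles used to cross-check the package's algorithms.

tinyTable <- function(x, mz = NULL, classes = NULL, sets = NULL,
                      reps = NULL, ids = NULL) {
  x <- as.matrix(x)
  if (is.null(mz)) mz <- 100 + seq_len(nrow(x))
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(x)))
  if (is.null(classes)) classes <- rep("ctrl", ncol(x))
  if (is.null(sets)) sets <- rep("none", ncol(x))
  if (is.null(reps)) reps <- rep(1L, ncol(x))
  PeakTable(mz, x, sample_id = ids, class = classes, set = sets,
            replicate = reps)
}

smallCohort <- function(seed = 1L, effectSize = 3, nPerClass = 12L,
                        nIons = 150L, nReplicates = 4L, noiseCv = 0.2,
                        nPlanted = 3L, ...) {
  generateCohort(cohortConfig(
    nPerClass = nPerClass, nIons = nIons, nPlanted = nPlanted,
    effectSize = effectSize, noiseCv = noiseCv,
    nReplicates = nReplicates, rngSeed = seed, ...))
}

runSmallPipeline <- function(seed = 1L, effectSize = 3, nPerClass = 12L,
                             buildSeed = seed, ...) {
  co <- smallCohort(seed = seed, effectSize = effectSize,
                    nPerClass = nPerClass, ...)
  rc <- runConfig(targetClass = "TARGET", rngSeed = buildSeed)
  fit <- suppressWarnings(buildLome(co$spectra, co$manifest, rc))
  list(cohort = co, fit = fit)
}

panelInPlanted <- function(panelMzs, plantedMz, tolPpm = 300) {
  all(vapply(panelMzs, function(p)
    any(abs(p - plantedMz) / plantedMz <= tolPpm * 1e-6), logical(1)))
}

# Brute-force confusion-matrix oracle for a score vector.
oracleConfusion <- function(ds, pos, threshold = 0) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(ds)) {
    predPos <- ds[i] > threshold
    if (pos[i] && predPos) tp <- tp + 1
    if (pos[i] && !predPos) fn <- fn + 1
    if (!pos[i] && predPos) fp <- fp + 1
    if (!pos[i] && !predPos) tn <- tn + 1
  }
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# Independent re-implementation of the germination/growth search used as
# the trajectory oracle for small candidate sets: plain lists and loops,
# its own score arithmetic and its own tie comparator.
oracleSearch2 <- function(x, pos, cand) {
  nPos <- sum(pos); nNeg <- sum(!pos)
  sc <- function(ions) {
    ds <- apply(x[ions, , drop = FALSE], 2, sum)
    pred <- ds > 0
    sens <- sum(pred[pos]) / nPos
    spec <- sum(!pred[!pos]) / nNeg
    mp <- mean(ds[pos]); mn <- mean(ds[!pos])
    vp <- if (nPos > 1) stats::var(ds[pos]) else 0
    vn <- if (nNeg > 1) stats::var(ds[!pos]) else 0
    f <- if (vp + vn == 0) {
      if ((mp - mn)^2 > 0) Inf else 0
    } else (mp - mn)^2 / (vp + vn)
    list(ions = sort(ions), ss = sens + spec, sens = sens, spec = spec,
         fisher = f)
  }
  lexCmp <- function(a, b) {
    for (i in seq_len(min(length(a), length(b))))
      if (a[i] != b[i]) return(sign(a[i] - b[i]))
    sign(length(a) - length(b))
  }
  pickBest <- function(opts) {
    ss <- vapply(opts, `[[`, numeric(1), "ss")
    opts <- opts[ss == max(ss)]
    sz <- vapply(opts, function(o) length(o$ions), integer(1))
    opts <- opts[sz == min(sz)]
    fi <- vapply(opts, `[[`, numeric(1), "fisher")
    opts <- opts[fi == max(fi)]
    best <- opts[[1]]
    for (o in opts[-1]) if (lexCmp(o$ions, best$ions) < 0) best <- o
    best
  }
  singles <- lapply(cand, sc)
  perf <- Filter(function(s) s$sens == 1 && s$spec == 1, singles)
  if (length(perf)) return(pickBest(perf)$ions)

  allUnits <- singles
  bestSS <- max(vapply(singles, `[[`, numeric(1), "ss"))
  units <- lapply(cand, identity)
  round <- 0
  while (length(units) >= 2) {
    round <- round + 1
    pool <- units
    aside <- list()
    rbest <- -Inf
    while (length(pool) >= 2) {
      opts <- list()
      m <- length(pool)
      for (s in 2:min(3, m)) {
        cm <- utils::combn(m, s)
        for (j in seq_len(ncol(cm))) {
          g <- sc(unlist(pool[cm[, j]]))
          g$members <- cm[, j]
          opts[[length(opts) + 1]] <- g
        }
      }
      w <- pickBest(opts)
      aside[[length(aside) + 1]] <- w$ions
      allUnits[[length(allUnits) + 1]] <- w
      rbest <- max(rbest, w$ss)
      pool <- pool[-w$members]
    }
    units <- if (round == 1) aside else c(aside, pool)
    if (rbest <= bestSS) break
    bestSS <- max(bestSS, rbest)
  }
  seed <- pickBest(allUnits)$ions
  sscore <- sc(seed)
  repeat {
    rest <- setdiff(cand, seed)
    if (!length(rest)) break
    opts <- list()
    for (s in 1:min(3, length(rest))) {
      cm <- utils::combn(length(rest), s)
      for (j in seq_len(ncol(cm)))
        opts[[length(opts) + 1]] <- sc(c(seed, rest[cm[, j]]))
    }
    w <- pickBest(opts)
    if (w$ss > sscore$ss) {
      seed <- w$ions
      sscore <- w
    } else break
  }
  sort(seed)
}

# Random weighted "averaged training table" with a weak planted signal,
# small enough for exhaustive oracle comparison.
randomSearchProblem <- function(seed, nIons = 12L, nPerClass = 12L,
                                signalIons = 1:3, shift = 0.8) {
  set.seed(seed)
  n <- 2L * nPerClass
  x <- matrix(rnorm(nIons * n), nrow = nIons)
  pos <- rep(c(TRUE, FALSE), each = nPerClass)
  x[signalIons, pos] <- x[signalIons, pos] + shift
  x[signalIons, !pos] <- x[signalIons, !pos] - shift
  classes <- ifelse(pos, "case", "ctrl")
  list(table = tinyTable(x, classes = classes), x = x, pos = pos,
       classes = classes)
}
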