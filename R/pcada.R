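#' PCA-based discriminant analysis on a Pareto-scaled peak table
#'
#' Reconstructs the classical PCA-DA: principal components of the column
#' vectors (no re-centering; the table is already Pareto-scaled, so
#' fitting columns have zero per-ion mean), retaining the smallest number
#' of components explaining at least `varianceRule` of the variance
#' (capped at `nColumns - 2` and optionally `maxComponents`), followed by
#' a two-class Fisher linear discriminant on the component scores with
#' the pooled covariance regularized by adding `1e-8 * trace / dim` to
#' its diagonal. The discriminant direction is back-projected to ion
#' space and scaled to unit Euclidean norm, yielding the weighting-factor
#' (loading) vector: the discriminant score of column j is exactly
#' `DS_j = sum_i w_i x_ij`. The sign is fixed so the target class has a
#' positive mean score.
#'
#' @param table a Pareto-scaled [PeakTable-class].
#' @param classes per-column class labels; defaults to the table's
#'   colData classes.
#' @param targetClass label of the positive (screened-for) class.
#' @param varianceRule fraction of variance the retained components must
#'   explain (default 0.95).
#' @param maxComponents optional hard cap on the retained components.
#' @return list with `loading` ([LoadingVector-class]), `ds` (per-column
#'   discriminant scores), `nComponents`, and `separation` (list with
#'   `sensitivity`, `specificity`, `sumSS`, `fisherRatio` at threshold 0).
#' @export
fitPcada <- function(table, classes = NULL, targetClass,
                     varianceRule = 0.95, maxComponents = NULL) {
  if (is.null(classes)) classes <- columnMeta(table)$class
  x <- peakIntensities(table)
  if (ncol(x) < 2) stop("PCA-DA needs >= 2 columns")
  if (length(classes) != ncol(x))
    stop("class labels must match the number of columns")
  pos <- classes == targetClass
  if (all(pos) || !any(pos))
    stop("both the target and the non-target class must be present")
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("PCA-DA needs >= 2 columns in each class")

  sv <- svd(x)
  varExpl <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(varExpl) >= varianceRule)[1]
  if (is.na(k)) k <- length(sv$d)
  kMax <- max(1L, ncol(x) - 2L)
  k <- min(k, kMax, if (is.null(maxComponents)) Inf else maxComponents,
           sum(sv$d > sv$d[1] * 1e-12))
  k <- max(1L, as.integer(k))

  U <- sv$u[, seq_len(k), drop = FALSE]
  scores <- crossprod(U, x)                      # k x n component scores

  m1 <- rowMeans(scores[, pos, drop = FALSE])
  m2 <- rowMeans(scores[, !pos, drop = FALSE])
  c1 <- var(t(scores[, pos, drop = FALSE]))
  c2 <- var(t(scores[, !pos, drop = FALSE]))
  n1 <- sum(pos); n2 <- sum(!pos)
  sp <- ((n1 - 1) * c1 + (n2 - 1) * c2) / (n1 + n2 - 2)
  sp <- sp + diag(1e-8 * sum(diag(sp)) / k, k)
  d <- solve(sp, m1 - m2)

  w <- as.numeric(U %*% d)
  w <- w / sqrt(sum(w^2))
  ds <- as.numeric(crossprod(x, w))
  if (mean(ds[pos]) < 0) {
    w <- -w
    ds <- -ds
  }
  loading <- LoadingVector(axisMz(table), w, targetClass)
  list(
    loading = loading,
    ds = ds,
    nComponents = k,
    separation = .separationScore(ds, pos)
  )
}

.separationScore <- function(ds, pos, threshold = 0) {
  pred <- ds > threshold
  sens <- sum(pred & pos) / sum(pos)
  spec <- sum(!pred & !pos) / sum(!pos)
  v1 <- if (sum(pos) > 1) var(ds[pos]) else 0
  v2 <- if (sum(!pos) > 1) var(ds[!pos]) else 0
  dm2 <- (mean(ds[pos]) - mean(ds[!pos]))^2
  fr <- if (v1 + v2 == 0) {
    if (dm2 > 0) Inf else 0
  } else dm2 / (v1 + v2)
  list(sensitivity = sens, specificity = spec, sumSS = sens + spec,
       fisherRatio = fr)
}

#' Select the reference measurement among replicates
#'
#' Each replicate's peak table is preprocessed independently (total-area
#' normalization, Pareto scaling) and fitted with [fitPcada()]; the
#' replicate with the highest separation performance (sensitivity +
#' specificity of the discriminant score at threshold 0) is chosen as the
#' reference mass spectrum. Ties break toward the larger Fisher
#' discriminant ratio, then the lower replicate index.
#'
#' @param replicateTables named/ordered list of [PeakTable-class], one
#'   per replicate, with identical sample composition.
#' @param targetClass the positive class label.
#' @param varianceRule,maxComponents passed to [fitPcada()].
#' @return list with `replicateIndex`, `separation` (per-replicate
#'   scores), and `fit` (the winning replicate's preprocessed fit:
#'   `table`, `stats`, `pcada`).
#' @export
selectReferenceMeasurement <- function(replicateTables, targetClass,
                                       varianceRule = 0.95,
                                       maxComponents = NULL) {
  if (length(replicateTables) < 2)
    stop("need >= 2 replicate tables to select a reference")
  sampleSets <- lapply(replicateTables, function(t)
    sort(columnMeta(t)$sample_id))
  if (!all(vapply(sampleSets, identical, logical(1), y = sampleSets[[1]])))
    stop("replicate tables do not share the same sample set")

  fits <- lapply(replicateTables, function(t) {
    norm <- normalizeTotalArea(t)
    par <- paretoScale(norm$table)
    pc <- fitPcada(par$table, targetClass = targetClass,
                   varianceRule = varianceRule,
                   maxComponents = maxComponents)
    stats <- par$stats
    stats@targetArea <- norm$targetArea
    list(table = par$table, stats = stats, pcada = pc)
  })
  sumSS <- vapply(fits, function(f) f$pcada$separation$sumSS, numeric(1))
  fisher <- vapply(fits, function(f) f$pcada$separation$fisherRatio,
                   numeric(1))
  best <- which(sumSS == max(sumSS))
  if (length(best) > 1) {
    fb <- fisher[best]
    best <- best[fb == max(fb)]
  }
  best <- best[1]
  list(
    replicateIndex = best,
    separation = data.frame(replicate = seq_along(fits), sumSS = sumSS,
                            fisherRatio = fisher),
    fit = fits[[best]]
  )
}
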