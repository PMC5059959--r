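test_that("alignment honours the inclusive ppm tolerance", {
  axis <- c(500, 1000, 1500)
  sp <- RawSpectrum("s", 1L, 1000.3, 7)          # exactly 300 ppm
  expect_equal(alignToReference(sp, axis, 300), c(0, 7, 0))
  sp <- RawSpectrum("s", 1L, 999.5, 7)           # 500 ppm away
  expect_equal(alignToReference(sp, axis, 300), c(0, 0, 0))
  sp <- RawSpectrum("s", 1L, c(999.9, 1000.1), c(2, 3))
  expect_equal(alignToReference(sp, axis, 300), c(0, 5, 0))
  expect_error(alignToReference(sp, numeric(0), 300), "empty")
})

test_that("every alignment assignment satisfies the ppm bound", {
  set.seed(11)
  for (rep in 1:10) {
    axis <- sort(runif(40, 100, 2000))
    mz <- sort(runif(120, 100, 2000))
    it <- runif(120, 1, 100)
    sp <- RawSpectrum("s", 1L, mz, it)
    col <- alignToReference(sp, axis, 300)
    # brute-force oracle: nearest in-ppm reference per peak, summed
    oracle <- numeric(length(axis))
    for (i in seq_along(mz)) {
      d <- abs(mz[i] - axis) / axis
      j <- which.min(d)
      if (d[j] <= 300e-6) oracle[j] <- oracle[j] + it[i]
    }
    expect_equal(col, oracle)
    # matched intensity only where some peak is within tolerance
    for (j in which(col > 0))
      expect_true(any(abs(mz - axis[j]) / axis[j] <= 300e-6))
  }
})

test_that("realignment is an idempotent projection onto the axis", {
  co <- smallCohort(seed = 4L, nPerClass = 3L, nIons = 60L,
                    nReplicates = 2L)
  axis <- co$truth$axisMz
  tab <- buildPeakTable(co$spectra[1:6], axis, tolerancePpm = 300)
  again <- realign(tab, axis, 300)
  expect_equal(peakIntensities(again), peakIntensities(tab))
  expect_equal(axisMz(again), axis)

  # axis perturbed by 100 ppm: intensities land on the matching ions
  perturbed <- tinyTable(peakIntensities(tab), mz = axis * (1 + 100e-6))
  re <- realign(perturbed, axis, 300)
  expect_equal(peakIntensities(re), peakIntensities(tab))

  # one ion pushed out to 400 ppm loses its intensity
  mz2 <- axis
  mz2[10] <- axis[10] * (1 + 400e-6)
  shifted <- tinyTable(peakIntensities(tab), mz = mz2)
  re <- realign(shifted, axis, 300)
  expect_equal(peakIntensities(re)[10, ],
               rep(0, ncol(tab)), ignore_attr = TRUE)
  expect_equal(peakIntensities(re)[-10, ], peakIntensities(tab)[-10, ])
})

test_that("total-area normalization equalizes column sums to the mean", {
  tab <- tinyTable(matrix(c(4, 6, 10, 20), nrow = 2))  # sums 10 and 30
  out <- normalizeTotalArea(tab)
  expect_equal(out$targetArea, 20)
  expect_equal(colSums(peakIntensities(out$table)), c(20, 20),
               ignore_attr = TRUE)
  expect_equal(peakIntensities(out$table)[, 1], c(8, 12))

  single <- tinyTable(matrix(c(1, 2, 3), nrow = 3))
  expect_equal(peakIntensities(normalizeTotalArea(single)$table),
               peakIntensities(single))

  set.seed(2)
  tab <- tinyTable(matrix(runif(50, 1, 10), nrow = 10))
  sums <- colSums(peakIntensities(normalizeTotalArea(tab)$table))
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)

  bad <- tinyTable(matrix(c(1, 2, 0, 0), nrow = 2),
                   ids = c("good", "empty"))
  expect_error(normalizeTotalArea(bad), "empty")
})

test_that("normalization with a frozen target is scale invariant", {
  set.seed(3)
  x <- matrix(runif(30, 1, 5), nrow = 6)
  tab <- tinyTable(x)
  ref <- normalizeTotalArea(tab, targetArea = 100)$table
  x2 <- x
  x2[, 2] <- x2[, 2] * 7.5
  scaled <- normalizeTotalArea(tinyTable(x2), targetArea = 100)$table
  expect_equal(peakIntensities(scaled), peakIntensities(ref))
})

test_that("Pareto scaling matches its closed form and guards zero variance", {
  tab <- tinyTable(rbind(c(4, 4, 4), c(-1, 0, 1)))
  out <- paretoScale(tab)
  expect_equal(peakIntensities(out$table)[1, ], c(0, 0, 0))

  tab <- tinyTable(matrix(c(-1, 1), nrow = 1))
  out <- paretoScale(tab)
  expect_equal(peakIntensities(out$table)[1, ],
               c(-1, 1) / 2^(1 / 4))  # mean 0, sample sd sqrt(2)

  set.seed(5)
  x <- matrix(rlnorm(200, 3, 1), nrow = 20)
  out <- paretoScale(tinyTable(x))
  sc <- peakIntensities(out$table)
  expect_equal(rowMeans(sc), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(sc, 1, var), apply(x, 1, sd), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(paretoScale(tinyTable(matrix(1:3, ncol = 1))), ">= 2")
})

test_that("frozen Pareto statistics transform new columns linearly", {
  set.seed(6)
  x <- matrix(rnorm(40, 10, 2), nrow = 8)
  fit <- paretoScale(tinyTable(x))
  a <- 2.5; b <- -4
  y <- a * x + b
  out <- peakIntensities(applyPareto(tinyTable(y), fit$stats))
  direct <- (y - fit$stats@ionMean) / sqrt(fit$stats@ionSd)
  expect_equal(out, direct)
  expect_error(applyPareto(tinyTable(matrix(1:4, nrow = 2)), fit$stats),
               "does not match")
})

test_that("weighting is an exact elementwise product", {
  tab <- tinyTable(matrix(c(1, 3, 2, 4), nrow = 2))
  expect_equal(peakIntensities(applyWeights(tab, c(1, 1))),
               peakIntensities(tab))
  expect_equal(peakIntensities(applyWeights(tab, c(0, 0))),
               matrix(0, 2, 2))
  expect_equal(peakIntensities(applyWeights(tab, c(2, -1))),
               rbind(c(2, 4), c(-3, -4)))
  expect_error(applyWeights(tab, c(1, 2, 3)), "does not match")
})

test_that("replicate averaging reproduces the per-sample mean", {
  tab <- tinyTable(matrix(1:5, nrow = 1),
                   ids = rep("s1", 5), reps = 1:5)
  avg <- averageReplicates(tab)
  expect_equal(ncol(avg), 1)
  expect_equal(peakIntensities(avg)[1, 1], 3)

  one <- tinyTable(matrix(c(1, 2), nrow = 2), ids = "only")
  expect_equal(peakIntensities(averageReplicates(one)),
               peakIntensities(one))

  set.seed(7)
  x <- matrix(runif(60), nrow = 4)
  ids <- rep(c("a", "b", "c"), each = 5)
  tab <- tinyTable(x, ids = ids, reps = rep(1:5, 3),
                   classes = rep(c("u", "v", "u"), each = 5))
  avg <- averageReplicates(tab)
  for (s in c("a", "b", "c"))
    expect_equal(peakIntensities(avg)[, which(columnMeta(avg)$sample_id == s)],
                 rowMeans(x[, ids == s]))
  expect_equal(columnMeta(avg)$class, c("u", "v", "u"))
})

test_that("the preprocessing chain is deterministic", {
  co <- smallCohort(seed = 9L, nPerClass = 3L, nIons = 50L,
                    nReplicates = 2L)
  run <- function() {
    tab <- buildPeakTable(co$spectra, co$truth$axisMz,
                          meta = co$manifest, tolerancePpm = 300)
    n <- normalizeTotalArea(tab)
    p <- paretoScale(n$table)
    peakIntensities(averageReplicates(p$table))
  }
  expect_identical(run(), run())
})
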