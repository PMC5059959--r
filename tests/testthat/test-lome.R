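test_that("trisection divides every stratum almost evenly", {
  man <- data.frame(sample_id = sprintf("s%02d", 1:16),
                    class = rep(c("a", "b"), c(9, 7)),
                    replicate = 1L)
  tri <- trisect(man, rngSeed = 3L)
  sizes <- table(tri$set[match(man$sample_id, tri$sample_id)],
                 man$class)
  expect_equal(sort(as.integer(sizes[, "a"])), c(3, 3, 3))
  expect_equal(sort(as.integer(sizes[, "b"])), c(2, 2, 3))
  # deterministic under a fixed seed
  expect_identical(tri, trisect(man, rngSeed = 3L))
  expect_error(trisect(man[0, ]), "empty")
})

test_that("holdout classes are assigned wholly to the validation set", {
  man <- data.frame(sample_id = sprintf("s%02d", 1:12),
                    class = rep(c("a", "ucc"), each = 6),
                    replicate = 1L)
  tri <- trisect(man, rngSeed = 1L, holdoutClasses = "ucc")
  expect_true(all(tri$set[match(sprintf("s%02d", 7:12),
                                tri$sample_id)] == "B"))
})

test_that("a stage column refines the trisection strata", {
  man <- data.frame(sample_id = sprintf("s%02d", 1:18),
                    class = "ovc",
                    stage = rep(c("I", "II", "III"), each = 6),
                    replicate = 1L)
  tri <- trisect(man, rngSeed = 2L)
  joined <- merge(man, tri)
  sizes <- table(joined$set, joined$stage)
  expect_true(all(sizes == 2))
})

test_that("the mean discriminant score is a linear panel sum", {
  axis <- c(100, 200, 300, 400)
  w <- c(0.5, -0.25, 0.8, 0.1)
  model <- new("LOMEModel", axisMz = axis, panel = c(2L, 3L),
               loading = LoadingVector(axis, w, "t"),
               scaling = ScalingStats(rep(0, 4), rep(1, 4), 1),
               threshold = 0, targetClass = "t",
               referenceReplicate = 1L, configHash = "x")
  x <- rbind(c(0, 1), c(0.5, 2), c(1.0, 3), c(9, 9))
  tab <- tinyTable(x, mz = axis)
  ds <- meanDS(tab, model)
  expect_equal(as.numeric(ds), c(0.5 + 1.0, 2 + 3))

  zero <- tinyTable(matrix(0, 4, 2), mz = axis)
  expect_equal(as.numeric(meanDS(zero, model)), c(0, 0))

  # linearity: scaling the intensities scales the score
  expect_equal(as.numeric(meanDS(tinyTable(3 * x, mz = axis), model)),
               3 * as.numeric(ds))

  # additivity over a partition of the panel
  m1 <- initialize(model, panel = 2L)
  m2 <- initialize(model, panel = 3L)
  expect_equal(as.numeric(meanDS(tab, m1) + meanDS(tab, m2)),
               as.numeric(ds))

  expect_error(meanDS(tinyTable(x, mz = axis + 1), model), "axis")
})

test_that("the sign rule classifies DS = 0 as screen-negative", {
  expect_true(classifyDS(0.01))
  expect_false(classifyDS(-0.01))
  expect_false(classifyDS(0))
  expect_equal(classifyDS(c(-1, 0, 2), threshold = 0),
               c(FALSE, FALSE, TRUE))
})

test_that("threshold training maximizes sum of sensitivity and specificity", {
  ds <- c(-2, -1, 1, 2)
  cls <- c("n", "n", "t", "t")
  expect_equal(trainThreshold(ds, cls, "t"), 0)

  # overlapping scores: exhaustive cut-point oracle
  for (seed in 1:5) {
    set.seed(seed)
    ds <- round(rnorm(30), 2)
    cls <- sample(c("t", "n"), 30, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(cls)) < 2) next
    thr <- trainThreshold(ds, cls, "t")
    pos <- cls == "t"
    ssAt <- function(t) {
      o <- oracleConfusion(ds, pos, t)
      o$sens + o$spec
    }
    best <- max(vapply(c(ds - 1e-6, ds + 1e-6), ssAt, numeric(1)))
    expect_equal(ssAt(thr), best)
  }

  # symmetry: negating scores and flipping labels negates the threshold
  ds <- c(-1.4, -0.2, 0.3, 0.9, 1.7)
  cls <- c("n", "t", "n", "t", "t")
  a <- trainThreshold(ds, cls, "t")
  b <- trainThreshold(-ds, cls, "n")
  expect_equal(b, -a)

  expect_error(trainThreshold(1:3, rep("t", 3), "t"), "both classes")
})

test_that("classification metrics reproduce the published arithmetic", {
  # 30 target, 351 non-target; perfect sensitivity, 3 false positives
  pred <- c(rep(TRUE, 30), rep(TRUE, 3), rep(FALSE, 348))
  act <- c(rep(TRUE, 30), rep(FALSE, 351))
  m <- evaluateMetrics(pred, act)
  expect_equal(m$counts, c(TP = 30, FP = 3, TN = 348, FN = 0))
  expect_equal(m$reported[["sensitivity"]], 100.00)
  expect_equal(m$reported[["specificity"]], 99.15)
  expect_equal(m$reported[["ppv"]], 90.91)
  expect_equal(m$reported[["npv"]], 100.00)

  # 29 target with 2 misses, clean non-target side
  pred <- c(rep(TRUE, 27), rep(FALSE, 2), rep(FALSE, 351))
  act <- c(rep(TRUE, 29), rep(FALSE, 351))
  m <- evaluateMetrics(pred, act)
  expect_equal(m$reported[["sensitivity"]], 93.10)
  expect_equal(m$reported[["npv"]], 99.43)
  expect_equal(m$reported[["specificity"]], 100.00)

  m <- evaluateMetrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(all(m$reported == 100))

  # undefined ratios are NA, never zero
  m <- evaluateMetrics(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
})

test_that("metrics identities hold and per-group specificity is separated", {
  set.seed(9)
  groups <- sample(c("t", "g1", "g2", "held"), 60, replace = TRUE)
  act <- groups == "t"
  pred <- act
  flip <- sample(60, 12)
  pred[flip] <- !pred[flip]
  m <- evaluateMetrics(pred, act, groups = groups,
                       excludeGroups = "held")
  inc <- groups != "held"
  expect_equal(sum(m$counts[c("TP", "FN")]), sum(act[inc]))
  expect_equal(sum(m$counts[c("TN", "FP")]), sum(!act[inc]))
  expect_equal(sum(m$counts), sum(inc))
  for (g in c("g1", "g2", "held")) {
    i <- groups == g
    expect_equal(m$groupSpecificity[[g]], 100 * sum(!pred[i]) / sum(i))
  }
})

test_that("the full pipeline recovers planted ions and separates Set B", {
  r <- runSmallPipeline(seed = 17L)
  fit <- r$fit
  expect_true(panelInPlanted(fit$report$panelMz, r$cohort$truth$plantedMz))
  b <- fit$report$sets$B
  expect_gte(b$sensitivity, 90)
  expect_gte(b$specificity, 90)
  # the reference replicate is excluded from the downstream columns
  expect_false(fit$model@referenceReplicate %in%
                 columnMeta(fit$tables$avgA)$replicate)
})

test_that("rebuilding with the same seed yields an identical model bundle", {
  a <- runSmallPipeline(seed = 23L, nPerClass = 8L)
  b <- runSmallPipeline(seed = 23L, nPerClass = 8L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeModelBundle(a$fit$model, d1)
  writeModelBundle(b$fit$model, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- readModelBundle(d1)$model
  expect_equal(back@panel, a$fit$model@panel)
  expect_equal(back@threshold, a$fit$model@threshold)
  expect_equal(back@loading@weight, a$fit$model@loading@weight,
               tolerance = 1e-12)
})

test_that("Set B never influences the trained model", {
  co <- smallCohort(seed = 29L, nPerClass = 8L)
  man <- co$manifest
  tri <- trisect(man, rngSeed = 5L)
  man$set <- tri$set[match(man$sample_id, tri$sample_id)]
  rc <- runConfig(targetClass = "TARGET", rngSeed = 5L)
  fit1 <- suppressWarnings(buildLome(co$spectra, man, rc))

  # permute the class labels of the Set B samples only
  man2 <- man
  bIds <- unique(man2$sample_id[man2$set == "B"])
  set.seed(1)
  relabel <- sample(c("TARGET", "CTRL", "OTHER"), length(bIds),
                    replace = TRUE)
  man2$class[man2$set == "B"] <-
    relabel[match(man2$sample_id[man2$set == "B"], bIds)]
  fit2 <- suppressWarnings(buildLome(co$spectra, man2, rc))

  expect_identical(fit1$model@panel, fit2$model@panel)
  expect_equal(fit1$model@loading@weight, fit2$model@loading@weight)
  expect_equal(fit1$model@threshold, fit2$model@threshold)
  expect_equal(fit1$model@scaling@ionMean, fit2$model@scaling@ionMean)
})

test_that("model augmentation unions ions and retrains the threshold", {
  r <- runSmallPipeline(seed = 31L, nPerClass = 8L)
  fit <- r$fit
  avgA <- fit$tables$avgA

  # empty augmentation: panel unchanged, decisions unchanged on the
  # separable training data
  aug <- augmentModel(fit$model, numeric(0), avgA)
  expect_identical(aug@panel, fit$model@panel)
  dsA <- meanDS(avgA, fit$model)
  expect_identical(classifyDS(dsA, aug@threshold),
                   classifyDS(dsA, fit$model@threshold))

  # adding axis ions grows the panel and keeps the loading weights
  extra <- setdiff(seq_along(fit$model@axisMz), fit$model@panel)[1:2]
  aug <- augmentModel(fit$model, fit$model@axisMz[extra], avgA)
  expect_true(all(extra %in% aug@panel))
  expect_true(all(fit$model@panel %in% aug@panel))
  expect_equal(aug@loading@weight, fit$model@loading@weight)

  expect_error(augmentModel(fit$model, 77.77, avgA), "300 ppm")
})

test_that("augmenting with noise ions does not help, withheld signal does not hurt", {
  deltaNoise <- c()
  deltaSignal <- c()
  for (seed in c(41L, 42L, 43L)) {
    co <- smallCohort(seed = seed, nPerClass = 10L, nPlanted = 4L)
    rc <- runConfig(targetClass = "TARGET", rngSeed = seed)
    fit <- suppressWarnings(buildLome(co$spectra, co$manifest, rc))
    avgA <- fit$tables$avgA
    avgB <- fit$tables$avgB
    cd <- columnMeta(avgB)
    bScore <- function(model) {
      ds <- meanDS(avgB, model)
      o <- oracleConfusion(ds, cd$class == "TARGET", model@threshold)
      o$sens + o$spec
    }
    base <- bScore(fit$model)

    axis <- fit$model@axisMz
    planted <- vapply(co$truth$plantedMz, function(p)
      which.min(abs(axis - p)), integer(1))
    noiseIons <- setdiff(seq_along(axis), planted)[1:3]
    deltaNoise <- c(deltaNoise,
                    bScore(augmentModel(fit$model, axis[noiseIons],
                                        avgA)) - base)
    withheld <- setdiff(planted, fit$model@panel)
    if (length(withheld))
      deltaSignal <- c(deltaSignal,
                       bScore(augmentModel(fit$model, axis[withheld[1]],
                                           avgA)) - base)
  }
  expect_lte(median(deltaNoise), 0.05)
  if (length(deltaSignal)) expect_gte(median(deltaSignal), -0.05)
})
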