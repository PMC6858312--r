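test_that("stratified folds balance sizes and classes", {
  y <- factor(rep(c("a", "b"), each = 50))
  plan <- stratifiedFolds(y, nFolds = 10, seed = 1)
  folds <- foldIndices(plan)
  expect_length(folds, 10L)
  expect_equal(sort(unlist(folds)), 1:100)
  expect_true(all(lengths(folds) == 10L))
  for (f in folds) expect_equal(sum(y[f] == "a"), 5L)
  ## same seed, same plan; different seed, different plan
  expect_identical(foldIndices(stratifiedFolds(y, 10, seed = 1)), folds)
  expect_false(identical(foldIndices(stratifiedFolds(y, 10, seed = 2)),
                         folds))
  ## a 3-sample class lands in 3 distinct folds
  y2 <- factor(c(rep("big", 47), rep("rare", 3)))
  folds2 <- foldIndices(stratifiedFolds(y2, 10, seed = 4))
  rareFolds <- vapply(folds2, function(f) sum(y2[f] == "rare"), integer(1))
  expect_equal(sum(rareFolds > 0), 3L)
  expect_true(all(rareFolds <= 1L))
  expect_error(stratifiedFolds(factor(c("a", "b")), nFolds = 10), "exceeds")
})

test_that("the leakage guard rejects any train/test overlap", {
  expect_true(assertNoLeakage(c("S1", "S2"), c("S3", "S4")))
  expect_error(assertNoLeakage(c("S1", "S2"), c("S2", "S3")), "leakage")
})

test_that("class metrics reproduce hand-checked precision/recall algebra", {
  ## published worked rows: F1 from the printed precision/recall pairs
  ## (the printed F1 carries the rounding of unprinted digits, so agreement
  ## is to within one unit in the last printed decimal)
  expect_equal(f1Score(96.10, 84.09), 89.70, tolerance = 1e-4)
  expect_equal(f1Score(88.36, 94.39), 91.27, tolerance = 1e-4)
  expect_equal(f1Score(0, 0), 0)

  yt <- c("a", "a", "a", "b", "b", "c")
  yp <- c("a", "a", "b", "b", "b", "b")
  m <- classMetrics(yt, yp)
  pc <- m$perClass
  expect_equal(pc$precision[pc$class == "a"], 100)     # 2 / 2
  expect_equal(pc$recall[pc$class == "a"], 100 * 2 / 3)
  expect_equal(pc$precision[pc$class == "b"], 100 * 2 / 4)
  expect_equal(pc$recall[pc$class == "c"], 0)
  expect_equal(pc$f1[pc$class == "c"], 0)              # P + R = 0
  expect_equal(m$overallAccuracy, 100 * 4 / 6)
  expect_equal(m$macroF1, mean(pc$f1))

  ## identity predictions give 100 everywhere
  m2 <- classMetrics(yt, yt)
  expect_true(all(m2$perClass$precision == 100))
  expect_equal(m2$overallAccuracy, 100)

  ## fold-averaged per-class accuracy averages within-fold recall
  m3 <- classMetrics(c("a", "a", "a", "a"), c("a", "x", "a", "a"),
                     labels = c("a", "x"), folds = c(1, 1, 2, 2))
  expect_equal(m3$perClass$accuracy[1], mean(c(50, 100)))
  expect_equal(m3$perClass$recall[1], 75)

  expect_error(classMetrics("a", "z", labels = c("a", "b")), "outside")
  expect_error(classMetrics(c("a", "b"), "a"), "differ")
})

test_that("agreement algebra satisfies inclusion-exclusion exactly", {
  ## enumerated 4-outcome case
  t4 <- agreementTable(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t4),
               c(pctA = 50, pctB = 50, pctBoth = 25, pctEither = 75,
                 pctOnlyA = 25, pctOnlyB = 25))
  ## identical classifiers collapse the algebra
  same <- agreementTable(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$pctBoth, same$pctA)
  expect_equal(same$pctOnlyA, 0)
  expect_equal(same$pctOnlyB, 0)
  ## published worked row: derived cells from printed A, B, A-and-B
  row <- agreementFromRates(82.25, 73.79, 67.81)
  expect_equal(row$pctEither, 88.23)
  expect_equal(row$pctOnlyA, 14.44)
  expect_equal(row$pctOnlyB, 5.98)
  ## identities hold for random draws
  withr::with_seed(1, for (i in 1:20) {
    a <- runif(37) < 0.7; b <- runif(37) < 0.5
    tt <- agreementTable(a, b)
    expect_equal(tt$pctEither, tt$pctA + tt$pctB - tt$pctBoth)
    expect_equal(tt$pctOnlyA, tt$pctA - tt$pctBoth)
    expect_equal(tt$pctOnlyB, tt$pctB - tt$pctBoth)
    expect_true(all(unlist(tt) >= 0 & unlist(tt) <= 100))
  })
  expect_error(agreementTable(TRUE, c(TRUE, FALSE)), "equal-length")
})

test_that("inner selection follows the grid contract and tie-breaks", {
  withr::with_seed(3, {
    y <- factor(rep(c("a", "b", "c"), each = 30))
    X <- matrix(rnorm(90 * 40), 90, 40)
    for (j in 1:4) X[, j] <- as.integer(y) + rnorm(90, sd = 0.4)
    colnames(X) <- paste0("f", 1:40)
    rownames(X) <- paste0("S", 1:90)
  })
  ## a singleton grid is returned directly
  one <- innerSelectConfig(X, y, methods = "lsvc", kGrid = 8, seed = 1)
  expect_equal(one$method, "lsvc")
  expect_equal(one$k, 8L)
  expect_equal(nrow(one$innerAccuracy), 0L)
  expect_error(innerSelectConfig(X, y, methods = character(0), kGrid = 8),
               "empty")
  expect_error(innerSelectConfig(X, y, kGrid = 100), "dimension")
})

test_that("the inner loop prefers the planted feature count", {
  ## only 4 planted features are informative; k = 4 should beat k = d
  hits <- 0L
  cfg <- mlpConfig(hiddenLayers = 1, unitsPerLayer = 8,
                   learningRate = 1e-2, maxEpochs = 15,
                   earlyStopPatience = 15)
  for (seed in 1:3) {
    withr::with_seed(seed, {
      y <- factor(rep(c("a", "b", "c"), each = 25))
      X <- matrix(rnorm(75 * 60), 75, 60)
      for (j in 1:4) X[, j] <- as.integer(y) + rnorm(75, sd = 0.35)
      colnames(X) <- paste0("f", 1:60)
      rownames(X) <- paste0("S", 1:75)
    })
    res <- innerSelectConfig(X, y, methods = "extra_trees",
                             kGrid = c(4L, 60L), seed = seed,
                             mlpCfg = cfg, rfTrees = 100,
                             selectionArgs = list(nTrees = 100))
    if (res$k == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("nested cross-validation predicts every sample exactly once", {
  co <- tinyCohort()
  fm <- tinyFeatureMatrix()
  cfg <- mlpConfig(hiddenLayers = 1, unitsPerLayer = 16,
                   learningRate = 1e-2, maxEpochs = 20,
                   earlyStopPatience = 20)
  rep <- nestedCV(fm, methods = "extra_trees", kGrid = 40L, seed = 5,
                  nFolds = 5, mlpCfg = cfg, rfTrees = 100,
                  selectionArgs = list(nTrees = 100))
  preds <- cvPredictions(rep)
  expect_equal(sort(preds$sample_id), sort(names(co$labels)))
  expect_false(anyDuplicated(preds$sample_id) > 0)
  ## planted tiny signal is easily found
  expect_gt(overallAccuracy(rep, "ensemble"), 60)
  ## metrics are recomputable from the stored predictions
  m <- classMetrics(preds$truth, preds$pred_ensemble,
                    labels = levels(co$labels), folds = preds$fold)
  expect_equal(m$overallAccuracy, overallAccuracy(rep, "ensemble"))
  expect_equal(rep@metrics$perClass, m$perClass)
  ## chosen configuration is logged per fold
  expect_equal(nrow(rep@foldChoices), 5L)
  ## nested CV is reproducible under the same seed
  rep2 <- nestedCV(fm, methods = "extra_trees", kGrid = 40L, seed = 5,
                   nFolds = 5, mlpCfg = cfg, rfTrees = 100,
                   selectionArgs = list(nTrees = 100))
  expect_identical(cvPredictions(rep2), preds)
})

test_that("ablation isolates signal planted in one feature block", {
  cfg <- defaultSimulationConfig("tiny")
  cfg$driverMutationProb <- 0          # no driver signal
  cfg$cnaLog2ShiftMean <- 0            # no copy-number shift
  cfg$cnaLog2ShiftSd <- 0.01
  cfg$burdenLognormalSigma <- 0.2
  cfg$hotContextSpectrum <- "C>T"      # spectrum marginals uninformative
  cfg$hotContextsPerType <- 5L
  co <- simulateCohort(cfg)
  fm <- cohortFeatureMatrix(co)
  acc <- ablationStudy(fm, seed = 2, rfTrees = 150)
  expect_length(acc, 5L)
  expect_equal(names(acc)[5], "profile+rates+spectra+scna+signatures")
  ## signatures carry the only planted signal
  expect_gte(acc[5] - acc[4], 10)
  expect_error(ablationStudy(fm, groupOrder = c("profile", "bogus")),
               "unknown")
  ## single-group prefix equals plain CV on that block
  accP <- ablationStudy(fm, groupOrder = "profile", seed = 2,
                        rfTrees = 150)
  expect_equal(unname(accP[1]), unname(acc[1]))
})

test_that("importance ranking surfaces planted features in order", {
  fm <- tinyFeatureMatrix()
  top <- rankImportance(fm, topN = 10, seed = 1, nTrees = 300)
  expect_equal(nrow(top), 10L)
  expect_true(all(diff(top$importance) <= 0))
  ## planted informative features dominate the top of the ranking
  expect_gte(sum(top$feature %in% tinyCohort()$truth$informativeFeatures), 5)
  ## topN = d returns a permutation of all features
  all <- rankImportance(fm, topN = nFeatures(fm), seed = 1, nTrees = 100)
  expect_setequal(all$feature, featureNames(fm))
  expect_error(rankImportance(fm, topN = 1e5), "exceeds")
})

test_that("class-size filtering drops small classes and guards degeneracy", {
  withr::with_seed(1, {
    labs <- factor(c(rep("A", 300), rep("B", 150), rep("C", 50)))
    X <- matrix(rnorm(500 * 3), 500, 3)
    rownames(X) <- paste0("S", 1:500)
    names(labs) <- rownames(X)
  })
  ## minSamples = 1 is the identity
  r1 <- filterByClassSize(X, labs, 1)
  expect_equal(nrow(r1$matrix), 500L)
  ## 100 keeps A and B
  r2 <- filterByClassSize(X, labs, 100)
  expect_equal(nrow(r2$matrix), 450L)
  expect_equal(levels(r2$labels), c("A", "B"))
  ## 200 keeps only A: too few classes to classify
  expect_error(filterByClassSize(X, labs, 200), "at least 2")
  ## FeatureMatrix input stays a FeatureMatrix
  fm <- tinyFeatureMatrix()
  rf <- filterByClassSize(fm, minSamples = 10)
  expect_s4_class(rf$matrix, "FeatureMatrix")
  expect_equal(ncol(rf$matrix), 90L)
})
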