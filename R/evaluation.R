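#' @include AllClasses.R AllGenerics.R feature-selection.R classification.R
NULL

#' Seeded stratified fold assignment
#'
#' Deals each class's (shuffled) samples to folds through one global rotating
#' pointer, so fold sizes differ by at most one overall, class proportions
#' are preserved within rounding, and a class with fewer samples than folds
#' lands in that many distinct folds.
#'
#' @param labels class labels (factor or character; a named factor keeps its
#'   names in the plan's index space).
#' @param nFolds number of folds (>= 2); must not exceed the sample count.
#' @param seed RNG seed; the same seed reproduces the plan exactly.
#' @return a [FoldPlan-class] whose folds partition `seq_along(labels)`.
#' @export
stratifiedFolds <- function(labels, nFolds = 10, seed = 1) {
  y <- factor(labels)
  n <- length(y)
  if (nFolds < 2) stop("nFolds must be >= 2")
  if (nFolds > n) stop("nFolds exceeds the number of samples")
  withr::with_seed(seed, {
    assignment <- integer(n)
    p <- sample.int(nFolds, 1) - 1L  # random starting fold
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      assignment[rows] <- (p + seq_along(rows) - 1L) %% nFolds + 1L
      p <- (p + length(rows)) %% nFolds
    }
    folds <- split(seq_len(n), factor(assignment, levels = seq_len(nFolds)))
    names(folds) <- NULL
    new("FoldPlan", folds = folds, seed = as.integer(seed))
  })
}

#' Leakage guard
#'
#' Asserts that the held-out test samples are disjoint from every sample seen
#' by standardization, selection or training inside a fold; any intersection
#' aborts the run.
#'
#' @param trainIds,testIds sample identifier vectors.
#' @return TRUE, invisibly.
#' @export
assertNoLeakage <- function(trainIds, testIds) {
  both <- intersect(trainIds, testIds)
  if (length(both) > 0)
    stop("leakage guard: ", length(both), " held-out sample(s) were seen ",
         "during fitting: ", paste(utils::head(both, 5), collapse = ", "))
  invisible(TRUE)
}

## Fit selection + ensemble on a training split, score on a validation split.
.fitScore <- function(Xtr, ytr, Xte, yte, method, k, seed, mlpCfg, rfTrees,
                      trainIds, testIds, selectionArgs = list()) {
  assertNoLeakage(trainIds, testIds)
  problem <- makeSelectionProblem(Xtr, ytr)
  sel <- do.call(selectK, c(list(method = method, problem = problem,
                                 kFeatures = k, seed = seed), selectionArgs))
  idx <- selectedFeatures(sel)
  XtrS <- standardizedValues(problem)[, idx, drop = FALSE]
  XteS <- standardizedValues(problem, Xte)[, idx, drop = FALSE]
  model <- trainEnsemble(XtrS, ytr, mlpCfg = mlpCfg, rfTrees = rfTrees,
                         seed = seed)
  pe <- ensemblePredict(predictProba(model@memberA, XteS),
                        predictProba(model@memberB, XteS))
  list(selection = sel, model = model, problem = problem,
       XteS = XteS,
       accuracy = mean(pe$labels == as.character(yte)),
       predEnsemble = pe$labels)
}

#' Choose the selector method and feature count on inner folds
#'
#' For every (method, k) pair in the grid, runs select-to-k on each inner
#' training set, trains the soft-voting ensemble on the selected features and
#' scores it on the held-out inner fold; the pair with the highest mean inner
#' accuracy wins, ties going to the smaller k and then to method order
#' (lsvc, lasso, extra_trees). When the grid holds exactly one pair it is
#' returned directly (the inner accuracy estimate could not change the
#' choice).
#'
#' @param Xtrain,ytrain outer-training rows and labels.
#' @param methods selector methods to search over; default "lsvc".
#' @param kGrid integer feature counts to search over (each <= ncol(Xtrain)).
#' @param innerPlan optional [FoldPlan-class] over the training rows; by
#'   default a stratified 10-fold plan drawn from `seed`.
#' @param seed RNG seed.
#' @param mlpCfg,rfTrees ensemble settings used for inner scoring.
#' @param selectionArgs extra arguments passed to [selectK()].
#' @return list with `method`, `k`, and `innerAccuracy` (a data.frame of mean
#'   inner accuracies per pair; empty for a singleton grid).
#' @export
innerSelectConfig <- function(Xtrain, ytrain, methods = "lsvc", kGrid,
                              innerPlan = NULL, seed = 1,
                              mlpCfg = mlpConfig(), rfTrees = 500,
                              selectionArgs = list()) {
  if (length(kGrid) == 0 || length(methods) == 0)
    stop("the (method, k) grid must not be empty")
  kGrid <- sort(unique(as.integer(kGrid)))
  if (any(kGrid > ncol(Xtrain)))
    stop("kGrid values must not exceed the feature dimension")
  methodOrder <- c("lsvc", "lasso", "extra_trees")
  methods <- methodOrder[methodOrder %in% methods]
  empty <- data.frame(method = character(0), k = integer(0),
                      meanAccuracy = numeric(0))
  if (length(methods) == 1 && length(kGrid) == 1)
    return(list(method = methods, k = kGrid, innerAccuracy = empty))
  if (is.null(innerPlan))
    innerPlan <- stratifiedFolds(ytrain, nFolds = 10, seed = seed)
  folds <- foldIndices(innerPlan)
  ids <- rownames(Xtrain)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xtrain)))
  grid <- expand.grid(k = kGrid, method = methods, stringsAsFactors = FALSE)
  grid$meanAccuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- vapply(folds, function(hold) {
      tr <- setdiff(seq_len(nrow(Xtrain)), hold)
      .fitScore(Xtrain[tr, , drop = FALSE], ytrain[tr],
                Xtrain[hold, , drop = FALSE], ytrain[hold],
                grid$method[g], grid$k[g], seed, mlpCfg, rfTrees,
                ids[tr], ids[hold], selectionArgs)$accuracy
    }, numeric(1))
    grid$meanAccuracy[g] <- mean(acc)
  }
  ## ties: smaller k, then method order
  grid$methodRank <- match(grid$method, methodOrder)
  grid <- grid[order(-grid$meanAccuracy, grid$k, grid$methodRank), ]
  list(method = grid$method[1], k = grid$k[1],
       innerAccuracy = grid[, c("method", "k", "meanAccuracy")])
}

#' Nested cross-validation of the full pipeline
#'
#' Outer stratified folds estimate generalization; within each outer training
#' set an inner 10-fold search ([innerSelectConfig()]) picks the selector
#' method and feature count, the selection and standardization are refitted
#' on the full outer-training rows, the soft-voting ensemble (and optionally
#' the OvR-SVM and KNN baselines) is trained, and predictions are recorded
#' for the outer-test rows. No outer-test row ever touches standardization,
#' selection or training: the leakage guard asserts this in every fold.
#'
#' @param fm a [FeatureMatrix-class] or samples-by-features matrix.
#' @param labels named factor of sample labels (defaults to the matrix's own
#'   labels).
#' @param methods selector methods searched in the inner loop.
#' @param kGrid feature-count grid; default 5/10/15/20% of the dimension.
#' @param seed RNG seed for folds, selection and training.
#' @param nFolds number of outer folds; default 10.
#' @param mlpCfg,rfTrees ensemble settings.
#' @param includeBaselines also train OvR-SVM and KNN per fold (needed for
#'   the four-classifier agreement analysis).
#' @param selectionArgs extra arguments passed to [selectK()].
#' @return a [CVReport-class]; every sample is predicted exactly once.
#' @export
nestedCV <- function(fm, labels = NULL, methods = "lsvc", kGrid = NULL,
                     seed = 1, nFolds = 10, mlpCfg = mlpConfig(),
                     rfTrees = 500, includeBaselines = FALSE,
                     selectionArgs = list()) {
  X <- if (is(fm, "FeatureMatrix")) featureValues(fm) else as.matrix(fm)
  if (is.null(labels) && is(fm, "FeatureMatrix")) labels <- sampleLabels(fm)
  if (is.null(labels)) stop("labels are required")
  labels <- labels[rownames(X)]
  y <- droplevels(factor(labels))
  if (is.null(kGrid))
    kGrid <- unique(pmax(1L, as.integer(round(
      c(0.05, 0.10, 0.15, 0.20) * ncol(X)))))
  plan <- stratifiedFolds(y, nFolds = nFolds, seed = seed)
  ids <- rownames(X)
  preds <- list(); choices <- list()
  for (f in seq_along(foldIndices(plan))) {
    hold <- foldIndices(plan)[[f]]
    tr <- setdiff(seq_len(nrow(X)), hold)
    assertNoLeakage(ids[tr], ids[hold])
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    cfg <- innerSelectConfig(Xtr, ytr, methods = methods, kGrid = kGrid,
                             seed = seed, mlpCfg = mlpCfg,
                             rfTrees = rfTrees,
                             selectionArgs = selectionArgs)
    problem <- makeSelectionProblem(Xtr, ytr)
    sel <- do.call(selectK,
                   c(list(method = cfg$method, problem = problem,
                          kFeatures = cfg$k, seed = seed), selectionArgs))
    idx <- selectedFeatures(sel)
    XtrS <- standardizedValues(problem)[, idx, drop = FALSE]
    XteS <- standardizedValues(problem,
                               X[hold, , drop = FALSE])[, idx, drop = FALSE]
    model <- trainEnsemble(XtrS, ytr, mlpCfg = mlpCfg, rfTrees = rfTrees,
                           seed = seed)
    pa <- predictProba(model@memberA, XteS)
    pb <- predictProba(model@memberB, XteS)
    pe <- ensemblePredict(pa, pb)
    fold <- data.frame(
      sample_id = ids[hold], fold = f, truth = as.character(y[hold]),
      pred_mlp = colnames(pa)[max.col(pa, ties.method = "first")],
      pred_rf = colnames(pb)[max.col(pb, ties.method = "first")],
      pred_ensemble = pe$labels,
      stringsAsFactors = FALSE)
    if (includeBaselines) {
      for (bk in c("ovr_svm", "knn")) {
        mdl <- trainClassifier(bk, XtrS, ytr, seed = seed)
        pp <- predictProba(mdl, XteS)
        fold[[paste0("pred_", sub("ovr_svm", "svm", bk))]] <-
          colnames(pp)[max.col(pp, ties.method = "first")]
      }
    }
    preds[[f]] <- fold
    choices[[f]] <- data.frame(fold = f, method = cfg$method, k = cfg$k,
                               regularization = sel@regularizationUsed)
  }
  predictions <- do.call(rbind, preds)
  metrics <- classMetrics(predictions$truth, predictions$pred_ensemble,
                          labels = levels(y), folds = predictions$fold)
  new("CVReport", predictions = predictions,
      foldChoices = do.call(rbind, choices), metrics = metrics,
      meta = list(seed = seed, nFolds = nFolds, methods = methods,
                  kGrid = kGrid, mlpConfig = mlpCfg, rfTrees = rfTrees,
                  foldPlan = plan))
}

#' F1 score from precision and recall
#'
#' `2 * P * R / (P + R)`, and 0 when `P + R = 0`; inputs and output share
#' whatever scale (fraction or percent) the inputs use.
#'
#' @param precision,recall numeric vectors.
#' @return numeric vector of F1 scores.
#' @examples
#' f1Score(96.10, 84.09)  # 89.70 to two decimals
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class classification metrics
#'
#' Per class: precision TP/(TP+FP), recall TP/(TP+FN), F1 (0 when P+R=0), and
#' "accuracy" in the per-class sense: the mean over folds of the within-fold
#' recall when a fold structure is supplied, else the pooled recall. Also
#' pooled overall accuracy and macro averages (macro F1 is the mean of the
#' per-class F1 values). All values are percentages at full precision.
#'
#' @param yTrue,yPred equal-length label vectors; predictions outside the
#'   label set are an error.
#' @param labels class label order; default the classes present in `yTrue`.
#' @param folds optional fold id per sample for fold-averaged per-class
#'   accuracy.
#' @return list with `perClass` (data.frame: class, n, precision, recall, f1,
#'   accuracy), `overallAccuracy`, `macroPrecision`, `macroRecall`,
#'   `macroF1`.
#' @export
classMetrics <- function(yTrue, yPred, labels = NULL, folds = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred lengths differ")
  if (is.null(labels)) labels <- sort(unique(yTrue))
  bad <- setdiff(unique(c(yTrue, yPred)), labels)
  if (length(bad) > 0)
    stop("label(s) outside the label set: ", paste(bad, collapse = ", "))
  perClass <- do.call(rbind, lapply(labels, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    precision <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    accuracy <- if (is.null(folds)) recall else {
      inFold <- vapply(unique(folds), function(f) {
        m <- folds == f & yTrue == cl
        if (!any(m)) NA_real_ else 100 * mean(yPred[m] == cl)
      }, numeric(1))
      mean(inFold, na.rm = TRUE)
    }
    data.frame(class = cl, n = tp + fn, precision = precision,
               recall = recall, f1 = f1Score(precision, recall),
               accuracy = accuracy, stringsAsFactors = FALSE)
  }))
  list(perClass = perClass,
       overallAccuracy = 100 * mean(yTrue == yPred),
       macroPrecision = mean(perClass$precision),
       macroRecall = mean(perClass$recall),
       macroF1 = mean(perClass$f1))
}

#' Classifier-agreement set algebra
#'
#' Given the per-sample correctness of two classifiers A and B, computes the
#' percentage of samples each predicts correctly, the intersection (both
#' correct), the union (either correct), and the two set differences, at full
#' precision. The inclusion-exclusion identities
#' `either = a + b - both`, `onlyA = a - both`, `onlyB = b - both` hold
#' exactly.
#'
#' @param correctA,correctB equal-length logical vectors.
#' @return one-row data.frame with columns pctA, pctB, pctBoth, pctEither,
#'   pctOnlyA, pctOnlyB (percentages of evaluated samples).
#' @export
agreementTable <- function(correctA, correctB) {
  if (length(correctA) != length(correctB) || length(correctA) == 0)
    stop("correctA and correctB must be equal-length, non-empty")
  n <- length(correctA)
  a <- 100 * sum(correctA) / n
  b <- 100 * sum(correctB) / n
  both <- 100 * sum(correctA & correctB) / n
  agreementFromRates(a, b, both)
}

#' @rdname agreementTable
#' @param pctA,pctB,pctBoth the percentages of samples A, B and both predict
#'   correctly; the remaining cells follow by inclusion-exclusion.
#' @export
agreementFromRates <- function(pctA, pctB, pctBoth) {
  data.frame(pctA = pctA, pctB = pctB, pctBoth = pctBoth,
             pctEither = pctA + pctB - pctBoth,
             pctOnlyA = pctA - pctBoth, pctOnlyB = pctB - pctBoth)
}

#' Pairwise agreement analysis over a cross-validation report
#'
#' Builds the agreement table for every pair of prediction columns in a
#' [CVReport-class] (mlp, rf, ensemble, and the baselines when recorded),
#' ordered so that the more accurate member of each pair is A.
#'
#' @param report a [CVReport-class].
#' @return data.frame with columns A, B and the [agreementTable()] cells.
#' @export
pairwiseAgreement <- function(report) {
  df <- cvPredictions(report)
  models <- sub("^pred_", "", grep("^pred_", colnames(df), value = TRUE))
  correct <- lapply(models, function(m)
    df[[paste0("pred_", m)]] == df$truth)
  names(correct) <- models
  pairs <- utils::combn(models, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    if (mean(correct[[b]]) > mean(correct[[a]])) { tmp <- a; a <- b; b <- tmp }
    cbind(data.frame(A = a, B = b, stringsAsFactors = FALSE),
          agreementTable(correct[[a]], correct[[b]]))
  })
  do.call(rbind, out)
}

#' Cumulative feature-group ablation
#'
#' Starting from the first feature group and consecutively adding the others
#' (default order: profile, rates, spectra, scna, signatures), runs plain
#' stratified 10-fold cross-validation with a random-forest classifier
#' restricted to the cumulative feature blocks and reports one accuracy per
#' prefix.
#'
#' @param fm a [FeatureMatrix-class].
#' @param labels named factor (default the matrix's labels).
#' @param groupOrder permutation-prefix of
#'   `c("profile","rates","spectra","scna","signatures")`.
#' @param seed RNG seed.
#' @param nFolds folds; default 10.
#' @param rfTrees trees; default 300.
#' @return named numeric vector of accuracies (percent), one per cumulative
#'   prefix, names like "profile", "profile+rates", ...
#' @export
ablationStudy <- function(fm, labels = NULL,
                          groupOrder = c("profile", "rates", "spectra",
                                         "scna", "signatures"),
                          seed = 1, nFolds = 10, rfTrees = 300) {
  stopifnot(is(fm, "FeatureMatrix"))
  known <- levels(featureGroups(fm))
  if (!all(groupOrder %in% known))
    stop("unknown feature group(s): ",
         paste(setdiff(groupOrder, known), collapse = ", "))
  if (anyDuplicated(groupOrder)) stop("duplicate feature group in order")
  if (is.null(labels)) labels <- sampleLabels(fm)
  X <- featureValues(fm)
  y <- droplevels(factor(labels[rownames(X)]))
  groups <- featureGroups(fm)
  plan <- stratifiedFolds(y, nFolds = nFolds, seed = seed)
  out <- numeric(length(groupOrder))
  names(out) <- vapply(seq_along(groupOrder), function(i)
    paste(groupOrder[seq_len(i)], collapse = "+"), character(1))
  for (i in seq_along(groupOrder)) {
    cols <- which(groups %in% groupOrder[seq_len(i)])
    Xi <- X[, cols, drop = FALSE]
    correct <- logical(nrow(Xi))
    for (hold in foldIndices(plan)) {
      tr <- setdiff(seq_len(nrow(Xi)), hold)
      mdl <- trainClassifier("random_forest", Xi[tr, , drop = FALSE],
                             y[tr], config = list(numTrees = rfTrees),
                             seed = seed)
      pp <- predictProba(mdl, Xi[hold, , drop = FALSE])
      correct[hold] <-
        colnames(pp)[max.col(pp, ties.method = "first")] ==
        as.character(y[hold])
    }
    out[i] <- 100 * mean(correct)
  }
  out
}

#' Random-forest feature-importance ranking
#'
#' Impurity importance of every feature from a random forest fitted to the
#' full labeled matrix, in non-increasing order (ties to the lower feature
#' index), with schema feature names attached.
#'
#' @param fm a [FeatureMatrix-class] or samples-by-features matrix.
#' @param labels named factor (default the matrix's labels).
#' @param topN number of features to return; default 10.
#' @param seed RNG seed.
#' @param nTrees trees; default 500.
#' @return data.frame with columns feature, importance.
#' @export
rankImportance <- function(fm, labels = NULL, topN = 10, seed = 1,
                           nTrees = 500) {
  X <- if (is(fm, "FeatureMatrix")) featureValues(fm) else as.matrix(fm)
  if (is.null(labels) && is(fm, "FeatureMatrix")) labels <- sampleLabels(fm)
  if (topN > ncol(X)) stop("topN exceeds the feature dimension")
  y <- droplevels(factor(labels[rownames(X)]))
  fnames <- colnames(X)
  Xn <- X; colnames(Xn) <- paste0("x", seq_len(ncol(X)))
  fit <- ranger::ranger(x = Xn, y = y, num.trees = nTrees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- unname(fit$variable.importance)
  ord <- order(-imp, seq_along(imp))[seq_len(topN)]
  data.frame(feature = fnames[ord], importance = imp[ord],
             stringsAsFactors = FALSE)
}

#' Drop classes below a minimum sample count
#'
#' Removes every class with fewer than `minSamples` samples together with its
#' rows. Classification needs at least two surviving classes; fewer is an
#' error.
#'
#' @param fm a [FeatureMatrix-class] or samples-by-features matrix.
#' @param labels named factor (default the matrix's labels).
#' @param minSamples minimum class size to keep (>= 1).
#' @return list with the subset `matrix` (same type as the input) and
#'   `labels`.
#' @export
filterByClassSize <- function(fm, labels = NULL, minSamples = 1) {
  if (minSamples < 1) stop("minSamples must be >= 1")
  isFm <- is(fm, "FeatureMatrix")
  if (is.null(labels) && isFm) labels <- sampleLabels(fm)
  ids <- if (isFm) sampleIds(fm) else rownames(fm)
  labels <- droplevels(factor(labels[ids]))
  sizes <- table(labels)
  keepClasses <- names(sizes)[sizes >= minSamples]
  if (length(keepClasses) < 2)
    stop(length(keepClasses), " class(es) have >= ", minSamples,
         " samples; classification needs at least 2")
  keep <- which(as.character(labels) %in% keepClasses)
  newLabels <- droplevels(labels[keep])
  names(newLabels) <- ids[keep]
  sub <- if (isFm) fm[, keep] else fm[keep, , drop = FALSE]
  list(matrix = sub, labels = newLabels)
}
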