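#' @include AllClasses.R AllGenerics.R
NULL

#' Multilayer-perceptron hyperparameters
#'
#' Defaults follow the reference architecture: three hidden layers of 2048
#' rectified-linear units, softmax output trained with multinomial
#' cross-entropy by Adam at learning rate 1e-5 with 40% dropout on the hidden
#' layers. Epoch budget, batch size and early stopping are configurable
#' (training stops when the held-out validation loss has not improved for
#' `earlyStopPatience` epochs, and the best-validation weights are kept).
#'
#' @param hiddenLayers number of hidden layers; default 3.
#' @param unitsPerLayer units per hidden layer; default 2048.
#' @param dropoutRate drop probability on hidden activations during training
#'   only; default 0.4.
#' @param learningRate Adam step size; default 1e-5.
#' @param batchSize minibatch size; default 128.
#' @param maxEpochs maximum training epochs; default 200.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping; default 10.
#' @param validationFraction fraction of training rows held out (stratified)
#'   for early stopping; default 0.1.
#' @return a validated `MlpConfig` list.
#' @export
mlpConfig <- function(hiddenLayers = 3, unitsPerLayer = 2048,
                      dropoutRate = 0.4, learningRate = 1e-5,
                      batchSize = 128, maxEpochs = 200,
                      earlyStopPatience = 10, validationFraction = 0.1) {
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must be in [0, 1)")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (hiddenLayers < 1 || unitsPerLayer < 1)
    stop("need at least one hidden layer and one unit")
  structure(list(hiddenLayers = as.integer(hiddenLayers),
                 unitsPerLayer = as.integer(unitsPerLayer),
                 dropoutRate = dropoutRate, learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 validationFraction = validationFraction),
            class = "MlpConfig")
}

## Numerically stable row-wise softmax.
.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---------------------------------------------------------------------------
## Multilayer perceptron (ReLU + dropout + softmax cross-entropy + Adam)
## ---------------------------------------------------------------------------

.mlpForward <- function(weights, X, dropoutRate = 0, training = FALSE) {
  nL <- length(weights$W)
  A <- X
  acts <- vector("list", nL)
  for (l in seq_len(nL - 1)) {
    Z <- A %*% weights$W[[l]] + rep(1, nrow(A)) %o% weights$b[[l]]
    A <- pmax(Z, 0)
    if (training && dropoutRate > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropoutRate, nrow(A))
      A <- A * mask / (1 - dropoutRate)  # inverted dropout
    }
    acts[[l]] <- A
  }
  Z <- A %*% weights$W[[nL]] + rep(1, nrow(A)) %o% weights$b[[nL]]
  list(scores = Z, acts = acts)
}

.mlpLoss <- function(scores, yIdx) {
  P <- .softmax(scores)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), yIdx)], 1e-12)))
}

.trainMlp <- function(X, y, config, seed) {
  withr::with_seed(seed, {
    y <- droplevels(factor(y))
    k <- nlevels(y)
    n <- nrow(X); d <- ncol(X)
    yIdx <- as.integer(y)

    ## stratified validation split
    valIdx <- integer(0)
    if (config$validationFraction > 0) {
      small <- names(which(table(y) < 2))
      if (length(small) > 0)
        stop("class(es) with < 2 training samples (",
             paste(small, collapse = ", "),
             ") cannot support a validation split; use stratified ",
             "handling or set validationFraction = 0")
      for (c in seq_len(k)) {
        rows <- which(yIdx == c)
        nv <- max(1L, floor(length(rows) * config$validationFraction))
        nv <- min(nv, length(rows) - 1L)  # keep >=1 training row per class
        valIdx <- c(valIdx, sample(rows, nv))
      }
    }
    trIdx <- setdiff(seq_len(n), valIdx)
    Xtr <- X[trIdx, , drop = FALSE]; ytr <- yIdx[trIdx]
    Xval <- X[valIdx, , drop = FALSE]; yval <- yIdx[valIdx]

    sizes <- c(d, rep(config$unitsPerLayer, config$hiddenLayers), k)
    nL <- length(sizes) - 1
    W <- lapply(seq_len(nL), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(nL), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0

    best <- list(W = W, b = b)
    bestVal <- Inf; wait <- 0
    valTrajectory <- numeric(0)

    for (epoch in seq_len(config$maxEpochs)) {
      perm <- sample(length(trIdx))
      batches <- split(perm, ceiling(seq_along(perm) / config$batchSize))
      for (bt in batches) {
        Xb <- Xtr[bt, , drop = FALSE]; yb <- ytr[bt]
        fw <- .mlpForward(list(W = W, b = b), Xb,
                          dropoutRate = config$dropoutRate, training = TRUE)
        P <- .softmax(fw$scores)
        m <- nrow(Xb)
        dZ <- P
        dZ[cbind(seq_len(m), yb)] <- dZ[cbind(seq_len(m), yb)] - 1
        dZ <- dZ / m
        gW <- vector("list", nL); gb <- vector("list", nL)
        for (l in rev(seq_len(nL))) {
          Ain <- if (l == 1) Xb else fw$acts[[l - 1]]
          gW[[l]] <- crossprod(Ain, dZ)
          gb[[l]] <- colSums(dZ)
          if (l > 1) {
            dA <- dZ %*% t(W[[l]])
            dZ <- dA * (fw$acts[[l - 1]] > 0)
          }
        }
        step <- step + 1
        lr <- config$learningRate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        for (l in seq_len(nL)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - lr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] - lr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      if (length(valIdx) > 0) {
        sc <- .mlpForward(list(W = W, b = b), Xval)$scores
        vl <- .mlpLoss(sc, yval)
        valTrajectory <- c(valTrajectory, vl)
        if (vl < bestVal - 1e-9) {
          bestVal <- vl; best <- list(W = W, b = b); wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= config$earlyStopPatience) break
        }
      } else {
        best <- list(W = W, b = b)
      }
    }
    list(weights = best, classLevels = levels(y),
         valTrajectory = valTrajectory, config = config, seed = seed)
  })
}

#' Train a probabilistic classifier
#'
#' Fits one of the four base classifiers behind the uniform probabilistic
#' contract of [predictProba()]:
#' \describe{
#'   \item{mlp}{multilayer perceptron: ReLU hidden layers, softmax output,
#'     multinomial cross-entropy, Adam, inverted dropout during training,
#'     early stopping on a stratified validation split (see [mlpConfig()]).}
#'   \item{random_forest}{500 Gini trees (configurable via
#'     `config$numTrees`); probabilities are per-class vote fractions.}
#'   \item{ovr_svm}{one linear SVM per class (one-vs-rest); probabilities are
#'     the softmax of the per-class decision values, or Platt-scaled
#'     per-class probabilities renormalized when `config$platt = TRUE`.}
#'   \item{knn}{k-nearest neighbours (`config$k`, default 5); probabilities
#'     are neighbour vote fractions.}
#' }
#'
#' @param kind classifier kind.
#' @param X samples-by-features training matrix.
#' @param y class labels (>= 2 classes represented).
#' @param config kind-specific configuration: an [mlpConfig()] for "mlp", a
#'   list for the others.
#' @param seed RNG seed (training is reproducible given the seed).
#' @return a fitted [ProbabilisticClassifier-class].
#' @importFrom e1071 svm
#' @importFrom caret knn3
#' @export
trainClassifier <- function(kind = c("mlp", "random_forest", "ovr_svm",
                                     "knn"),
                            X, y, config = NULL, seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes represented in y")
  fit <- switch(kind,
    mlp = {
      cfg <- if (is.null(config)) mlpConfig() else config
      .trainMlp(X, y, cfg, seed)
    },
    random_forest = {
      nt <- if (!is.null(config$numTrees)) config$numTrees else 500
      Xn <- X; colnames(Xn) <- paste0("x", seq_len(ncol(X)))
      list(model = ranger::ranger(x = Xn, y = y, num.trees = nt,
                                  probability = TRUE, seed = seed,
                                  num.threads = 1),
           classLevels = levels(y))
    },
    ovr_svm = {
      cost <- if (!is.null(config$cost)) config$cost else 1
      platt <- isTRUE(config$platt)
      models <- lapply(levels(y), function(cl) {
        yb <- factor(ifelse(y == cl, "pos", "neg"),
                     levels = c("pos", "neg"))
        withr::with_seed(seed,
          e1071::svm(X, yb, kernel = "linear", cost = cost, scale = FALSE,
                     probability = platt))
      })
      list(models = models, classLevels = levels(y), platt = platt)
    },
    knn = {
      kk <- if (!is.null(config$k)) config$k else 5
      list(model = caret::knn3(X, y, k = kk), classLevels = levels(y))
    })
  new("ProbabilisticClassifier", kind = kind, classLevels = levels(y),
      nFeatures = ncol(X), fit = fit)
}

#' Per-class probability predictions
#'
#' Returns an m x k matrix of class probabilities: non-negative rows summing
#' to 1 (within 1e-6), columns in the class order fixed at fit time.
#' Inference is deterministic. An empty input yields a 0-row matrix with k
#' columns; a feature-dimension mismatch is an error.
#'
#' @param object a fitted [ProbabilisticClassifier-class] or
#'   [EnsembleModel-class].
#' @param X samples-by-features matrix.
#' @return m x k probability matrix with class-level column names.
#' @export
setMethod("predictProba", "ProbabilisticClassifier", function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object@nFeatures)
    stop(sprintf("model was fitted on %d feature(s) but got %d",
                 object@nFeatures, ncol(X)))
  k <- length(object@classLevels)
  if (nrow(X) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = k,
                  dimnames = list(NULL, object@classLevels)))
  P <- switch(object@kind,
    mlp = .softmax(.mlpForward(object@fit$weights, X)$scores),
    random_forest = {
      Xn <- X; colnames(Xn) <- paste0("x", seq_len(ncol(X)))
      pr <- stats::predict(object@fit$model, data = Xn)$predictions
      pr[, object@classLevels, drop = FALSE]
    },
    ovr_svm = {
      if (object@fit$platt) {
        S <- matrix(vapply(object@fit$models, function(m) {
          p <- stats::predict(m, X, probability = TRUE)
          attr(p, "probabilities")[, "pos"]
        }, numeric(nrow(X))), nrow = nrow(X))
        S / rowSums(S)
      } else {
        S <- vapply(object@fit$models, function(m) {
          dv <- attr(stats::predict(m, X, decision.values = TRUE),
                     "decision.values")
          ## orient so that larger means "pos"
          if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
        }, numeric(nrow(X)))
        .softmax(matrix(S, nrow = nrow(X)))
      }
    },
    knn = {
      pr <- stats::predict(object@fit$model, X, type = "prob")
      pr[, object@classLevels, drop = FALSE]
    })
  P <- matrix(pmax(P, 0), nrow = nrow(X),
              dimnames = list(rownames(X), object@classLevels))
  P / rowSums(P)
})

#' @rdname predictProba-ProbabilisticClassifier-method
#' @export
setMethod("predictProba", "EnsembleModel", function(object, X) {
  (predictProba(object@memberA, X) + predictProba(object@memberB, X)) / 2
})

#' Train the two-member soft-voting ensemble
#'
#' Trains the default ensemble members — a multilayer perceptron and a random
#' forest — on the same feature set and wraps them in an
#' [EnsembleModel-class].
#'
#' @param X samples-by-features training matrix.
#' @param y class labels.
#' @param mlpCfg an [mlpConfig()] for the perceptron member.
#' @param rfTrees random-forest tree count; default 500.
#' @param seed RNG seed shared by the members.
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(X, y, mlpCfg = mlpConfig(), rfTrees = 500,
                          seed = 1) {
  a <- trainClassifier("mlp", X, y, config = mlpCfg, seed = seed)
  b <- trainClassifier("random_forest", X, y,
                       config = list(numTrees = rfTrees), seed = seed)
  new("EnsembleModel", memberA = a, memberB = b)
}

#' Soft-voting combination of two probability matrices
#'
#' Averages the members' per-class probability rows and predicts the argmax;
#' ties resolve to the lowest class index. The inputs must have identical
#' shape and class-column order.
#'
#' @param probsA,probsB m x k probability matrices with matching class
#'   columns.
#' @return list with `labels` (length-m character) and `probs` (m x k
#'   averaged matrix).
#' @examples
#' a <- matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("x", "y")))
#' b <- matrix(c(0.2, 0.8), 1, dimnames = list(NULL, c("x", "y")))
#' ensemblePredict(a, b)$labels  # "y"
#' @export
ensemblePredict <- function(probsA, probsB) {
  if (!identical(dim(probsA), dim(probsB)))
    stop("probability matrices must have identical shapes")
  if (!identical(colnames(probsA), colnames(probsB)))
    stop("probability matrices must share the class-column order")
  probs <- (probsA + probsB) / 2
  labels <- if (nrow(probs) == 0) character(0) else
    colnames(probs)[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs)
}
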