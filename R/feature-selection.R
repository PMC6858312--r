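#' @include AllClasses.R AllGenerics.R
NULL

#' Create a supervised feature-selection problem
#'
#' Couples a samples-by-features matrix with class labels and learns the
#' per-feature standardization statistics (population mean and standard
#' deviation) from these rows. The statistics are frozen in the object so
#' held-out rows can be transformed with the training statistics only.
#'
#' @param X numeric samples-by-features matrix (a [FeatureMatrix-class] is
#'   also accepted).
#' @param y class labels (factor, character, or a named factor whose names
#'   match the rows).
#' @return a [SelectionProblem-class].
#' @export
makeSelectionProblem <- function(X, y) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))  # population sd
  scale[scale == 0] <- 1
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  new("SelectionProblem", X = X, y = y, center = center, scale = scale,
      sampleIds = ids)
}

#' Standardize rows with a problem's training statistics
#'
#' @param problem a [SelectionProblem-class].
#' @param X matrix to transform; default the problem's own rows.
#' @return standardized matrix.
#' @export
standardizedValues <- function(problem, X = problem@X) {
  if (ncol(X) != ncol(problem@X))
    stop("feature dimension mismatch")
  sweep(sweep(X, 2, problem@center), 2, problem@scale, "/")
}

## Rank scores descending, ties broken by lower feature index.
.topK <- function(scores, k) {
  order(-scores, seq_along(scores))[seq_len(k)]
}

.checkProblem <- function(problem) {
  if (nlevels(droplevels(problem@y)) < 2)
    stop("feature selection needs at least 2 classes")
}

#' Extra-trees feature selection
#'
#' Fits an extremely randomized trees classifier on the raw feature values
#' and ranks features by mean impurity-decrease importance; the top
#' `kFeatures` are selected (ties broken by lower feature index).
#'
#' @param problem a [SelectionProblem-class].
#' @param kFeatures number of features to keep, in `[1, d]`.
#' @param nTrees number of trees; default 500.
#' @param seed RNG seed for the forest.
#' @return a [SelectionResult-class].
#' @importFrom ranger ranger
#' @export
extraTreesSelect <- function(problem, kFeatures, nTrees = 500, seed = 1) {
  .checkProblem(problem)
  d <- ncol(problem@X)
  if (kFeatures < 1 || kFeatures > d)
    stop("kFeatures must be between 1 and ", d)
  X <- problem@X
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(d))
  colnames(X) <- paste0("x", seq_len(d))  # guard against exotic symbols
  fit <- ranger::ranger(x = X, y = problem@y, num.trees = nTrees,
                        splitrule = "extratrees", num.random.splits = 1,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  scores <- unname(fit$variable.importance)
  new("SelectionResult", method = "extra_trees",
      selected = sort(as.integer(.topK(scores, kFeatures))),
      scores = scores, regularizationUsed = NA_real_,
      coefficients = NULL, intercepts = numeric(0), featureNames = cn,
      path = data.frame(regularization = numeric(0),
                        n_selected = integer(0)))
}

#' LASSO feature selection
#'
#' Encodes the class labels as one signed indicator target per class (+1 for
#' members, -1 otherwise) and solves one L1-penalized least-squares
#' regression per target column on the standardized features; a feature is
#' selected when it carries a nonzero coefficient for any class, and its
#' score is the maximum absolute coefficient across classes. The objective
#' per class is `(1/(2n)) * sum((y - b - Xw)^2) + alpha * ||w||_1` (the
#' glmnet convention; an L1 weight stated for the `(1/n)` sum-of-squares
#' convention corresponds to `alpha/2` here).
#'
#' @param problem a [SelectionProblem-class].
#' @param alpha non-negative L1 weight; `alpha = 0` gives ordinary least
#'   squares (requires `d < n`).
#' @param maxIter,tol solver budget and convergence threshold.
#' @return a [SelectionResult-class] with the classes-by-features coefficient
#'   matrix in `@coefficients`.
#' @importFrom glmnet glmnet
#' @export
lassoSelect <- function(problem, alpha, maxIter = 1e5, tol = 1e-7) {
  .checkProblem(problem)
  if (alpha < 0) stop("alpha must be non-negative")
  Xs <- standardizedValues(problem)
  y <- problem@y
  k <- nlevels(y)
  d <- ncol(Xs)
  n <- nrow(Xs)
  Y <- 2 * outer(y, levels(y), "==") - 1  # signed one-vs-rest targets
  W <- matrix(0, nrow = k, ncol = d, dimnames = list(levels(y), NULL))
  b <- numeric(k)
  if (alpha == 0) {
    if (d >= n) stop("alpha = 0 requires fewer features than samples")
    for (c in seq_len(k)) {
      fit <- stats::lm.fit(cbind(1, Xs), Y[, c])
      b[c] <- fit$coefficients[1]
      W[c, ] <- fit$coefficients[-1]
    }
  } else if (d == 1) {
    ## univariate closed form: soft-threshold of the population covariance
    v <- mean(Xs[, 1]^2)
    for (c in seq_len(k)) {
      cv <- mean(Xs[, 1] * (Y[, c] - mean(Y[, c])))
      W[c, 1] <- sign(cv) * max(0, abs(cv) - alpha) / v
      b[c] <- mean(Y[, c])
    }
  } else {
    for (c in seq_len(k)) {
      fit <- glmnet::glmnet(Xs, Y[, c], family = "gaussian", alpha = 1,
                            lambda = alpha, standardize = FALSE,
                            intercept = TRUE, maxit = maxIter, thresh = tol)
      cf <- as.numeric(stats::coef(fit))
      b[c] <- cf[1]
      W[c, ] <- cf[-1]
    }
  }
  W[abs(W) < 1e-10] <- 0
  scores <- apply(abs(W), 2, max)
  cn <- colnames(problem@X)
  if (is.null(cn)) cn <- paste0("f", seq_len(d))
  new("SelectionResult", method = "lasso",
      selected = unname(which(scores > 0)), scores = unname(scores),
      regularizationUsed = alpha, coefficients = W, intercepts = b,
      featureNames = cn,
      path = data.frame(regularization = numeric(0),
                        n_selected = integer(0)))
}

## ---------------------------------------------------------------------------
## L1-penalized multiclass squared-hinge linear classifier (LSVC)
## ---------------------------------------------------------------------------

## Margin-violation loss: for sample i with true class y_i,
## sum over c != y_i of max(0, 1 + f_c(x_i) - f_{y_i}(x_i))^2,
## averaged over samples. F is the n x k decision-value matrix.
.sqHingeLoss <- function(F, yIdx) {
  n <- nrow(F)
  fy <- F[cbind(seq_len(n), yIdx)]
  R <- pmax(1 + F - fy, 0)
  R[cbind(seq_len(n), yIdx)] <- 0
  sum(R^2) / n
}

## Gradient of the mean loss with respect to F (n x k).
.sqHingeGradF <- function(F, yIdx) {
  n <- nrow(F)
  fy <- F[cbind(seq_len(n), yIdx)]
  R <- pmax(1 + F - fy, 0)
  R[cbind(seq_len(n), yIdx)] <- 0
  G <- 2 * R / n
  G[cbind(seq_len(n), yIdx)] <- -rowSums(G)
  G
}

#' Multiclass squared-hinge objective with L1 penalty
#'
#' Evaluates the selection objective: the mean margin-violation loss
#' `sum_{c != y_i} max(0, 1 + f_c(x_i) - f_{y_i}(x_i))^2` over samples, with
#' per-class linear decision functions `f_c(x) = w_c' x + b_c` on the
#' standardized features, plus the L1 term `(1/penalty) * sum_c ||w_c||_1`.
#' The L1-budget constraint form (`sum_c ||w_c||_1 <= eps`) is implemented in
#' this equivalent penalized form; larger `penalty` means weaker
#' regularization (a larger budget). Pure function; used directly by the
#' solver's tests.
#'
#' @param weights k x d coefficient matrix (one row per class).
#' @param intercepts length-k intercepts.
#' @param problem a [SelectionProblem-class].
#' @param penalty positive inverse regularization strength.
#' @return the objective value (a single number).
#' @export
lsvcObjective <- function(weights, intercepts, problem, penalty) {
  k <- nlevels(problem@y)
  d <- ncol(problem@X)
  if (!is.matrix(weights) || nrow(weights) != k || ncol(weights) != d)
    stop(sprintf("weights must be a %d x %d matrix", k, d))
  if (length(intercepts) != k)
    stop("intercepts must have one entry per class")
  if (penalty <= 0) stop("penalty must be positive")
  Xs <- standardizedValues(problem)
  F <- Xs %*% t(weights) + rep(1, nrow(Xs)) %o% intercepts
  .sqHingeLoss(F, as.integer(problem@y)) + sum(abs(weights)) / penalty
}

#' L1 squared-hinge linear classifier (LSVC) feature selection
#'
#' Minimizes the multiclass squared-hinge loss of [lsvcObjective()] with an
#' L1 penalty `(1/penalty) * sum_c ||w_c||_1` over per-class linear decision
#' functions, by accelerated proximal gradient descent (FISTA with adaptive
#' restart; the smooth part is differentiable, the L1 part is handled by
#' soft-thresholding, so exact zeros are produced). Features with a nonzero
#' coefficient in any class are selected; scores are the maximum absolute
#' coefficient across classes. Intercepts are not penalized. Runs on the
#' standardized features.
#'
#' @param problem a [SelectionProblem-class].
#' @param penalty positive inverse regularization strength C (small C kills
#'   all weights; large C keeps many features).
#' @param maxIter maximum FISTA iterations; default 300.
#' @param tol relative objective-change convergence threshold.
#' @param warmStart optional list(weights, intercepts) to initialize from.
#' @return a [SelectionResult-class].
#' @export
lsvcSelect <- function(problem, penalty, maxIter = 250, tol = 1e-6,
                       warmStart = NULL) {
  .checkProblem(problem)
  if (penalty <= 0) stop("penalty must be positive")
  Xs <- standardizedValues(problem)
  n <- nrow(Xs); d <- ncol(Xs)
  y <- as.integer(problem@y)
  k <- nlevels(problem@y)
  lambda <- 1 / penalty

  ## Lipschitz bound of the smooth part: (2k/n) * sigma_max([Xs, 1])^2
  smax2 <- .powerIterSigma2(cbind(Xs, 1))
  L <- 2 * k * smax2 / n

  W <- matrix(0, k, d); b <- numeric(k)
  if (!is.null(warmStart)) {
    W <- warmStart$weights; b <- warmStart$intercepts
  }
  Vw <- W; Vb <- b
  t <- 1
  for (it in seq_len(maxIter)) {
    F <- Xs %*% t(Vw) + rep(1, n) %o% Vb
    G <- .sqHingeGradF(F, y)
    gradW <- crossprod(G, Xs)
    gradB <- colSums(G)
    Wn <- Vw - gradW / L
    Wn <- sign(Wn) * pmax(abs(Wn) - lambda / L, 0)  # prox: soft-threshold
    bn <- Vb - gradB / L
    ## gradient-based adaptive restart
    if (sum((Vw - Wn) * (Wn - W)) + sum((Vb - bn) * (bn - b)) > 0) {
      t <- 1
      Vw <- Wn; Vb <- bn
    } else {
      tn <- (1 + sqrt(1 + 4 * t^2)) / 2
      Vw <- Wn + ((t - 1) / tn) * (Wn - W)
      Vb <- bn + ((t - 1) / tn) * (bn - b)
      t <- tn
    }
    W <- Wn; b <- bn
    ## windowed convergence check on the true objective
    if (it %% 25 == 0) {
      Fw <- Xs %*% t(W) + rep(1, n) %o% b
      objNow <- .sqHingeLoss(Fw, y) + lambda * sum(abs(W))
      if (exists("objWin", inherits = FALSE) &&
          abs(objWin - objNow) < tol * max(1e-12, abs(objWin))) break
      objWin <- objNow
    }
  }
  W[abs(W) < 1e-10] <- 0
  scores <- apply(abs(W), 2, max)
  cn <- colnames(problem@X)
  if (is.null(cn)) cn <- paste0("f", seq_len(d))
  dimnames(W) <- list(levels(problem@y), NULL)
  new("SelectionResult", method = "lsvc",
      selected = unname(which(scores > 0)), scores = unname(scores),
      regularizationUsed = penalty, coefficients = W, intercepts = b,
      featureNames = cn,
      path = data.frame(regularization = numeric(0),
                        n_selected = integer(0)))
}

## Squared largest singular value by power iteration on t(A) %*% A.
.powerIterSigma2 <- function(A, iters = 50, tol = 1e-8) {
  v <- rep(1 / sqrt(ncol(A)), ncol(A))
  s2 <- 0
  for (i in seq_len(iters)) {
    u <- crossprod(A, A %*% v)
    s2new <- sqrt(sum(u^2))
    if (s2new == 0) return(0)
    v <- u / s2new
    if (abs(s2new - s2) < tol * s2new) { s2 <- s2new; break }
    s2 <- s2new
  }
  s2
}

#' Select a target number of features with any method
#'
#' `extra_trees` takes the exact top-k by importance. For the L1 methods the
#' regularization value that yields about `kFeatures` nonzero features is
#' found by bisection on the log of the regularization strength, bracketed at
#' `[1e-4, 1e4]` in the solver's parameterization, until the selected count
#' falls in `[k(1-tol), k(1+tol)]` or 40 probes are spent; if the window is
#' never hit, the probe with the smallest count >= k (or failing that the
#' largest count) is truncated to exactly `kFeatures` by score rank (ties to
#' the lower index). The probes are recorded in the result's `@path` and the
#' regularization actually used in `@regularizationUsed`. LSVC probes are
#' warm-started from the previous solution.
#'
#' @param method "extra_trees", "lasso" or "lsvc".
#' @param problem a [SelectionProblem-class].
#' @param kFeatures target number of features, in `[1, d]`.
#' @param toleranceFrac acceptable relative deviation from `kFeatures`
#'   (default 0.05); 0 forces exact truncation to `kFeatures`.
#' @param seed seed for the tree-based method.
#' @param ... passed to the underlying selector (e.g. `nTrees`, `maxIter`).
#' @return a [SelectionResult-class].
#' @export
selectK <- function(method = c("lsvc", "lasso", "extra_trees"), problem,
                    kFeatures, toleranceFrac = 0.05, seed = 1, ...) {
  method <- match.arg(method)
  d <- ncol(problem@X)
  if (kFeatures < 1 || kFeatures > d)
    stop("kFeatures must be between 1 and ", d)
  if (method == "extra_trees")
    return(extraTreesSelect(problem, kFeatures, seed = seed, ...))

  ## Unified knob: larger `reg` -> fewer features.
  ## lasso: reg = alpha; lsvc: reg = 1/penalty = lambda.
  run <- local({
    seen <- list()  # per-probe solutions, for nearest-reg warm starts
    function(reg) {
      if (method == "lasso") {
        lassoSelect(problem, alpha = reg, ...)
      } else {
        warm <- NULL
        if (length(seen) > 0) {
          regs <- vapply(seen, `[[`, numeric(1), "reg")
          warm <- seen[[which.min(abs(log(regs) - log(reg)))]]$sol
        }
        res <- lsvcSelect(problem, penalty = 1 / reg, warmStart = warm, ...)
        seen[[length(seen) + 1]] <<-
          list(reg = reg, sol = list(weights = res@coefficients,
                                     intercepts = res@intercepts))
        res
      }
    }
  })
  lo <- 1e-4; hi <- 1e4
  kLo <- kFeatures * (1 - toleranceFrac)
  kHi <- kFeatures * (1 + toleranceFrac)
  path <- data.frame(regularization = numeric(0), n_selected = integer(0))
  best <- NULL; bestCount <- NA_integer_
  probe <- function(reg) {
    res <- run(reg)
    cnt <- length(res@selected)
    path <<- rbind(path, data.frame(regularization = reg, n_selected = cnt))
    cnt0 <- if (is.na(bestCount)) -1L else bestCount
    ## prefer the smallest count >= k; else the largest count seen
    better <- if (cnt >= kFeatures)
      (cnt0 < kFeatures || cnt < cnt0) else (cnt0 < kFeatures && cnt > cnt0)
    if (better) { best <<- res; bestCount <<- cnt }
    res
  }
  resLo <- probe(hi)   # strongest regularization -> fewest features
  resHi <- probe(lo)   # weakest -> most features
  chosen <- NULL
  for (res in list(resLo, resHi)) {
    cnt <- length(res@selected)
    if (cnt >= kLo && cnt <= kHi) { chosen <- res; break }
  }
  if (is.null(chosen)) {
    a <- log(lo); bnd <- log(hi)
    for (i in seq_len(38)) {
      if (bnd - a < 0.01) break  # bracket collapsed on a count plateau
      mid <- (a + bnd) / 2
      res <- probe(exp(mid))
      cnt <- length(res@selected)
      if (cnt >= kLo && cnt <= kHi) { chosen <- res; break }
      if (cnt > kFeatures) a <- mid else bnd <- mid
    }
  }
  if (is.null(chosen)) {
    chosen <- best
    if (is.null(chosen) || length(chosen@selected) == 0)
      stop("bisection could not reach ", kFeatures, " features")
  }
  if (length(chosen@selected) > kHi || toleranceFrac == 0) {
    ## truncate the nonzero features to exactly k by |score| rank
    nz <- chosen@selected
    kk <- min(kFeatures, length(nz))
    keep <- nz[.topK(chosen@scores[nz], kk)]
    chosen@selected <- sort(as.integer(keep))
  }
  chosen@path <- path
  chosen
}
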