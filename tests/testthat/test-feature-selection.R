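## Small labeled problem: first `nInf` features carry the class signal.
makeToyProblem <- function(n = 60, d = 20, nInf = 3, seed = 1, sd = 0.3) {
  stopifnot(nInf <= d)
  withr::with_seed(seed, {
    y <- factor(rep(c("a", "b"), length.out = n))
    sgn <- ifelse(y == "a", 1, -1)
    X <- matrix(rnorm(n * d, sd = 1), n, d)
    for (j in seq_len(nInf)) X[, j] <- sgn + rnorm(n, sd = sd)
    colnames(X) <- paste0("f", seq_len(d))
    rownames(X) <- paste0("S", seq_len(n))
    makeSelectionProblem(X, y)
  })
}

test_that("standardization statistics come from training rows only", {
  pb <- makeToyProblem()
  Xs <- standardizedValues(pb)
  expect_lt(max(abs(colMeans(Xs))), 1e-12)
  expect_lt(max(abs(colMeans(Xs^2) - 1)), 1e-9)  # population scaling
  ## held-out rows reuse the training statistics unchanged
  held <- matrix(rnorm(5 * ncol(pb@X)), 5)
  manual <- sweep(sweep(held, 2, pb@center), 2, pb@scale, "/")
  expect_equal(standardizedValues(pb, held), manual)
  ## constant feature gets scale 1, not 0
  X <- cbind(pb@X, const = 5)
  pb2 <- makeSelectionProblem(X, pb@y)
  expect_equal(unname(pb2@scale[ncol(X)]), 1)
})

test_that("extra-trees selection ranks a class-determining feature on top", {
  ## one feature fully determines the labels among 50 noise features
  for (seed in 1:10) {
    pb <- withr::with_seed(seed, {
      y <- factor(rep(c("a", "b", "c"), each = 20))
      X <- cbind(det = as.integer(y), matrix(rnorm(60 * 50), 60))
      colnames(X) <- c("det", paste0("n", 1:50))
      makeSelectionProblem(X, y)
    })
    res <- extraTreesSelect(pb, kFeatures = 5, nTrees = 100, seed = seed)
    expect_true(1L %in% selectedFeatures(res))
  }
  pb <- makeToyProblem()
  expect_equal(selectedFeatures(extraTreesSelect(pb, ncol(pb@X))),
               seq_len(ncol(pb@X)))
  expect_error(extraTreesSelect(pb, 0), "between")
})

test_that("LASSO selection follows the soft-threshold closed form", {
  ## very strong regularization empties the support
  pb <- makeToyProblem()
  expect_length(selectedFeatures(lassoSelect(pb, alpha = 1e6)), 0L)
  expect_error(lassoSelect(pb, alpha = -1), "non-negative")

  ## univariate case: coefficient = soft-threshold(1, alpha) on x = (1, -1)
  pb1 <- makeSelectionProblem(matrix(c(1, -1), 2, 1), factor(c("a", "b")))
  res <- lassoSelect(pb1, alpha = 0.5)
  expect_equal(max(abs(res@coefficients)), 0.5, tolerance = 1e-8)
  expect_equal(selectedFeatures(res), 1L)
  ## threshold at/above the covariance kills the coefficient
  expect_length(selectedFeatures(lassoSelect(pb1, alpha = 1.0)), 0L)

  ## alpha = 0 reduces to ordinary least squares supports
  pb2 <- makeToyProblem(n = 50, d = 6)
  res0 <- lassoSelect(pb2, alpha = 0)
  Xs <- standardizedValues(pb2)
  ols <- sapply(levels(pb2@y), function(cl)
    stats::lm.fit(cbind(1, Xs), as.numeric(pb2@y == cl))$coefficients[-1])
  expect_equal(selectedFeatures(res0),
               unname(which(apply(abs(ols) > 1e-10, 1, any))))
})

test_that("squared-hinge objective matches hand-computed margin losses", {
  ## d = 1, two samples x = (1, -1); weights chosen to realize the margins
  pb <- makeSelectionProblem(matrix(c(1, -1), 2, 1), factor(c("a", "b")))
  ## f_y = 2, f_other = 0 for both samples -> zero loss
  W <- matrix(c(2, 0), 2, 1)
  expect_equal(lsvcObjective(W, c(0, 0), pb, penalty = 1e12), 0,
               tolerance = 1e-9)
  ## all decision values zero -> each competing class contributes 1
  W0 <- matrix(0, 2, 1)
  expect_equal(lsvcObjective(W0, c(0, 0), pb, penalty = 1), 1)
  ## k = 3, all f = 0 -> two competing classes, loss 2
  pb3 <- makeSelectionProblem(matrix(rnorm(6), 3, 2),
                              factor(c("a", "b", "c")))
  expect_equal(lsvcObjective(matrix(0, 3, 2), c(0, 0, 0), pb3, penalty = 1),
               2)
  expect_error(lsvcObjective(matrix(0, 2, 2), c(0, 0, 0), pb3, penalty = 1),
               "3 x 2")
  expect_error(lsvcObjective(matrix(0, 3, 2), c(0, 0, 0), pb3, penalty = 0),
               "positive")
})

test_that("LSVC selection empties under infinite regularization and skips
           constant features", {
  pb <- makeToyProblem()
  expect_length(selectedFeatures(lsvcSelect(pb, penalty = 1e-8)), 0L)
  expect_error(lsvcSelect(pb, penalty = 0), "positive")
  ## a constant feature provides no gradient signal and is never selected
  y2 <- factor(rep(c("a", "b"), each = 20))
  X <- cbind(sep = ifelse(y2 == "a", 2, -2), const = 0)
  pb2 <- makeSelectionProblem(X, y2)
  res <- lsvcSelect(pb2, penalty = 10)
  expect_false(2L %in% selectedFeatures(res))
  expect_true(1L %in% selectedFeatures(res))
})

test_that("fitted LSVC solution beats the zero solution and random draws", {
  pb <- makeToyProblem(n = 20, d = 5, nInf = 2, seed = 3)
  res <- lsvcSelect(pb, penalty = 5)
  objFit <- lsvcObjective(res@coefficients, res@intercepts, pb, penalty = 5)
  expect_lte(objFit,
             lsvcObjective(matrix(0, 2, 5), c(0, 0), pb, penalty = 5))
  withr::with_seed(1, for (i in 1:100) {
    W <- matrix(rnorm(10, sd = 0.5), 2, 5)
    expect_lte(objFit, lsvcObjective(W, rnorm(2, sd = 0.5), pb, penalty = 5))
  })
})

test_that("LSVC support matches a brute-force lattice oracle", {
  ## n = 20, d = 5, k = 2; symmetric classes so the optimal intercept is ~0.
  pb <- withr::with_seed(7, {
    y <- factor(rep(c("a", "b"), each = 10))
    sgn <- ifelse(y == "a", 1, -1)
    X <- cbind(sgn + rnorm(20, sd = 0.1), matrix(rnorm(20 * 4), 20))
    colnames(X) <- paste0("f", 1:5)
    makeSelectionProblem(X, y)
  })
  penalty <- 2
  fit <- lsvcSelect(pb, penalty = penalty, maxIter = 2000, tol = 1e-10)

  ## independent oracle: exhaustive search over the weight lattice
  ## {-1, -0.5, 0, 0.5, 1}^d per class, zero intercepts
  lattice <- c(-1, -0.5, 0, 0.5, 1)
  grid <- as.matrix(expand.grid(rep(list(lattice), 5)))
  Xs <- standardizedValues(pb)
  Fa <- Xs %*% t(grid)   # n x nGrid decision values per candidate row
  isA <- pb@y == "a"
  best <- list(obj = Inf, support = integer(0))
  l1 <- rowSums(abs(grid))
  for (j in seq_len(nrow(grid))) {
    ## margins for every candidate w_a = grid[i,], w_b = grid[j,]
    ra <- pmax(1 + Fa[, j] - Fa, 0)   # violation of class-a samples
    rb <- pmax(1 + Fa - Fa[, j], 0)   # violation of class-b samples
    loss <- (colSums(ra[isA, , drop = FALSE]^2) +
               colSums(rb[!isA, , drop = FALSE]^2)) / nrow(Xs)
    obj <- loss + (l1 + l1[j]) / penalty
    i <- which.min(obj)
    if (obj[i] < best$obj) {
      best$obj <- obj[i]
      best$support <- unname(which(abs(grid[i, ]) > 0 | abs(grid[j, ]) > 0))
    }
  }
  expect_equal(selectedFeatures(fit), best$support)
  ## and the continuous fit is at least as good as the lattice optimum
  expect_lte(lsvcObjective(fit@coefficients, fit@intercepts, pb, penalty),
             best$obj + 1e-8)
})

test_that("select-to-k hits the requested support size", {
  pb <- makeToyProblem(n = 80, d = 40, nInf = 5)
  ## extra-trees: exact top-k
  expect_length(selectedFeatures(selectK("extra_trees", pb, 7)), 7L)
  expect_length(selectedFeatures(selectK("extra_trees", pb, 40)), 40L)
  ## zero tolerance forces exact truncation
  res0 <- selectK("lsvc", pb, 10, toleranceFrac = 0)
  expect_length(selectedFeatures(res0), 10L)
  ## default tolerance lands within +/-5%
  res <- selectK("lsvc", pb, 20)
  expect_gte(length(selectedFeatures(res)), 19L)
  expect_lte(length(selectedFeatures(res)), 21L)
  expect_false(is.na(res@regularizationUsed))
  resL <- selectK("lasso", pb, 20)
  expect_gte(length(selectedFeatures(resL)), 19L)
  expect_lte(length(selectedFeatures(resL)), 21L)
  expect_error(selectK("lsvc", pb, 0), "between")
  expect_error(selectK("pca", pb, 5))
})

test_that("support size is monotone along the recorded regularization path", {
  ## label noise keeps the loss curved at weak regularization, so the
  ## support path is well defined across the whole bracket
  pb <- withr::with_seed(5, {
    y <- factor(rep(c("a", "b"), length.out = 80))
    sgn <- ifelse(y == "a", 1, -1) * sample(c(1, -1), 80, TRUE,
                                            prob = c(0.85, 0.15))
    X <- matrix(rnorm(80 * 40), 80, 40)
    for (j in 1:5) X[, j] <- sgn + rnorm(80, sd = 0.5)
    colnames(X) <- paste0("f", 1:40)
    makeSelectionProblem(X, y)
  })
  for (m in c("lasso", "lsvc")) {
    res <- selectK(m, pb, 20, maxIter = 3000, tol = 1e-9)
    path <- res@path[order(res@path$regularization), ]
    expect_gte(nrow(path), 2L)
    ## counts non-increasing as regularization strengthens
    expect_true(all(diff(path$n_selected) <= 0))
  }
})
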