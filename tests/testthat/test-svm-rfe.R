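test_that("linear SVM satisfies the dual identities and orients its decision", {
  # symmetric separable pair: sign(D(x)) = sign(x), b = 0
  m <- trainLinearSVM(matrix(c(-1, 1), ncol = 1), c(-1, 1), C = 100)
  expect_equal(m@b, 0, tolerance = 1e-6)
  expect_gt(predict(m, matrix(0.5)), 0)
  expect_lt(predict(m, matrix(-0.5)), 0)

  # KKT identities on random fits: sum(alpha y) = 0, w = sum(alpha y x),
  # 0 <= alpha <= C
  set.seed(4)
  for (i in 1:5) {
    n <- 30
    X <- matrix(rnorm(n * 3), n, 3)
    y <- ifelse(X[, 1] + rnorm(n, sd = 0.5) > 0, 1, -1)
    if (length(unique(y)) < 2) next
    fit <- trainLinearSVM(X, y, C = 1)
    expect_lt(abs(sum(fit@alphas * y)), 1e-6)
    expect_lt(max(abs(fit@w - colSums(fit@alphas * y * X))), 1e-6)
    expect_true(all(fit@alphas >= -1e-9 & fit@alphas <= 1 + 1e-9))
  }
  expect_error(trainLinearSVM(matrix(rnorm(10), 5), rep(1, 5), C = 1),
               "two classes")
})

test_that("linear SVM agrees with an independent convex-QP solve of the dual", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  n <- 10
  X <- cbind(rnorm(n) + rep(c(-2, 2), each = n / 2), rnorm(n))
  y <- rep(c(-1, 1), each = n / 2)
  C <- 1
  fit <- trainLinearSVM(X, y, C = C)

  Q <- (y %o% y) * (X %*% t(X))
  sol <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 12,
                       maxiter = 400)
  alpha <- kernlab::primal(sol)
  wQP <- colSums(alpha * y * X)
  free <- which(alpha > 1e-5 & alpha < C - 1e-5)
  bQP <- mean(y[free] - X[free, , drop = FALSE] %*% wQP)
  expect_equal(unname(fit@w), unname(wQP), tolerance = 1e-4)
  expect_equal(fit@b, bQP, tolerance = 1e-4)
})

test_that("CV-averaged scores equal the mean of per-fold squared weights", {
  dat <- syntheticFeatureData(n = 60, nNoise = 4, effect = 2, seed = 3)
  scores <- cvAverageScores(dat$X, dat$y, C = 1, nFolds = 10, seed = 5)
  # loop-free recomputation with the same folds but independent fitting
  yf <- factor(dat$y)
  fold <- emotionatlas:::stratifiedFolds(yf, 10, 5)
  W2 <- t(vapply(1:10, function(f) {
    m <- e1071::svm(dat$X[fold != f, ], factor(dat$y[fold != f]),
                    kernel = "linear", cost = 1, scale = FALSE)
    as.numeric(crossprod(m$coefs, m$SV))^2
  }, numeric(ncol(dat$X))))
  expect_equal(unname(scores), unname(colMeans(W2)), tolerance = 1e-8)
  # informative features outrank noise
  expect_true(min(scores[1:2]) > max(scores[-(1:2)]))
})

test_that("RFE bookkeeping conserves counts and records one accuracy per round", {
  dat <- syntheticFeatureData(n = 40, nNoise = 6, effect = 1, seed = 7)
  res <- rfeSelect(dat$X, dat$y, C = 1, seed = 2)
  p <- ncol(dat$X)
  expect_length(accuracyTrajectory(res), p - 1)
  expect_equal(length(eliminationOrder(res)) + length(selectedFeatureIds(res)), p)
  expect_length(res@fullEliminationOrder, p - 1)
  expect_setequal(c(res@fullEliminationOrder,
                    setdiff(colnames(dat$X), res@fullEliminationOrder)),
                  colnames(dat$X))

  # 2-feature minimal case
  res2 <- rfeSelect(dat$X[, 1:2], dat$y, C = 1, seed = 2)
  expect_length(accuracyTrajectory(res2), 1)
  expect_equal(length(eliminationOrder(res2)) + length(selectedFeatureIds(res2)), 2)

  # determinism per seed
  resB <- rfeSelect(dat$X, dat$y, C = 1, seed = 2)
  expect_identical(selectedFeatureIds(res), selectedFeatureIds(resB))
  expect_identical(accuracyTrajectory(res), accuracyTrajectory(resB))

  expect_error(rfeSelect(matrix(1, 10, 3), rep(c(-1, 1), 5)), "degenerate")
  expect_error(rfeSelect(dat$X[, 1, drop = FALSE], dat$y), "2 features")
})

test_that("RFE recovers implanted informative features", {
  hits <- vapply(1:5, function(s) {
    dat <- syntheticFeatureData(n = 126, nNoise = 8, effect = 3, seed = 200 + s)
    res <- rfeSelect(dat$X, dat$y, C = 1, seed = 1)
    all(c("inf1", "inf2") %in% selectedFeatureIds(res))
  }, TRUE)
  expect_true(all(hits))
})

test_that("permuted labels remove the informative features' advantage", {
  # with shuffled labels the implanted features are selected no more often
  # than the selected-subset size implies by chance
  inclusion <- chance <- numeric(8)
  for (s in 1:8) {
    dat <- syntheticFeatureData(n = 60, nNoise = 8, effect = 3, seed = 300 + s)
    set.seed(400 + s)
    yPerm <- sample(dat$y)
    res <- rfeSelect(dat$X, yPerm, C = 1, seed = 1)
    sel <- selectedFeatureIds(res)
    inclusion[s] <- mean(c("inf1", "inf2") %in% sel)
    chance[s] <- length(sel) / ncol(dat$X)
  }
  expect_lt(mean(inclusion), mean(chance) + 0.25)
})
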