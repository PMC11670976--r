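test_that("feature scaling: hand example, idempotence and the constant-column guard", {
  sc <- fitScaler(matrix(c(1, 3), ncol = 1))
  expect_equal(as.vector(applyScaler(sc, matrix(c(1, 3), ncol = 1))),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)   # n-1 denominator
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  Xs <- applyScaler(fitScaler(X), X)
  expect_equal(colMeans(Xs), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(Xs, 2, sd), c(1, 1), tolerance = 1e-12)
  # an already standardized column passes through unchanged
  expect_equal(applyScaler(fitScaler(Xs), Xs), Xs, tolerance = 1e-12)
  # constant column scales to zero with a warning
  Xc <- cbind(X[, 1], 5)
  expect_warning(sc2 <- fitScaler(Xc), "constant")
  expect_true(all(applyScaler(sc2, Xc)[, 2] == 0))
  expect_error(fitScaler(matrix(1, 1, 2)), "at least 2")
})

test_that("ridge logistic fit: analytic limits, separable data, stationarity", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.numeric(runif(n) < plogis(X %*% c(2, -1, 0)))
  # lambda -> infinity: weights -> 0, intercept -> logit of prevalence
  m <- fitPLR(X, y, lambda = 1e6, standardize = FALSE)
  expect_lt(max(abs(m@weights)), 1e-4)
  expect_equal(m@intercept, qlogis(mean(y)), tolerance = 1e-4)
  # 1-D separable data: perfect training accuracy at threshold 0.5
  Xsep <- matrix(c(rnorm(15, -4), rnorm(15, 4)), ncol = 1)
  ysep <- rep(c(0, 1), each = 15)
  msep <- fitPLR(Xsep, ysep, lambda = 0.01)
  expect_equal(mean((predict(msep, Xsep)$prob >= 0.5) == (ysep == 1)), 1)
  # penalized gradient at the optimum vanishes (numerical-gradient oracle)
  lam <- 0.05
  mf <- fitPLR(X, y, lambda = lam, standardize = FALSE)
  expect_lt(mf@gradNorm, 1e-6)
  b <- c(mf@intercept, mf@weights)
  obj <- function(bb) {
    eta <- bb[1] + X %*% bb[-1]
    mean(log(1 + exp(eta)) - y * eta) + lam * sum(bb[-1]^2)
  }
  h <- 1e-6
  ng <- vapply(seq_along(b), function(i) {
    e <- numeric(length(b)); e[i] <- h
    (obj(b + e) - obj(b - e)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(ng^2)), 1e-6)
  expect_error(fitPLR(X, rep(1, n), lambda = 0.1), "both classes")
  expect_error(fitPLR(X, y, lambda = -1), "lambda")
})

test_that("ridge fit agrees with glmnet at matched penalty", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.numeric(runif(n) < plogis(X %*% c(1, -2, 0.5, 0)))
  lam <- 0.02
  m <- fitPLR(X, y, lambda = lam, standardize = FALSE)
  # glmnet solves (1/n) deviance + lambda_g/2 * ||w||^2, so lambda_g = 2 lam
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 2 * lam, standardize = FALSE, thresh = 1e-14)
  expect_equal(c(m@intercept, m@weights),
               c(as.numeric(g$a0), as.numeric(g$beta)), tolerance = 1e-6)
})

test_that("larger lambda never increases the weight norm", {
  set.seed(12)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- as.numeric(runif(80) < plogis(X %*% c(1.5, -1, 0.5, 0, 2)))
  grid <- 10^seq(-4, 2, length.out = 12)
  norms <- vapply(grid, function(l)
    sqrt(sum(fitPLR(X, y, lambda = l, standardize = FALSE)@weights^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("LOOCV tuning: grid size, determinism, separability, manual refit identity", {
  set.seed(9)
  X <- matrix(c(rnorm(12, -4), rnorm(12, 4)), ncol = 1)
  y <- rep(c("correct", "not correct"), each = 12)
  t1 <- tuneLOOCV(X, y, seed = 123)
  t2 <- tuneLOOCV(X, y, seed = 123)
  expect_length(t1@grid, 60L)
  expect_identical(t1@grid, t2@grid)
  expect_identical(t1@selected, t2@selected)
  expect_identical(t1@auc, t2@auc)
  expect_equal(max(t1@auc), 1)   # separable -> perfect LOOCV AUC
  # the winner must be among the AUC-tied candidates, and the selected
  # model must give calibrated labels at the 0.5 threshold
  winners <- t1@grid[t1@auc >= max(t1@auc) - 1e-12]
  expect_true(t1@selected %in% winners)
  expect_equal(unname(predict(t1@model, X)$label), y)
  # the pooled LOOCV AUC equals brute-force per-sample refitting at the
  # selected lambda (identity of procedure)
  lam <- t1@selected
  probs <- vapply(seq_len(nrow(X)), function(i) {
    m <- fitPLR(X[-i, , drop = FALSE], y[-i], lambda = lam)
    predict(m, X[i, , drop = FALSE])$prob
  }, numeric(1))
  expect_equal(bruteAUC(probs, y == "not correct"),
               t1@auc[which(t1@grid == lam)], tolerance = 1e-10)
})

test_that("prediction goes through the stored scaler and validates input", {
  set.seed(3)
  X <- matrix(rnorm(40 * 15, mean = 5, sd = 2), 40, 15)
  y <- as.numeric(runif(40) < 0.5); y[1:2] <- c(0, 1)
  m <- fitPLR(X, y, lambda = 0.1)
  # a point at the training mean scores plogis(intercept)
  p0 <- predict(m, colMeans(X))$prob
  expect_equal(p0, plogis(m@intercept), tolerance = 1e-12)
  # scaling convention is internal: same answer for matrix or vector input
  expect_equal(predict(m, X[3, ])$prob, predict(m, X[3, , drop = FALSE])$prob)
  expect_error(predict(m, rep(0.5, 14)), "15 features")
})

test_that("tuned model recovers a known two-Gaussian separation", {
  # features from two classes with unit-variance Gaussians 2 apart:
  # the Bayes AUC is pnorm(delta / sqrt(2)) ~ 0.921
  set.seed(31)
  n <- 200
  delta <- 2
  ytr <- rep(c(0, 1), each = n / 2)
  Xtr <- matrix(rnorm(n), ncol = 1) + delta * ytr
  tune <- tuneLOOCV(Xtr, ytr, seed = 42)
  yte <- rep(c(0, 1), each = 100)
  Xte <- matrix(rnorm(200), ncol = 1) + delta * yte
  auc <- rocAuc(predict(tune@model, Xte)$prob, yte == 1)$auc
  expect_gte(auc, pnorm(delta / sqrt(2)) - 0.05)
})

test_that("model JSON round trip preserves predictions", {
  set.seed(4)
  X <- matrix(rnorm(30 * 15), 30, 15)
  y <- rep(c("correct", "not correct"), 15)
  m <- fitPLR(X, y, lambda = 6.619512e-4)
  f <- withr::local_tempfile(fileext = ".json")
  writePLRModel(m, f)
  m2 <- readPLRModel(f)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2@lambda, 6.619512e-4)
})
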