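makeXY <- function(n, seed, noise = 0) {
  set.seed(seed)
  x <- matrix(runif(n, 0, 10), ncol = 1, dimnames = list(NULL, "x"))
  list(x = x, y = 2 * x[, 1] + 1 + rnorm(n, 0, noise))
}

test_that("noiseless linear data are recovered exactly", {
  d <- makeXY(200, 1)
  fit <- modelTree(d$x, d$y)
  expect_lt(max(abs(predict(fit, d$x) - d$y)), 1e-6)

  # multivariate, held out: R2 >= 0.999
  set.seed(2)
  X <- matrix(runif(600 * 3), 600, 3)
  y <- 3 * X[, 1] - 2 * X[, 2] + 0.5 * X[, 3] + 5
  fit2 <- modelTree(X[1:400, ], y[1:400])
  pred <- predict(fit2, X[401:600, ])
  r2 <- cor(pred, y[401:600])^2
  expect_gte(r2, 0.999)
})

test_that("degenerate inputs give single-leaf models or errors", {
  # constant response -> a single leaf predicting it
  x <- matrix(runif(100), ncol = 1)
  fit <- modelTree(x, rep(7, 100))
  expect_equal(length(fit@committees), 1L)
  expect_equal(agbUpscale:::countLeaves(fit@committees[[1]]), 1L)
  expect_equal(predict(fit, x), rep(7, 100))

  # constant predictors with varying response: no split possible, no error
  xc <- matrix(1, 50, 2)
  yc <- seq_len(50) / 10
  fitc <- modelTree(xc, yc)
  expect_equal(agbUpscale:::countLeaves(fitc@committees[[1]]), 1L)
  expect_equal(predict(fitc, xc), rep(mean(yc), 50), tolerance = 1e-8)

  expect_error(modelTree(x[1:4, , drop = FALSE], 1:4, minLeafSize = 8),
               "fewer training rows")
  expect_error(modelTree(matrix(c(1, NA), 8, 2), 1:8), "missing")
})

test_that("piecewise structure is learned to near the brute-force oracle", {
  gen <- function(n, seed) {
    set.seed(seed)
    x <- matrix(runif(n, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
    truth <- ifelse(x[, 1] < 0, 5, x[, 1])
    list(x = x, y = truth + rnorm(n, 0, 0.1), truth = truth)
  }
  train <- gen(2000, 10)
  test <- gen(4000, 11)
  fit <- modelTree(train$x, train$y)
  # the break is located to within the training-point spacing; away from
  # it predictions reach the noise floor (points inside the sliver cost
  # the step height for any learner that estimates the break)
  expect_lt(abs(fit@committees[[1]]$threshold), 0.01)
  off <- abs(test$x[, 1]) > 0.01
  rmse <- sqrt(mean((predict(fit, test$x[off, , drop = FALSE]) -
                       test$y[off])^2))
  expect_lte(rmse, 0.15)

  # independent oracle: least squares on each side of the known break
  left <- train$x[, 1] < 0
  lmL <- lm(y ~ x, data.frame(x = train$x[left, 1], y = train$y[left]))
  lmR <- lm(y ~ x, data.frame(x = train$x[!left, 1], y = train$y[!left]))
  oraclePred <- ifelse(test$x[off, 1] < 0,
                       predict(lmL, data.frame(x = test$x[off, 1])),
                       predict(lmR, data.frame(x = test$x[off, 1])))
  oracleRMSE <- sqrt(mean((oraclePred - test$y[off])^2))
  expect_lte(rmse, 1.5 * oracleRMSE)
})

test_that("fits are deterministic and equivariant to response scaling", {
  set.seed(3)
  X <- matrix(runif(400 * 2), 400, 2)
  y <- sin(3 * X[, 1]) * 10 + X[, 2] + rnorm(400, 0, 0.3)
  newX <- matrix(runif(100 * 2), 100, 2)

  f1 <- modelTree(X, y)
  f2 <- modelTree(X, y)
  expect_identical(predict(f1, newX), predict(f2, newX))

  # fit on a*y + b predicts a*yhat + b, smoothing and clamping included
  a <- 2.5; b <- -40
  fs <- modelTree(X, a * y + b)
  expect_equal(predict(fs, newX), a * predict(f1, newX) + b,
               tolerance = 1e-8)
})

test_that("predictions are clamped to the extended training range", {
  d <- makeXY(200, 4, noise = 0.5)
  fit <- modelTree(d$x, d$y)
  far <- matrix(c(-1e4, 1e4), ncol = 1, dimnames = list(NULL, "x"))
  p <- predict(fit, far)
  cap <- 0.1 * diff(range(d$y))
  expect_true(all(p >= min(d$y) - cap - 1e-9))
  expect_true(all(p <= max(d$y) + cap + 1e-9))
})

test_that("prediction validates the predictor columns", {
  d <- makeXY(100, 5)
  fit <- modelTree(d$x, d$y)
  bad <- matrix(1:4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(predict(fit, bad), "columns")
  expect_error(predict(fit, matrix(1:4, ncol = 2)), "expects")
})

test_that("committees average residual-adjusted members deterministically", {
  set.seed(6)
  X <- matrix(runif(300 * 2), 300, 2)
  y <- 20 * X[, 1]^2 + rnorm(300, 0, 0.5)
  f1 <- modelTree(X, y, nCommittees = 1)
  f3 <- modelTree(X, y, nCommittees = 3)
  expect_equal(length(f3@committees), 3L)
  # committees stay close to the data and at least match the single tree
  rmse1 <- sqrt(mean((predict(f1, X) - y)^2))
  rmse3 <- sqrt(mean((predict(f3, X) - y)^2))
  expect_lt(rmse3, 1.5 * rmse1)
})

test_that("JSON serialization reproduces the fitted model", {
  set.seed(7)
  X <- matrix(runif(300 * 2), 300, 2,
              dimnames = list(NULL, c("hv", "ndvi")))
  y <- 100 * X[, 1] + 10 * X[, 2] + rnorm(300, 0, 1)
  fit <- modelTree(X, y)
  back <- modelTreeFromJSON(modelTreeToJSON(fit))
  newX <- matrix(runif(50 * 2), 50, 2,
                 dimnames = list(NULL, c("hv", "ndvi")))
  expect_equal(predict(back, newX), predict(fit, newX), tolerance = 1e-12)
})

test_that("smoothed trees agree with an independent recursive-partition fit", {
  # rpart (independent implementation) as a coarse cross-check on a step
  # function: both learners must place the break near zero
  skip_if_not_installed("rpart")
  set.seed(8)
  x <- matrix(runif(1000, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
  y <- ifelse(x[, 1] < 0, 0, 10) + rnorm(1000, 0, 0.2)
  ours <- modelTree(x, y)
  rp <- rpart::rpart(y ~ x, data.frame(x = x[, 1], y = y))
  grid <- matrix(seq(-0.9, 0.9, by = 0.05), ncol = 1,
                 dimnames = list(NULL, "x"))
  pOurs <- predict(ours, grid)
  pRp <- predict(rp, data.frame(x = grid[, 1]))
  expect_lt(mean(abs(pOurs - pRp)), 0.5)
})
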