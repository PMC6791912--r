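test_that("initialization is seeded and shaped by the architecture", {
  m1 <- initMLP(100, 19, seed = 5)
  m2 <- initMLP(100, 19, seed = 5)
  m3 <- initMLP(100, 19, seed = 6)
  expect_identical(m1@W1, m2@W1)
  expect_false(identical(m1@W1, m3@W1))
  expect_equal(dim(m1@W1), c(19L, 100L))
  expect_length(m1@b1, 19)
  expect_equal(dim(m1@W2), c(2L, 19L))
  expect_length(m1@b2, 2)
  expect_error(initMLP(3, 0), "nHidden")
  expect_error(initMLP(3, 2, hiddenActivation = "relu"), "activation")
  expect_error(initMLP(3, 2, outputActivation = "linear", errorFn = "entropy"),
               "entropy")
})

test_that("forward pass honors activations and emits valid posteriors", {
  m <- initMLP(2, 3, "tanh", "linear", "sse", seed = 1)
  m@W1[] <- 0; m@b1[] <- 0; m@W2[] <- 0; m@b2[] <- 0
  r <- mlpForward(m, c(0.3, -0.8))
  expect_equal(as.numeric(r$outputs), c(0, 0))
  expect_equal(r$posterior, 0.5)

  ms <- initMLP(4, 3, "tanh", "softmax", "entropy", seed = 2)
  X <- matrix(rnorm(40), 10, 4)
  rs <- mlpForward(ms, X)
  expect_equal(rowSums(rs$outputs), rep(1, 10), tolerance = 1e-12)
  expect_true(all(rs$posterior >= 0 & rs$posterior <= 1))

  # 2-2-2 toy net with hand-set weights, tanh hidden / softmax output
  mt <- initMLP(2, 2, "tanh", "softmax", "entropy", seed = 3)
  mt@W1 <- matrix(c(1, -1, 0.5, 2), 2, 2)   # rows = hidden units
  mt@b1 <- c(0.1, -0.2)
  mt@W2 <- matrix(c(1, 0, -1, 1), 2, 2)
  mt@b2 <- c(0.05, -0.05)
  x <- c(0.4, -0.3)
  a1 <- tanh(mt@W1 %*% x + mt@b1)
  z2 <- mt@W2 %*% a1 + mt@b2
  yhand <- exp(z2) / sum(exp(z2))
  expect_equal(as.numeric(mlpForward(mt, x)$outputs), as.numeric(yhand),
               tolerance = 1e-12)
  expect_error(mlpForward(mt, c(1, 2, 3)), "dimension mismatch")
})

test_that("loss values match hand arithmetic for a (0.5, 0.5) output", {
  m <- initMLP(2, 2, "tanh", "softmax", "entropy", seed = 1)
  m@W1[] <- 0; m@b1[] <- 0; m@W2[] <- 0; m@b2[] <- 0  # outputs (0.5, 0.5)
  X <- matrix(c(1, 2), 1, 2)
  expect_equal(mlpLoss(m, X, 1), log(2), tolerance = 1e-12)
  ms <- initMLP(2, 2, "tanh", "softmax", "sse", seed = 1)
  ms@W1[] <- 0; ms@b1[] <- 0; ms@W2[] <- 0; ms@b2[] <- 0
  expect_equal(mlpLoss(ms, X, 1), 0.5, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  combos <- expand.grid(
    hidden = c("tanh", "exponential", "logistic", "linear"),
    output = c("softmax", "logistic", "exponential", "linear", "tanh"),
    error = c("sse", "entropy"), stringsAsFactors = FALSE)
  combos <- combos[!(combos$error == "entropy" &
                     combos$output %in% c("linear", "tanh")), ]
  X <- matrix(rnorm(15), 5, 3)
  y <- c(1, 2, 1, 2, 1)
  for (r in seq_len(nrow(combos))) {
    m <- initMLP(3, 4, combos$hidden[r], combos$output[r], combos$error[r],
                 seed = 7)
    m@xMean <- colMeans(X); m@xSd <- apply(X, 2, sd)
    Xs <- chloroMS:::.standardize(m, X)
    Tm <- chloroMS:::.oneHot(y)
    th <- chloroMS:::.flatten(m)
    g <- chloroMS:::.mlpLossGrad(m, th, Xs, Tm)$grad
    fd <- vapply(seq_along(th), function(j) {
      e <- th; e[j] <- th[j] + 1e-6
      f1 <- chloroMS:::.mlpLossGrad(m, e, Xs, Tm)$loss
      e[j] <- th[j] - 1e-6
      f0 <- chloroMS:::.mlpLossGrad(m, e, Xs, Tm)$loss
      (f1 - f0) / 2e-6
    }, 0)
    rel <- max(abs(g - fd) / pmax(1e-6, abs(g) + abs(fd)))
    expect_lt(rel, 1e-5,
              label = paste("gradient", combos$hidden[r], combos$output[r],
                            combos$error[r]))
  }
})

test_that("BFGS learns XOR and separable blobs, and never worsens train error", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(2L, 1L, 1L, 2L)
  m <- initMLP(2, 4, "tanh", "softmax", "entropy", seed = 1)
  tm <- trainMLP(m, X, y, X, y, maxIter = 200)
  expect_equal(mlpPredict(tm, X), y)
  expect_lte(tm@meta$iterations, 200)

  set.seed(33)
  n <- 200
  Xb <- rbind(matrix(rnorm(n, 2, 1), n / 2, 2), matrix(rnorm(n, -2, 1), n / 2, 2))
  yb <- rep(c(1L, 2L), each = n / 2)
  idx <- sample(n)
  tr <- idx[1:140]; va <- idx[141:200]
  mb <- initMLP(2, 5, "tanh", "softmax", "entropy", seed = 2)
  tb <- trainMLP(mb, Xb[tr, ], yb[tr], Xb[va, ], yb[va], maxIter = 120)
  expect_gte(mean(mlpPredict(tb, Xb[va, ]) == yb[va]), 0.95)

  h <- tb@meta$history
  expect_lte(mlpLoss(tb, Xb[tr, ], yb[tr]), h$train[1])
  # standardization: training features mean 0, sd 1 inside the model
  Xs <- chloroMS:::.standardize(tb, Xb[tr, ])
  expect_equal(colMeans(Xs), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(Xs, 2, sd), c(1, 1), tolerance = 1e-9)
})

test_that("training is deterministic for identical data, config and seed", {
  set.seed(10)
  X <- matrix(rnorm(120), 40, 3)
  y <- ifelse(X[, 1] + rnorm(40, 0, 0.3) > 0, 1L, 2L)
  t1 <- trainMLP(initMLP(3, 4, seed = 9), X[1:30, ], y[1:30], X[31:40, ], y[31:40])
  t2 <- trainMLP(initMLP(3, 4, seed = 9), X[1:30, ], y[1:30], X[31:40, ], y[31:40])
  expect_identical(chloroMS:::.flatten(t1), chloroMS:::.flatten(t2))
})

test_that("BFGS reaches the same loss basin as a reference optimizer", {
  set.seed(4)
  X <- matrix(rnorm(100), 50, 2)
  y <- ifelse(X[, 1] - X[, 2] > 0, 1L, 2L)
  m <- initMLP(2, 3, "tanh", "softmax", "entropy", seed = 5)
  m@xMean <- colMeans(X); m@xSd <- apply(X, 2, sd)
  Xs <- chloroMS:::.standardize(m, X)
  Tm <- chloroMS:::.oneHot(y)
  th0 <- chloroMS:::.flatten(m)
  ref <- optim(th0, fn = function(t) chloroMS:::.mlpLossGrad(m, t, Xs, Tm)$loss,
               gr = function(t) chloroMS:::.mlpLossGrad(m, t, Xs, Tm)$grad,
               method = "BFGS", control = list(maxit = 200))
  tm <- trainMLP(m, X, y, X, y, maxIter = 200)
  expect_lte(mlpLoss(tm, X, y), max(ref$value * 1.5, 1e-3))
})

test_that("mean-substitution sensitivity ranks informative features first", {
  set.seed(21)
  n <- 300
  X <- cbind(strong = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n),
             const = rep(1, n))
  y <- ifelse(X[, "strong"] > 0, 1L, 2L)
  m <- initMLP(4, 4, "tanh", "softmax", "entropy", seed = 3,
               featureNames = colnames(X))
  tm <- trainMLP(m, X[1:240, ], y[1:240], X[241:300, ], y[241:300], maxIter = 120)
  sens <- mlpSensitivity(tm, X[1:240, ], y[1:240])
  expect_equal(sens$ranking[1], "strong")
  expect_gt(sens$ratio[["strong"]], max(sens$ratio[c("noise1", "noise2")]))
  # substituting a constant feature is the identity
  expect_equal(sens$ratio[["const"]], 1, tolerance = 1e-4)
  # a feature the net ignores has ratio ~ 1
  tz <- tm; tz@W1[, 2] <- 0
  sz <- mlpSensitivity(tz, X[1:240, ], y[1:240])
  expect_lt(abs(sz$ratio[["noise1"]] - 1), 0.05)
  expect_true(all(sort(sens$ranking) == sort(colnames(X))))
})

test_that("models survive a JSON round trip bit-exactly", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  y <- ifelse(X[, 1] > 0, 1L, 2L)
  m <- trainMLP(initMLP(3, 3, "exponential", "exponential", "sse", seed = 8),
                X[1:15, ], y[1:15], X[16:20, ], y[16:20], maxIter = 50)
  f <- tempfile(fileext = ".json")
  saveMLP(m, f)
  m2 <- loadMLP(f)
  expect_identical(m2@W1, m@W1)
  expect_identical(m2@xMean, m@xMean)
  expect_identical(mlpForward(m2, X)$outputs, mlpForward(m, X)$outputs)
  # reloaded model reproduces the stored validation error
  expect_equal(mlpLoss(m2, X[16:20, ], y[16:20]),
               min(m@meta$history$validation), tolerance = 1e-12)

  writeLines("{\"schema\": \"something-else\"}", f)
  expect_error(loadMLP(f), "schema")
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 10), f)
  expect_error(loadMLP(f), "")
})
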