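test_that("confusion matrices and per-class accuracies are mutually consistent", {
  expect_equal(confusionAccuracy(c(1, 2, 1), c(1, 2, 1))$accuracy, 100)

  # the reference split of 228 class-1 and 250 class-2 test spectra:
  # 204 + 24 in row 1, 13 + 237 in row 2
  labels <- rep(c(1L, 2L), c(228, 250))
  preds <- c(rep(1L, 204), rep(2L, 24), rep(1L, 13), rep(2L, 237))
  r <- confusionAccuracy(preds, labels)
  expect_equal(unname(r$confusion), matrix(c(204L, 13L, 24L, 237L), 2))
  expect_equal(unname(r$classAccuracy["1"]), 100 * 204 / 228, tolerance = 1e-10)
  expect_equal(round(r$classAccuracy[["1"]], 2), 89.47)
  expect_equal(round(r$classAccuracy[["2"]], 2), 94.80)
  expect_equal(round(r$accuracy, 2), 92.26)
  # overall equals the class-size weighted mean
  expect_equal(r$accuracy,
               sum(r$classAccuracy * table(labels)) / length(labels))

  # random coin flips on balanced labels sit near 50%
  set.seed(1)
  n <- 1e4
  lab <- rep(c(1L, 2L), n / 2)
  acc <- confusionAccuracy(sample(c(1L, 2L), n, TRUE), lab)$accuracy
  expect_lt(abs(acc - 50), 5)
  expect_error(confusionAccuracy(integer(0), integer(0)), "empty")
})

test_that("trapezoid AUC equals the Mann-Whitney pair count", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 2, 2))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(1, 2), 5))$auc, 0.5)
  set.seed(6)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    labels <- c(1, 2, sample(c(1, 2), n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_equal(rocAuc(scores, labels)$auc, aucByPairs(scores, labels),
                 tolerance = 1e-12)
  }
  # ROC points are monotone in both coordinates
  set.seed(7)
  r <- rocAuc(runif(50), sample(c(1, 2), 50, TRUE))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(rocAuc(runif(5), rep(1, 5)), "each class")
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  library(pROC)
  set.seed(17)
  scores <- runif(80)
  labels <- ifelse(scores + rnorm(80, 0, 0.4) > 0.5, 1, 2)
  ours <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("2", "1"), direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("gain curves capture positives along the ranking", {
  # perfect ranking at 50% prevalence: all positives captured at half selected
  g <- gainCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 2, 2))
  expect_equal(g$captured[g$selected == 0.5], 1)
  expect_equal(g$captured[1], 0)
  expect_equal(unlist(g[nrow(g), ]), c(selected = 1, captured = 1))
  expect_true(all(diff(g$captured) >= 0))

  # uniform random scores track the diagonal
  set.seed(3)
  n <- 1e4
  gu <- gainCurve(runif(n), sample(c(1, 2), n, TRUE))
  expect_lt(max(abs(gu$captured - gu$selected)), 0.05)

  # the gain curve dominates the diagonal when AUC > 0.5
  set.seed(4)
  sc <- runif(400); lb <- ifelse(sc + rnorm(400, 0, 0.3) > 0.5, 1, 2)
  if (rocAuc(sc, lb)$auc > 0.5) {
    gd <- gainCurve(sc, lb)
    expect_gte(min(gd$captured - gd$selected), -0.02)
  }
  expect_error(gainCurve(c(0.1, 0.2), c(2, 2)), "positive")
})

test_that("class-separation tests behave on identical, shifted and tied samples", {
  x <- c(rnorm(30), rnorm(30))
  lab <- rep(c(1, 2), each = 30)
  x[31:60] <- x[1:30]                       # identical distributions
  r <- classSeparationTests(x, lab)
  expect_equal(r$statistic[r$test == "t"], 0)
  expect_equal(r$statistic[r$test == "KS"], 0)

  # two normals two sd apart: all three tests fire
  set.seed(9)
  hits <- replicate(50, {
    z <- c(rnorm(200), rnorm(200, 2))
    all(classSeparationTests(z, rep(c(1, 2), each = 200))$p < 0.05)
  })
  expect_true(all(hits))

  # U equals the brute-force pair count
  set.seed(11)
  a <- sample(1:10, 8, TRUE); b <- sample(1:10, 6, TRUE)
  r2 <- classSeparationTests(c(a, b), rep(c(1, 2), c(8, 6)))
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(r2$statistic[r2$test == "U"], U)

  expect_warning(classSeparationTests(rep(c(5, 5), each = 3), rep(c(1, 2), each = 3)),
                 "zero variance")
  expect_error(classSeparationTests(1:3, c(1, 2, 2)), "2 cases")
})

test_that("ensemble reports combine calls by majority with disagreement flags", {
  # linear single-feature models with hand-set weights: sign of x decides
  mk <- function(flip = 1) {
    m <- initMLP(1, 1, "linear", "linear", "sse", seed = 1, featureNames = "x")
    m@W1[] <- 1; m@b1[] <- 0
    m@W2 <- matrix(c(flip, -flip), 2, 1); m@b2 <- c(0, 0)
    m
  }
  X <- matrix(c(2, -2), 2, 1, dimnames = list(c("a", "b"), "x"))
  same <- replicate(5, mk(1), simplify = FALSE)
  r <- ensembleReport(same, X)
  expect_equal(unname(r$consensus), c(1L, 2L))
  expect_false(any(r$disagreement))
  expect_true(all(r$calls == c(1L, 2L)))

  mixed <- c(replicate(3, mk(1), simplify = FALSE),
             replicate(2, mk(-1), simplify = FALSE))
  r2 <- ensembleReport(mixed, X)
  expect_equal(unname(r2$consensus), c(1L, 2L))   # 3-vs-2 majority
  expect_true(all(r2$disagreement))

  other <- mk(1); other@featureNames <- "y"
  expect_error(ensembleReport(c(same[1:4], other), X), "feature")
})
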