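test_that("metrics match an independently coded formulation", {
  # worked example
  m <- computeMetrics(c(TP = 6, TN = 9, FP = 1, FN = 4))
  expect_equal(unname(m["Sn"]), 0.6)
  expect_equal(unname(m["Sp"]), 0.9)
  expect_equal(unname(m["Pr"]), 6 / 7)
  expect_equal(unname(m["Ac"]), 0.75)
  expect_equal(unname(m["MCC"]), 50 / sqrt(9100))

  perfect <- computeMetrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1))

  # no-information symmetry: TP = FN and TN = FP
  expect_equal(unname(computeMetrics(c(TP = 5, TN = 3, FP = 3,
                                       FN = 5))["MCC"]), 0)

  set.seed(99)
  ours <- oracle <- NULL
  for (i in 1:1000) {
    counts <- c(TP = sample(0:30, 1), TN = sample(0:30, 1),
                FP = sample(0:30, 1), FN = sample(0:30, 1))
    if (sum(counts) == 0) next
    ours <- rbind(ours, suppressWarnings(computeMetrics(counts)))
    oracle <- rbind(oracle, suppressWarnings(metricsFromVectors(counts)))
  }
  defined <- !is.nan(oracle)  # zero-denominator convention differs
  expect_equal(ours[defined], oracle[defined], tolerance = 1e-12)
  expect_error(computeMetrics(c(TP = -1, TN = 1, FP = 1, FN = 1)),
               "negative")
})

test_that("AUC equals the pairwise ordering count, with tie handling", {
  expect_equal(rocAuc(c(0.9, 0.4, 0.5, 0.1),
                      c("positive", "positive", "negative", "negative")),
               0.75)
  set.seed(6)
  for (i in 1:20) {
    nP <- sample(3:25, 1)
    nN <- sample(3:25, 1)
    sc <- round(runif(nP + nN), 2)   # rounding forces some ties
    labs <- c(rep("positive", nP), rep("negative", nN))
    expect_equal(rocAuc(sc, labs), pairwiseAuc(sc, labs))
  }
  # label inversion flips the area
  sc <- runif(30)
  labs <- sample(c("positive", "negative"), 30, replace = TRUE,
                 prob = c(0.5, 0.5))
  if (length(unique(labs)) == 2) {
    inv <- ifelse(labs == "positive", "negative", "positive")
    expect_equal(rocAuc(sc, inv), 1 - rocAuc(sc, labs))
  }
  expect_error(rocAuc(runif(5), rep("positive", 5)), "both classes")
})

test_that("specificity anchoring returns the minimal achieving threshold", {
  scores <- seq(0.1, 1, by = 0.1)
  labs <- rep("negative", 10)
  expect_equal(thresholdAtSpecificity(scores, labs, 0.9), 0.9)
  expect_equal(thresholdAtSpecificity(scores, labs, 0), -Inf)
  # all negatives at zero: any threshold >= 0 gives Sp 1
  expect_equal(thresholdAtSpecificity(c(0, 0, 0, 0.7),
                                      c(rep("negative", 3), "positive"),
                                      0.9), 0)
  set.seed(13)
  for (i in 1:30) {
    sc <- round(runif(40), 2)
    labs <- sample(c("positive", "negative"), 40, replace = TRUE)
    if (!any(labs == "negative")) next
    t0 <- thresholdAtSpecificity(sc, labs, 0.9)
    spAt <- function(t) mean(sc[labs == "negative"] <= t)
    expect_gte(spAt(t0), 0.9)
    smaller <- unique(sc[sc < t0])
    expect_true(all(vapply(smaller, spAt, 0) < 0.9))
  }
})

test_that("forest training is deterministic and handles degenerate input", {
  set.seed(3)
  n <- 60
  x <- matrix(rnorm(n * 10), nrow = n,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  x[, 1] <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
  labs <- rep(c("positive", "negative"), each = n / 2)
  m1 <- trainRF(x, labs, nTrees = 51, seed = 42)
  m2 <- trainRF(x, labs, nTrees = 51, seed = 42)
  expect_identical(predictScores(m1, x), predictScores(m2, x))
  expect_gte(rocAuc(predictScores(m1, x), labs), 0.95)

  constant <- matrix(1, nrow = n, ncol = 3,
                     dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(mc <- trainRF(constant, labs, nTrees = 25, seed = 1),
                 "class prior")
  expect_identical(unique(predictScores(mc, constant)), 0.5)
  expect_error(extractPaths(mc), "no accessible tree structure")

  expect_error(trainRF(x, rep("positive", n)), "2 samples per class")
  xb <- x
  xb[1, 1] <- NaN
  expect_error(trainRF(xb, labs), "non-finite")
  expect_error(predictScores(m1, x[, 1:5]), "missing feature")
})

test_that("vote fractions equal the per-tree vote average", {
  set.seed(23)
  n <- 40
  x <- matrix(rnorm(n * 5), nrow = n,
              dimnames = list(NULL, sprintf("f%d", 1:5)))
  labs <- sample(rep(c("positive", "negative"), each = n / 2))
  m <- trainRF(x, labs, nTrees = 33, seed = 9)
  sc <- predictScores(m, x)
  per <- predict(modelForest(m), x, predict.all = TRUE)$individual
  expect_equal(sc, unname(rowMeans(per == "positive")))
})

test_that("the strict score > threshold boundary rule is applied", {
  set.seed(14)
  x <- matrix(rnorm(40 * 4), nrow = 40,
              dimnames = list(NULL, sprintf("f%d", 1:4)))
  labs <- rep(c("positive", "negative"), each = 20)
  m <- trainRF(x, labs, nTrees = 20, seed = 2)
  sc <- predictScores(m, x)
  modelThreshold(m) <- sc[1]
  expect_identical(predictCalls(m, x)[1], "negative")
})

test_that("stratified CV balances folds, is seeded, and reports both views", {
  set.seed(77)
  n <- 60
  x <- matrix(rnorm(n * 12), nrow = n,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  x[, 2] <- c(rnorm(n / 2, 2.5), rnorm(n / 2, -2.5))
  labs <- rep(c("positive", "negative"), each = n / 2)
  cv <- kfoldCV(x, labs, k = 5, nestedSelection = TRUE, nSelect = 6,
                nTrees = 40, seed = 3)
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(c("Ac", "Sn", "Sp", "Pr", "MCC", "AUC") %in%
                  names(cv$meanMetrics)))
  expect_true(all(is.finite(cv$pooled$scores)))
  cv2 <- kfoldCV(x, labs, k = 5, nestedSelection = TRUE, nSelect = 6,
                 nTrees = 40, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfoldCV(x, labs, k = 40), "exceeds a class size")
  # separable data stays separable out of fold
  expect_gte(cv$meanMetrics[["AUC"]], 0.9)
})

test_that("precision falls as the negative pool grows, threshold fixed", {
  set.seed(100)
  posScores <- runif(200, 0.4, 1)
  negPool <- runif(3000, 0, 0.8)
  prAt <- function(nNeg) {
    sc <- c(posScores, negPool[seq_len(nNeg)])
    labs <- c(rep("positive", 200), rep("negative", nNeg))
    calls <- ifelse(sc > 0.6, "positive", "negative")
    suppressWarnings(computeMetrics(confusionCounts(calls, labs))[["Pr"]])
  }
  pr <- vapply(c(200, 600, 1800), prAt, 0)
  expect_true(all(diff(pr) < 0))
})
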