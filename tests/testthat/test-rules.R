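mkRule <- function(feature, op, threshold, class = "positive") {
  new("Rule",
      conditions = data.frame(feature = feature, op = op,
                              threshold = threshold,
                              stringsAsFactors = FALSE),
      predictedClass = class)
}

test_that("extracted rules cover exactly the samples reaching their leaf", {
  set.seed(55)
  n <- 80
  x <- matrix(rnorm(n * 6), nrow = n,
              dimnames = list(NULL, paste0("pb:", c("AK", "KxL", "AxxxxK",
                                                    "GxxH", "SxK", "EV"))))
  labs <- ifelse(x[, 1] + x[, 2] > 0, "positive", "negative")
  if (length(unique(labs)) < 2) labs[1:5] <- "positive"
  m <- trainRF(x, labs, nTrees = 7, seed = 8)
  rules <- extractPaths(m, "positive")
  expect_gt(length(rules), 0L)
  for (r in rules[seq_len(min(40, length(rules)))]) {
    leafOf <- routeToLeaf(modelForest(m), r@tree, x)
    expect_identical(unname(applyRule(r, x)), unname(leafOf == r@leaf))
  }
  # per-feature conditions are merged to single tightest bounds
  for (r in rules) {
    cond <- ruleConditions(r)
    expect_false(anyDuplicated(cond[, c("feature", "op")]) > 0)
  }
})

test_that("interval merging keeps the tightest bounds", {
  df <- data.frame(feature = c("f", "f", "g"), op = c("<=", "<=", ">"),
                   threshold = c(5, 3, 1), stringsAsFactors = FALSE)
  merged <- nitroRF:::.mergeConditions(df)
  expect_identical(merged$threshold[merged$feature == "f"], 3)
  expect_error(validObject(mkRule(c("f", "f"), c(">", "<="), c(5, 3))),
               "contradictory")
})

test_that("greedy cover reproduces the hand-simulated selection order", {
  # positives 1..5 (feature values 1..5), negative sample 6 (value 6)
  x <- matrix(1:6, ncol = 1, dimnames = list(NULL, "f"))
  labs <- c(rep("positive", 5), "negative")
  r1 <- mkRule("f", "<=", 3)                       # covers {1,2,3}
  r2 <- mkRule(c("f", "f"), c(">", "<="), c(2, 4)) # covers {3,4}
  r3 <- mkRule(c("f", "f"), c(">", "<="), c(4, 5)) # covers {5}
  cov <- greedyCover(list(r1, r2, r3), x, labs)
  expect_identical(cov$ruleIndex, c(1L, 2L, 3L))
  expect_identical(cov$nNew, c(3L, 1L, 1L))
  expect_identical(cov$nCovered, c(3L, 2L, 1L))
  # coverage is non-increasing along the selection order
  expect_true(all(diff(cov$nNew) <= 0))

  # a single all-covering rule gives a singleton output
  all5 <- mkRule("f", "<=", 5)
  covAll <- greedyCover(list(all5, r2), x, labs)
  expect_identical(nrow(covAll), 1L)
  expect_identical(covAll$nCovered, 5L)

  # a rule covering no positives is never selected
  none <- mkRule("f", ">", 5)
  covNone <- greedyCover(list(none, r1), x, labs)
  expect_false(1L %in% covNone$ruleIndex)
  expect_error(greedyCover(list(), x, labs), "empty rule list")
})

test_that("greedy union equals the union over all extracted rules", {
  set.seed(19)
  x <- matrix(rnorm(50 * 4), nrow = 50,
              dimnames = list(NULL, paste0("pb:", c("AK", "KL", "GA", "EV"))))
  labs <- ifelse(x[, 1] > 0, "positive", "negative")
  m <- trainRF(x, labs, nTrees = 5, seed = 4)
  rules <- extractPaths(m, "positive")
  cov <- greedyCover(rules, x, labs)
  anyCover <- Reduce(`|`, lapply(rules, applyRule, features = x))
  posIdx <- which(labs == "positive")
  expect_identical(sum(cov$nNew), sum(anyCover[posIdx]))
})

test_that("rule application is an inclusive-<= strict-> conjunction", {
  r <- parseRule("I(A××××K) > 0.118 & I(H××××A) ≤ 0.013")
  sample1 <- c("pb:AxxxxK" = 0.119, "pb:HxxxxA" = 0.013)
  expect_true(applyRule(r, sample1))
  atBoundary <- c("pb:AxxxxK" = 0.118, "pb:HxxxxA" = 0.013)
  expect_false(applyRule(r, atBoundary))     # > is strict
  le <- mkRule("f", "<=", 1)
  expect_true(applyRule(le, c(f = 1)))       # <= is inclusive
  expect_error(applyRule(r, c("pb:AxxxxK" = 1)), "lacks rule feature")
  expect_error(validObject(new("Rule",
                               conditions = data.frame(feature = character(),
                                                       op = character(),
                                                       threshold = numeric()),
                               predictedClass = "positive")),
               "at least one condition")
})

test_that("pair-frequency notation formats and round-trips", {
  expect_identical(formatRule(mkRule("pb:KxL", ">", 0.197)),
                   "I(K×L) > 0.197")
  expect_identical(formatRule(mkRule("pb:AxxxxK", ">", 0.118)),
                   "I(A××××K) > 0.118")
  expect_identical(formatRule(mkRule("pb:GK", "<=", 0.113)),
                   "I(GK) ≤ 0.113")
  txt <- "I(GK) > 0.113 & I(K××××L) ≤ 0.097 & I(ST) ≤ 0.038"
  expect_identical(formatRule(parseRule(txt)), txt)
  r <- mkRule(c("pb:SxxxxG", "pb:RxxK"), c("<=", ">"), c(0.039, 0.089))
  expect_identical(formatRule(parseRule(formatRule(r))), formatRule(r))
})
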