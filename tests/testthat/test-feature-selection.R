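test_that("exact Wilcoxon p-values match full enumeration on small samples", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    m <- sample(2:4, 1)
    vals <- sample(1:50, n + m)   # untied by construction
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    expect_equal(wilcoxonRankSum(x, y)$p.value, enumWilcoxP(x, y))
  }
})

test_that("tied and degenerate samples take the documented paths", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(wilcoxonRankSum(c(5, 5, 5), c(5, 5, 5))$p.value, 1)
  # large-sample approximation agrees with the reference implementation
  set.seed(4)
  x <- rnorm(30)
  y <- rnorm(40, 0.5)
  ours <- wilcoxonRankSum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("WR ranking orders by evidence and ignores row order", {
  set.seed(8)
  n <- 30
  labels <- rep(c("positive", "negative"), each = n)
  sep <- c(rnorm(n, 5), rnorm(n, -5))       # perfectly separated
  noise <- rnorm(2 * n)
  const <- rep(1, 2 * n)
  mat <- cbind(separated = sep, noise = noise, constant = const)
  rk <- rankingTable(rankFeaturesWR(mat, labels))
  expect_identical(rk$feature[1], "separated")
  expect_identical(rk$feature[3], "constant")
  expect_equal(rk$score[rk$feature == "constant"], 1)

  perm <- sample(2 * n)
  rk2 <- rankingTable(rankFeaturesWR(mat[perm, ], labels[perm]))
  expect_identical(rk$feature, rk2$feature)
  expect_equal(rk$score, rk2$score)

  expect_error(rankFeaturesWR(mat, rep("positive", 2 * n)), "both classes")
})

test_that("top-n selection preserves rank order and validates n", {
  set.seed(2)
  mat <- matrix(rnorm(40 * 300), nrow = 40,
                dimnames = list(NULL, sprintf("f%03d", 1:300)))
  labels <- rep(c("positive", "negative"), each = 20)
  rk <- rankFeaturesWR(mat, labels)
  expect_identical(selectTop(rk, 200), rankingTable(rk)$feature[1:200])
  expect_length(selectTop(rk, 200), 200L)
  expect_identical(selectTop(rk, 1), rankingTable(rk)$feature[1])
  expect_identical(selectTop(rk, 300), rankingTable(rk)$feature)
  expect_error(selectTop(rk, 301), "only 300")
})

test_that("information gain hits known values and monotone invariance", {
  labels <- rep(c("positive", "negative"), each = 10)
  perfect <- c(rnorm(10, 10), rnorm(10, -10))
  const <- rep(3, 20)
  mat <- cbind(perfect = perfect, constant = const)
  rk <- rankingTable(rankFeaturesIG(mat, labels))
  expect_equal(rk$score[rk$feature == "perfect"], 1)   # 1 bit
  expect_equal(rk$score[rk$feature == "constant"], 0)
  # strictly monotone transform leaves the gain unchanged
  mono <- cbind(f = exp(perfect / 5))
  expect_equal(rankingTable(rankFeaturesIG(cbind(f = perfect), labels))$score,
               rankingTable(rankFeaturesIG(mono, labels))$score)
})

test_that("mRMR prefers relevance first, then penalizes redundancy", {
  set.seed(12)
  n <- 120
  labels <- rep(c("positive", "negative"), each = n / 2)
  strong <- c(rnorm(n / 2, 2), rnorm(n / 2, -2))
  duplicate <- strong                      # perfectly redundant copy
  weak <- c(rnorm(n / 2, 0.8), rnorm(n / 2, -0.8))
  mat <- cbind(f1_strong = strong, f2_dup = duplicate, f3_weak = weak)
  rk <- rankingTable(rankFeaturesMRMR(mat, labels, n = 3))
  # brute-force the relevance ordering to confirm the greedy base case
  disc <- apply(mat, 2, nitroRF:::.discretize3)
  rel <- apply(disc, 2, nitroRF:::.mi, b = as.integer(labels == "positive"))
  expect_identical(rk$feature[1], names(which.max(rel)))
  # the duplicate of the first pick must not be picked second
  expect_identical(rk$feature[2], "f3_weak")
  expect_setequal(rk$feature, colnames(mat))  # n = M gives a permutation
})

test_that("planted informative features dominate the WR top of the list", {
  bench <- benchmarkDataset(fixtureSpec(nProteins = 60, seed = 11),
                            encoder = "ksaap")
  rk <- rankFeaturesWR(bench$features, bench$labels)
  planted <- truthTable(bench$spec)$ks
  expect_true(all(planted %in% selectTop(rk, 50)))
})
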