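test_that("encoder dimension laws hold for arbitrary configurations", {
  for (km in c(0L, 2L, 4L)) {
    for (w in c(4L, 10L, 20L)) {
      cfg <- encoderConfig(kMax = km, w = w)
      pep <- randomPeptide(2 * w + 1, c("A", "K", "Y", "G"))
      prof <- matrix(0, 2 * w + 1, 20, dimnames = list(NULL, AA_ALPHABET20))
      expect_length(encodePbCksaap(pep, prof, cfg), 400L * (km + 1L))
      expect_length(encodeKsaap(pep, cfg), 400L * (km + 1L))
      expect_length(encodeBinary(pep), 20L * (2L * w + 1L))
      expect_length(encodeAaindex(pep, cfg), 8L * (2L * w + 1L))
    }
  }
})

test_that("profile-weighted pair composition matches the worked example", {
  # peptide AKYAK, k = 0: pair (A,K) occurs at v = 1 and v = 4
  sc <- matrix(0, 5, 20, dimnames = list(NULL, AA_ALPHABET20))
  sc[1, "A"] <- 2
  sc[2, "K"] <- 3
  sc[4, "A"] <- -1
  sc[5, "K"] <- 5
  cfg <- encoderConfig(kMax = 0, w = 2)
  v <- encodePbCksaap("AKYAK", sc, cfg)
  expect_equal(unname(v["pb:AK"]), (min(2, 3) + max(min(-1, 5), 0)) / 4)
  expect_equal(unname(v["pb:AK"]), 0.5)
})

test_that("pair counts match the worked KSAAP example", {
  cfg <- encoderConfig(kMax = 1, w = 2)
  v <- encodeKsaap("AKAKA", cfg)
  expect_equal(unname(v["ks:AxA"]), 2 / 3)
  expect_equal(unname(v["ks:KxK"]), 1 / 3)
  expect_equal(sum(v[grepl("x", names(v), fixed = TRUE)]), 1)  # 3 pairs / 3
  expect_equal(unname(v["ks:AK"]), 2 / 4)
  expect_true(all(encodeKsaap(strrep("-", 5), cfg) == 0))
})

test_that("pair encoders agree with a brute-force enumerator", {
  cfg <- encoderConfig(kMax = 3, w = 2)  # length-5 windows, k up to 3
  alph <- c("A", "K", "Y", "G")
  grid <- expand.grid(rep(list(alph), 5), stringsAsFactors = FALSE)
  peps <- apply(grid, 1, paste, collapse = "")
  prof <- randomProfile(5, seed = 77)
  worstPb <- worstKs <- 0
  othersZero <- TRUE
  for (pep in peps) {
    oracle <- brutePairEncode(pep, prof, 3, alph, weighted = TRUE)
    got <- encodePbCksaap(pep, prof, cfg)
    worstPb <- max(worstPb, abs(got[names(oracle)] - oracle))
    oracleK <- brutePairEncode(pep, prof, 3, alph, weighted = FALSE)
    gotK <- encodeKsaap(pep, cfg)
    worstKs <- max(worstKs, abs(gotK[names(oracleK)] - oracleK))
    # features outside the 4-letter alphabet stay zero
    other <- setdiff(names(got), names(oracle))
    othersZero <- othersZero && all(got[other] == 0)
  }
  expect_identical(worstPb, 0)
  expect_identical(worstKs, 0)
  expect_true(othersZero)
})

test_that("longer random windows with gaps also match the enumerator", {
  cfg <- encoderConfig(kMax = 4, w = 4)
  set.seed(5)
  worst <- 0
  for (i in 1:40) {
    pep <- randomPeptide(9, c("A", "K", "Y", "G"),
                         padLeft = sample(0:2, 1), padRight = sample(0:2, 1))
    prof <- randomProfile(9, seed = i)
    prof[strsplit(pep, "")[[1]] == "-", ] <- 0
    oracle <- brutePairEncode(pep, prof, 4, weighted = TRUE)
    worst <- max(worst, abs(encodePbCksaap(pep, prof, cfg)[names(oracle)] -
                            oracle))
  }
  expect_identical(worst, 0)
})

test_that("with unit one-hot profiles pbCKSAAP reduces to KSAAP", {
  cfg <- encoderConfig()
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    pep <- randomPeptide(41, AA_ALPHABET20,
                         padLeft = sample(0:5, 1), padRight = sample(0:5, 1))
    prof <- profileScores(pseudoProfile(pep, mode = "one-hot", scale = 1))
    worst <- max(worst, abs(unname(encodePbCksaap(pep, prof, cfg)) -
                            unname(encodeKsaap(pep, cfg))))
  }
  expect_identical(worst, 0)
})

test_that("binary encoding is one-hot with zero blocks at padding", {
  v <- encodeBinary("-AY")
  expect_length(v, 60L)
  expect_true(all(v[1:20] == 0))
  expect_identical(unname(v["be:+0:A"]), 1)
  expect_identical(sum(v), 2)
  full <- encodeBinary(randomPeptide(41, c("A", "C")))
  expect_length(full, 820L)
  expect_identical(sum(full), 41)
})

test_that("AAindex encoding uses the shipped physicochemical tables", {
  tab <- aaindexTable()
  expect_identical(dim(tab), c(20L, 8L))
  cfg <- encoderConfig(kMax = 1, w = 1)
  v <- encodeAaindex("AGY", cfg)
  expect_length(v, 24L)
  expect_equal(unname(v["aa:+0:BLAM930101"]), unname(tab["G", "BLAM930101"]))
  expect_true(all(encodeAaindex("-Y-", cfg)[c(1:8, 17:24)] == 0))
  expect_error(aaindexTable("NOPE000000"), "unknown AAindex id")
  # the shipped values come from the AAindex database itself
  raw <- local({
    e <- new.env()
    data("aaindex", package = "seqinr", envir = e)
    e$aaindex
  })
  entry <- raw[[which(vapply(raw, function(a) a$H, "") == "BLAM930101")]]
  expect_equal(unname(tab["G", "BLAM930101"]), unname(entry$I[["Gly"]]))
})

test_that("pair features are invariant only under adjacency-preserving maps", {
  cfg <- encoderConfig(kMax = 2, w = 3)
  pep <- "AKYGAKC"
  prof <- randomProfile(7, seed = 3)
  base <- encodeKsaap(pep, cfg)
  expect_identical(encodeKsaap(pep, cfg), base)  # identity permutation
  swapped <- "KAYGAKC"                           # transposition breaks pairs
  expect_false(identical(encodeKsaap(swapped, cfg), base))
})
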