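test_that("FASTA reading preserves order, normalizes case, validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mya", ">p2", "GGYK"), fa)
  prot <- readFastaProteins(fa)
  expect_length(prot, 2L)
  expect_identical(names(prot), c("p1", "p2"))
  expect_identical(as.character(prot[["p1"]]), "MYA")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MYA", ">p1", "AAA"), bad)
  expect_error(readFastaProteins(bad), "sequence before header")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MYA", ">p1", "AAA"), dup)
  expect_error(readFastaProteins(dup), "duplicate")
})

test_that("record count equals the number of FASTA headers", {
  paths <- generateBenchmark(fixtureSpec(nProteins = 50, seed = 3),
                             withr::local_tempdir())
  nHeaders <- sum(startsWith(readLines(paths$fasta), ">"))
  expect_identical(length(readFastaProteins(paths$fasta)), nHeaders)
})

test_that("tyrosine enumeration labels annotated sites and flags bad input", {
  sites <- enumerateTyrosineSites("MYAYK", positives = 2)
  expect_identical(sites$position, c(2L, 4L))
  expect_identical(sites$label, c("positive", "negative"))
  expect_identical(nrow(enumerateTyrosineSites("MAAK")), 0L)
  expect_error(enumerateTyrosineSites("MYA", positives = 3), "not a 'Y'")
})

test_that("window extraction pads symmetrically and obeys the length law", {
  expect_identical(extractWindow("MYA", 2, w = 2), "-MYA-")
  seq100 <- paste(rep("A", 100), collapse = "")
  win <- extractWindow(paste0("Y", substr(seq100, 2, 100)), 1, w = 20)
  expect_identical(nchar(win), 41L)
  expect_identical(substr(win, 1, 20), strrep("-", 20))
  expect_false(grepl("-", substr(win, 21, 41)))
  # default width gives 41-mers wherever the site lies
  set.seed(1)
  for (pos in c(1, 7, 50, 100)) {
    expect_identical(nchar(extractWindow(seq100, pos)), 41L)
  }
  expect_error(extractWindow("MYA", 9), "out of range")
})

test_that("non-standard residues are collapsed to X on ingest", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MBYUZ"), fa)
  expect_identical(as.character(readFastaProteins(fa)[[1]]), "MXYXX")
})

test_that("redundancy filter drops at >= 40% identity within a class", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "D", "E"), 41, replace = TRUE),
                collapse = "")
  substr(base, 21, 21) <- "Y"
  variantWithIdentity <- function(orig, nSame) {
    chars <- strsplit(orig, "")[[1]]
    keep <- c(21L, sample(setdiff(1:41, 21L), nSame - 1L))
    other <- setdiff(1:41, keep)
    chars[other] <- ifelse(chars[other] == "G", "H", "G")
    paste(chars, collapse = "")
  }
  near <- variantWithIdentity(base, 17)   # 17/41 = 0.415 >= 0.40
  far <- variantWithIdentity(base, 16)    # 16/41 = 0.390 <  0.40
  expect_identical(sum(strsplit(base, "")[[1]] ==
                       strsplit(near, "")[[1]]), 17L)
  expect_identical(sum(strsplit(base, "")[[1]] ==
                       strsplit(far, "")[[1]]), 16L)

  dupSet <- makeWindowSet(c(base, base), c("positive", "positive"))
  expect_identical(length(filterRedundantPeptides(dupSet)), 1L)

  keptSet <- makeWindowSet(c(base, far), c("positive", "positive"))
  expect_identical(length(filterRedundantPeptides(keptSet)), 2L)

  dropSet <- makeWindowSet(c(base, near), c("positive", "positive"))
  expect_identical(peptides(filterRedundantPeptides(dropSet)), base)

  # cross-class pairs are never compared
  crossSet <- makeWindowSet(c(base, base), c("positive", "negative"))
  expect_identical(length(filterRedundantPeptides(crossSet)), 2L)

  # idempotence
  once <- filterRedundantPeptides(dropSet)
  expect_identical(peptides(filterRedundantPeptides(once)), peptides(once))
})

test_that("balancing keeps all positives and draws negatives per seed", {
  set.seed(9)
  peps <- replicate(110, randomPeptide(41, c("A", "C", "Y", "D")))
  peps <- vapply(peps, function(p) {
    substr(p, 21, 21) <- "Y"
    p
  }, "")
  labs <- c(rep("positive", 10), rep("negative", 100))
  sws <- makeWindowSet(unname(peps), labs)
  b1 <- balanceSample(sws, "1:1", seed = 5)
  expect_identical(as.vector(table(siteLabels(b1))[c("positive", "negative")]),
                   c(10L, 10L))
  b3 <- balanceSample(sws, "1:3", seed = 5)
  expect_identical(sum(siteLabels(b3) == "negative"), 30L)
  ball <- balanceSample(sws, "1:all", seed = 5)
  expect_identical(length(ball), 110L)
  # determinism
  b2 <- balanceSample(sws, "1:2", seed = 11)
  expect_identical(as.data.frame(b2),
                   as.data.frame(balanceSample(sws, "1:2", seed = 11)))
  # under-supplied ratio warns and keeps all negatives
  few <- makeWindowSet(unname(peps[1:15]),
                       c(rep("positive", 10), rep("negative", 5)))
  expect_warning(bf <- balanceSample(few, "1:1", seed = 1), "keeping all")
  expect_identical(sum(siteLabels(bf) == "negative"), 5L)
})

test_that("annotation validation catches unknown proteins and non-Y sites", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MYAYK"), fa)
  prot <- readFastaProteins(fa)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p2\t2\t1", tsv)
  expect_error(readSiteAnnotations(tsv, prot), "unknown proteins")
  writeLines("p1\t3\t1", tsv)
  expect_error(readSiteAnnotations(tsv, prot), "not 'Y'")
  writeLines("p1\t2\t1", tsv)
  ann <- readSiteAnnotations(tsv, prot)
  sws <- makeSiteWindows(prot, ann, w = 2)
  expect_identical(siteLabels(sws), c("positive", "negative"))
  expect_identical(substr(peptides(sws), 3, 3), c("Y", "Y"))
})
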