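# Shared fixtures and independent oracles used across the suite.

ALPH4 <- c("A", "K", "Y", "G")

# random peptide over a restricted alphabet, with optional terminal padding
randomPeptide <- function(L, alphabet = ALPH4, padLeft = 0L, padRight = 0L) {
  core <- paste(sample(alphabet, L - padLeft - padRight, replace = TRUE),
                collapse = "")
  paste0(strrep("-", padLeft), core, strrep("-", padRight))
}

# build a SiteWindowSet directly from peptides (central residue must not be
# padding); positions are synthesized to keep (protein, position) unique
makeWindowSet <- function(peptideVec, labels, w = (nchar(peptideVec[1]) - 1) %/% 2) {
  new("SiteWindowSet",
      windows = data.frame(
        protein_id = sprintf("P%04d", seq_along(peptideVec)),
        position = rep.int(50L, length(peptideVec)),
        peptide = peptideVec, label = labels, stringsAsFactors = FALSE),
      w = as.integer(w))
}

# independent brute-force pair enumerator: for every residue pair and
# spacing, scan all positions and test the literal letters
brutePairEncode <- function(peptide, profile, kMax, alphabet = ALPH4,
                            weighted = TRUE) {
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  out <- c()
  for (k in 0:kMax) {
    for (a in alphabet) {
      for (b in alphabet) {
        s <- 0
        for (v in seq_len(max(0L, L - k - 1L))) {
          if (chars[v] == a && chars[v + k + 1] == b) {
            s <- s + if (weighted) {
              max(min(profile[v, a], profile[v + k + 1, b]), 0)
            } else 1
          }
        }
        out[paste0(if (weighted) "pb" else "ks", ":", a, strrep("x", k), b)] <-
          s / (L - k - 1)
      }
    }
  }
  out
}

# independently coded metric formulas, via binary outcome vectors:
# accuracy as a mean, MCC as the Pearson correlation of the indicators
metricsFromVectors <- function(counts) {
  truth <- rep(c(1, 0, 0, 1), counts[c("TP", "TN", "FP", "FN")])
  call <- rep(c(1, 0, 1, 0), counts[c("TP", "TN", "FP", "FN")])
  mcc <- suppressWarnings(stats::cor(truth, call))
  c(Ac = mean(truth == call),
    Sn = mean(call[truth == 1]),
    Sp = mean(1 - call[truth == 0]),
    Pr = mean(truth[call == 1]),
    MCC = ifelse(is.na(mcc), 0, mcc))
}

# exact two-sided Wilcoxon p by full enumeration of rank partitions
enumWilcoxP <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  uAll <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# AUC by direct pairwise counting, ties counted one half
pairwiseAuc <- function(scores, labels) {
  ps <- scores[labels == "positive"]
  ns <- scores[labels == "negative"]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# independent routing of samples through one tree of a randomForest fit
routeToLeaf <- function(forest, treeIndex, x) {
  tree <- randomForest::getTree(forest, treeIndex, labelVar = FALSE)
  apply(x, 1, function(row) {
    node <- 1L
    while (tree[node, "status"] != -1L) {
      v <- row[tree[node, "split var"]]
      node <- if (v <= tree[node, "split point"]) {
        tree[node, "left daughter"]
      } else tree[node, "right daughter"]
    }
    node
  })
}

# small deterministic profile matrix for encoder tests
randomProfile <- function(L, seed, lo = -4, hi = 8) {
  set.seed(seed)
  m <- matrix(sample(lo:hi, L * 20, replace = TRUE), nrow = L)
  colnames(m) <- nitroRF::AA_ALPHABET20
  m
}
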