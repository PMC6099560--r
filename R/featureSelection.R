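#' Wilcoxon rank-sum (Mann-Whitney) two-sample test
#'
#' Computes the Mann-Whitney U statistic of \code{x} with midranks for
#' ties. The two-sided p-value is exact (from the null U distribution) when
#' \code{length(x) + length(y) <= 10} and the pooled sample has no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. A pooled sample with zero rank variance (all values
#' equal) is degenerate and returns p = 1.
#'
#' @param x,y numeric samples (positive-class and negative-class values).
#' @return list with \code{statistic} (U of \code{x}), \code{z} (the
#'   standardized statistic; 0 for the degenerate case), and \code{p.value}
#'   (two-sided).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
wilcoxonRankSum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    .stopf("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(pooled)
  hasTies <- any(ties > 1L)
  mu <- n * m / 2
  tieTerm <- sum(ties^3 - ties)
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, z = 0, p.value = 1))
  if (N <= 10L && !hasTies) {
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n, m)
    }
    p <- min(1, p)
    z <- (U - mu) / sqrt(sigma2)
  } else {
    corr <- sign(U - mu) * 0.5
    z <- (U - mu - corr) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, z = z, p.value = p)
}

# vectorized tie-corrected normal-approximation p for every column of a
# matrix; same arithmetic as the approximate branch of wilcoxonRankSum
.wrColumnStats <- function(mat, posMask) {
  n <- sum(posMask)
  m <- sum(!posMask)
  N <- n + m
  mu <- n * m / 2
  res <- apply(mat, 2L, function(col) {
    r <- rank(col)
    U <- sum(r[posMask]) - n * (n + 1) / 2
    ties <- table(col)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) return(c(U, 0, 1))
    corr <- sign(U - mu) * 0.5
    z <- (U - mu - corr) / sqrt(sigma2)
    c(U, z, min(1, 2 * stats::pnorm(-abs(z))))
  })
  list(statistic = res[1L, ], z = res[2L, ], p = res[3L, ])
}

.checkRankInput <- function(features, labels) {
  if (is.null(colnames(features))) .stopf("feature matrix must have colnames")
  if (nrow(features) != length(labels))
    .stopf("labels must align with feature-matrix rows")
  posMask <- labels %in% c("positive", "1", 1, TRUE)
  if (all(posMask) || !any(posMask))
    .stopf("both classes must be present")
  posMask
}

#' Rank features by Wilcoxon rank-sum test
#'
#' One two-sided test per feature column; features are ordered by ascending
#' p-value, ties broken by descending absolute standardized statistic, then
#' by feature name. The ranking is deterministic and invariant to row
#' order.
#'
#' @param features numeric matrix with named columns, one row per sample.
#' @param labels class labels aligned to rows (\code{"positive"} /
#'   \code{"negative"}, logical, or 0/1).
#' @return a \code{\linkS4class{FeatureRanking}} with method \code{"WR"};
#'   \code{score} holds the p-value.
#' @export
rankFeaturesWR <- function(features, labels) {
  posMask <- .checkRankInput(features, labels)
  N <- nrow(features)
  if (N <= 10L) {
    res <- lapply(seq_len(ncol(features)), function(j)
      wilcoxonRankSum(features[posMask, j], features[!posMask, j]))
    stat <- vapply(res, `[[`, 0, "statistic")
    z <- vapply(res, `[[`, 0, "z")
    p <- vapply(res, `[[`, 0, "p.value")
  } else {
    cs <- .wrColumnStats(features, posMask)
    stat <- cs$statistic
    z <- cs$z
    p <- cs$p
  }
  ord <- order(p, -abs(z), colnames(features), method = "radix")
  tab <- data.frame(rank = seq_len(ncol(features)),
                    feature = colnames(features)[ord],
                    statistic = stat[ord], score = p[ord],
                    stringsAsFactors = FALSE)
  new("FeatureRanking", method = "WR", table = tab)
}

#' Select the top-n features of a ranking
#'
#' @param ranking a \code{\linkS4class{FeatureRanking}}.
#' @param n number of features to keep (default 200).
#' @return character vector of the first \code{n} feature names in rank
#'   order.
#' @export
selectTop <- function(ranking, n = 200L) {
  tab <- rankingTable(ranking)
  if (n > nrow(tab))
    .stopf("requested top %d of only %d ranked features", n, nrow(tab))
  tab$feature[seq_len(n)]
}

# entropy (bits) of a 0/1 split given counts
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# best-threshold information gain of one continuous feature vs binary labels
.igain <- function(x, posMask) {
  n <- length(x)
  nPos <- sum(posMask)
  H <- .entropy(c(nPos, n - nPos))
  ord <- order(x)
  xs <- x[ord]
  ps <- cumsum(posMask[ord])   # positives at or below each sorted value
  cut <- which(diff(xs) > 0)   # candidate thresholds between distinct values
  if (length(cut) == 0L) return(0)
  nl <- cut
  pl <- ps[cut]
  nr <- n - nl
  pr <- nPos - pl
  condH <- vapply(seq_along(cut), function(i) {
    (nl[i] * .entropy(c(pl[i], nl[i] - pl[i])) +
     nr[i] * .entropy(c(pr[i], nr[i] - pr[i]))) / n
  }, 0)
  max(H - condH)
}

#' Rank features by information gain
#'
#' Each feature is binarized at the threshold maximizing the information
#' gain about the labels; features are ordered by descending gain, ties by
#' feature name. Gain is invariant to strictly monotone transforms of a
#' feature.
#'
#' @inheritParams rankFeaturesWR
#' @return a \code{\linkS4class{FeatureRanking}} with method \code{"IG"};
#'   \code{score} holds the gain in bits.
#' @export
rankFeaturesIG <- function(features, labels) {
  posMask <- .checkRankInput(features, labels)
  ig <- apply(features, 2L, .igain, posMask = posMask)
  ord <- order(-ig, colnames(features), method = "radix")
  tab <- data.frame(rank = seq_len(ncol(features)),
                    feature = colnames(features)[ord],
                    statistic = ig[ord], score = ig[ord],
                    stringsAsFactors = FALSE)
  new("FeatureRanking", method = "IG", table = tab)
}

# 3-bin discretization at mean +/- sd
.discretize3 <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep.int(1L, length(x)))
  1L + (x > mu - s) + (x > mu + s)
}

# mutual information (bits) between two discrete vectors
.mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log2(p[idx] / outer(pa, pb)[idx]))
}

#' Rank features by minimum-redundancy-maximum-relevance (mRMR)
#'
#' Features are discretized into three bins at mean +/- sd. Greedy forward
#' selection under the mutual-information difference (MID) scheme: the
#' first pick maximizes relevance (MI with the labels); each later pick
#' maximizes relevance minus mean redundancy (mean MI with the already
#' selected features).
#'
#' @inheritParams rankFeaturesWR
#' @param n number of features to select (default: all).
#' @return a \code{\linkS4class{FeatureRanking}} with method \code{"mRMR"};
#'   rank is selection order, \code{score} the MID objective at selection,
#'   \code{statistic} the relevance.
#' @export
rankFeaturesMRMR <- function(features, labels, n = ncol(features)) {
  posMask <- .checkRankInput(features, labels)
  disc <- apply(features, 2L, .discretize3)
  lab <- as.integer(posMask)
  M <- ncol(features)
  n <- min(n, M)
  relevance <- apply(disc, 2L, .mi, b = lab)
  selected <- integer(0)
  objective <- numeric(n)
  redSum <- numeric(M)   # running sum of MI with selected features
  avail <- rep.int(TRUE, M)
  for (step in seq_len(n)) {
    score <- if (step == 1L) relevance
             else relevance - redSum / (step - 1L)
    score[!avail] <- -Inf
    # deterministic tie-break on name
    best <- which(score == max(score))
    if (length(best) > 1L) best <- best[order(colnames(features)[best])]
    pick <- best[1L]
    selected <- c(selected, pick)
    objective[step] <- score[pick]
    avail[pick] <- FALSE
    if (step < n) {
      newMi <- apply(disc[, avail, drop = FALSE], 2L, .mi, b = disc[, pick])
      redSum[avail] <- redSum[avail] + newMi
    }
  }
  tab <- data.frame(rank = seq_len(n),
                    feature = colnames(features)[selected],
                    statistic = relevance[selected], score = objective,
                    stringsAsFactors = FALSE)
  new("FeatureRanking", method = "mRMR", table = tab)
}

#' Write a feature ranking as TSV
#'
#' @param ranking a \code{\linkS4class{FeatureRanking}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRanking <- function(ranking, path) {
  tab <- rankingTable(ranking)
  tab$method <- rankingMethod(ranking)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
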