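#' Train the random-forest site classifier
#'
#' Bootstrap-aggregated classification trees grown to purity (or to
#' \code{minLeaf}) with \code{mtry = floor(sqrt(p))} candidate features per
#' split and 500 trees by default. Deterministic given the seed. The
#' decision threshold on the positive vote fraction defaults to 0.5 and is
#' typically re-anchored with \code{\link{thresholdAtSpecificity}}.
#'
#' @param features numeric matrix with named columns, one row per sample.
#' @param labels class labels aligned to rows (\code{"positive"} /
#'   \code{"negative"}).
#' @param nTrees number of trees (default 500).
#' @param mtry candidate features per split (default
#'   \code{floor(sqrt(ncol(features)))}).
#' @param minLeaf minimum terminal-node size (default 1: grow to purity).
#' @param seed integer RNG seed.
#' @param threshold initial decision cutoff in [0, 1].
#' @return a \code{\linkS4class{NitroModel}}.
#' @export
trainRF <- function(features, labels, nTrees = 500L,
                    mtry = max(1L, floor(sqrt(ncol(features)))),
                    minLeaf = 1L, seed = 1L, threshold = 0.5) {
  if (is.null(colnames(features))) .stopf("feature matrix must have colnames")
  if (any(!is.finite(features))) .stopf("non-finite feature values")
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (anyNA(y)) .stopf("labels must be 'positive' or 'negative'")
  if (any(table(y) < 2L)) .stopf("need at least 2 samples per class")
  variance <- apply(features, 2L, function(col) max(col) - min(col))
  if (all(variance == 0)) {
    # no splittable feature: an uninformative ensemble predicts the base
    # rate for every sample
    .warnf("all features are constant; predictions equal the class prior")
    fit <- structure(list(classes = levels(y), ntree = nTrees,
                          prior = mean(y == "positive")),
                     class = "priorForest")
    return(new("NitroModel", forest = fit,
               featureNames = colnames(features), threshold = threshold,
               seed = as.integer(seed)))
  }
  fit <- .withSeed(seed, randomForest::randomForest(
    x = features, y = y, ntree = nTrees, mtry = mtry, nodesize = minLeaf,
    importance = FALSE, keep.forest = TRUE))
  new("NitroModel", forest = fit, featureNames = colnames(features),
      threshold = threshold, seed = as.integer(seed))
}

#' Positive-class vote fractions for new samples
#'
#' The score of a sample is the fraction of trees voting for the positive
#' class; the hard call (see \code{\link{predictCalls}}) is positive when
#' the score is strictly greater than the model threshold.
#'
#' @param model a \code{\linkS4class{NitroModel}}.
#' @param features numeric matrix containing at least the model's feature
#'   columns (extra columns are ignored, order is fixed by the model).
#' @return numeric vector of scores in [0, 1].
#' @export
predictScores <- function(model, features) {
  missing <- setdiff(modelFeatures(model), colnames(features))
  if (length(missing))
    .stopf("missing feature columns: %s", paste(missing, collapse = ", "))
  x <- features[, modelFeatures(model), drop = FALSE]
  forest <- modelForest(model)
  if (inherits(forest, "priorForest"))
    return(rep.int(forest$prior, nrow(x)))
  votes <- stats::predict(forest, x, type = "vote", norm.votes = TRUE)
  unname(votes[, "positive"])
}

#' @rdname predictScores
#' @return \code{predictCalls}: character vector \code{"positive"} /
#'   \code{"negative"} under the strict \code{score > threshold} rule.
#' @export
predictCalls <- function(model, features) {
  ifelse(predictScores(model, features) > modelThreshold(model),
         "positive", "negative")
}

#' Confusion counts from calls and labels
#'
#' @param calls predicted labels (\code{"positive"} / \code{"negative"}).
#' @param labels true labels.
#' @return named integer vector \code{c(TP, TN, FP, FN)}.
#' @export
confusionCounts <- function(calls, labels) {
  pos <- labels == "positive"
  callPos <- calls == "positive"
  c(TP = sum(callPos & pos), TN = sum(!callPos & !pos),
    FP = sum(callPos & !pos), FN = sum(!callPos & pos))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and the Matthews
#' correlation coefficient:
#' \deqn{Ac = (TP+TN)/(TP+TN+FP+FN), \quad Sn = TP/(TP+FN),}
#' \deqn{Sp = TN/(TN+FP), \quad Pr = TP/(TP+FP),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TN+FN)(TP+FP)(TP+FN)(TN+FP)}.}
#' A zero denominator makes the affected metric 0, with a warning.
#'
#' @param counts named vector with elements \code{TP}, \code{TN},
#'   \code{FP}, \code{FN} (see \code{\link{confusionCounts}}).
#' @return named numeric vector \code{c(Ac, Sn, Sp, Pr, MCC)}.
#' @examples
#' computeMetrics(c(TP = 6, TN = 9, FP = 1, FN = 4))
#' @export
computeMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) .stopf("negative confusion counts")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      .warnf("zero denominator for %s; reporting 0", what)
      return(0)
    }
    num / den
  }
  ac <- safeDiv(tp + tn, tp + tn + fp + fn, "Ac")
  sn <- safeDiv(tp, tp + fn, "Sn")
  sp <- safeDiv(tn, tn + fp, "Sp")
  pr <- safeDiv(tp, tp + fp, "Pr")
  den <- (tn + fn) * (tp + fp) * (tp + fn) * (tn + fp)
  mcc <- if (den == 0) {
    .warnf("zero denominator for MCC; reporting 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(den)
  }
  c(Ac = ac, Sn = sn, Sp = sp, Pr = pr, MCC = mcc)
}

#' Area under the ROC curve
#'
#' AUC equals the normalized Mann-Whitney statistic of the scores: the
#' fraction of (positive, negative) pairs where the positive scores higher,
#' ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels aligned to scores.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  pos <- labels == "positive"
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) .stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve points
#'
#' One point per distinct threshold under the strict \code{score > t} rule,
#' plus the (0, 0) and (1, 1) endpoints.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns \code{threshold}, \code{fpr} (1 - Sp),
#'   \code{tpr} (Sn), ordered by increasing fpr.
#' @export
rocCurve <- function(scores, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) .stopf("both classes must be present")
  th <- sort(unique(scores))
  fpr <- vapply(th, function(t) mean(scores[!pos] > t), 0)
  tpr <- vapply(th, function(t) mean(scores[pos] > t), 0)
  out <- data.frame(threshold = c(-Inf, th), fpr = c(1, fpr),
                    tpr = c(1, tpr))
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Anchor the decision threshold at a target specificity
#'
#' Returns the smallest threshold t such that, under the strict
#' \code{score > t} positive rule, the specificity on the given scores
#' reaches the target; being smallest, it maximizes sensitivity subject to
#' the specificity constraint.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels aligned to scores (negatives required).
#' @param target required specificity (default 0.90).
#' @return threshold value; \code{-Inf} when target is 0.
#' @examples
#' thresholdAtSpecificity(seq(0.1, 1, by = 0.1),
#'                        rep("negative", 10), target = 0.9)  # 0.9
#' @export
thresholdAtSpecificity <- function(scores, labels, target = 0.90) {
  neg <- scores[labels == "negative"]
  if (length(neg) == 0L) .stopf("negatives required to anchor specificity")
  if (target <= 0) return(-Inf)
  cand <- sort(unique(neg))
  sp <- cumsum(tabulate(match(sort(neg), cand),
                        nbins = length(cand))) / length(neg)
  ok <- which(sp >= target)
  if (length(ok) == 0L) {
    .warnf("target specificity %.3f not achievable; returning max score",
           target)
    return(max(scores))
  }
  cand[ok[1L]]
}

#' Stratified k-fold cross-validation with optional nested selection
#'
#' Samples of each class are partitioned into k near-equal folds (sizes
#' differing by at most one per class). For each fold, the model is trained
#' on the remaining folds and evaluated on the held-out fold. With
#' \code{nestedSelection = TRUE} (default) the Wilcoxon rank-sum top-n
#' feature subset is recomputed on each training partition, so the held-out
#' fold never influences selection; with \code{FALSE} the features are
#' selected once on the full matrix before the loop (the protocol used for
#' a whole-training-set selection, which leaks selection information into
#' the folds). Each fold's decision threshold is anchored at the target
#' specificity on the training partition's out-of-bag vote fractions.
#'
#' @param features numeric matrix with named columns.
#' @param labels class labels aligned to rows.
#' @param k number of folds (default 10).
#' @param nestedSelection recompute feature selection inside each fold.
#' @param nSelect number of features to select (default 200); \code{NULL}
#'   or a value >= ncol disables selection.
#' @param spTarget specificity anchor for the fold thresholds (default
#'   0.90).
#' @param nTrees trees per fold model.
#' @param seed integer seed controlling fold assignment and training.
#' @return list with \code{folds} (per-fold metrics, AUC and threshold),
#'   \code{meanMetrics} (mean over folds), \code{pooled} (metrics and AUC
#'   of the pooled out-of-fold predictions, plus \code{roc} points,
#'   \code{scores} and \code{labels}).
#' @export
kfoldCV <- function(features, labels, k = 10L, nestedSelection = TRUE,
                    nSelect = 200L, spTarget = 0.90, nTrees = 500L,
                    seed = 1L) {
  labels <- as.character(labels)
  ipos <- which(labels == "positive")
  ineg <- which(labels == "negative")
  if (k < 2L) .stopf("k must be >= 2")
  if (k > length(ipos) || k > length(ineg))
    .stopf("k = %d exceeds a class size (%d pos, %d neg)",
           k, length(ipos), length(ineg))
  doSelect <- !is.null(nSelect) && nSelect < ncol(features)
  fold <- integer(length(labels))
  fold[ipos] <- .withSeed(seed, sample(rep_len(seq_len(k), length(ipos))))
  fold[ineg] <- .withSeed(seed + 1L,
                          sample(rep_len(seq_len(k), length(ineg))))
  if (doSelect && !nestedSelection) {
    globalSel <- selectTop(rankFeaturesWR(features, labels), nSelect)
  }
  oofScores <- rep(NA_real_, length(labels))
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(fold != f)
    teIdx <- which(fold == f)
    sel <- if (!doSelect) colnames(features)
           else if (nestedSelection)
             selectTop(rankFeaturesWR(features[trIdx, , drop = FALSE],
                                      labels[trIdx]), nSelect)
           else globalSel
    model <- trainRF(features[trIdx, sel, drop = FALSE], labels[trIdx],
                     nTrees = nTrees, seed = seed + f)
    oob <- modelForest(model)$votes[, "positive"]
    thr <- thresholdAtSpecificity(oob, labels[trIdx], spTarget)
    sc <- predictScores(model, features[teIdx, sel, drop = FALSE])
    oofScores[teIdx] <- sc
    calls <- ifelse(sc > thr, "positive", "negative")
    met <- suppressWarnings(
      computeMetrics(confusionCounts(calls, labels[teIdx])))
    perFold[[f]] <- c(fold = f, met, AUC = rocAuc(sc, labels[teIdx]),
                      threshold = thr)
  }
  folds <- as.data.frame(do.call(rbind, perFold))
  meanMetrics <- colMeans(folds[, c("Ac", "Sn", "Sp", "Pr", "MCC", "AUC")])
  pooledThr <- stats::median(folds$threshold)
  pooledCalls <- ifelse(oofScores > pooledThr, "positive", "negative")
  pooled <- list(
    metrics = suppressWarnings(
      computeMetrics(confusionCounts(pooledCalls, labels))),
    auc = rocAuc(oofScores, labels),
    roc = rocCurve(oofScores, labels),
    scores = oofScores, labels = labels, threshold = pooledThr)
  list(folds = folds, meanMetrics = meanMetrics, pooled = pooled)
}
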