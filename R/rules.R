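#' Extract root-to-leaf rules from the trained forest
#'
#' Every leaf predicting the target class yields one rule: the conjunction
#' of the split conditions along its path (numeric splits send
#' \code{x <= t} left and \code{x > t} right). Conditions on the same
#' feature are merged into the tightest bounds.
#'
#' @param model a \code{\linkS4class{NitroModel}} (the forest structure
#'   must be available).
#' @param targetClass class whose leaves become rules (default
#'   \code{"positive"}).
#' @param maxTrees optionally restrict extraction to the first trees.
#' @return list of \code{\linkS4class{Rule}} objects.
#' @export
extractPaths <- function(model, targetClass = "positive", maxTrees = NULL) {
  forest <- modelForest(model)
  if (!inherits(forest, "randomForest") || is.null(forest$forest))
    .stopf("model has no accessible tree structure")
  classes <- forest$classes
  if (!targetClass %in% classes)
    .stopf("unknown class '%s' (model classes: %s)", targetClass,
           paste(classes, collapse = ", "))
  targetIdx <- match(targetClass, classes)
  feats <- modelFeatures(model)
  nTrees <- forest$ntree
  if (!is.null(maxTrees)) nTrees <- min(nTrees, maxTrees)
  rules <- list()
  for (t in seq_len(nTrees)) {
    tree <- randomForest::getTree(forest, t, labelVar = FALSE)
    walk <- function(node, cond) {
      if (tree[node, "status"] == -1L) {
        if (tree[node, "prediction"] == targetIdx && length(cond)) {
          df <- do.call(rbind, cond)
          rules[[length(rules) + 1L]] <<-
            new("Rule", conditions = .mergeConditions(df),
                predictedClass = targetClass, tree = t,
                leaf = as.integer(node))
        }
        return(invisible())
      }
      f <- feats[tree[node, "split var"]]
      s <- tree[node, "split point"]
      walk(tree[node, "left daughter"],
           c(cond, list(data.frame(feature = f, op = "<=", threshold = s,
                                   stringsAsFactors = FALSE))))
      walk(tree[node, "right daughter"],
           c(cond, list(data.frame(feature = f, op = ">", threshold = s,
                                   stringsAsFactors = FALSE))))
    }
    walk(1L, list())
  }
  rules
}

# tightest bound per (feature, direction)
.mergeConditions <- function(df) {
  parts <- lapply(split(df, df$feature), function(sub) {
    out <- NULL
    if (any(sub$op == ">")) {
      out <- rbind(out, data.frame(feature = sub$feature[1L], op = ">",
                                   threshold = max(sub$threshold[sub$op == ">"]),
                                   stringsAsFactors = FALSE))
    }
    if (any(sub$op == "<=")) {
      out <- rbind(out, data.frame(feature = sub$feature[1L], op = "<=",
                                   threshold = min(sub$threshold[sub$op == "<="]),
                                   stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  # keep first-encounter feature order
  out[order(match(out$feature, df$feature)), , drop = FALSE]
}

#' Apply a rule to samples
#'
#' Evaluates the conjunction of the rule's conditions. \code{<=} is
#' inclusive; \code{>} strict.
#'
#' @param rule a \code{\linkS4class{Rule}}.
#' @param features named numeric vector (one sample) or matrix with named
#'   columns (one row per sample).
#' @return logical: does each sample satisfy every condition?
#' @export
applyRule <- function(rule, features) {
  cond <- ruleConditions(rule)
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  missing <- setdiff(cond$feature, colnames(features))
  if (length(missing))
    .stopf("sample lacks rule feature(s): %s",
           paste(missing, collapse = ", "))
  hit <- rep.int(TRUE, nrow(features))
  for (i in seq_len(nrow(cond))) {
    v <- features[, cond$feature[i]]
    hit <- hit & if (cond$op[i] == "<=") v <= cond$threshold[i]
                 else v > cond$threshold[i]
  }
  hit
}

#' Greedy covering rule set
#'
#' Iteratively selects the rule covering the most not-yet-covered positive
#' samples, removes the samples it covers, and repeats until every
#' coverable positive is covered or no rule adds coverage. Ties are broken
#' by fewer conditions, then by rule discovery order. With
#' \code{negativeDeletion = TRUE} the loop instead scores rules by total
#' covered samples and deletes covered negatives each round (an alternative
#' reading of the assembly loop); the default positive set-cover is the
#' standard one.
#'
#' @param rules list of \code{\linkS4class{Rule}} objects.
#' @param features numeric matrix with named columns.
#' @param labels class labels aligned to rows.
#' @param maxRules stop after this many selections (default: no limit).
#' @param negativeDeletion use the negative-deletion variant.
#' @return data.frame with one row per selected rule: \code{rank},
#'   \code{rule} (formatted), \code{nNew} (newly covered positives),
#'   \code{nCovered} (absolute positive coverage), \code{ruleIndex} into
#'   \code{rules}; the selected \code{Rule} objects (with support filled
#'   in) are attached as attribute \code{"rules"}.
#' @export
greedyCover <- function(rules, features, labels, maxRules = Inf,
                        negativeDeletion = FALSE) {
  if (length(rules) == 0L) .stopf("empty rule list")
  posIdx <- which(labels == "positive")
  cover <- vapply(rules, applyRule, logical(nrow(features)),
                  features = features)
  if (is.null(dim(cover)))
    cover <- matrix(cover, nrow = nrow(features))
  nCond <- vapply(rules, function(r) nrow(ruleConditions(r)), 0L)
  uncovered <- rep.int(TRUE, nrow(features))
  selected <- list()
  out <- NULL
  rank <- 0L
  while (rank < maxRules) {
    scorePool <- if (negativeDeletion) which(uncovered)
                 else intersect(posIdx, which(uncovered))
    if (length(scorePool) == 0L) break
    gains <- colSums(cover[scorePool, , drop = FALSE])
    best <- max(gains)
    if (best == 0L) break
    cand <- which(gains == best)
    cand <- cand[order(nCond[cand], cand)]
    pick <- cand[1L]
    rank <- rank + 1L
    absCov <- sum(cover[posIdx, pick])
    rule <- rules[[pick]]
    rule@support <- as.integer(absCov)
    selected[[rank]] <- rule
    newCov <- if (negativeDeletion) {
      sum(cover[intersect(posIdx, which(uncovered)), pick])
    } else best
    out <- rbind(out, data.frame(
      rank = rank, rule = formatRule(rule), nNew = as.integer(newCov),
      nCovered = as.integer(absCov), ruleIndex = pick,
      stringsAsFactors = FALSE))
    if (negativeDeletion) {
      uncovered[cover[, pick]] <- FALSE
    } else {
      uncovered[intersect(posIdx, which(cover[, pick]))] <- FALSE
    }
  }
  attr(out, "rules") <- selected
  out
}

# pair feature name "pb:AxxxxK" -> list(a, k, b) or NULL
.parsePairFeature <- function(name) {
  m <- regmatches(name,
                  regexec("^(pb|ks):([A-Z])(x*)([A-Z])$", name))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(prefix = m[2L], a = m[3L], k = nchar(m[4L]), b = m[5L])
}

#' Render a rule in pair-frequency notation
#'
#' Pair features print as \code{I(<qi><× repeated k times><qj>)} with the
#' relation and a 3-decimal threshold, conditions joined by \code{" & "}:
#' e.g. \code{"I(A××××K) > 0.118"} for the k = 4 pair
#' A..K. Non-pair features print with their plain names.
#'
#' @param rule a \code{\linkS4class{Rule}}.
#' @return single string.
#' @export
formatRule <- function(rule) {
  cond <- ruleConditions(rule)
  parts <- vapply(seq_len(nrow(cond)), function(i) {
    p <- .parsePairFeature(cond$feature[i])
    lhs <- if (is.null(p)) cond$feature[i]
           else sprintf("I(%s%s%s)", p$a, strrep("\u00d7", p$k), p$b)
    rel <- if (cond$op[i] == "<=") "\u2264" else ">"
    sprintf("%s %s %.3f", lhs, rel, cond$threshold[i])
  }, "")
  paste(parts, collapse = " & ")
}

#' Parse a formatted rule string back into a Rule
#'
#' Inverse of \code{\link{formatRule}} for pair-feature conditions
#' (thresholds at their printed 3-decimal precision).
#'
#' @param text rule string such as
#'   \code{"I(K×L) > 0.197 & I(GK) ≤ 0.113"}.
#' @param predictedClass class label to attach (default
#'   \code{"positive"}).
#' @param prefix feature-name prefix for the reconstructed conditions
#'   (default \code{"pb"}).
#' @return a \code{\linkS4class{Rule}}.
#' @export
parseRule <- function(text, predictedClass = "positive", prefix = "pb") {
  parts <- strsplit(text, " & ", fixed = TRUE)[[1L]]
  pat <- sprintf("^I\\(([A-Z])(%s*)([A-Z])\\)\\s*(>|%s|<=)\\s*([0-9.]+)$",
                 "\u00d7", "\u2264")
  cond <- do.call(rbind, lapply(parts, function(p) {
    m <- regmatches(trimws(p), regexec(pat, trimws(p)))[[1L]]
    if (length(m) == 0L) .stopf("cannot parse rule condition: '%s'", p)
    data.frame(feature = paste0(prefix, ":", m[2L],
                                strrep("x", nchar(m[3L])), m[4L]),
               op = if (m[5L] == ">") ">" else "<=",
               threshold = as.numeric(m[6L]), stringsAsFactors = FALSE)
  }))
  new("Rule", conditions = cond, predictedClass = predictedClass)
}

#' Write a covering rule report as TSV
#'
#' Columns: rank, formatted rule, newly-covered and absolute
#' covered-positive counts.
#'
#' @param cov data.frame from \code{\link{greedyCover}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRuleReport <- function(cov, path) {
  utils::write.table(cov[, c("rank", "rule", "nNew", "nCovered")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
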