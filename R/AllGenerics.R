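#' @include AllClasses.R
NULL

#' @describeIn SiteWindowSet number of windows
#' @param x a \code{SiteWindowSet}
#' @export
setMethod("length", "SiteWindowSet", function(x) nrow(x@windows))

#' Accessors for SiteWindowSet
#'
#' @param x a \code{\linkS4class{SiteWindowSet}}.
#' @return \code{peptides} the peptide strings; \code{siteLabels} the class
#'   labels; \code{proteinIds} the protein accessions; \code{sitePositions}
#'   the 1-based central positions; \code{windowHalfWidth} the half-width w.
#' @name SiteWindowSet-accessors
#' @aliases peptides siteLabels proteinIds sitePositions windowHalfWidth
NULL

#' @rdname SiteWindowSet-accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname SiteWindowSet-accessors
#' @export
setMethod("peptides", "SiteWindowSet", function(x) x@windows$peptide)

#' @rdname SiteWindowSet-accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname SiteWindowSet-accessors
#' @export
setMethod("siteLabels", "SiteWindowSet", function(x) x@windows$label)

#' @rdname SiteWindowSet-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname SiteWindowSet-accessors
#' @export
setMethod("proteinIds", "SiteWindowSet", function(x) x@windows$protein_id)

#' @rdname SiteWindowSet-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname SiteWindowSet-accessors
#' @export
setMethod("sitePositions", "SiteWindowSet", function(x) x@windows$position)

#' @rdname SiteWindowSet-accessors
#' @export
setGeneric("windowHalfWidth", function(x) standardGeneric("windowHalfWidth"))
#' @rdname SiteWindowSet-accessors
#' @export
setMethod("windowHalfWidth", "SiteWindowSet", function(x) x@w)

#' @describeIn SiteWindowSet subset windows
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "SiteWindowSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, windows = x@windows[i, , drop = FALSE])
})

#' @describeIn SiteWindowSet coerce to data.frame
#' @param row.names,optional passed through
setMethod("as.data.frame", "SiteWindowSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
  df <- x@windows
  rownames(df) <- row.names
  df
})

setMethod("show", "SiteWindowSet", function(object) {
  tab <- table(factor(object@windows$label,
                      levels = c("positive", "negative", "unknown")))
  cat(sprintf(
    "SiteWindowSet: %d windows (w = %d, length %d): %d positive, %d negative, %d unknown\n",
    length(object), object@w, 2L * object@w + 1L,
    tab[["positive"]], tab[["negative"]], tab[["unknown"]]))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata),
                             unlist(lapply(object@metadata, format)),
                             sep = "=", collapse = ", "), "\n")
})

#' Accessors for ProfileMatrix and WindowProfile
#'
#' @param x a \code{\linkS4class{ProfileMatrix}} or
#'   \code{\linkS4class{WindowProfile}}.
#' @return \code{profileScores} the numeric score matrix (columns in
#'   canonical order); \code{profileResidues} the residue per row.
#' @name profile-accessors
#' @aliases profileScores profileResidues
NULL

#' @rdname profile-accessors
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))
#' @rdname profile-accessors
#' @export
setMethod("profileScores", "ProfileMatrix", function(x) x@scores)
#' @rdname profile-accessors
#' @export
setMethod("profileScores", "WindowProfile", function(x) x@scores)

#' @rdname profile-accessors
#' @export
setGeneric("profileResidues", function(x) standardGeneric("profileResidues"))
#' @rdname profile-accessors
#' @export
setMethod("profileResidues", "ProfileMatrix", function(x) x@residues)

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix for '%s': %d positions x 20 residues\n",
              object@proteinId, nrow(object@scores)))
})

setMethod("show", "WindowProfile", function(object) {
  cat(sprintf("WindowProfile '%s' @%d: %d x 20 (%d padded rows)\n",
              object@proteinId, object@position, nrow(object@scores),
              sum(object@padded)))
})

#' Accessors for FeatureRanking
#'
#' @param x a \code{\linkS4class{FeatureRanking}}.
#' @return \code{rankingTable} the ordered data.frame of (rank, feature,
#'   statistic, score); \code{rankingMethod} the method label.
#' @name FeatureRanking-accessors
#' @aliases rankingTable rankingMethod
NULL

#' @rdname FeatureRanking-accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
#' @rdname FeatureRanking-accessors
#' @export
setMethod("rankingTable", "FeatureRanking", function(x) x@table)

#' @rdname FeatureRanking-accessors
#' @export
setGeneric("rankingMethod", function(x) standardGeneric("rankingMethod"))
#' @rdname FeatureRanking-accessors
#' @export
setMethod("rankingMethod", "FeatureRanking", function(x) x@method)

setMethod("show", "FeatureRanking", function(object) {
  cat(sprintf("FeatureRanking (%s): %d features\n", object@method,
              nrow(object@table)))
  print(utils::head(object@table, 5L))
})

#' Accessors for NitroModel
#'
#' @param x a \code{\linkS4class{NitroModel}}.
#' @param value replacement threshold in [0, 1].
#' @return \code{modelFeatures} the ordered feature names;
#'   \code{modelThreshold} the decision cutoff on the positive vote
#'   fraction; \code{modelForest} the underlying \code{randomForest} fit.
#' @name NitroModel-accessors
#' @aliases modelFeatures modelThreshold modelThreshold<- modelForest
NULL

#' @rdname NitroModel-accessors
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @rdname NitroModel-accessors
#' @export
setMethod("modelFeatures", "NitroModel", function(x) x@featureNames)

#' @rdname NitroModel-accessors
#' @export
setGeneric("modelThreshold", function(x) standardGeneric("modelThreshold"))
#' @rdname NitroModel-accessors
#' @export
setMethod("modelThreshold", "NitroModel", function(x) x@threshold)

#' @rdname NitroModel-accessors
#' @export
setGeneric("modelThreshold<-",
           function(x, value) standardGeneric("modelThreshold<-"))
#' @rdname NitroModel-accessors
#' @export
setMethod("modelThreshold<-", "NitroModel", function(x, value) {
  x@threshold <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname NitroModel-accessors
#' @export
setGeneric("modelForest", function(x) standardGeneric("modelForest"))
#' @rdname NitroModel-accessors
#' @export
setMethod("modelForest", "NitroModel", function(x) x@forest)

setMethod("show", "NitroModel", function(object) {
  cat(sprintf(
    "NitroModel: %d trees on %d features; threshold %.3f (call = score > t)\n",
    object@forest$ntree, length(object@featureNames), object@threshold))
})

#' Accessors for Rule
#'
#' @param x a \code{\linkS4class{Rule}}.
#' @return \code{ruleConditions} the data.frame of conditions;
#'   \code{ruleClass} the predicted class; \code{ruleSupport} the covered
#'   sample count (NA until coverage is computed).
#' @name Rule-accessors
#' @aliases ruleConditions ruleClass ruleSupport
NULL

#' @rdname Rule-accessors
#' @export
setGeneric("ruleConditions", function(x) standardGeneric("ruleConditions"))
#' @rdname Rule-accessors
#' @export
setMethod("ruleConditions", "Rule", function(x) x@conditions)

#' @rdname Rule-accessors
#' @export
setGeneric("ruleClass", function(x) standardGeneric("ruleClass"))
#' @rdname Rule-accessors
#' @export
setMethod("ruleClass", "Rule", function(x) x@predictedClass)

#' @rdname Rule-accessors
#' @export
setGeneric("ruleSupport", function(x) standardGeneric("ruleSupport"))
#' @rdname Rule-accessors
#' @export
setMethod("ruleSupport", "Rule", function(x) x@support)

setMethod("show", "Rule", function(object) {
  cat(formatRule(object), sprintf(" -> %s", object@predictedClass))
  if (!is.na(object@support)) cat(sprintf(" (support %d)", object@support))
  cat("\n")
})
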