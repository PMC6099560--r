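#' @import methods
NULL

#' Set of fixed-length tyrosine-centered sequence windows
#'
#' Container for peptide windows of length \eqn{2w+1} centered on a
#' (candidate) nitration site, each carrying its protein of origin, the
#' 1-based position of the central residue, and a class label. Out-of-range
#' positions are padded with \code{"-"}, which every downstream encoder
#' treats as a zero contribution.
#'
#' @slot windows data.frame with columns \code{protein_id}, \code{position},
#'   \code{peptide}, \code{label} (one of \code{"positive"},
#'   \code{"negative"}, \code{"unknown"}).
#' @slot w integer half-width; peptides have length \code{2*w + 1}.
#' @slot metadata list of provenance information (e.g. balancing ratio and
#'   seed for sampled splits).
#'
#' @exportClass SiteWindowSet
setClass("SiteWindowSet",
         representation(windows = "data.frame", w = "integer",
                        metadata = "list"),
         prototype(windows = data.frame(protein_id = character(),
                                        position = integer(),
                                        peptide = character(),
                                        label = character(),
                                        stringsAsFactors = FALSE),
                   w = 20L, metadata = list()))

setValidity("SiteWindowSet", function(object) {
  win <- object@windows
  need <- c("protein_id", "position", "peptide", "label")
  if (!all(need %in% colnames(win)))
    return(paste("windows must have columns", paste(need, collapse = ", ")))
  if (nrow(win) == 0L) return(TRUE)
  len <- 2L * object@w + 1L
  if (any(nchar(win$peptide) != len))
    return(sprintf("all peptides must have length 2w+1 = %d", len))
  centers <- substr(win$peptide, object@w + 1L, object@w + 1L)
  if (any(centers == "-"))
    return("central window character must be a residue, not padding")
  # padding only as contiguous prefix/suffix
  if (any(grepl("-", gsub("^-+|-+$", "", win$peptide), fixed = TRUE)))
    return("'-' padding must be a contiguous prefix and/or suffix")
  if (anyDuplicated(win[, c("protein_id", "position")]))
    return("duplicate (protein_id, position) entries")
  if (!all(win$label %in% c("positive", "negative", "unknown")))
    return("labels must be 'positive', 'negative' or 'unknown'")
  TRUE
})

#' Position-specific scoring matrix for one protein
#'
#' L x 20 log-odds scores with the canonical PSI-BLAST residue column order
#' \code{ARNDCQEGHILKMFPSTWYV}. Row \code{v} corresponds to sequence
#' position \code{v} (1-based).
#'
#' @slot proteinId protein accession the profile belongs to.
#' @slot residues character vector, the residue at each row (the profile's
#'   own sequence column); used to cross-check against protein sequences.
#' @slot scores numeric L x 20 matrix of log-odds values.
#'
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
         representation(proteinId = "character", residues = "character",
                        scores = "matrix"))

setValidity("ProfileMatrix", function(object) {
  if (ncol(object@scores) != 20L) return("scores must have 20 columns")
  if (!identical(colnames(object@scores), AA_ALPHABET20))
    return("score columns must be in canonical order ARNDCQEGHILKMFPSTWYV")
  if (nrow(object@scores) != length(object@residues))
    return("one residue per score row required")
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
    return("proteinId must be a single non-empty string")
  TRUE
})

#' Profile slice aligned to one sequence window
#'
#' A \eqn{(2w+1) \times 20} slice of a \linkS4class{ProfileMatrix} aligned
#' to a window peptide; rows falling outside the protein (padding) are
#' all-zero and flagged.
#'
#' @slot proteinId protein accession.
#' @slot position 1-based position of the central residue.
#' @slot peptide the window peptide (with \code{"-"} padding).
#' @slot scores numeric (2w+1) x 20 matrix.
#' @slot padded logical vector flagging all-zero padding rows.
#'
#' @exportClass WindowProfile
setClass("WindowProfile",
         representation(proteinId = "character", position = "integer",
                        peptide = "character", scores = "matrix",
                        padded = "logical"))

setValidity("WindowProfile", function(object) {
  L <- nchar(object@peptide)
  if (nrow(object@scores) != L) return("one score row per peptide position")
  if (ncol(object@scores) != 20L) return("scores must have 20 columns")
  if (length(object@padded) != L) return("one padded flag per position")
  if (any(object@padded) &&
      any(object@scores[object@padded, , drop = FALSE] != 0))
    return("padded rows must be all-zero")
  TRUE
})

#' Ranked features from a selection method
#'
#' @slot method one of \code{"WR"}, \code{"IG"}, \code{"mRMR"}.
#' @slot table data.frame with columns \code{rank}, \code{feature},
#'   \code{statistic}, \code{score} (p-value for WR, gain for IG, objective
#'   for mRMR), ordered by rank.
#'
#' @exportClass FeatureRanking
setClass("FeatureRanking",
         representation(method = "character", table = "data.frame"))

setValidity("FeatureRanking", function(object) {
  if (!object@method %in% c("WR", "IG", "mRMR"))
    return("method must be WR, IG or mRMR")
  tab <- object@table
  if (!all(c("rank", "feature", "statistic", "score") %in% colnames(tab)))
    return("table needs rank/feature/statistic/score columns")
  if (nrow(tab) && !identical(tab$rank, seq_len(nrow(tab))))
    return("ranks must be 1..M in order, without ties")
  if (anyDuplicated(tab$feature)) return("duplicate feature names")
  TRUE
})

#' Trained random-forest site predictor
#'
#' Wraps the fitted ensemble together with the ordered feature subset it was
#' trained on, the decision threshold on the positive-class vote fraction
#' (a sample is called positive when its score is strictly greater than the
#' threshold), and the training seed.
#'
#' @slot forest fitted \code{randomForest} classifier (with forest kept, so
#'   individual trees are accessible for rule extraction).
#' @slot featureNames ordered feature names the model consumes.
#' @slot threshold decision cutoff on the positive vote fraction, in [0,1].
#' @slot seed integer RNG seed used for training.
#'
#' @exportClass NitroModel
setClass("NitroModel",
         representation(forest = "ANY", featureNames = "character",
                        threshold = "numeric", seed = "integer"))

setValidity("NitroModel", function(object) {
  if (!inherits(object@forest, c("randomForest", "priorForest")))
    return("forest must be a randomForest fit (or a degenerate prior model)")
  if (inherits(object@forest, "randomForest") &&
      is.null(object@forest$forest))
    return("forest structure missing (train with keep.forest = TRUE)")
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold > 1)
    return("threshold must be a single value in [0, 1]")
  TRUE
})

#' Conjunctive threshold rule extracted from a decision tree
#'
#' A root-to-leaf path rendered as a conjunction of conditions
#' \code{feature <= t} / \code{feature > t}, predicting one class.
#'
#' @slot conditions data.frame with columns \code{feature}, \code{op}
#'   (\code{"<="} or \code{">"}), \code{threshold}; at most one bound of
#'   each direction per feature (tightest bounds kept).
#' @slot predictedClass class label at the leaf.
#' @slot support number of training samples covered (filled by
#'   \code{\link{greedyCover}}; \code{NA} until then).
#' @slot tree index of the source tree in the forest (0 if hand-built).
#' @slot leaf node index of the source leaf (0 if hand-built).
#'
#' @exportClass Rule
setClass("Rule",
         representation(conditions = "data.frame", predictedClass = "character",
                        support = "integer", tree = "integer",
                        leaf = "integer"),
         prototype(support = NA_integer_, tree = 0L, leaf = 0L))

setValidity("Rule", function(object) {
  cond <- object@conditions
  if (nrow(cond) == 0L) return("a rule must have at least one condition")
  if (!all(c("feature", "op", "threshold") %in% colnames(cond)))
    return("conditions need feature/op/threshold columns")
  if (!all(cond$op %in% c("<=", ">"))) return("ops must be '<=' or '>'")
  # per-feature intervals must be non-empty
  for (f in unique(cond$feature)) {
    sub <- cond[cond$feature == f, ]
    lo <- suppressWarnings(max(sub$threshold[sub$op == ">"], -Inf))
    hi <- suppressWarnings(min(sub$threshold[sub$op == "<="], Inf))
    if (lo >= hi) return(sprintf("contradictory conditions on '%s'", f))
  }
  TRUE
})
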