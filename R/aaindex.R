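#' Default AAindex accession ids
#'
#' Eight physicochemical indices (AAindex release 9.1) covering side-chain
#' volume and composition, hydrophobicity, contact energy and secondary
#' structure propensity, used by the positional physicochemical encoder.
#'
#' @export
DEFAULT_AAINDEX_IDS <- c("LIFS790101", "TSAJ990101", "NAKH920108",
                         "MAXF760101", "BLAM930101", "BIOV880101",
                         "CEDJ970104", "MIYS990104")

#' Look up AAindex physicochemical index values
#'
#' Pulls the requested indices from the AAindex database shipped with the
#' \pkg{seqinr} package and arranges the 20 values per index in canonical
#' residue order \code{ARNDCQEGHILKMFPSTWYV}.
#'
#' @param ids AAindex accession ids (default: the eight curated indices).
#' @param standardize center and scale each index over the 20 residues.
#' @return numeric 20 x length(ids) matrix, rownames the residues, colnames
#'   the ids; \code{NA} table entries are preserved (encoders map them to
#'   0).
#' @examples
#' aaindexTable("BLAM930101")["G", ]
#' @export
aaindexTable <- function(ids = DEFAULT_AAINDEX_IDS, standardize = FALSE) {
  db <- .aaindexDb()
  acc <- vapply(db, function(a) a$H, "")
  hit <- match(ids, acc)
  if (anyNA(hit))
    .stopf("unknown AAindex id(s): %s (available: %d indices in AAindex)",
           paste(ids[is.na(hit)], collapse = ", "), length(db))
  out <- vapply(hit, function(i) unname(db[[i]]$I), numeric(20L))
  # seqinr stores values in three-letter-code order Ala..Val, which is the
  # same residue order as ARNDCQEGHILKMFPSTWYV
  dimnames(out) <- list(AA_ALPHABET20, ids)
  if (standardize)
    out <- scale(out)[, , drop = FALSE]
  out
}

.aaindexDb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("aaindex", package = "seqinr", envir = env)
      cache <<- env$aaindex
    }
    cache
  }
})
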