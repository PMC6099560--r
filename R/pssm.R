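#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard \code{-out_ascii_pssm} layout: a header, then one row
#' per sequence position carrying the position index, the query residue,
#' 20 integer log-odds columns and 20 weighted-percentage columns. Only the
#' first 20 numeric columns (the log-odds) are captured.
#'
#' @param path path to the PSSM file.
#' @param proteinId accession to record; defaults to the file name without
#'   its extension.
#' @return a \code{\linkS4class{ProfileMatrix}}.
#' @export
parsePsiblastPssm <- function(path, proteinId = NULL) {
  if (!file.exists(path)) .stopf("PSSM file not found: %s", path)
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rowpat <- "^\\s*[0-9]+\\s+[A-Z]\\s"
  idx <- grep(rowpat, lines)
  if (length(idx) == 0L)
    .stopf("no PSSM data rows found in %s (truncated or header-only file?)",
           path)
  res <- character(length(idx))
  scores <- matrix(NA_real_, nrow = length(idx), ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_along(idx)) {
    ln <- idx[j]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    pos <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(pos) || pos != j)
      .stopf("PSSM rows out of order at line %d of %s", ln, path)
    res[j] <- tok[2L]
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(vals) < 20L)
      .stopf("expected at least 20 score columns at line %d of %s (got %d)",
             ln, path, length(vals))
    if (anyNA(vals[1:20]))
      .stopf("non-numeric score cell at line %d of %s", ln, path)
    scores[j, ] <- vals[1:20]
  }
  new("ProfileMatrix", proteinId = proteinId, residues = res,
      scores = scores)
}

#' Write a ProfileMatrix in PSI-BLAST ASCII layout
#'
#' Emits a file that \code{\link{parsePsiblastPssm}} round-trips: standard
#' header, one row per position with 20 log-odds columns followed by 20
#' percentage columns (filled with zeros) and the two per-position trailing
#' statistics.
#'
#' @param profile a \code{\linkS4class{ProfileMatrix}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePsiblastPssm <- function(profile, path) {
  sc <- profile@scores
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ",
                      paste(sprintf("%3s", AA_ALPHABET20), collapse = ""),
                      "  ",
                      paste(sprintf("%3s", AA_ALPHABET20), collapse = ""))),
             con)
  for (v in seq_len(nrow(sc))) {
    writeLines(paste0(sprintf("%5d %s ", v, profile@residues[v]),
                      paste(sprintf("%3d", as.integer(round(sc[v, ]))),
                            collapse = ""),
                      "  ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %4.2f %4.2f", 0, 0)),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Database-free pseudo-profile for a sequence
#'
#' Stands in for a PSI-BLAST profile when none is available: in
#' \code{"substitution"} mode each row is the BLOSUM62 row of the residue at
#' that position; in \code{"one-hot"} mode each row is \code{scale} at the
#' residue's own column and 0 elsewhere. Rows for \code{"X"} or \code{"-"}
#' are all-zero.
#'
#' @param sequence protein sequence string.
#' @param mode \code{"substitution"} (default) or \code{"one-hot"}.
#' @param scale scalar weight for one-hot mode (default 1).
#' @param proteinId accession to record.
#' @return a \code{\linkS4class{ProfileMatrix}}.
#' @examples
#' profileScores(pseudoProfile("AY", mode = "one-hot"))
#' @export
pseudoProfile <- function(sequence, mode = c("substitution", "one-hot"),
                          scale = 1, proteinId = "protein") {
  mode <- match.arg(mode)
  sequence <- .normalizeSequence(sequence)
  if (!nzchar(sequence)) .stopf("empty sequence")
  chars <- .splitChars(sequence)[[1L]]
  sc <- matrix(0, nrow = length(chars), ncol = 20L,
               dimnames = list(NULL, AA_ALPHABET20))
  std <- .isStandard(chars)
  if (mode == "substitution") {
    blosum <- .blosum62()
    sc[std, ] <- blosum[chars[std], AA_ALPHABET20]
  } else {
    sc[cbind(which(std), .AA_INDEX[chars[std]])] <- scale
  }
  new("ProfileMatrix", proteinId = proteinId, residues = chars, scores = sc)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Slice a profile to one window, zero-padding out-of-range rows
#'
#' Copies profile rows \code{position - w .. position + w}; rows outside
#' the protein are all-zero and flagged as padded. The profile's residue
#' column is cross-checked against the window peptide.
#'
#' @param profile a \code{\linkS4class{ProfileMatrix}}.
#' @param proteinId,position,peptide the window's identity; normally taken
#'   from a \code{\linkS4class{SiteWindowSet}} row.
#' @return a \code{\linkS4class{WindowProfile}}.
#' @export
sliceWindowProfile <- function(profile, proteinId, position, peptide) {
  if (profile@proteinId != proteinId)
    .stopf("profile is for '%s', window is from '%s'",
           profile@proteinId, proteinId)
  L <- nchar(peptide)
  w <- (L - 1L) %/% 2L
  n <- nrow(profile@scores)
  rows <- (position - w):(position + w)
  inside <- rows >= 1L & rows <= n
  sc <- matrix(0, nrow = L, ncol = 20L,
               dimnames = list(NULL, AA_ALPHABET20))
  sc[inside, ] <- profile@scores[rows[inside], , drop = FALSE]
  chars <- .splitChars(peptide)[[1L]]
  mism <- inside & chars != "-" & chars != "X" &
    profile@residues[pmax(pmin(rows, n), 1L)] != chars
  if (any(mism))
    .stopf("window peptide disagrees with profile sequence for '%s' at %s",
           proteinId, paste(rows[mism], collapse = ", "))
  new("WindowProfile", proteinId = proteinId, position = as.integer(position),
      peptide = peptide, scores = sc, padded = !inside)
}

#' Window profiles for every window of a set
#'
#' Looks up each window's protein profile (by id) and slices it. Proteins
#' without a profile fall back to \code{\link{pseudoProfile}} with a
#' warning.
#'
#' @param x a \code{\linkS4class{SiteWindowSet}}.
#' @param profiles named list of \code{\linkS4class{ProfileMatrix}} objects,
#'   or \code{NULL} to use pseudo-profiles throughout.
#' @param sequences named character vector (or \code{AAStringSet}) of
#'   protein sequences; required for the pseudo-profile fallback.
#' @param pseudoMode mode passed to \code{\link{pseudoProfile}}.
#' @param pseudoScale scale passed to \code{\link{pseudoProfile}}.
#' @return list of \code{\linkS4class{WindowProfile}}, one per window.
#' @export
windowProfiles <- function(x, profiles = NULL, sequences = NULL,
                           pseudoMode = "substitution", pseudoScale = 1) {
  ids <- proteinIds(x)
  if (!is.null(sequences)) {
    nm <- names(sequences)
    sequences <- as.character(sequences)   # strips names on plain vectors
    names(sequences) <- nm
  }
  perProtein <- new.env(parent = emptyenv())
  getProfile <- function(id) {
    if (!is.null(profiles) && id %in% names(profiles))
      return(profiles[[id]])
    if (exists(id, envir = perProtein)) return(get(id, envir = perProtein))
    if (is.null(sequences) || !id %in% names(sequences))
      .stopf("no profile and no sequence for protein '%s'", id)
    .warnf("no PSSM for protein '%s'; using %s pseudo-profile",
           id, pseudoMode)
    p <- pseudoProfile(sequences[[id]], mode = pseudoMode,
                       scale = pseudoScale, proteinId = id)
    assign(id, p, envir = perProtein)
    p
  }
  lapply(seq_len(length(x)), function(i) {
    sliceWindowProfile(getProfile(ids[i]), ids[i], sitePositions(x)[i],
                       peptides(x)[i])
  })
}

#' Per-position average PSSM value (APV)
#'
#' For each window position, the mean over windows and over the 20 residue
#' columns of the profile scores. Padded rows contribute zeros and are
#' included in the mean, mirroring the gap-neutralization rule.
#'
#' @param windowProfiles list of \code{\linkS4class{WindowProfile}} with a
#'   common window length.
#' @return numeric vector of length \code{2*w + 1}, named by offset
#'   \code{-w..+w}.
#' @export
apvProfile <- function(windowProfiles) {
  if (length(windowProfiles) == 0L) .stopf("empty window-profile list")
  L <- unique(vapply(windowProfiles, function(p) nrow(p@scores), 0L))
  if (length(L) != 1L) .stopf("window profiles have unequal lengths")
  acc <- Reduce(`+`, lapply(windowProfiles, function(p) rowMeans(p@scores)))
  apv <- acc / length(windowProfiles)
  w <- (L - 1L) %/% 2L
  names(apv) <- sprintf("%+d", -w:w)
  apv
}

#' Average APV over the upstream and downstream flanks
#'
#' Summarizes a per-position APV vector into two scalars: the mean over
#' upstream offsets \code{[-w, -1]} and over downstream offsets
#' \code{[+1, +w]} (the central residue is excluded).
#'
#' @param apv vector from \code{\link{apvProfile}}.
#' @return named numeric vector \code{c(upstream=, downstream=)}.
#' @export
flankApv <- function(apv) {
  L <- length(apv)
  w <- (L - 1L) %/% 2L
  c(upstream = mean(apv[seq_len(w)]),
    downstream = mean(apv[(w + 2L):L]))
}
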