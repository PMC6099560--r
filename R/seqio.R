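#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased, whitespace-stripped, and non-standard residue
#' codes (B, J, O, U, Z, ...) are collapsed to \code{"X"}. Record order is
#' preserved; the accession is the first whitespace-delimited token of the
#' header.
#'
#' @param path path to a FASTA file.
#' @return a named \code{\link[Biostrings]{AAStringSet}}, one entry per
#'   record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MYAYK", ">p2", "ggyk"), fa)
#' readFastaProteins(fa)
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) .stopf("empty FASTA file: %s", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    .stopf("malformed FASTA: sequence before header at line %d of %s",
           first, path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  if (any(!nzchar(ids))) .stopf("empty FASTA header in %s", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .stopf("duplicate FASTA ids in %s: %s", path, paste(dup, collapse = ", "))
  out <- Biostrings::AAStringSet(.normalizeSequence(as.character(seqs)))
  names(out) <- ids
  if (any(Biostrings::width(out) < 1L)) .stopf("zero-length sequence in %s", path)
  out
}

#' Read site annotations from a 3-column TSV
#'
#' Expected columns (no header): protein id, 1-based position of the
#' annotated tyrosine, label (1 = experimentally verified nitration site,
#' 0 = annotated non-site). Every annotated position must be a tyrosine of
#' a known protein.
#'
#' @param path path to the TSV file.
#' @param proteins optional \code{AAStringSet}; if supplied, annotations are
#'   validated against it (unknown protein, out-of-range position, or a
#'   non-tyrosine residue raise an error).
#' @return data.frame with columns \code{protein_id}, \code{position},
#'   \code{label} (integer 0/1).
#' @export
readSiteAnnotations <- function(path, proteins = NULL) {
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("protein_id", "position", "label"),
                           colClasses = c("character", "integer", "integer"),
                           stringsAsFactors = FALSE)
  if (!all(ann$label %in% c(0L, 1L)))
    .stopf("annotation labels must be 0 or 1 in %s", path)
  if (!is.null(proteins)) {
    unknown <- setdiff(unique(ann$protein_id), names(proteins))
    if (length(unknown))
      .stopf("annotations reference unknown proteins: %s",
             paste(unknown, collapse = ", "))
    seqs <- as.character(proteins)
    for (r in seq_len(nrow(ann))) {
      s <- seqs[[ann$protein_id[r]]]
      p <- ann$position[r]
      if (p < 1L || p > nchar(s))
        .stopf("annotation out of range: %s position %d (length %d)",
               ann$protein_id[r], p, nchar(s))
      if (substr(s, p, p) != "Y")
        .stopf("annotated residue is not 'Y': %s position %d is '%s'",
               ann$protein_id[r], p, substr(s, p, p))
    }
  }
  ann
}

#' Enumerate candidate tyrosine sites in one protein
#'
#' Every tyrosine in the sequence yields a site: annotated positions become
#' positives, all remaining tyrosines negatives.
#'
#' @param sequence protein sequence string.
#' @param positives integer vector of annotated (positive) 1-based
#'   positions; each must point at a \code{"Y"}.
#' @param proteinId accession used in error messages.
#' @return data.frame with columns \code{position}, \code{label}.
#' @examples
#' enumerateTyrosineSites("MYAYK", positives = 2)
#' @export
enumerateTyrosineSites <- function(sequence, positives = integer(0),
                                   proteinId = "protein") {
  sequence <- .normalizeSequence(sequence)
  ypos <- which(.splitChars(sequence)[[1L]] == "Y")
  positives <- as.integer(positives)
  bad <- positives[!(positives %in% ypos)]
  if (length(bad))
    .stopf("annotated position is not a 'Y' (or out of range): %s position %s",
           proteinId, paste(bad, collapse = ", "))
  if (length(ypos) == 0L)
    return(data.frame(position = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  data.frame(position = ypos,
             label = ifelse(ypos %in% positives, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Extract a gap-padded fixed-length window around one position
#'
#' The peptide covers positions \code{position - w .. position + w};
#' positions outside the protein are filled with \code{"-"}, so padding is
#' always a contiguous prefix and/or suffix.
#'
#' @param sequence protein sequence string.
#' @param position 1-based central position.
#' @param w half-width; the peptide has length \code{2*w + 1} (default 20,
#'   giving the 41-mer windows used throughout).
#' @return peptide string of length \code{2*w + 1}.
#' @examples
#' extractWindow("MYA", 2, w = 2)   # "-MYA-"
#' @export
extractWindow <- function(sequence, position, w = 20L) {
  sequence <- .normalizeSequence(sequence)
  n <- nchar(sequence)
  if (position < 1L || position > n)
    .stopf("position %d out of range 1..%d", position, n)
  lo <- position - w
  hi <- position + w
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("-", max(0L, 1L - lo)), core, strrep("-", max(0L, hi - n)))
}

#' Assemble tyrosine-centered windows for a protein collection
#'
#' Enumerates every tyrosine of every protein, labels it from the
#' annotation table, and extracts the \code{2*w + 1} window.
#'
#' @param proteins named \code{AAStringSet} (see
#'   \code{\link{readFastaProteins}}).
#' @param annotations data.frame as returned by
#'   \code{\link{readSiteAnnotations}}; rows with label 1 mark positives.
#' @param w window half-width (default 20).
#' @return a \code{\linkS4class{SiteWindowSet}}.
#' @export
makeSiteWindows <- function(proteins, annotations, w = 20L) {
  if (anyDuplicated(names(proteins)))
    .stopf("duplicate protein ids")
  unknown <- setdiff(unique(annotations$protein_id), names(proteins))
  if (length(unknown))
    .stopf("annotations reference unknown proteins: %s",
           paste(unknown, collapse = ", "))
  seqs <- .normalizeSequence(as.character(proteins))
  names(seqs) <- names(proteins)
  parts <- lapply(names(seqs), function(id) {
    pos1 <- annotations$position[annotations$protein_id == id &
                                 annotations$label == 1L]
    sites <- enumerateTyrosineSites(seqs[[id]], pos1, proteinId = id)
    if (nrow(sites) == 0L) return(NULL)
    data.frame(protein_id = id, position = sites$position,
               peptide = vapply(sites$position,
                                function(p) extractWindow(seqs[[id]], p, w),
                                ""),
               label = sites$label, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, parts)
  if (is.null(win))
    win <- data.frame(protein_id = character(), position = integer(),
                      peptide = character(), label = character(),
                      stringsAsFactors = FALSE)
  new("SiteWindowSet", windows = win, w = as.integer(w))
}

#' Drop peptide-level redundant windows
#'
#' Greedy scan in input order: a window is dropped when its positionwise
#' identity (matching characters over the full window length, padding
#' \code{"-"} counted like any character) with an already-retained window of
#' the same label class reaches the cutoff. Retained windows keep their
#' input order, so the filter is idempotent.
#'
#' @param x a \code{\linkS4class{SiteWindowSet}}.
#' @param identityCutoff fraction in (0, 1]; default 0.40 (a window is
#'   dropped at >= 40\% identity).
#' @return filtered \code{SiteWindowSet}.
#' @export
filterRedundantPeptides <- function(x, identityCutoff = 0.40) {
  pep <- peptides(x)
  if (length(pep) == 0L) return(x)
  L <- unique(nchar(pep))
  if (length(L) != 1L) .stopf("windows have unequal lengths")
  lab <- siteLabels(x)
  chars <- do.call(rbind, .splitChars(pep))  # n x L character matrix
  keep <- logical(length(pep))
  kept <- list(positive = integer(0), negative = integer(0),
               unknown = integer(0))
  for (i in seq_along(pep)) {
    prior <- kept[[lab[i]]]
    drop <- FALSE
    if (length(prior)) {
      same <- chars[prior, , drop = FALSE] ==
        matrix(chars[i, ], nrow = length(prior), ncol = L, byrow = TRUE)
      if (any(rowSums(same) / L >= identityCutoff)) drop <- TRUE
    }
    if (!drop) {
      keep[i] <- TRUE
      kept[[lab[i]]] <- c(prior, i)
    }
  }
  x[keep]
}

#' Balance positive and negative windows at a target ratio
#'
#' All positives are retained; negatives are drawn uniformly without
#' replacement to reach the requested positive:negative ratio. Ratio
#' \code{"1:all"} keeps every negative. If fewer negatives exist than the
#' ratio requires, all are kept with a warning.
#'
#' @param x a \code{\linkS4class{SiteWindowSet}} with both classes present.
#' @param ratio one of \code{"1:1"}, \code{"1:2"}, \code{"1:3"},
#'   \code{"1:all"}.
#' @param seed integer RNG seed; the same seed reproduces the same subset.
#' @return balanced \code{SiteWindowSet}; the realized ratio and seed are
#'   recorded in its metadata.
#' @export
balanceSample <- function(x, ratio = c("1:1", "1:2", "1:3", "1:all"),
                          seed = 1L) {
  ratio <- match.arg(ratio)
  lab <- siteLabels(x)
  ipos <- which(lab == "positive")
  ineg <- which(lab == "negative")
  if (length(ipos) == 0L || length(ineg) == 0L)
    .stopf("both classes must be present to balance")
  if (ratio == "1:all") {
    isel <- ineg
  } else {
    mult <- as.integer(sub("^1:", "", ratio))
    want <- mult * length(ipos)
    if (want > length(ineg)) {
      .warnf("ratio %s requires %d negatives but only %d exist; keeping all",
             ratio, want, length(ineg))
      isel <- ineg
    } else {
      isel <- .withSeed(seed, sample(ineg, want))
    }
  }
  out <- x[sort(c(ipos, isel))]
  out@metadata <- c(x@metadata, list(ratio = ratio, seed = as.integer(seed)))
  out
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a window manifest as TSV
#'
#' @param x a \code{\linkS4class{SiteWindowSet}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeWindowManifest <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
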