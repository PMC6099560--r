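#' Encoder configuration
#'
#' @param kMax largest pair spacing (default 4, giving five k blocks 0..4).
#' @param w window half-width (default 20, window length 41).
#' @param aaindexIds AAindex accession ids used by the physicochemical
#'   encoder (default: the eight curated indices).
#' @param clipNegative clip each pair's profile contribution at zero
#'   (default TRUE; the composition formula's \code{max(., 0)}).
#' @param dense use the dense profile-pair variant that sums the clipped
#'   min over every position pair for every residue pair, instead of gating
#'   on the literal occurrences of the pair in the peptide (default FALSE).
#' @param standardizeAaindex standardize each AAindex index to zero mean and
#'   unit variance over the 20 residues before encoding (default FALSE; raw
#'   table values).
#' @return a list of class \code{"EncoderConfig"}.
#' @export
encoderConfig <- function(kMax = 4L, w = 20L,
                          aaindexIds = DEFAULT_AAINDEX_IDS,
                          clipNegative = TRUE, dense = FALSE,
                          standardizeAaindex = FALSE) {
  kMax <- as.integer(kMax)
  w <- as.integer(w)
  if (kMax < 0L) .stopf("kMax must be >= 0")
  if (2L * w + 1L <= kMax + 1L) .stopf("window too short for kMax = %d", kMax)
  structure(list(kMax = kMax, w = w, aaindexIds = aaindexIds,
                 clipNegative = clipNegative, dense = dense,
                 standardizeAaindex = standardizeAaindex),
            class = "EncoderConfig")
}

#' Canonical names for k-spaced pair features
#'
#' Pair \code{(qi, qj)} at spacing k is named
#' \code{"<prefix>:<qi><x repeated k times><qj>"}, e.g. \code{"pb:AxxxxK"}
#' for the k = 4 pair A..K. Order: k ascending, then first residue, then
#' second residue, both in canonical alphabet order.
#'
#' @param prefix \code{"pb"} (profile-weighted) or \code{"ks"} (counts).
#' @param kMax largest spacing.
#' @return character vector of length \code{400 * (kMax + 1)}.
#' @export
pairFeatureNames <- function(prefix = "pb", kMax = 4L) {
  unlist(lapply(0:kMax, function(k) {
    as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, function(a, b)
      paste0(prefix, ":", a, strrep("x", k), b))))
  }))
}

# names for positional encoders: "<prefix>:<+offset>:<channel>"
.positionalNames <- function(prefix, w, channels) {
  offs <- sprintf("%+d", -w:w)
  as.vector(t(outer(offs, channels, function(o, c)
    paste0(prefix, ":", o, ":", c))))
}

# Shared pair enumeration: for each k, the valid (v, v+k+1) index pairs of
# a peptide, with both partners standard residues.
.pairOccurrences <- function(chars, k) {
  L <- length(chars)
  if (L < k + 2L) return(NULL)
  v <- seq_len(L - k - 1L)
  a <- chars[v]
  b <- chars[v + k + 1L]
  ok <- .isStandard(a) & .isStandard(b)
  if (!any(ok)) return(NULL)
  list(v = v[ok], a = a[ok], b = b[ok])
}

#' Profile-weighted k-spaced amino-acid-pair composition (pbCKSAAP)
#'
#' For each spacing k in \code{0..kMax} and each ordered residue pair
#' \code{(qi, qj)}, sums over the occurrences of the literal pair
#' \code{qi{k}qj} in the peptide (positions v with \code{peptide[v] = qi}
#' and \code{peptide[v+k+1] = qj}, neither a gap or \code{X}) the clipped
#' minimum \code{max(min(PSSM(v, qi), PSSM(v+k+1, qj)), 0)}, and divides by
#' \code{L - k - 1} with L the full (padded) window length. With
#' \code{cfg$dense = TRUE} the sum instead runs over every position pair
#' for every residue pair, regardless of the letters actually present.
#'
#' @param peptide window peptide string (length \code{2*w + 1}).
#' @param profile a \code{\linkS4class{WindowProfile}} aligned to the
#'   peptide, or its \eqn{L \times 20} score matrix.
#' @param cfg an \code{\link{encoderConfig}}.
#' @return named numeric vector of length \code{400 * (kMax + 1)} (2000 at
#'   the defaults).
#' @export
encodePbCksaap <- function(peptide, profile, cfg = encoderConfig()) {
  sc <- if (is(profile, "WindowProfile")) profile@scores else profile
  chars <- .splitChars(peptide)[[1L]]
  L <- length(chars)
  if (nrow(sc) != L)
    .stopf("profile has %d rows but peptide has %d positions", nrow(sc), L)
  if (is(profile, "WindowProfile") && profile@peptide != peptide)
    .stopf("profile/window peptide mismatch")
  out <- numeric(400L * (cfg$kMax + 1L))
  names(out) <- pairFeatureNames("pb", cfg$kMax)
  for (k in 0:cfg$kMax) {
    denom <- L - k - 1L
    if (cfg$dense) {
      v <- seq_len(L - k - 1L)
      # clipped min over all position pairs, accumulated per residue pair
      s1 <- sc[v, , drop = FALSE]
      s2 <- sc[v + k + 1L, , drop = FALSE]
      block <- matrix(0, 20L, 20L)
      for (ii in seq_len(length(v))) {
        m <- outer(s1[ii, ], s2[ii, ], pmin)
        if (cfg$clipNegative) m[m < 0] <- 0
        block <- block + m
      }
      out[k * 400L + seq_len(400L)] <- as.vector(t(block)) / denom
    } else {
      occ <- .pairOccurrences(chars, k)
      if (is.null(occ)) next
      s <- pmin(sc[cbind(occ$v, .AA_INDEX[occ$a])],
                sc[cbind(occ$v + k + 1L, .AA_INDEX[occ$b])])
      if (cfg$clipNegative) s <- pmax(s, 0)
      cell <- (.AA_INDEX[occ$a] - 1L) * 20L + .AA_INDEX[occ$b]
      block <- numeric(400L)
      agg <- rowsum(s, cell)
      block[as.integer(rownames(agg))] <- agg[, 1L]
      out[k * 400L + seq_len(400L)] <- block / denom
    }
  }
  out
}

#' k-spaced amino-acid-pair composition (KSAAP)
#'
#' Counts, for each spacing k and ordered residue pair, the occurrences of
#' the pair in the peptide (gap/\code{X} positions excluded) and divides by
#' \code{L - k - 1}.
#'
#' @inheritParams encodePbCksaap
#' @return named numeric vector of length \code{400 * (kMax + 1)}.
#' @examples
#' v <- encodeKsaap("AKAKA", encoderConfig(kMax = 1, w = 2))
#' v[v > 0]
#' @export
encodeKsaap <- function(peptide, cfg = encoderConfig()) {
  chars <- .splitChars(peptide)[[1L]]
  L <- length(chars)
  out <- numeric(400L * (cfg$kMax + 1L))
  names(out) <- pairFeatureNames("ks", cfg$kMax)
  for (k in 0:cfg$kMax) {
    occ <- .pairOccurrences(chars, k)
    if (is.null(occ)) next
    cell <- (.AA_INDEX[occ$a] - 1L) * 20L + .AA_INDEX[occ$b]
    counts <- tabulate(cell, nbins = 400L)
    out[k * 400L + seq_len(400L)] <- counts / (L - k - 1L)
  }
  out
}

#' Binary (one-hot) positional encoding
#'
#' Each position contributes a 20-length indicator of its residue in
#' canonical alphabet order; gaps and \code{X} give an all-zero block.
#'
#' @param peptide window peptide string.
#' @return named numeric vector of length \code{20 * nchar(peptide)} (820
#'   for 41-mers).
#' @export
encodeBinary <- function(peptide) {
  chars <- .splitChars(peptide)[[1L]]
  L <- length(chars)
  w <- (L - 1L) %/% 2L
  out <- numeric(20L * L)
  names(out) <- .positionalNames("be", w, AA_ALPHABET20)
  std <- which(.isStandard(chars))
  out[(std - 1L) * 20L + .AA_INDEX[chars[std]]] <- 1
  out
}

#' AAindex physicochemical positional encoding
#'
#' Each position contributes the values of the configured AAindex indices
#' for its residue; gaps, \code{X}, and table \code{NA} entries give 0.
#'
#' @param peptide window peptide string.
#' @param cfg an \code{\link{encoderConfig}}; \code{cfg$aaindexIds} selects
#'   the indices.
#' @return named numeric vector of length
#'   \code{length(aaindexIds) * nchar(peptide)} (328 at the defaults).
#' @export
encodeAaindex <- function(peptide, cfg = encoderConfig()) {
  tab <- aaindexTable(cfg$aaindexIds,
                      standardize = isTRUE(cfg$standardizeAaindex))
  chars <- .splitChars(peptide)[[1L]]
  L <- length(chars)
  w <- (L - 1L) %/% 2L
  nIdx <- ncol(tab)
  out <- matrix(0, nrow = L, ncol = nIdx)
  std <- .isStandard(chars)
  out[std, ] <- tab[chars[std], , drop = FALSE]
  out[is.na(out)] <- 0
  res <- as.vector(t(out))
  names(res) <- .positionalNames("aa", w, colnames(tab))
  res
}

#' Encode every window of a set into a feature matrix
#'
#' @param x a \code{\linkS4class{SiteWindowSet}}.
#' @param encoder one of \code{"pbcksaap"}, \code{"ksaap"}, \code{"binary"},
#'   \code{"aaindex"}.
#' @param profiles list of \code{\linkS4class{WindowProfile}} aligned to
#'   \code{x} (required for \code{"pbcksaap"}).
#' @param cfg an \code{\link{encoderConfig}}.
#' @return numeric matrix, one row per window (rownames
#'   \code{protein:position}), columns in canonical feature order.
#' @export
encodeWindows <- function(x, encoder = c("pbcksaap", "ksaap", "binary",
                                         "aaindex"),
                          profiles = NULL, cfg = encoderConfig()) {
  encoder <- match.arg(encoder)
  pep <- peptides(x)
  if (encoder == "pbcksaap") {
    if (is.null(profiles) || length(profiles) != length(pep))
      .stopf("pbcksaap needs one WindowProfile per window")
    rows <- lapply(seq_along(pep), function(i)
      encodePbCksaap(pep[i], profiles[[i]], cfg))
  } else {
    fn <- switch(encoder,
                 ksaap = function(p) encodeKsaap(p, cfg),
                 binary = encodeBinary,
                 aaindex = function(p) encodeAaindex(p, cfg))
    rows <- lapply(pep, fn)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- paste0(proteinIds(x), ":", sitePositions(x))
  mat
}
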