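#' Specification for the synthetic benchmark generator
#'
#' Describes a fully seeded synthetic dataset: proteins with tyrosine
#' sites, a planted sequence motif around positive sites, and
#' PSI-BLAST-style PSSM files with controllable conservation. The defaults
#' emulate the qualitative structure of curated nitration data: a modest
#' enrichment of K, V and G in the immediate flanks of modified tyrosines
#' and elevated evolutionary conservation at the informative positions.
#'
#' @param nProteins number of proteins (default 500).
#' @param lengthRange min/max protein length (default 80-160).
#' @param sitesPerProtein min/max tyrosine sites per protein (default 2-4).
#' @param posFraction probability that a site is a (planted) positive
#'   (default 0.5).
#' @param motif data.frame with columns \code{offset} (relative to the
#'   central Y, within \code{-w..+w}), \code{residue}, \code{prob}
#'   (planting probability). Default: G at -2 (0.85), K at -1 (0.90),
#'   V at +1 (0.85).
#' @param w window half-width the motif must fit (default 20).
#' @param conservation PSSM log-odds scale at planted motif positions and
#'   positive-site centers (default 8).
#' @param baseScale PSSM log-odds scale at background positions (default
#'   4).
#' @param noiseSd sd of the Gaussian noise added to PSSM cells before
#'   rounding (default 2).
#' @param background \code{"uniform"} residue usage (default) or
#'   \code{"natural"} (approximate database frequencies).
#' @param seed integer seed; generation is fully determined by it.
#' @return a list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(nProteins = 500L, lengthRange = c(80L, 160L),
                        sitesPerProtein = c(2L, 4L), posFraction = 0.5,
                        motif = data.frame(
                          offset = c(-2L, -1L, 1L),
                          residue = c("G", "K", "V"),
                          prob = c(0.85, 0.90, 0.85),
                          stringsAsFactors = FALSE),
                        w = 20L, conservation = 8, baseScale = 4,
                        noiseSd = 2, background = c("uniform", "natural"),
                        seed = 7L) {
  background <- match.arg(background)
  if (any(abs(motif$offset) > w))
    .stopf("motif offsets must lie within the window (-%d..+%d)", w, w)
  if (any(motif$prob < 0 | motif$prob > 1))
    .stopf("motif probabilities must be in [0, 1]")
  if (any(motif$offset == 0L))
    .stopf("offset 0 is the central tyrosine and cannot carry a motif")
  if (!all(motif$residue %in% AA_ALPHABET20))
    .stopf("motif residues must be standard amino acids")
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 sitesPerProtein = as.integer(sitesPerProtein),
                 posFraction = posFraction, motif = motif, w = as.integer(w),
                 conservation = conservation, baseScale = baseScale,
                 noiseSd = noiseSd, background = background,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

# approximate database residue frequencies (Robinson-Robinson style),
# canonical order ARNDCQEGHILKMFPSTWYV
.NATURAL_FREQ <- c(0.078, 0.051, 0.045, 0.054, 0.019, 0.043, 0.063, 0.074,
                   0.022, 0.051, 0.091, 0.057, 0.022, 0.039, 0.052, 0.071,
                   0.058, 0.013, 0.032, 0.064)

#' Generate a synthetic benchmark (FASTA + sites TSV + PSSM directory)
#'
#' Proteins are drawn residue-iid from the background distribution (Y
#' placed only at the designated sites); around each positive site the
#' motif residues are planted with their probabilities. PSSMs are written
#' in PSI-BLAST ASCII layout as scaled one-hot profiles plus rounded
#' Gaussian noise, clipped to [-8, 12]; planted motif positions and
#' positive-site centers use the elevated \code{conservation} scale.
#' Re-running with the same spec reproduces byte-identical files.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return list with paths \code{fasta}, \code{sites}, \code{pssmDir}.
#' @export
generateBenchmark <- function(spec, dir = tempfile("benchmark")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssmDir <- file.path(dir, "pssm")
  dir.create(pssmDir, showWarnings = FALSE)
  freq <- if (spec$background == "uniform") rep(1 / 20, 20) else .NATURAL_FREQ
  # background letters exclude Y so candidate sites are exactly the planted Ys
  bgLetters <- setdiff(AA_ALPHABET20, "Y")
  bgFreq <- freq[match(bgLetters, AA_ALPHABET20)]
  bgFreq <- bgFreq / sum(bgFreq)
  .withSeed(spec$seed, {
    seqs <- character(spec$nProteins)
    ids <- sprintf("SYN%04d", seq_len(spec$nProteins))
    ann <- vector("list", spec$nProteins)
    # sites are spaced so that no window contains another site's planted
    # residues (or another tyrosine): negatives stay background by
    # construction
    motifReach <- if (nrow(spec$motif)) max(abs(spec$motif$offset)) else 0L
    minSpacing <- spec$w + motifReach + 1L
    for (i in seq_len(spec$nProteins)) {
      L <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], 1L)
      chars <- sample(bgLetters, L, replace = TRUE, prob = bgFreq)
      nSites <- sample(spec$sitesPerProtein[1L]:spec$sitesPerProtein[2L], 1L)
      margin <- max(3L, motifReach)
      avail <- sample(seq(margin + 1L, L - margin))
      sites <- integer(0)
      for (p in avail) {
        if (length(sites) >= nSites) break
        if (all(abs(p - sites) >= minSpacing)) sites <- c(sites, p)
      }
      sites <- sort(sites)
      nSites <- length(sites)
      chars[sites] <- "Y"
      lab <- stats::rbinom(nSites, 1L, spec$posFraction)
      conserved <- sites[lab == 1L]
      for (s in sites[lab == 1L]) {
        for (r in seq_len(nrow(spec$motif))) {
          tpos <- s + spec$motif$offset[r]
          if (tpos < 1L || tpos > L || chars[tpos] == "Y") next
          if (stats::runif(1L) < spec$motif$prob[r]) {
            chars[tpos] <- spec$motif$residue[r]
            conserved <- c(conserved, tpos)
          }
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      ann[[i]] <- data.frame(protein_id = ids[i], position = sites,
                             label = lab, stringsAsFactors = FALSE)
      # PSSM: scaled one-hot + rounded noise, clipped to the log-odds range
      scale <- rep(spec$baseScale, L)
      scale[conserved] <- spec$conservation
      sc <- matrix(stats::rnorm(L * 20L, 0, spec$noiseSd), nrow = L)
      sc[cbind(seq_len(L), .AA_INDEX[chars])] <-
        scale + stats::rnorm(L, 0, spec$noiseSd / 2)
      sc <- pmin(pmax(round(sc), -8), 12)
      colnames(sc) <- AA_ALPHABET20
      writePsiblastPssm(new("ProfileMatrix", proteinId = ids[i],
                            residues = chars, scores = sc),
                        file.path(pssmDir, paste0(ids[i], ".pssm")))
    }
    fasta <- file.path(dir, "proteins.fasta")
    writeLines(paste0(">", ids, "\n", seqs), fasta)
    sites <- file.path(dir, "sites.tsv")
    annAll <- do.call(rbind, ann)
    utils::write.table(annAll, sites, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(fasta = fasta, sites = sites, pssmDir = pssmDir)
  })
}

#' Planted informative pair features implied by a fixture spec
#'
#' Enumerates the k-spaced residue-pair features that the planted motif
#' makes informative: every ordered pair of planted offsets (including the
#' central tyrosine) whose spacing fits \code{k <= kMax}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param kMax largest spacing considered (default 4).
#' @return data.frame with columns \code{first}, \code{k}, \code{second},
#'   \code{pb}, \code{ks} (canonical feature names); zero rows for an
#'   empty motif.
#' @examples
#' truthTable(fixtureSpec(motif = data.frame(offset = -1L, residue = "K",
#'                                           prob = 1)))
#' @export
truthTable <- function(spec, kMax = 4L) {
  stopifnot(inherits(spec, "FixtureSpec"))
  pts <- rbind(spec$motif[, c("offset", "residue")],
               data.frame(offset = 0L, residue = "Y",
                          stringsAsFactors = FALSE))
  pts <- pts[order(pts$offset), , drop = FALSE]
  out <- NULL
  n <- nrow(pts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- pts$offset[j] - pts$offset[i]
      if (d >= 1L && d <= kMax + 1L) {
        k <- d - 1L
        out <- rbind(out, data.frame(
          first = pts$residue[i], k = k, second = pts$residue[j],
          pb = paste0("pb:", pts$residue[i], strrep("x", k),
                      pts$residue[j]),
          ks = paste0("ks:", pts$residue[i], strrep("x", k),
                      pts$residue[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(first = character(), k = integer(),
                      second = character(), pb = character(),
                      ks = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate, ingest and encode a benchmark in one step
#'
#' Convenience wrapper: writes the synthetic files, reads them back through
#' the standard ingest path (FASTA, sites TSV, PSSM parser), balances the
#' classes 1:1, optionally subsamples a fixed number of windows per class,
#' and encodes the windows.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param nPerClass windows to keep per class (default \code{NULL}: keep
#'   the full balanced set); subsampling is seeded by \code{spec$seed}.
#' @param encoder encoder id passed to \code{\link{encodeWindows}}.
#' @param dir where to write the files (default: a temporary directory).
#' @return list with \code{features} (matrix), \code{labels},
#'   \code{windows} (\code{\linkS4class{SiteWindowSet}}), \code{profiles}
#'   (list of \code{\linkS4class{WindowProfile}}, or \code{NULL}),
#'   \code{paths}, and \code{spec}.
#' @export
benchmarkDataset <- function(spec = fixtureSpec(), nPerClass = NULL,
                             encoder = "pbcksaap",
                             dir = tempfile("benchmark")) {
  paths <- generateBenchmark(spec, dir)
  proteins <- readFastaProteins(paths$fasta)
  ann <- readSiteAnnotations(paths$sites, proteins)
  sws <- makeSiteWindows(proteins, ann, w = spec$w)
  sws <- balanceSample(sws, "1:1", seed = spec$seed)
  if (!is.null(nPerClass)) {
    lab <- siteLabels(sws)
    if (min(table(lab)) < nPerClass)
      .stopf("benchmark yields %d windows in the smaller class; %d requested",
             min(table(lab)), nPerClass)
    keep <- .withSeed(spec$seed + 1L,
                      c(sample(which(lab == "positive"), nPerClass),
                        sample(which(lab == "negative"), nPerClass)))
    sws <- sws[sort(keep)]
  }
  profs <- NULL
  if (encoder == "pbcksaap") {
    pms <- .loadProfiles(unique(proteinIds(sws)), paths$pssmDir)
    profs <- windowProfiles(sws, pms)
  }
  cfg <- encoderConfig(w = spec$w)
  feats <- encodeWindows(sws, encoder = encoder, profiles = profs,
                         cfg = cfg)
  list(features = feats, labels = siteLabels(sws), windows = sws,
       profiles = profs, paths = paths, spec = spec)
}
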