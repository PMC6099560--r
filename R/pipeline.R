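#' Pipeline run configuration
#'
#' Bundles the end-to-end settings: window half-width 20 (41-mers), pair
#' spacings up to k = 4, profile-weighted pair encoding, Wilcoxon rank-sum
#' top-200 selection nested inside 10-fold cross-validation, 1:1
#' balancing, and a decision threshold anchored at 90\% specificity.
#'
#' @param fasta,sites,pssmDir,outDir input/output paths (\code{pssmDir}
#'   may be \code{NULL}: pseudo-profiles are then used with a warning).
#' @param w window half-width.
#' @param kMax largest pair spacing.
#' @param encoder feature encoder id.
#' @param selectionMethod \code{"WR"}, \code{"IG"} or \code{"mRMR"}.
#' @param nSelect selected feature count (\code{NULL} disables selection).
#' @param ratio positive:negative balancing ratio.
#' @param kFolds cross-validation folds.
#' @param spTarget specificity anchor.
#' @param nTrees forest size.
#' @param redundancyFilter apply the 40\% peptide-identity filter.
#' @param globalSelection select features once on the full balanced set
#'   instead of inside each fold (the whole-training-set protocol; leaks
#'   selection information into the CV estimate).
#' @param ruleTrees number of trees mined for rules (default 25; rule
#'   counts grow linearly with trees).
#' @param seed master seed.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(fasta = NULL, sites = NULL, pssmDir = NULL,
                      outDir = NULL, w = 20L, kMax = 4L,
                      encoder = "pbcksaap", selectionMethod = "WR",
                      nSelect = 200L, ratio = "1:1", kFolds = 10L,
                      spTarget = 0.90, nTrees = 500L,
                      redundancyFilter = FALSE, globalSelection = FALSE,
                      ruleTrees = 25L, seed = 7L) {
  structure(list(fasta = fasta, sites = sites, pssmDir = pssmDir,
                 outDir = outDir, w = as.integer(w), kMax = as.integer(kMax),
                 encoder = encoder, selectionMethod = selectionMethod,
                 nSelect = nSelect, ratio = ratio, kFolds = as.integer(kFolds),
                 spTarget = spTarget, nTrees = as.integer(nTrees),
                 redundancyFilter = redundancyFilter,
                 globalSelection = globalSelection,
                 ruleTrees = as.integer(ruleTrees), seed = as.integer(seed)),
            class = "RunConfig")
}

.loadProfiles <- function(ids, pssmDir) {
  if (is.null(pssmDir)) return(list())
  found <- list()
  for (id in ids) {
    f <- file.path(pssmDir, paste0(id, ".pssm"))
    if (file.exists(f)) found[[id]] <- parsePsiblastPssm(f, proteinId = id)
  }
  found
}

.logStage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Train the full prediction pipeline
#'
#' Runs windows -> profiles -> encoding -> cross-validated evaluation with
#' (nested) feature selection -> final fit on the full balanced set ->
#' specificity-anchored threshold -> rule extraction, writing the window
#' manifest, metrics, ROC points, rule report and serialized model to
#' \code{config$outDir} when set.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose log per-stage counts (default TRUE).
#' @return invisibly, a list with \code{model}
#'   (\code{\linkS4class{NitroModel}}), \code{cv} (from
#'   \code{\link{kfoldCV}}), \code{ranking}, \code{selected},
#'   \code{rules} (greedy cover report), \code{windows}, \code{features}.
#' @export
runTrain <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  proteins <- readFastaProteins(config$fasta)
  ann <- readSiteAnnotations(config$sites, proteins)
  .logStage(verbose, "read %d proteins, %d annotations", length(proteins),
            nrow(ann))
  sws <- makeSiteWindows(proteins, ann, w = config$w)
  .logStage(verbose, "enumerated %d tyrosine windows (%d positive)",
            length(sws), sum(siteLabels(sws) == "positive"))
  if (config$redundancyFilter) {
    sws <- filterRedundantPeptides(sws)
    .logStage(verbose, "redundancy filter retained %d windows", length(sws))
  }
  sws <- balanceSample(sws, ratio = config$ratio, seed = config$seed)
  .logStage(verbose, "balanced (%s): %d windows", config$ratio, length(sws))
  profiles <- .loadProfiles(unique(proteinIds(sws)), config$pssmDir)
  if (length(profiles) == 0L && !is.null(config$pssmDir))
    .warnf("no PSSM files found under %s; falling back to pseudo-profiles",
           config$pssmDir)
  cfg <- encoderConfig(kMax = config$kMax, w = config$w)
  wps <- if (config$encoder == "pbcksaap") {
    suppressWarnings(windowProfiles(sws, profiles,
                                    sequences = as.character(proteins)))
  } else NULL
  features <- encodeWindows(sws, encoder = config$encoder, profiles = wps,
                            cfg = cfg)
  labels <- siteLabels(sws)
  .logStage(verbose, "encoded %d x %d feature matrix", nrow(features),
            ncol(features))
  cv <- kfoldCV(features, labels, k = config$kFolds,
                nestedSelection = !config$globalSelection,
                nSelect = config$nSelect, spTarget = config$spTarget,
                nTrees = config$nTrees, seed = config$seed)
  .logStage(verbose, "%d-fold CV mean AUC %.3f", config$kFolds,
            cv$meanMetrics[["AUC"]])
  ranking <- switch(config$selectionMethod,
                    WR = rankFeaturesWR(features, labels),
                    IG = rankFeaturesIG(features, labels),
                    mRMR = rankFeaturesMRMR(features, labels,
                                            n = config$nSelect))
  selected <- if (is.null(config$nSelect) ||
                  config$nSelect >= ncol(features)) colnames(features)
              else selectTop(ranking, config$nSelect)
  model <- trainRF(features[, selected, drop = FALSE], labels,
                   nTrees = config$nTrees, seed = config$seed)
  oob <- modelForest(model)$votes[, "positive"]
  modelThreshold(model) <- thresholdAtSpecificity(oob, labels,
                                                  config$spTarget)
  .logStage(verbose, "final model: %d features, threshold %.3f",
            length(selected), modelThreshold(model))
  rules <- extractPaths(model, "positive", maxTrees = config$ruleTrees)
  cover <- greedyCover(rules, features[, selected, drop = FALSE], labels)
  .logStage(verbose, "extracted %d rules; greedy cover kept %d",
            length(rules), nrow(cover))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeWindowManifest(sws, file.path(config$outDir, "windows.tsv"))
    writeRanking(ranking, file.path(config$outDir, "ranking.tsv"))
    utils::write.table(cv$folds, file.path(config$outDir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cv$pooled$roc, file.path(config$outDir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRuleReport(cover, file.path(config$outDir, "rules.tsv"))
    saveRDS(list(model = model, config = config),
            file.path(config$outDir, "model.rds"))
  }
  invisible(list(model = model, cv = cv, ranking = ranking,
                 selected = selected, rules = cover, windows = sws,
                 features = features))
}

#' Score every tyrosine of new proteins
#'
#' Extracts a window around each tyrosine, encodes it with the model's
#' configuration, and reports the positive vote fraction and the call at
#' the stored threshold.
#'
#' @param model a \code{\linkS4class{NitroModel}}, or the path to a
#'   \code{model.rds} archive written by \code{\link{runTrain}}.
#' @param fasta FASTA file of query proteins.
#' @param pssmDir optional directory of \code{<id>.pssm} files.
#' @param config a \code{\link{runConfig}} describing the encoding; taken
#'   from the archive when \code{model} is a path.
#' @param out optional TSV output path.
#' @return data.frame with columns \code{protein}, \code{position},
#'   \code{peptide}, \code{score}, \code{call}.
#' @export
runPredict <- function(model, fasta, pssmDir = NULL, config = runConfig(),
                       out = NULL) {
  if (is.character(model)) {
    archive <- readRDS(model)
    config <- archive$config
    model <- archive$model
  }
  proteins <- readFastaProteins(fasta)
  if (length(proteins) == 0L) .stopf("no proteins in %s", fasta)
  empty <- data.frame(protein_id = character(), position = integer(),
                      label = integer())
  sws <- makeSiteWindows(proteins, empty, w = config$w)
  if (length(sws) == 0L)
    return(data.frame(protein = character(), position = integer(),
                      peptide = character(), score = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  profiles <- .loadProfiles(unique(proteinIds(sws)), pssmDir)
  cfg <- encoderConfig(kMax = config$kMax, w = config$w)
  wps <- if (config$encoder == "pbcksaap") {
    suppressWarnings(windowProfiles(sws, profiles,
                                    sequences = as.character(proteins)))
  } else NULL
  features <- encodeWindows(sws, encoder = config$encoder, profiles = wps,
                            cfg = cfg)
  sc <- predictScores(model, features)
  res <- data.frame(protein = proteinIds(sws), position = sitePositions(sws),
                    peptide = peptides(sws), score = sc,
                    call = ifelse(sc > modelThreshold(model), "positive",
                                  "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
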