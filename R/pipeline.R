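#' Run the full analysis end to end
#'
#' Orchestrates the complete study on a dataset: curation (nanobody,
#' homology and middle-drop-out filters), featurization into the enabled
#' feature sets, per-set repeated cross-validated classification, the
#' combined classifier on the top features from every set, and the
#' label-randomization control. Deterministic given the seeds in the
#' configurations.
#'
#' @param dataset list of \linkS4class{AbAgComplex} with KD annotations, or
#'   NULL to generate one from \code{generatorCfg}.
#' @param generatorCfg a \code{\link{generatorConfig}} used when
#'   \code{dataset} is NULL.
#' @param curationCfg a \code{\link{curationConfig}}.
#' @param cvCfg a \code{\link{cvConfig}}.
#' @param sets feature sets to compute (adapter sets are skipped unless
#'   their inputs are given).
#' @param propensity propensity matrix for the AIF set; when NULL and AIF
#'   is enabled, one is trained on an independent synthetic reference set
#'   seeded from \code{cvCfg$seed}.
#' @param residueScores,energetics,classAnnotation adapter inputs (see
#'   \code{\link{assembleFeatureTable}}).
#' @param kPerSetCombined features per set for the combined classifier
#'   (default 2, giving 16 features over the eight sets).
#' @param runControl also run the label-randomization control on the
#'   combined features (default TRUE).
#' @param outDir optional directory; when given, the curation report,
#'   feature table and a JSON results summary are written there.
#' @return list with \code{curated}, \code{featureTable}, \code{reports}
#'   (named list of \linkS4class{CVReport}, one per set plus
#'   \code{combined}), \code{control} (randomization-control report or
#'   NULL), \code{summary} (per-set median AUROC/F1 data.frame) and
#'   \code{flagged} (recurrently misclassified complex ids).
#' @export
runEndToEnd <- function(dataset = NULL, generatorCfg = generatorConfig(),
                        curationCfg = curationConfig(),
                        cvCfg = cvConfig(),
                        sets = c("aa_counts", "aa_counts_CDR",
                                 "num_multivalent", "Ab_info", "SIN",
                                 "AIF"),
                        propensity = NULL, residueScores = NULL,
                        energetics = NULL, classAnnotation = NULL,
                        kPerSetCombined = 2, runControl = TRUE,
                        outDir = NULL) {
  if (is.null(dataset)) dataset <- generateDataset(generatorCfg)$complexes
  curated <- curateDataset(dataset, curationCfg)
  if (length(curated$dataset) < 2 * cvCfg$nFolds)
    stop("curated dataset too small for ", cvCfg$nFolds, "-fold CV (",
         length(curated$dataset), " complexes)")
  if ("AIF" %in% sets && is.null(propensity))
    propensity <- trainPropensity(
      generateReferenceSet(20, 50, seed = cvCfg$seed))
  ft <- assembleFeatureTable(curated$dataset, sets = sets,
                             propensity = propensity,
                             residueScores = residueScores,
                             energetics = energetics,
                             classAnnotation = classAnnotation)
  labels <- curated$labels
  reports <- list()
  for (s in featureSetNames(ft)) {
    m <- getFeatureSet(ft, s)
    keep <- stats::complete.cases(m)
    if (sum(keep) < 2 * cvCfg$nFolds) next
    reports[[s]] <- runCV(m[keep, , drop = FALSE], labels[keep], cvCfg)
  }
  combinedNames <- combinedSelect(ft, labels, kPerSet = kPerSetCombined)
  full <- featureMatrix(ft)[, combinedNames, drop = FALSE]
  keep <- stats::complete.cases(full)
  combCfg <- cvCfg
  combCfg$selectorK <- length(combinedNames)
  reports$combined <- runCV(full[keep, , drop = FALSE], labels[keep],
                            combCfg)
  control <- if (runControl)
    randomizationControl(full[keep, , drop = FALSE], labels[keep], combCfg)
  else NULL
  summary <- data.frame(
    set = names(reports),
    nFeatures = c(vapply(featureSetNames(ft)[featureSetNames(ft) %in%
                                               names(reports)],
                         function(s) ncol(getFeatureSet(ft, s)),
                         numeric(1)),
                  length(combinedNames)),
    medianAUC = vapply(reports, medianAUC, numeric(1)),
    medianF1 = vapply(reports, medianF1, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  flagged <- trackMisclassified(reports,
                                setThreshold = min(7, length(reports)))
  out <- list(curated = curated, featureTable = ft, reports = reports,
              control = control, summary = summary, flagged = flagged,
              combinedFeatures = combinedNames)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCurationReport(curated, file.path(outDir, "curation.json"))
    writeFeatureTable(ft, file.path(outDir, "features.csv"))
    jsonlite::write_json(
      list(summary = summary,
           combinedFeatures = combinedNames,
           controlMedianAUC = if (!is.null(control)) medianAUC(control)
           else NULL,
           flagged = flagged),
      file.path(outDir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
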