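#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Construct a FeatureTable from per-set matrices
#'
#' @param setMatrices named list (names in
#'   \code{aa_counts}, \code{aa_counts_CDR}, \code{num_multivalent},
#'   \code{Ab_info}, \code{SIN}, \code{AIF}, \code{dMaSIF},
#'   \code{Energetics}) of complexes-x-features numeric matrices sharing
#'   row (complex) names. Fixed-width sets are validated against the
#'   schema; missing values (masked adapter sets) stay NA.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(setMatrices) {
  stopifnot(length(setMatrices) > 0, !is.null(names(setMatrices)))
  bad <- setdiff(names(setMatrices), FEATURE_SET_NAMES)
  if (length(bad))
    stop("unknown feature set(s): ", paste(bad, collapse = ", "))
  ids <- rownames(setMatrices[[1]])
  for (s in names(setMatrices)) {
    m <- setMatrices[[s]]
    if (!identical(rownames(m), ids))
      stop("complex ids of set '", s, "' do not match")
    if (s %in% names(FEATURE_SET_WIDTHS) &&
        ncol(m) != FEATURE_SET_WIDTHS[[s]])
      stop(sprintf("feature set '%s' has width %d, schema requires %d",
                   s, ncol(m), FEATURE_SET_WIDTHS[[s]]))
  }
  assayMat <- t(do.call(cbind, unname(setMatrices)))
  setTag <- rep(names(setMatrices),
                vapply(setMatrices, ncol, integer(1)))
  se <- SummarizedExperiment(
    assays = list(features = assayMat),
    rowData = DataFrame(featureSet = setTag),
    colData = DataFrame(row.names = ids))
  new("FeatureTable", se)
}

setMethod("show", "FeatureTable", function(object) {
  sets <- table(rowData(object)$featureSet)
  cat("FeatureTable: ", ncol(object), " complexes x ", nrow(object),
      " features\n  sets: ",
      paste(sprintf("%s(%d)", names(sets), sets), collapse = ", "),
      "\n", sep = "")
  nMasked <- sum(is.na(assay(object, "features")))
  if (nMasked) cat("  masked entries:", nMasked, "\n")
})

#' FeatureTable accessors
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param set a feature-set name.
#' @return \code{featureMatrix} returns the complexes x features matrix;
#'   \code{featureSetNames} the set names present; \code{getFeatureSet} the
#'   complexes x features matrix of one set; \code{featureSetOf} the named
#'   per-feature set tags.
#' @name FeatureTable-accessors
NULL

#' @rdname FeatureTable-accessors
#' @export
featureMatrix <- function(ft) t(assay(ft, "features"))

#' @rdname FeatureTable-accessors
#' @export
featureSetNames <- function(ft) unique(as.character(
  rowData(ft)$featureSet))

#' @rdname FeatureTable-accessors
#' @export
featureSetOf <- function(ft) setNames(
  as.character(rowData(ft)$featureSet), rownames(ft))

#' @rdname FeatureTable-accessors
#' @export
getFeatureSet <- function(ft, set) {
  stopifnot(set %in% featureSetNames(ft))
  t(assay(ft, "features")[rowData(ft)$featureSet == set, , drop = FALSE])
}

#' Assemble the feature table of a dataset
#'
#' Computes the requested feature sets for every complex and column-aligns
#' them. The simple sets and the network/statistical sets are computed
#' in-package; the surface-score and energetics sets are taken from adapter
#' inputs, and complexes without an adapter entry get masked (NA) values
#' for that set only.
#'
#' @param complexes list of \linkS4class{AbAgComplex}.
#' @param sets character vector of feature-set names to include.
#' @param propensity a \linkS4class{PropensityMatrix}; required for the AIF
#'   set (trained with \code{\link{trainPropensity}} or loaded from file).
#' @param residueScores data.frame from \code{\link{readResidueScores}} for
#'   the dMaSIF set.
#' @param energetics named list of 18-field records (names = complex ids)
#'   for the Energetics set.
#' @param classAnnotation canonical-class annotation for the Ab_info set
#'   (see \code{\link{abInfoFeatures}}).
#' @param sinCfg network edge configuration (see \code{\link{sinConfig}}).
#' @return A \linkS4class{FeatureTable}.
#' @export
assembleFeatureTable <- function(complexes,
                                 sets = c("aa_counts", "aa_counts_CDR",
                                          "num_multivalent", "Ab_info",
                                          "SIN", "AIF"),
                                 propensity = NULL, residueScores = NULL,
                                 energetics = NULL, classAnnotation = NULL,
                                 sinCfg = sinConfig()) {
  stopifnot(all(sets %in% FEATURE_SET_NAMES))
  ids <- vapply(complexes, complexId, character(1))
  cms <- lapply(complexes, computeContactMap)
  ifaces <- mapply(defineInterface, complexes, cms, SIMPLIFY = FALSE)
  perComplex <- function(fun, width, names_) {
    m <- t(vapply(seq_along(complexes), fun, numeric(width)))
    rownames(m) <- ids
    m
  }
  out <- list()
  for (s in sets) {
    out[[s]] <- switch(s,
      aa_counts = perComplex(function(i) aaCounts(cms[[i]]), 400),
      aa_counts_CDR = perComplex(function(i) aaCountsByCdr(cms[[i]]), 150),
      num_multivalent = perComplex(function(i)
        multivalencyFeatures(cms[[i]]), 7),
      Ab_info = abInfoFeatures(complexes, classAnnotation),
      SIN = perComplex(function(i) {
        g <- buildSinGraph(complexes[[i]], sinCfg)
        sinFeatures(residueNetworking(g, complexes[[i]], ifaces[[i]]),
                    ifaces[[i]], complexes[[i]])
      }, 26),
      AIF = {
        if (is.null(propensity))
          stop("the AIF set requires a propensity matrix")
        perComplex(function(i)
          aifFeatures(aifResidueScores(cms[[i]], propensity),
                      ifaces[[i]], complexes[[i]]), 26)
      },
      dMaSIF = {
        nm <- names(aggregateInterfaceScores(
          setNames(numeric(0), character(0)), ifaces[[1]],
          complexes[[1]], "dMaSIF"))
        m <- matrix(NA_real_, length(complexes), 26,
                    dimnames = list(ids, nm))
        if (!is.null(residueScores)) {
          for (i in seq_along(complexes)) {
            sc <- residueScores[residueScores$complex_id == ids[i], ,
                                drop = FALSE]
            if (nrow(sc))
              m[i, ] <- dmasifFeatures(sc, ifaces[[i]], complexes[[i]])
          }
        }
        m
      },
      Energetics = {
        m <- matrix(NA_real_, length(complexes), 18,
                    dimnames = list(ids, ENERGETICS_FIELDS))
        for (i in seq_along(complexes))
          if (!is.null(energetics) && ids[i] %in% names(energetics))
            m[i, ] <- energeticsFeatures(energetics[[ids[i]]])
        m
      })
  }
  FeatureTable(out)
}

#' Write / read a feature table as CSV
#'
#' The CSV has a \code{complex_id} key column; the per-feature set tags go
#' to a sidecar TSV (\code{<path>.sets.tsv}) so the table round-trips.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param path CSV path.
#' @return \code{writeFeatureTable} returns the path invisibly;
#'   \code{readFeatureTable} a \linkS4class{FeatureTable}.
#' @export
writeFeatureTable <- function(ft, path) {
  m <- featureMatrix(ft)
  df <- data.frame(complex_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sets <- featureSetOf(ft)
  write.table(data.frame(feature = names(sets), set = sets),
              paste0(path, ".sets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$complex_id
  ## na.strings = NULL: "NA" is a real feature name (the Asn-Ala pair count)
  sets <- read.delim(paste0(path, ".sets.tsv"), stringsAsFactors = FALSE,
                     na.strings = NULL)
  tag <- setNames(sets$set, sets$feature)[colnames(m)]
  mats <- lapply(split(colnames(m), tag[colnames(m)])[unique(tag)],
                 function(cols) m[, cols, drop = FALSE])
  FeatureTable(mats)
}
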