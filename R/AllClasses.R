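#' AbAgComplex: a role-annotated antibody-antigen complex
#'
#' Holds one antibody-antigen complex: per-residue identities and
#' coordinates (alpha carbon plus side-chain heavy atoms), the chain role
#' assignment (heavy / light / antigen), per-residue CDR membership, and the
#' affinity annotation.
#'
#' @slot id character(1) complex identifier.
#' @slot residues data.frame with one row per residue: \code{chain},
#'   \code{resno} (Chothia number), \code{ins} (insertion code, \code{""} if
#'   none), \code{aa} (one-letter code), \code{x}, \code{y}, \code{z}
#'   (alpha-carbon coordinates, Angstrom).
#' @slot sidechains list parallel to \code{residues}; each element an n x 3
#'   matrix of side-chain heavy-atom coordinates (0-row matrix for glycine).
#' @slot chainRoles named character; values in \code{heavy}, \code{light},
#'   \code{antigen}, names are chain identifiers.
#' @slot cdr character parallel to \code{residues}; one of H1..L3 or NA.
#' @slot kd numeric(1) equilibrium dissociation constant in molar, or NA.
#' @slot resolution numeric(1) structure resolution in Angstrom, or NA.
#' @exportClass AbAgComplex
setClass("AbAgComplex",
  representation(id = "character", residues = "data.frame",
                 sidechains = "list", chainRoles = "character",
                 cdr = "character", kd = "numeric", resolution = "numeric"))

setValidity("AbAgComplex", function(object) {
  r <- object@residues
  msg <- character()
  need <- c("chain", "resno", "ins", "aa", "x", "y", "z")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns", paste(need, collapse = ", ")))
  if (!all(r$aa %in% AA20))
    msg <- c(msg, "residue amino acids must be in the 20-letter alphabet")
  if (!all(is.finite(r$x) & is.finite(r$y) & is.finite(r$z)))
    msg <- c(msg, "alpha-carbon coordinates must be finite")
  if (length(object@sidechains) != nrow(r))
    msg <- c(msg, "sidechains must be parallel to residues")
  if (!all(object@chainRoles %in% c("heavy", "light", "antigen")))
    msg <- c(msg, "chain roles must be heavy, light or antigen")
  if (!"heavy" %in% object@chainRoles)
    msg <- c(msg, "a heavy chain is required")
  if (!"antigen" %in% object@chainRoles)
    msg <- c(msg, "at least one antigen chain is required")
  if (length(object@cdr) != nrow(r))
    msg <- c(msg, "cdr must be parallel to residues")
  onAb <- object@chainRoles[r$chain] %in% c("heavy", "light")
  if (any(!is.na(object@cdr) & !onAb))
    msg <- c(msg, "CDR assignments are only valid on antibody chains")
  if (!is.na(object@kd) && object@kd <= 0)
    msg <- c(msg, "kd must be positive when present")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ContactMap: antibody-antigen residue contacts of one complex
#'
#' The set of (antibody residue, antigen residue) pairs satisfying the
#' side-chain-aware distance criterion. Pairs are ordered: the first member
#' is always on an antibody chain, the second on an antigen chain.
#'
#' @slot complexId character(1).
#' @slot pairs data.frame with columns \code{ab}, \code{ag} (row indices into
#'   the complex's residue table; may be NA for training-only maps),
#'   \code{abAa}, \code{agAa} (one-letter codes) and \code{abCdr} (CDR of the
#'   antibody residue or NA).
#' @exportClass ContactMap
setClass("ContactMap",
  representation(complexId = "character", pairs = "data.frame"))

setValidity("ContactMap", function(object) {
  p <- object@pairs
  need <- c("ab", "ag", "abAa", "agAa", "abCdr")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (nrow(p) && anyDuplicated(p[, c("ab", "ag")]) && !anyNA(p$ab))
    return("duplicate contact pairs")
  if (!all(p$abAa %in% AA20) || !all(p$agAa %in% AA20))
    return("contact amino acids must be in the 20-letter alphabet")
  TRUE
})

#' InterfaceDefinition: epitope, paratope and per-CDR epitopes
#'
#' @slot epitope integer residue indices (antigen side) of the interface.
#' @slot paratope integer residue indices (antibody side).
#' @slot cdrEpitopes named list (H1..L3) of integer antigen residue indices
#'   contacted by at least one residue of that CDR.
#' @exportClass InterfaceDefinition
setClass("InterfaceDefinition",
  representation(epitope = "integer", paratope = "integer",
                 cdrEpitopes = "list"))

setValidity("InterfaceDefinition", function(object) {
  if (!identical(sort(names(object@cdrEpitopes)), sort(CDR_IDS)))
    return("cdrEpitopes must have exactly the six CDR names")
  ok <- vapply(object@cdrEpitopes, function(e) all(e %in% object@epitope),
               logical(1))
  if (!all(ok)) return("cdrEpitopes must be subsets of the epitope")
  TRUE
})

#' SinGraph: weighted residue interaction network of one complex
#'
#' Undirected residue graph in which edges are detected from eight geometric
#' interaction categories, each contributing a configurable weight.
#'
#' @slot complexId character(1).
#' @slot nResidues integer(1).
#' @slot edges data.frame with columns \code{i}, \code{j} (residue indices,
#'   i < j), \code{weight}, and one numeric column per interaction category.
#' @exportClass SinGraph
setClass("SinGraph",
  representation(complexId = "character", nResidues = "integer",
                 edges = "data.frame"))

setValidity("SinGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$i == e$j)) return("self-edges are not allowed")
    if (any(e$weight < 0)) return("edge weights must be non-negative")
    if (any(e$i > e$j)) return("edges must be stored with i < j")
  }
  TRUE
})

#' PropensityMatrix: amino-acid pairing interface propensity scores
#'
#' 20 x 20 log-odds matrix of observed-over-expected interface pairing
#' frequencies, rows indexed by the antibody-side amino acid and columns by
#' the antigen-side amino acid (ordered pairs).
#'
#' @slot scores numeric 20 x 20 matrix with amino-acid dimnames.
#' @slot pseudocount numeric(1) > 0.
#' @slot trainingSize integer(1), number of reference complexes.
#' @exportClass PropensityMatrix
setClass("PropensityMatrix",
  representation(scores = "matrix", pseudocount = "numeric",
                 trainingSize = "integer"))

setValidity("PropensityMatrix", function(object) {
  s <- object@scores
  if (!identical(dim(s), c(20L, 20L))) return("scores must be 20 x 20")
  if (!identical(rownames(s), AA20) || !identical(colnames(s), AA20))
    return("scores must have the 20 amino acids as dimnames")
  if (!all(is.finite(s))) return("scores must be finite")
  if (object@pseudocount <= 0) return("pseudocount must be positive")
  TRUE
})

#' CVReport: repeated cross-validation results
#'
#' @slot foldMetrics data.frame with one row per evaluated fold:
#'   \code{rep}, \code{fold}, \code{auc}, \code{f1}, \code{nTest}.
#' @slot medianAUC numeric(1) median AUROC over all evaluated folds.
#' @slot medianF1 numeric(1).
#' @slot importances data.frame \code{feature}, \code{importance}
#'   (normalized mean gain; empty for non-tree classifiers).
#' @slot misclassification data.frame per complex: \code{id},
#'   \code{timesHeldOut}, \code{timesWrong}, \code{rate}.
#' @slot selectedFeatures list of character vectors, one per evaluated fold.
#' @slot folds list of integer fold-assignment vectors, one per repeat.
#' @slot skippedFolds integer(1) folds skipped for single-class training.
#' @slot config list, the CV configuration used.
#' @exportClass CVReport
setClass("CVReport",
  representation(foldMetrics = "data.frame", medianAUC = "numeric",
                 medianF1 = "numeric", importances = "data.frame",
                 misclassification = "data.frame", selectedFeatures = "list",
                 folds = "list", skippedFolds = "integer", config = "list"))

setValidity("CVReport", function(object) {
  m <- object@foldMetrics
  if (nrow(m)) {
    if (any(m$auc < 0 | m$auc > 1, na.rm = TRUE))
      return("AUC must lie in [0, 1]")
    if (any(m$f1 < 0 | m$f1 > 1, na.rm = TRUE))
      return("F1 must lie in [0, 1]")
  }
  TRUE
})

#' FeatureTable: complexes x features, partitioned into feature sets
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"features"} stores
#' features in rows and complexes in columns; \code{rowData(x)$featureSet}
#' tags each feature with its parent set. Missing external-adapter values are
#' NA (masked), never zero-filled.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"featureSet" %in% names(rd)) return("rowData$featureSet is required")
  if (anyDuplicated(colnames(object))) return("complex ids must be unique")
  if (anyDuplicated(rownames(object))) return("feature names must be unique")
  sets <- as.character(rd$featureSet)
  if (!all(sets %in% FEATURE_SET_NAMES))
    return("unknown feature-set tag")
  for (s in intersect(unique(sets), names(FEATURE_SET_WIDTHS))) {
    w <- sum(sets == s)
    if (w != FEATURE_SET_WIDTHS[[s]])
      return(sprintf("feature set '%s' has width %d, schema requires %d",
                     s, w, FEATURE_SET_WIDTHS[[s]]))
  }
  TRUE
})
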