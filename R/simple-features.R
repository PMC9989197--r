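#' Pairwise amino-acid contact counts (400 features)
#'
#' Counts every ordered antibody-amino-acid x antigen-amino-acid contact in
#' the interface. Features are named by the two one-letter codes, antibody
#' side first (e.g. \code{"YY"}, \code{"IE"}); the sum over all 400 features
#' equals the number of contact pairs.
#'
#' @param cm a \linkS4class{ContactMap}.
#' @return Named numeric vector of length 400.
#' @export
aaCounts <- function(cm) {
  nm <- as.vector(outer(AA20, AA20, function(a, b) paste0(a, b)))
  v <- setNames(numeric(400), nm)
  p <- cm@pairs
  if (nrow(p)) {
    tab <- table(factor(paste0(p$abAa, p$agAa), levels = nm))
    v[] <- as.numeric(tab)
  }
  v
}

#' Per-CDR chemical-class contact counts (150 features)
#'
#' Reduces the pairwise contact counts by amino-acid chemical class and CDR:
#' for each of the six CDRs, the 25 (antibody class, antigen class)
#' combinations are counted. Contacts from framework (non-CDR) antibody
#' residues are excluded.
#'
#' @param cm a \linkS4class{ContactMap} from a complex with CDRs assigned.
#' @return Named numeric vector of length 150, e.g.
#'   \code{"H3_aromatic_aromatic"}.
#' @export
aaCountsByCdr <- function(cm) {
  cls <- chemClass()
  nm <- as.vector(vapply(CDR_IDS, function(c)
    as.vector(outer(CHEM_CLASSES, CHEM_CLASSES,
                    function(a, b) paste(c, a, b, sep = "_"))),
    character(25)))
  v <- setNames(numeric(150), nm)
  p <- cm@pairs
  p <- p[!is.na(p$abCdr), , drop = FALSE]
  if (nrow(p)) {
    lab <- paste(p$abCdr, cls[p$abAa], cls[p$agAa], sep = "_")
    tab <- table(factor(lab, levels = nm))
    v[] <- as.numeric(tab)
  }
  v
}

#' Interface multivalency features (7 features)
#'
#' For each epitope residue, the number of distinct CDRs contacting it is
#' counted. A CDR's multivalency feature is the number of epitope residues
#' it contacts that are each contacted by at least two additional CDRs
#' (i.e. at least three distinct CDRs in total). The seventh feature is the
#' number of CDRs with at least \code{perCdrThreshold} such multivalent
#' interactions.
#'
#' @param cm a \linkS4class{ContactMap} with CDRs assigned.
#' @param perCdrThreshold minimum multivalent interactions per CDR counted
#'   by the seventh feature (default 5).
#' @return Named numeric vector of length 7
#'   (\code{H1_multivalent} .. \code{L3_multivalent},
#'   \code{num_multivalent_CDRs}).
#' @export
multivalencyFeatures <- function(cm, perCdrThreshold = 5) {
  p <- cm@pairs
  p <- p[!is.na(p$abCdr), , drop = FALSE]
  v <- setNames(numeric(7),
                c(paste0(CDR_IDS, "_multivalent"), "num_multivalent_CDRs"))
  if (nrow(p)) {
    ## distinct CDRs per epitope residue
    inc <- unique(p[, c("ag", "abCdr")])
    nCdrs <- table(inc$ag)
    multi <- as.integer(names(nCdrs)[nCdrs >= 3])
    for (c in CDR_IDS) {
      sites <- unique(p$ag[p$abCdr == c])
      v[paste0(c, "_multivalent")] <- sum(sites %in% multi)
    }
  }
  v["num_multivalent_CDRs"] <- sum(v[seq_len(6)] >= perCdrThreshold)
  v
}

#' Antibody descriptive features (CDR lengths + canonical classes)
#'
#' Builds, for a list of complexes, the six CDR-length features followed by a
#' one-hot encoding of per-CDR canonical classes. The one-hot vocabulary is
#' determined from the annotation supplied at table-build time (plus a
#' \code{"None"} category per CDR for missing or failed assignments), so the
#' block width is data-driven.
#'
#' @param complexes list of \linkS4class{AbAgComplex}.
#' @param classAnnotation optional data.frame with columns
#'   \code{complex_id}, \code{cdr_id}, \code{class_label}; NULL means every
#'   CDR is in the \code{"None"} category.
#' @return Numeric matrix, one row per complex, with CDR-length columns
#'   (\code{H1_length} ..) followed by one-hot columns named
#'   \code{<cdr>_<class>}.
#' @export
abInfoFeatures <- function(complexes, classAnnotation = NULL) {
  ids <- vapply(complexes, complexId, character(1))
  lens <- t(vapply(complexes, function(cx) {
    vapply(CDR_IDS, function(c) sum(!is.na(cx@cdr) & cx@cdr == c),
           numeric(1))
  }, numeric(6)))
  colnames(lens) <- paste0(CDR_IDS, "_length")
  ## per-CDR class labels, "None" where unannotated
  lab <- matrix("None", nrow = length(complexes), ncol = 6,
                dimnames = list(ids, CDR_IDS))
  if (!is.null(classAnnotation)) {
    stopifnot(all(c("complex_id", "cdr_id", "class_label") %in%
                    names(classAnnotation)))
    for (k in seq_len(nrow(classAnnotation))) {
      i <- which(ids == classAnnotation$complex_id[k])
      cl <- classAnnotation$class_label[k]
      if (length(i) && !is.na(cl) && nzchar(cl))
        lab[i, classAnnotation$cdr_id[k]] <- cl
    }
  }
  onehot <- lapply(CDR_IDS, function(c) {
    vocab <- sort(unique(lab[, c]))
    m <- outer(lab[, c], vocab, "==") * 1
    colnames(m) <- paste(c, vocab, sep = "_")
    m
  })
  out <- cbind(lens, do.call(cbind, onehot))
  rownames(out) <- ids
  out
}
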