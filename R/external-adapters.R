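#' Read externally computed per-residue scores
#'
#' Reads a TSV of per-residue surface-interface scores (dMaSIF-site style)
#' with columns \code{complex_id}, \code{chain_id}, \code{resnum},
#' \code{score}. \code{resnum} may carry an insertion code suffix (e.g.
#' \code{"100A"}).
#'
#' @param path TSV file path.
#' @return data.frame of typed rows; duplicated (chain, resnum) rows are an
#'   error.
#' @export
readResidueScores <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(resnum = "character"))
  need <- c("complex_id", "chain_id", "resnum", "score")
  if (!all(need %in% names(d)))
    stop("residue score file must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(d[, c("complex_id", "chain_id", "resnum")]))
    stop("duplicated residue row in ", path)
  d$score <- as.numeric(d$score)
  d
}

#' Write per-residue scores (fixture/export helper)
#'
#' @param scores data.frame as returned by \code{\link{readResidueScores}}.
#' @param path output TSV.
#' @return The path, invisibly.
#' @export
writeResidueScores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## resolve score rows to residue indices of a complex
.resolveScores <- function(scores, cx) {
  r <- cx@residues
  key <- paste(r$chain, paste0(r$resno, r$ins), sep = "|")
  skey <- paste(scores$chain_id, scores$resnum, sep = "|")
  idx <- match(skey, key)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " score row(s) do not resolve to residues of '",
            cx@id, "' and were excluded")
  }
  keep <- !is.na(idx)
  setNames(scores$score[keep], idx[keep])
}

#' Surface-score (dMaSIF-site style) feature set (26 features)
#'
#' Resolves externally computed per-residue scores against the complex and
#' aggregates them through the shared avg/total schema.
#'
#' @param scores data.frame from \code{\link{readResidueScores}} (rows for
#'   this complex), or a named numeric vector of residue-index scores.
#' @param iface an \linkS4class{InterfaceDefinition}.
#' @param cx the complex.
#' @return Named numeric vector of length 26. If no score covers an
#'   interface residue the vector is all zero, with a warning.
#' @export
dmasifFeatures <- function(scores, iface, cx) {
  if (is.data.frame(scores)) {
    scores <- scores[scores$complex_id == cx@id, , drop = FALSE]
    scores <- .resolveScores(scores, cx)
  }
  covered <- as.integer(names(scores))
  if (!any(covered %in% c(iface@epitope, iface@paratope)))
    warning("score file covers no interface residue of '", cx@id,
            "'; dMaSIF features are all zero")
  aggregateInterfaceScores(scores, iface, cx, "dMaSIF")
}

#' Energetics feature set (18 features)
#'
#' Validates and passes through an externally computed per-complex
#' energetics record: epitope residue count, epitope SASA, epitope total
#' energy, interaction energy, crossterm interface energy, interface dG,
#' separated interface energy ratio, total complex energy,
#' antibody/antigen normalized scores, surface complementarity
#' (\code{sc_total}), dSASA, and the six per-CDR interaction energies.
#'
#' @param rec named numeric vector or list with exactly the 18 fields.
#' @return Named numeric vector of length 18 in schema order.
#' @export
energeticsFeatures <- function(rec) {
  rec <- unlist(rec)
  missing <- setdiff(ENERGETICS_FIELDS, names(rec))
  if (length(missing))
    stop("energetics record is missing field(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(rec), ENERGETICS_FIELDS)
  if (length(extra))
    stop("energetics record has unknown field(s): ",
         paste(extra, collapse = ", "))
  out <- as.numeric(rec[ENERGETICS_FIELDS])
  if (!all(is.finite(out)))
    stop("energetics record has non-finite field(s): ",
         paste(ENERGETICS_FIELDS[!is.finite(out)], collapse = ", "))
  setNames(out, ENERGETICS_FIELDS)
}

#' Read / write an energetics record as JSON
#'
#' One JSON object per complex with the 18 schema keys.
#'
#' @param path JSON file.
#' @return \code{readEnergeticsRecord} returns the validated named numeric
#'   vector; \code{writeEnergeticsRecord} the path, invisibly.
#' @export
readEnergeticsRecord <- function(path) {
  energeticsFeatures(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname readEnergeticsRecord
#' @param rec named numeric vector with the 18 schema fields.
#' @export
writeEnergeticsRecord <- function(rec, path) {
  jsonlite::write_json(as.list(energeticsFeatures(rec)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
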