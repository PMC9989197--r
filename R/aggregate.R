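#' Aggregate per-residue interface scores into the 26-feature schema
#'
#' Shared aggregation layer for the network (SIN), statistical (AIF) and
#' surface (dMaSIF-site style) scores: average and total score per CDR
#' (12 features), per CDR-epitope (12 features), and the average over the
#' entire epitope and entire paratope (2 features). For each CDR the residue
#' set is the scored residues belonging to that CDR; for each CDR-epitope it
#' is the scored antigen residues that CDR contacts. Averages over empty
#' sets are 0, so the vector is always total.
#'
#' @param scores numeric vector of per-residue scores, names are residue
#'   indices into the complex residue table.
#' @param iface an \linkS4class{InterfaceDefinition}.
#' @param cx the \linkS4class{AbAgComplex}.
#' @param suffix feature-name suffix, e.g. \code{"SIN"}.
#' @return Named numeric vector of length 26.
#' @export
aggregateInterfaceScores <- function(scores, iface, cx, suffix) {
  idx <- as.integer(names(scores))
  pick <- function(set) scores[idx %in% set]
  avg <- function(v) if (length(v)) mean(v) else 0
  tot <- function(v) if (length(v)) sum(v) else 0
  out <- numeric(0)
  for (c in CDR_IDS) {
    inCdr <- which(!is.na(cx@cdr) & cx@cdr == c)
    v <- pick(inCdr)
    out[paste0(c, "_avg_", suffix)] <- avg(v)
    out[paste0(c, "_total_", suffix)] <- tot(v)
  }
  for (c in CDR_IDS) {
    v <- pick(iface@cdrEpitopes[[c]])
    out[paste0(c, "_avg_epitope_", suffix)] <- avg(v)
    out[paste0(c, "_total_epitope_", suffix)] <- tot(v)
  }
  out[paste0("avg_epitope_", suffix)] <- avg(pick(iface@epitope))
  out[paste0("avg_paratope_", suffix)] <- avg(pick(iface@paratope))
  out
}
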