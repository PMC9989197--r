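#' Train an amino-acid pairing propensity matrix
#'
#' Pools ordered (antibody amino acid, antigen amino acid) contact counts
#' over a reference set of contact maps and scores each pairing by its
#' pseudocount-adjusted observed-over-expected log-odds:
#' \deqn{score(x,y) = \log_2 \frac{(n_{xy}+pc)/N'}{p(x)\,p(y)}}
#' where \eqn{N' = \sum_{xy}(n_{xy}+pc)} and \eqn{p(x)}, \eqn{p(y)} are the
#' pseudocount-adjusted marginal frequencies of \eqn{x} among antibody-side
#' and \eqn{y} among antigen-side contact residues.
#'
#' @param reference list of \linkS4class{ContactMap}.
#' @param pseudocount positive real, default 1.
#' @return A \linkS4class{PropensityMatrix}.
#' @export
trainPropensity <- function(reference, pseudocount = 1.0) {
  stopifnot(pseudocount > 0)
  if (length(reference) == 0L)
    stop("no reference contacts")
  n <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  total <- 0L
  for (cm in reference) {
    p <- cm@pairs
    if (nrow(p)) {
      tab <- table(factor(p$abAa, levels = AA20),
                   factor(p$agAa, levels = AA20))
      n <- n + matrix(as.numeric(tab), 20, 20)
      total <- total + nrow(p)
    }
  }
  if (total == 0L) stop("no reference contacts")
  nAdj <- n + pseudocount
  Nprime <- sum(nAdj)
  pAb <- rowSums(nAdj) / Nprime
  pAg <- colSums(nAdj) / Nprime
  scores <- log2((nAdj / Nprime) / outer(pAb, pAg))
  new("PropensityMatrix", scores = scores, pseudocount = pseudocount,
      trainingSize = length(reference))
}

#' @rdname trainPropensity
#' @param x a PropensityMatrix.
#' @export
propensityScores <- function(x) x@scores

setMethod("show", "PropensityMatrix", function(object) {
  cat("PropensityMatrix: 20 x 20 log2 pairing propensities, trained on ",
      object@trainingSize, " reference map(s), pseudocount ",
      object@pseudocount, "\n", sep = "")
  cat("  score range: [", round(min(object@scores), 3), ", ",
      round(max(object@scores), 3), "]\n", sep = "")
})

#' Read / write a propensity matrix as TSV
#'
#' The file is a 20 x 20 table with one-letter amino-acid row and column
#' headers (rows antibody-side, columns antigen-side), so externally
#' published weights can be dropped in.
#'
#' @param path file path.
#' @param pseudocount,trainingSize metadata recorded on read.
#' @return \code{readPropensityMatrix} returns a
#'   \linkS4class{PropensityMatrix}; \code{writePropensityMatrix} the path,
#'   invisibly.
#' @export
readPropensityMatrix <- function(path, pseudocount = 1.0,
                                 trainingSize = NA_integer_) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  m <- m[AA20, AA20]
  new("PropensityMatrix", scores = m, pseudocount = pseudocount,
      trainingSize = as.integer(trainingSize))
}

#' @rdname readPropensityMatrix
#' @param P a \linkS4class{PropensityMatrix}.
#' @export
writePropensityMatrix <- function(P, path) {
  write.table(P@scores, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Per-residue interface propensity (AIF) scores
#'
#' Each interface residue is scored by the mean propensity of its
#' cross-interface contact partners; residues with no contacts are excluded.
#'
#' @param cm a \linkS4class{ContactMap}.
#' @param P a \linkS4class{PropensityMatrix}.
#' @return Named numeric vector (names are residue indices) over antibody
#'   and antigen interface residues.
#' @export
aifResidueScores <- function(cm, P) {
  p <- cm@pairs
  s <- P@scores
  if (nrow(p) == 0L) return(setNames(numeric(0), character(0)))
  pairScore <- s[cbind(p$abAa, p$agAa)]
  abScores <- tapply(pairScore, p$ab, mean)
  agScores <- tapply(pairScore, p$ag, mean)
  out <- c(abScores, agScores)
  setNames(as.numeric(out), names(out))
}

#' Statistical (AIF) feature set (26 features)
#'
#' Aggregates per-residue propensity scores through the shared avg/total
#' schema (see \code{\link{aggregateInterfaceScores}}).
#'
#' @param scores output of \code{\link{aifResidueScores}}.
#' @param iface an \linkS4class{InterfaceDefinition}.
#' @param cx the complex.
#' @return Named numeric vector of length 26.
#' @export
aifFeatures <- function(scores, iface, cx) {
  aggregateInterfaceScores(scores, iface, cx, "AIF")
}
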