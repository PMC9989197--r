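#' Default interaction-network edge configuration
#'
#' Eight geometric interaction categories with detection cutoffs (Angstrom)
#' and weights. Every cutoff and weight can be overridden; a category with
#' weight 0 still appears in the per-edge breakdown but contributes nothing
#' to edge weights.
#'
#' @return Named list of \code{list(cutoff=, weight=)} entries for
#'   \code{hbond}, \code{salt_bridge}, \code{disulfide}, \code{pi_pi},
#'   \code{cation_pi}, \code{hydrophobic}, \code{vdw}, \code{backbone}.
#' @export
sinConfig <- function() {
  list(
    hbond       = list(cutoff = 3.5, weight = 1),
    salt_bridge = list(cutoff = 4.0, weight = 1),
    disulfide   = list(cutoff = 2.5, weight = 1),
    pi_pi       = list(cutoff = 7.0, weight = 1),
    cation_pi   = list(cutoff = 6.0, weight = 1),
    hydrophobic = list(cutoff = 5.0, weight = 1),
    vdw         = list(cutoff = 4.5, weight = 1),
    backbone    = list(cutoff = 6.0, weight = 1))
}

SIN_TYPES <- c("hbond", "salt_bridge", "disulfide", "pi_pi", "cation_pi",
               "hydrophobic", "vdw", "backbone")

## minimum heavy-atom distance between two residues' atom sets
.minDist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Build the residue interaction network of a complex
#'
#' Each residue is a node; edges are detected from eight geometric
#' interaction categories. Hydrogen bonds, salt bridges, disulfides,
#' hydrophobic and van der Waals contacts are detected from minimum
#' heavy-atom distances (side-chain atoms for chemistry-specific
#' categories, all heavy atoms for van der Waals); pi-pi and cation-pi use
#' side-chain centroids of aromatic residues; the backbone category uses the
#' alpha-carbon distance. The edge weight is the sum of the weights of the
#' detected categories.
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param config edge configuration, see \code{\link{sinConfig}}.
#' @return A \linkS4class{SinGraph}.
#' @export
buildSinGraph <- function(cx, config = sinConfig()) {
  r <- cx@residues
  n <- nrow(r)
  ca <- as.matrix(r[, c("x", "y", "z")])
  sc <- cx@sidechains
  allAtoms <- lapply(seq_len(n), function(i) rbind(ca[i, , drop = FALSE],
                                                   sc[[i]]))
  centroid <- lapply(seq_len(n), function(i) {
    if (nrow(sc[[i]]) == 0L) ca[i, , drop = FALSE]
    else matrix(colMeans(sc[[i]]), nrow = 1)
  })
  aa <- r$aa
  cut <- vapply(config, `[[`, numeric(1), "cutoff")
  wgt <- vapply(config, `[[`, numeric(1), "weight")
  maxCut <- max(cut)
  maxSl <- vapply(seq_len(n), function(i) {
    s <- sc[[i]]
    if (nrow(s) == 0L) 0 else
      max(sqrt(rowSums((s - matrix(ca[i, ], nrow(s), 3, byrow = TRUE))^2)))
  }, numeric(1))
  caD <- as.matrix(stats::dist(ca))
  rows <- vector("list", 0L)
  for (i in seq_len(n - 1L)) {
    ## coarse prune: atoms of i and j cannot be within maxCut otherwise
    js <- which(caD[i, ] < maxCut + maxSl[i] + maxSl)
    js <- js[js > i]
    for (j in js) {
      det <- setNames(numeric(8), SIN_TYPES)
      dSc <- .minDist(sc[[i]], sc[[j]])
      dAll <- min(.minDist(allAtoms[[i]], allAtoms[[j]]), caD[i, j])
      if (aa[i] %in% HBOND_CAPABLE && aa[j] %in% HBOND_CAPABLE &&
          dSc < cut[["hbond"]]) det[["hbond"]] <- 1
      if (((aa[i] %in% POSITIVE_AA && aa[j] %in% NEGATIVE_AA) ||
           (aa[i] %in% NEGATIVE_AA && aa[j] %in% POSITIVE_AA)) &&
          dSc < cut[["salt_bridge"]]) det[["salt_bridge"]] <- 1
      if (aa[i] == "C" && aa[j] == "C" && dSc < cut[["disulfide"]])
        det[["disulfide"]] <- 1
      if (aa[i] %in% AROMATIC_AA && aa[j] %in% AROMATIC_AA &&
          .minDist(centroid[[i]], centroid[[j]]) < cut[["pi_pi"]])
        det[["pi_pi"]] <- 1
      if ((aa[i] %in% POSITIVE_AA && aa[j] %in% AROMATIC_AA &&
           .minDist(sc[[i]], centroid[[j]]) < cut[["cation_pi"]]) ||
          (aa[j] %in% POSITIVE_AA && aa[i] %in% AROMATIC_AA &&
           .minDist(sc[[j]], centroid[[i]]) < cut[["cation_pi"]]))
        det[["cation_pi"]] <- 1
      if (aa[i] %in% HYDROPHOBIC_AA && aa[j] %in% HYDROPHOBIC_AA &&
          dSc < cut[["hydrophobic"]]) det[["hydrophobic"]] <- 1
      if (dAll < cut[["vdw"]]) det[["vdw"]] <- 1
      if (caD[i, j] < cut[["backbone"]]) det[["backbone"]] <- 1
      if (any(det > 0)) {
        w <- sum(det * wgt)
        rows[[length(rows) + 1L]] <-
          c(i = i, j = j, weight = w, det * wgt)
      }
    }
  }
  edges <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else as.data.frame(matrix(numeric(0), ncol = 11,
                            dimnames = list(NULL, c("i", "j", "weight",
                                                    SIN_TYPES))))
  new("SinGraph", complexId = cx@id, nResidues = as.integer(n),
      edges = edges)
}

setMethod("show", "SinGraph", function(object) {
  cat("SinGraph '", object@complexId, "': ", object@nResidues, " residues, ",
      nrow(object@edges), " edges\n", sep = "")
})

#' Export a residue interaction network as an edge-list TSV
#'
#' @param g a \linkS4class{SinGraph}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSinGraph <- function(g, path) {
  write.table(g@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-interface residue networking scores
#'
#' For each epitope and paratope residue, sums the weights of its network
#' edges whose other endpoint lies on the opposite side of the
#' antibody-antigen interface. Interface residues with no cross-interface
#' edge score 0.
#'
#' @param g a \linkS4class{SinGraph}.
#' @param cx the \linkS4class{AbAgComplex} the graph was built from.
#' @param iface an \linkS4class{InterfaceDefinition}.
#' @return Named numeric vector over the interface residues (names are
#'   residue indices).
#' @export
residueNetworking <- function(g, cx, iface) {
  ab <- isAntibodyResidue(cx)
  members <- sort(c(iface@epitope, iface@paratope))
  scores <- setNames(numeric(length(members)), members)
  e <- g@edges
  if (nrow(e)) {
    cross <- ab[e$i] != ab[e$j]
    e <- e[cross, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      for (v in c(e$i[k], e$j[k])) {
        key <- as.character(v)
        if (key %in% names(scores))
          scores[key] <- scores[key] + e$weight[k]
      }
    }
  }
  scores
}

#' Network (SIN) feature set (26 features)
#'
#' Aggregates cross-interface residue networking scores through the shared
#' avg/total schema (see \code{\link{aggregateInterfaceScores}}).
#'
#' @param scores output of \code{\link{residueNetworking}}.
#' @param iface an \linkS4class{InterfaceDefinition}.
#' @param cx the complex.
#' @return Named numeric vector of length 26.
#' @export
sinFeatures <- function(scores, iface, cx) {
  aggregateInterfaceScores(scores, iface, cx, "SIN")
}
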