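#' Curation configuration
#'
#' @param identityThreshold heavy-chain sequence identity above which two
#'   antibodies are treated as homologs (fraction, default 0.95).
#' @param mdoWidth middle-drop-out half-width in log10 units of KD
#'   (default 1.0: affinities within one order of magnitude of the median
#'   are dropped).
#' @param affinityCutoff high/low class boundary in molar (default 1e-9).
#' @param includeNanobodies keep heavy-chain-only complexes (default FALSE).
#' @param includeHomologs skip the homology filter (default FALSE);
#'   enabling either flag strictly enlarges the dataset.
#' @return list of class \code{"curationConfig"}.
#' @export
curationConfig <- function(identityThreshold = 0.95, mdoWidth = 1.0,
                           affinityCutoff = 1e-9,
                           includeNanobodies = FALSE,
                           includeHomologs = FALSE) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1,
            affinityCutoff > 0, mdoWidth >= 0)
  structure(list(identityThreshold = identityThreshold,
                 mdoWidth = mdoWidth, affinityCutoff = affinityCutoff,
                 includeNanobodies = includeNanobodies,
                 includeHomologs = includeHomologs),
            class = "curationConfig")
}

#' Affinity on the -log10(KD) scale
#'
#' @param kd dissociation constant(s) in molar; must be positive.
#' @return \code{-log10(kd)}; higher means stronger binding
#'   (1e-9 M -> 9).
#' @export
negLog10Kd <- function(kd) {
  stopifnot(all(kd > 0, na.rm = TRUE))
  -log10(kd)
}

datasetKd <- function(dataset) vapply(dataset, kdValue, numeric(1))
datasetIds <- function(dataset) vapply(dataset, complexId, character(1))

#' Remove nanobodies (heavy-chain-only complexes)
#'
#' @param dataset list of \linkS4class{AbAgComplex}.
#' @param cfg a \code{\link{curationConfig}}.
#' @return Filtered dataset (unchanged if \code{includeNanobodies}).
#' @export
filterNanobodies <- function(dataset, cfg = curationConfig()) {
  if (cfg$includeNanobodies) return(dataset)
  keep <- vapply(dataset, function(cx) "light" %in% cx@chainRoles,
                 logical(1))
  dataset[keep]
}

#' Heavy-chain sequence of a complex
#'
#' Concatenates the one-letter codes of the heavy-chain residues in
#' numbering order.
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @return character(1).
#' @export
heavyChainSequence <- function(cx) {
  r <- cx@residues
  heavy <- names(cx@chainRoles)[cx@chainRoles == "heavy"]
  r <- r[r$chain %in% heavy, , drop = FALSE]
  r <- r[order(r$resno, r$ins), , drop = FALSE]
  paste(r$aa, collapse = "")
}

## identity substitution matrix over the 20-letter alphabet
.idMat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- diag(1, 20)
      dimnames(m) <<- list(AA20, AA20)
    }
    m
  }
})

#' Heavy-chain sequence identity between two complexes
#'
#' Global (Needleman-Wunsch) alignment with match score 1, mismatch 0 and
#' gap penalty 1 (alignment only); identity is the number of identical
#' aligned positions divided by the alignment length including gaps.
#' Symmetric in its arguments.
#'
#' @param a,b \linkS4class{AbAgComplex} objects, or heavy-chain sequences as
#'   character strings.
#' @return fraction in [0, 1].
#' @export
heavyChainIdentity <- function(a, b) {
  sa <- if (is.character(a)) a else heavyChainSequence(a)
  sb <- if (is.character(b)) b else heavyChainSequence(b)
  if (identical(sa, sb)) return(1.0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = .idMat(), gapOpening = 0, gapExtension = 1,
    type = "global")
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / width
}

#' Homology filter: collapse high-identity antibody clusters
#'
#' Greedy clustering over complexes sorted by id: a complex joins the first
#' existing cluster whose representative (its first member) exceeds the
#' identity threshold, otherwise founds a new cluster. From each cluster the
#' member whose affinity is furthest from the dataset median (on the
#' -log10 KD scale) is retained; ties go to the lexicographically lower id.
#'
#' @param dataset list of \linkS4class{AbAgComplex} with KD annotations.
#' @param cfg a \code{\link{curationConfig}}.
#' @return Filtered dataset in original order (unchanged if
#'   \code{includeHomologs}).
#' @export
homologyFilter <- function(dataset, cfg = curationConfig()) {
  if (cfg$includeHomologs || length(dataset) <= 1L) return(dataset)
  ids <- datasetIds(dataset)
  nlk <- negLog10Kd(datasetKd(dataset))
  med <- median(nlk)
  ord <- order(ids)
  seqs <- vapply(dataset, heavyChainSequence, character(1))
  clusters <- list()   # each: integer indices, first = representative
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep <- clusters[[k]][1]
      if (heavyChainIdentity(seqs[rep], seqs[i]) > cfg$identityThreshold) {
        clusters[[k]] <- c(clusters[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- i
  }
  keep <- vapply(clusters, function(members) {
    dist <- abs(nlk[members] - med)
    best <- members[dist == max(dist)]
    best[order(ids[best])][1]
  }, integer(1))
  dataset[sort(keep)]
}

#' Middle-drop-out (MDO) filter
#'
#' Removes complexes whose affinity lies within \code{mdoWidth} log10 units
#' of the dataset median affinity. The median is computed on the input
#' (post-homology-filter) set, before any removal.
#'
#' @param dataset list of \linkS4class{AbAgComplex} with KD annotations.
#' @param cfg a \code{\link{curationConfig}}.
#' @return Filtered dataset.
#' @export
mdoFilter <- function(dataset, cfg = curationConfig()) {
  if (length(dataset) == 0L) return(dataset)
  nlk <- negLog10Kd(datasetKd(dataset))
  med <- median(nlk)
  dataset[abs(nlk - med) >= cfg$mdoWidth]
}

#' Binary affinity label
#'
#' \code{"high"} iff KD is strictly below the affinity cutoff
#' (default 1 nM); KD exactly at the cutoff is \code{"low"}.
#'
#' @param x an \linkS4class{AbAgComplex}, or numeric KD value(s) in molar.
#' @param cfg a \code{\link{curationConfig}}.
#' @return character vector of \code{"high"} / \code{"low"}.
#' @export
binaryLabel <- function(x, cfg = curationConfig()) {
  kd <- if (is.numeric(x)) x else kdValue(x)
  ifelse(kd < cfg$affinityCutoff, "high", "low")
}

#' Run the full curation pipeline
#'
#' Nanobody removal, heavy-chain homology filtering and middle-drop-out, in
#' that order, recording every removal with its reason.
#'
#' @param dataset list of \linkS4class{AbAgComplex}.
#' @param cfg a \code{\link{curationConfig}}.
#' @return list with \code{dataset} (the retained complexes),
#'   \code{labels} (their binary affinity labels) and \code{report}
#'   (data.frame \code{id}, \code{stage}, \code{reason} for every removal).
#' @export
curateDataset <- function(dataset, cfg = curationConfig()) {
  report <- data.frame(id = character(), stage = character(),
                       reason = character(), stringsAsFactors = FALSE)
  note <- function(removedIds, stage, reason) {
    if (length(removedIds))
      report <<- rbind(report, data.frame(id = removedIds, stage = stage,
                                          reason = reason,
                                          stringsAsFactors = FALSE))
  }
  d1 <- filterNanobodies(dataset, cfg)
  note(setdiff(datasetIds(dataset), datasetIds(d1)), "nanobody",
       "no light chain")
  d2 <- homologyFilter(d1, cfg)
  note(setdiff(datasetIds(d1), datasetIds(d2)), "homology",
       sprintf("heavy-chain identity > %g with a retained representative",
               cfg$identityThreshold))
  d3 <- mdoFilter(d2, cfg)
  note(setdiff(datasetIds(d2), datasetIds(d3)), "mdo",
       sprintf("affinity within %g log10 of the dataset median",
               cfg$mdoWidth))
  list(dataset = d3,
       labels = binaryLabel(datasetKd(d3), cfg),
       report = report)
}

#' Write a curation report as JSON
#'
#' @param curated result of \code{\link{curateDataset}}.
#' @param path output JSON file.
#' @return The path, invisibly.
#' @export
writeCurationReport <- function(curated, path) {
  jsonlite::write_json(
    list(retained = datasetIds(curated$dataset),
         removals = curated$report),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest
#'
#' TSV with columns \code{complex_id}, \code{pdb_path}, \code{heavy_chain},
#' \code{light_chain} (empty for nanobodies), \code{antigen_chains}
#' (comma-separated), \code{kd_molar}, \code{resolution}; parses each PDB
#' into an \linkS4class{AbAgComplex}.
#'
#' @param path manifest TSV.
#' @param dir directory PDB paths are relative to (default: the manifest's).
#' @return list of \linkS4class{AbAgComplex}.
#' @export
readDatasetManifest <- function(path, dir = dirname(path)) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(light_chain = "character"))
  lapply(seq_len(nrow(m)), function(i) {
    roles <- c(setNames("heavy", m$heavy_chain[i]))
    if (!is.na(m$light_chain[i]) && nzchar(m$light_chain[i]))
      roles <- c(roles, setNames("light", m$light_chain[i]))
    ag <- strsplit(m$antigen_chains[i], ",")[[1]]
    roles <- c(roles, setNames(rep("antigen", length(ag)), ag))
    parseComplex(file.path(dir, m$pdb_path[i]), roles,
                 id = m$complex_id[i], kd = m$kd_molar[i],
                 resolution = m$resolution[i])
  })
}
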