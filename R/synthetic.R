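#' Synthetic complex generator configuration
#'
#' Controls the toy antibody-antigen complexes used for testing the
#' pipeline end to end. Residues are a single alpha carbon plus one pseudo
#' side-chain heavy atom (length 1 Angstrom; glycine has none), which keeps
#' the contact criterion analytic: planted contacts sit 3.54 Angstrom
#' apart (always under the minimum 4.5 threshold) and everything else at
#' least 11 Angstrom apart (always over the maximum 6.5 threshold).
#'
#' @param nComplexes number of complexes to generate.
#' @param cdrLengths named integer vector of residues per CDR; must fit the
#'   Chothia boundary windows.
#' @param nFramework framework residues per antibody chain.
#' @param nAgExtra non-interface antigen residues.
#' @param meanSites mean number of epitope contact sites per complex
#'   (Poisson, at least 1).
#' @param maxCdrsPerSite maximum distinct CDRs contacting one site.
#' @param aaWeights sampling weights over the 20 amino acids.
#' @param effects named numeric: planted logistic coefficients on
#'   standardized feature columns (names must be feature names produced by
#'   the simple feature sets).
#' @param noiseScale logistic label-noise scale.
#' @param seed RNG seed; generation is byte-identical given it.
#' @return list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(nComplexes = 60,
                            cdrLengths = c(H1 = 7L, H2 = 6L, H3 = 10L,
                                           L1 = 7L, L2 = 5L, L3 = 6L),
                            nFramework = 15L, nAgExtra = 8L,
                            meanSites = 8, maxCdrsPerSite = 4,
                            aaWeights = setNames(rep(1, 20), AA20),
                            effects = c(H3_multivalent = 1,
                                        L1_multivalent = 1),
                            noiseScale = 1, seed = 1L) {
  b <- cdrBoundaries()
  width <- setNames(b$end - b$start + 1L, b$cdr_id)
  stopifnot(identical(sort(names(cdrLengths)), sort(CDR_IDS)),
            all(cdrLengths >= 1L), all(cdrLengths <= width[names(cdrLengths)]),
            meanSites > 0, maxCdrsPerSite >= 1, maxCdrsPerSite <= 6,
            all(aaWeights >= 0), noiseScale >= 0)
  structure(list(nComplexes = as.integer(nComplexes),
                 cdrLengths = cdrLengths[CDR_IDS],
                 nFramework = as.integer(nFramework),
                 nAgExtra = as.integer(nAgExtra),
                 meanSites = meanSites,
                 maxCdrsPerSite = as.integer(maxCdrsPerSite),
                 aaWeights = aaWeights[AA20] / sum(aaWeights),
                 effects = effects, noiseScale = noiseScale,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

.sampleAa <- function(n, cfg) sample(AA20, n, replace = TRUE,
                                     prob = cfg$aaWeights)

## random contact plan: a list of character vectors, one per epitope site,
## naming the CDRs that contact the site
.randomPlan <- function(cfg) {
  nSites <- max(1L, stats::rpois(1, cfg$meanSites))
  plan <- replicate(nSites, {
    k <- sample.int(cfg$maxCdrsPerSite, 1)
    sort(sample(CDR_IDS, k))
  }, simplify = FALSE)
  ## feasibility: a CDR can serve at most cdrLengths[c] sites
  for (c in CDR_IDS) {
    uses <- which(vapply(plan, function(s) c %in% s, logical(1)))
    excess <- length(uses) - cfg$cdrLengths[[c]]
    if (excess > 0)
      for (u in uses[seq_len(excess)])
        plan[[u]] <- setdiff(plan[[u]], c)
  }
  plan[lengths(plan) > 0]
}

#' Generate one synthetic antibody-antigen complex
#'
#' Places epitope contact sites 14 Angstrom apart and, for each site, one
#' residue from each planned CDR on a 2.5 Angstrom ring 2.5 Angstrom above
#' it; remaining antibody and antigen residues are parked far from the
#' interface. Under the contact criterion the realized contact map equals
#' the plan exactly, and the returned ground truth records it.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param index complex index (used for the id; RNG state is taken as-is,
#'   see \code{\link{generateDataset}} for seeded generation).
#' @param plan optional explicit contact plan: list of character vectors of
#'   CDR ids, one per epitope site. Sites using one CDR more often than it
#'   has residues are an error.
#' @param nFrameworkContacts extra epitope sites contacted by one
#'   framework (non-CDR) antibody residue each.
#' @return list with \code{complex} (an \linkS4class{AbAgComplex}) and
#'   \code{truth} (planned contact pairs, per-CDR contact counts,
#'   multivalency features).
#' @export
generateComplex <- function(cfg, index = 1L, plan = NULL,
                            nFrameworkContacts = 0L) {
  if (is.null(plan)) plan <- .randomPlan(cfg)
  for (c in CDR_IDS) {
    uses <- sum(vapply(plan, function(s) c %in% s, logical(1)))
    if (uses > cfg$cdrLengths[[c]])
      stop("infeasible plan: CDR ", c, " must contact ", uses,
           " sites but has only ", cfg$cdrLengths[[c]], " residues")
  }
  if (nFrameworkContacts > cfg$nFramework)
    stop("infeasible plan: more framework contacts than framework residues")
  b <- cdrBoundaries()
  rows <- list()
  sidech <- list()
  addResidue <- function(chain, resno, aa, ca, withSc = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, ins = "", aa = aa,
      x = ca[1], y = ca[2], z = ca[3], stringsAsFactors = FALSE)
    sidech[[length(sidech) + 1L]] <<-
      if (aa == "G" || !withSc) matrix(numeric(0), 0, 3)
      else matrix(ca + c(0, 0, 1), 1, 3)
  }
  nSites <- length(plan)
  siteX <- (seq_len(nSites + nFrameworkContacts) - 1) * 14
  siteAa <- .sampleAa(nSites + nFrameworkContacts, cfg)
  ## antigen: epitope sites on the x-axis, extras parked at z = -60
  for (s in seq_along(siteX))
    addResidue("A", s, siteAa[s], c(siteX[s], 0, 0))
  extraAa <- .sampleAa(cfg$nAgExtra, cfg)
  for (e in seq_len(cfg$nAgExtra))
    addResidue("A", nSites + nFrameworkContacts + e, extraAa[e],
               c((e - 1) * 14, 0, -60))
  ## antibody CDR residues: next free residue of each CDR serves each site
  cdrChain <- setNames(b$chain_role, b$cdr_id)
  cdrUsed <- setNames(rep(0L, 6), CDR_IDS)
  truthPairs <- list()
  for (s in seq_len(nSites)) {
    cdrs <- plan[[s]]
    for (t in seq_along(cdrs)) {
      c <- cdrs[t]
      cdrUsed[c] <- cdrUsed[c] + 1L
      resno <- b$start[b$cdr_id == c] + cdrUsed[c] - 1L
      chain <- if (cdrChain[c] == "heavy") "H" else "L"
      ang <- 2 * pi * t / length(cdrs)
      ca <- c(siteX[s] + 2.5 * cos(ang), 2.5, 2.5 * sin(ang))
      aa <- .sampleAa(1, cfg)
      addResidue(chain, resno, aa, ca)
      truthPairs[[length(truthPairs) + 1L]] <- data.frame(
        abChain = chain, abResno = resno, abAa = aa, abCdr = c,
        agResno = s, agAa = siteAa[s], stringsAsFactors = FALSE)
    }
  }
  ## framework contacts: numbered outside every CDR window
  fwUsed <- 0L
  if (nFrameworkContacts > 0) {
    for (s in seq_len(nFrameworkContacts)) {
      fwUsed <- fwUsed + 1L
      resno <- 110L + fwUsed       # beyond H3's window
      aa <- .sampleAa(1, cfg)
      addResidue("H", resno, aa, c(siteX[nSites + s], 3.5, 0))
      truthPairs[[length(truthPairs) + 1L]] <- data.frame(
        abChain = "H", abResno = resno, abAa = aa, abCdr = NA_character_,
        agResno = nSites + s, agAa = siteAa[nSites + s],
        stringsAsFactors = FALSE)
    }
  }
  ## unused CDR residues and framework, parked at y = 60
  park <- 0L
  for (c in CDR_IDS) {
    chain <- if (cdrChain[c] == "heavy") "H" else "L"
    start <- b$start[b$cdr_id == c]
    for (k in seq(cdrUsed[c] + 1L, length.out = cfg$cdrLengths[[c]] -
                    cdrUsed[c])) {
      park <- park + 1L
      addResidue(chain, start + k - 1L, .sampleAa(1, cfg),
                 c(park * 14, 60, 0))
    }
  }
  for (k in seq_len(cfg$nFramework - fwUsed)) {
    park <- park + 1L
    addResidue("H", 120L + k, .sampleAa(1, cfg), c(park * 14, 60, 20))
    park <- park + 1L
    addResidue("L", 120L + k, .sampleAa(1, cfg), c(park * 14, 60, 40))
  }
  res <- do.call(rbind, rows)
  cx <- AbAgComplex(id = sprintf("syn%04d", index), residues = res,
                    sidechains = sidech,
                    chainRoles = c(H = "heavy", L = "light", A = "antigen"))
  truth <- do.call(rbind, truthPairs)
  perCdr <- vapply(CDR_IDS, function(c)
    sum(vapply(plan, function(s) c %in% s, logical(1))), numeric(1))
  mv <- vapply(CDR_IDS, function(c)
    sum(vapply(plan, function(s) c %in% s && length(s) >= 3, logical(1))),
    numeric(1))
  mvFeatures <- setNames(c(mv, sum(mv >= 5)),
                         c(paste0(CDR_IDS, "_multivalent"),
                           "num_multivalent_CDRs"))
  list(complex = cx,
       truth = list(pairs = truth, plan = plan,
                    perCdrContacts = setNames(perCdr, CDR_IDS),
                    multivalency = mvFeatures,
                    nContacts = if (is.null(truth)) 0L else nrow(truth)))
}

#' Generate a full synthetic dataset with planted affinity labels
#'
#' Generates \code{nComplexes} complexes from random contact plans,
#' computes their simple contact features, and plants affinity labels and
#' KD values through \code{\link{plantAffinity}} on the configured effect
#' features.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return list with \code{complexes} (each carrying its planted KD),
#'   \code{truths}, \code{labels}, \code{features} (the simple-set feature
#'   matrix used for planting).
#' @export
generateDataset <- function(cfg) {
  set.seed(cfg$seed)
  gen <- lapply(seq_len(cfg$nComplexes), function(i)
    generateComplex(cfg, i))
  complexes <- lapply(gen, `[[`, "complex")
  feats <- t(vapply(complexes, function(cx) {
    cm <- computeContactMap(cx)
    c(aaCounts(cm), aaCountsByCdr(cm), multivalencyFeatures(cm))
  }, numeric(557)))
  rownames(feats) <- vapply(complexes, complexId, character(1))
  planted <- plantAffinity(feats, cfg$effects, cfg$noiseScale)
  for (i in seq_along(complexes))
    complexes[[i]]@kd <- unname(planted$kd[i])
  list(complexes = complexes, truths = lapply(gen, `[[`, "truth"),
       labels = planted$labels, features = feats)
}

#' Plant affinity labels from a logistic model on chosen features
#'
#' Standardizes the named effect features, forms the linear predictor, adds
#' logistic noise, and thresholds at zero to obtain high/low labels. KD
#' values are then drawn consistent with the label on a log-normal spread
#' of about five logs centred near 3 nM (the scale of curated structural
#' affinity data), with high-affinity complexes strictly below 1 nM and
#' low-affinity ones at or above it.
#'
#' @param features numeric matrix, complexes x features.
#' @param effects named numeric coefficients; names must be feature
#'   columns. Zero-variance effect columns contribute nothing.
#' @param noiseScale logistic noise scale (0 = deterministic labels).
#' @param seed optional seed; NULL uses the current RNG state.
#' @return list with \code{labels} (\code{"high"}/\code{"low"}),
#'   \code{kd} (molar), \code{negLogKd} and \code{linearPredictor}.
#' @export
plantAffinity <- function(features, effects, noiseScale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(names(effects), colnames(features))
  if (length(missing))
    stop("effect feature(s) not in table: ", paste(missing, collapse = ", "))
  n <- nrow(features)
  lp <- numeric(n)
  for (nm in names(effects)) {
    v <- features[, nm]
    s <- sd(v)
    if (is.finite(s) && s > 0) lp <- lp + effects[[nm]] * (v - mean(v)) / s
  }
  lp <- lp + noiseScale * rlogis(n)
  labels <- ifelse(lp > 0, "high", "low")
  ## reflect a 3 nM-centred normal spread around the 1 nM class boundary
  draw <- rnorm(n, mean = 8.52, sd = 1.25)
  dev <- abs(draw - 9) + 0.02
  nlk <- ifelse(labels == "high", 9 + dev, 9 - dev)
  list(labels = labels, kd = 10^(-nlk), negLogKd = nlk,
       linearPredictor = lp)
}

#' Generate a reference contact-map set for propensity training
#'
#' Draws contact maps whose amino-acid pairings are either independent on
#' the two sides (null for the propensity matrix) or enriched for a chosen
#' pair.
#'
#' @param nMaps number of maps (> 0).
#' @param contactsPerMap contacts per map.
#' @param mode \code{"independent"} or \code{"enriched"}.
#' @param enrichPair c(antibody aa, antigen aa) to enrich.
#' @param enrichFraction fraction of contacts forced to the enriched pair.
#' @param aaWeights sampling weights over the 20 amino acids.
#' @param seed optional seed.
#' @return list of \linkS4class{ContactMap}.
#' @export
generateReferenceSet <- function(nMaps, contactsPerMap = 50,
                                 mode = c("independent", "enriched"),
                                 enrichPair = c("Y", "Y"),
                                 enrichFraction = 0.3,
                                 aaWeights = setNames(rep(1, 20), AA20),
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (nMaps <= 0) stop("nMaps must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- aaWeights[AA20] / sum(aaWeights)
  lapply(seq_len(nMaps), function(k) {
    abAa <- sample(AA20, contactsPerMap, replace = TRUE, prob = w)
    agAa <- sample(AA20, contactsPerMap, replace = TRUE, prob = w)
    if (mode == "enriched") {
      forced <- runif(contactsPerMap) < enrichFraction
      abAa[forced] <- enrichPair[1]
      agAa[forced] <- enrichPair[2]
    }
    pairs <- data.frame(ab = seq_len(contactsPerMap),
                        ag = seq_len(contactsPerMap),
                        abAa = abAa, agAa = agAa,
                        abCdr = NA_character_, stringsAsFactors = FALSE)
    new("ContactMap", complexId = sprintf("ref%04d", k), pairs = pairs)
  })
}

#' Synthetic feature table with planted signal
#'
#' Standard-normal feature matrix with a planted logistic relationship on
#' the first \code{nInformative} columns; the table-level counterpart of
#' \code{\link{generateDataset}} for classifier benchmarking.
#'
#' @param n complexes (default 142, the size of a middle-drop-out curated
#'   structural affinity set).
#' @param p features (default 16, the combined-selection width).
#' @param nInformative columns carrying signal.
#' @param effect standardized coefficient on each informative column.
#' @param noiseScale logistic noise scale.
#' @param seed RNG seed.
#' @return list with \code{x} (n x p matrix), \code{labels}, \code{kd}.
#' @export
syntheticFeatureTable <- function(n = 142, p = 16, nInformative = 2,
                                  effect = 2, noiseScale = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("cx%03d", seq_len(n)),
                              sprintf("feat%02d", seq_len(p))))
  eff <- setNames(rep(effect, nInformative),
                  colnames(x)[seq_len(nInformative)])
  planted <- plantAffinity(x, eff, noiseScale)
  list(x = x, labels = planted$labels, kd = planted$kd)
}

#' Write a complex as a PDB file
#'
#' Emits standard fixed-width ATOM records: the alpha carbon and the
#' side-chain heavy atoms (named CB, CG, CD, CE, CZ in order) of every
#' residue.
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeComplexPdb <- function(cx, path) {
  r <- cx@residues
  aa1to3 <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)
  scNames <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CK")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(r))) {
    emit <- function(name, xyz, elem) {
      serial <<- serial + 1L
      lines[length(lines) + 1L] <<- sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", name), aa1to3[r$aa[i]], r$chain[i], r$resno[i],
        ifelse(nzchar(r$ins[i]), r$ins[i], " "),
        xyz[1], xyz[2], xyz[3], 1.0, 0.0, elem)
    }
    emit("CA", c(r$x[i], r$y[i], r$z[i]), "C")
    s <- cx@sidechains[[i]]
    for (k in seq_len(nrow(s))) emit(scNames[k], s[k, ], "C")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a dataset manifest and its PDB files
#'
#' @param complexes list of \linkS4class{AbAgComplex}.
#' @param dir output directory (created if needed).
#' @return Path to the manifest TSV, invisibly.
#' @export
writeDatasetManifest <- function(complexes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(complexes, function(cx) {
    fn <- paste0(cx@id, ".pdb")
    writeComplexPdb(cx, file.path(dir, fn))
    roles <- cx@chainRoles
    data.frame(
      complex_id = cx@id, pdb_path = fn,
      heavy_chain = names(roles)[roles == "heavy"][1],
      light_chain = if (any(roles == "light"))
        names(roles)[roles == "light"][1] else "",
      antigen_chains = paste(names(roles)[roles == "antigen"],
                             collapse = ","),
      kd_molar = cx@kd, resolution = cx@resolution,
      stringsAsFactors = FALSE)
  })
  path <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
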