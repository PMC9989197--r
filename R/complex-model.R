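#' Construct an AbAgComplex
#'
#' Low-level constructor used by the parser and the synthetic generator.
#'
#' @param id complex identifier.
#' @param residues data.frame with columns \code{chain}, \code{resno},
#'   \code{ins}, \code{aa}, \code{x}, \code{y}, \code{z}.
#' @param sidechains list of n x 3 coordinate matrices, parallel to
#'   \code{residues}.
#' @param chainRoles named character mapping chain id to
#'   \code{"heavy"}, \code{"light"} or \code{"antigen"}.
#' @param cdr optional character vector of CDR ids parallel to residues;
#'   computed from \code{\link{cdrBoundaries}} when NULL.
#' @param kd dissociation constant (molar) or NA.
#' @param resolution structure resolution (Angstrom) or NA.
#' @param cdrAnnotation optional CDR boundary table (see
#'   \code{\link{assignCdrs}}).
#' @return An \linkS4class{AbAgComplex}.
#' @export
AbAgComplex <- function(id, residues, sidechains, chainRoles, cdr = NULL,
                        kd = NA_real_, resolution = NA_real_,
                        cdrAnnotation = NULL) {
  residues$ins[is.na(residues$ins)] <- ""
  rownames(residues) <- NULL
  obj <- new("AbAgComplex", id = as.character(id), residues = residues,
             sidechains = sidechains, chainRoles = chainRoles,
             cdr = if (is.null(cdr)) rep(NA_character_, nrow(residues))
                   else cdr,
             kd = as.numeric(kd), resolution = as.numeric(resolution))
  if (is.null(cdr)) obj <- assignCdrs(obj, cdrAnnotation)
  validObject(obj)
  obj
}

#' @describeIn AbAgComplex number of residues
#' @param x,object an AbAgComplex.
#' @export
setMethod("length", "AbAgComplex", function(x) nrow(x@residues))

#' Accessors for AbAgComplex
#'
#' @param x an \linkS4class{AbAgComplex}.
#' @return \code{residues} returns the residue data.frame; \code{chainRoles}
#'   the named role vector; \code{cdrAssignments} the per-residue CDR vector;
#'   \code{kdValue} the dissociation constant (molar); \code{complexId} the
#'   identifier.
#' @name AbAgComplex-accessors
NULL

#' @rdname AbAgComplex-accessors
#' @export
residues <- function(x) x@residues

#' @rdname AbAgComplex-accessors
#' @export
chainRoles <- function(x) x@chainRoles

#' @rdname AbAgComplex-accessors
#' @export
cdrAssignments <- function(x) x@cdr

#' @rdname AbAgComplex-accessors
#' @export
kdValue <- function(x) x@kd

#' @rdname AbAgComplex-accessors
#' @export
complexId <- function(x) x@id

setMethod("show", "AbAgComplex", function(object) {
  roles <- object@chainRoles
  cat("AbAgComplex '", object@id, "': ", nrow(object@residues),
      " residues, chains [",
      paste(sprintf("%s=%s", names(roles), roles), collapse = ", "),
      "]\n", sep = "")
  cat("  CDR residues: ", sum(!is.na(object@cdr)),
      "; KD: ", if (is.na(object@kd)) "NA" else format(object@kd), " M\n",
      sep = "")
})

## role of the chain each residue sits on
residueRoles <- function(cx) unname(cx@chainRoles[cx@residues$chain])

isAntibodyResidue <- function(cx) residueRoles(cx) %in% c("heavy", "light")

#' Assign CDR identities to antibody residues
#'
#' Marks residues whose Chothia number falls inside the CDR boundaries.
#' Defaults to the embedded North-definition boundary table
#' (\code{\link{cdrBoundaries}}); an explicit annotation overrides it.
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param annotation optional data.frame with columns \code{chain_id},
#'   \code{start}, \code{end}, \code{cdr_id} (Chothia positions, both ends
#'   inclusive), e.g. read from a TSV with \code{read.delim}.
#' @return The complex with its \code{cdr} slot populated.
#' @export
assignCdrs <- function(cx, annotation = NULL) {
  r <- cx@residues
  cdr <- rep(NA_character_, nrow(r))
  if (is.null(annotation)) {
    b <- cdrBoundaries()
    for (k in seq_len(nrow(b))) {
      chains <- names(cx@chainRoles)[cx@chainRoles == b$chain_role[k]]
      hit <- r$chain %in% chains & r$resno >= b$start[k] & r$resno <= b$end[k]
      cdr[hit] <- b$cdr_id[k]
    }
  } else {
    stopifnot(all(c("chain_id", "start", "end", "cdr_id") %in%
                    names(annotation)))
    for (k in seq_len(nrow(annotation))) {
      hit <- r$chain == annotation$chain_id[k] &
        r$resno >= annotation$start[k] & r$resno <= annotation$end[k]
      cdr[hit] <- annotation$cdr_id[k]
    }
  }
  cx@cdr <- cdr
  validObject(cx)
  cx
}

#' Parse a PDB-format antibody-antigen complex
#'
#' Reads ATOM records, keeps only chains with an assigned role, drops waters,
#' heteroatoms, hydrogens and non-standard residues, resolves alternate
#' locations to the highest-occupancy conformer (first wins ties), and
#' collects per-residue alpha-carbon and side-chain heavy-atom coordinates.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param roles named character chain-role map, e.g.
#'   \code{c(H = "heavy", L = "light", A = "antigen")}.
#' @param cdrAnnotation optional CDR boundary table (see
#'   \code{\link{assignCdrs}}); NULL uses the embedded boundaries.
#' @param id complex identifier; defaults to the file base name.
#' @param kd,resolution optional affinity (molar) and resolution annotations.
#' @return An \linkS4class{AbAgComplex}. Residues with unknown names are
#'   skipped with a warning; a retained residue lacking an alpha carbon is an
#'   error ("incomplete residue"); a role chain absent from the file is an
#'   error ("chain role unresolved").
#' @export
parseComplex <- function(pdb, roles, cdrAnnotation = NULL, id = NULL,
                         kd = NA_real_, resolution = NA_real_) {
  if (length(pdb) > 1L || grepl("\n", pdb) ||
      (!file.exists(pdb) && grepl("^ATOM|^HEADER", pdb))) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(if (length(pdb) == 1L) strsplit(pdb, "\n")[[1]] else pdb, tf)
    if (is.null(id)) id <- "complex"
    pdb <- tf
  }
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(pdb))
  p <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  missing <- setdiff(names(roles), unique(at$chain))
  if (length(missing))
    stop("chain role unresolved: chain(s) ", paste(missing, collapse = ", "),
         " not present in the file")
  at <- at[at$chain %in% names(roles), , drop = FALSE]
  ## drop hydrogens
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  ## non-standard residues (incl. residual waters in ATOM records)
  known <- at$resid %in% names(AA_THREE_TO_ONE)
  if (any(!known)) {
    skipped <- unique(at$resid[!known])
    warning(sum(!known), " atoms in ", length(skipped),
            " unknown residue type(s) skipped: ",
            paste(skipped, collapse = ", "))
    at <- at[known, , drop = FALSE]
  }
  at$insert[is.na(at$insert)] <- ""
  ## altloc: per residue+atom keep highest occupancy, first on tie
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  o <- order(key, -replace(at$o, is.na(at$o), 1))
  at <- at[o, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ridx <- match(rkey, unique(rkey))
  backbone <- c("N", "CA", "C", "O", "OXT")
  res <- do.call(rbind, lapply(split(seq_len(nrow(at)), ridx), function(ii) {
    a <- at[ii, , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L)
      stop("incomplete residue: no alpha carbon for ", a$chain[1], " ",
           a$resno[1], a$insert[1])
    data.frame(chain = a$chain[1], resno = a$resno[1], ins = a$insert[1],
               aa = unname(AA_THREE_TO_ONE[a$resid[1]]),
               x = ca$x[1], y = ca$y[1], z = ca$z[1],
               stringsAsFactors = FALSE)
  }))
  sc <- lapply(split(seq_len(nrow(at)), ridx), function(ii) {
    a <- at[ii, , drop = FALSE]
    a <- a[!a$elety %in% backbone, , drop = FALSE]
    unname(as.matrix(a[, c("x", "y", "z")]))
  })
  AbAgComplex(id = id, residues = res, sidechains = unname(sc),
              chainRoles = roles, kd = kd, resolution = resolution,
              cdrAnnotation = cdrAnnotation)
}

#' Side-chain lengths
#'
#' The side-chain length of a residue is the distance from its alpha carbon
#' to its furthest side-chain heavy atom; 0 for glycine (no side-chain heavy
#' atoms).
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param i optional residue indices; default all residues.
#' @return numeric vector of lengths in Angstrom.
#' @export
sidechainLength <- function(cx, i = seq_len(length(cx))) {
  r <- cx@residues
  vapply(i, function(k) {
    s <- cx@sidechains[[k]]
    if (is.null(s) || nrow(s) == 0L) return(0)
    d <- sqrt((s[, 1] - r$x[k])^2 + (s[, 2] - r$y[k])^2 +
                (s[, 3] - r$z[k])^2)
    max(d)
  }, numeric(1))
}

#' Residue contact criterion
#'
#' Two residues are in contact when their alpha-carbon distance is strictly
#' less than the sum of their side-chain lengths plus an interaction
#' distance (default 4.5 Angstrom).
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param i,j residue indices.
#' @param interactionDistance Angstrom, default 4.5.
#' @return logical(1); symmetric in \code{i}, \code{j}.
#' @export
inContact <- function(cx, i, j, interactionDistance = 4.5) {
  r <- cx@residues
  d <- sqrt((r$x[i] - r$x[j])^2 + (r$y[i] - r$y[j])^2 + (r$z[i] - r$z[j])^2)
  d < sidechainLength(cx, i) + sidechainLength(cx, j) + interactionDistance
}

#' Compute the antibody-antigen contact map
#'
#' Applies the contact criterion to every antibody x antigen residue pair.
#' Intra-antibody and intra-antigen pairs are never included.
#'
#' @param cx an \linkS4class{AbAgComplex}.
#' @param interactionDistance Angstrom, default 4.5.
#' @return A \linkS4class{ContactMap} (possibly empty).
#' @export
computeContactMap <- function(cx, interactionDistance = 4.5) {
  r <- cx@residues
  abIdx <- which(isAntibodyResidue(cx))
  agIdx <- which(residueRoles(cx) == "antigen")
  if (length(abIdx) == 0L || length(agIdx) == 0L)
    stop("complex must have antibody and antigen residues")
  sl <- sidechainLength(cx)
  ## vectorized pairwise CA distances with per-pair thresholds
  dx <- outer(r$x[abIdx], r$x[agIdx], "-")
  dy <- outer(r$y[abIdx], r$y[agIdx], "-")
  dz <- outer(r$z[abIdx], r$z[agIdx], "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  thr <- outer(sl[abIdx], sl[agIdx], "+") + interactionDistance
  hit <- which(d < thr, arr.ind = TRUE)
  pairs <- data.frame(
    ab = abIdx[hit[, 1]], ag = agIdx[hit[, 2]],
    abAa = r$aa[abIdx[hit[, 1]]], agAa = r$aa[agIdx[hit[, 2]]],
    abCdr = cx@cdr[abIdx[hit[, 1]]],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$ab, pairs$ag), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactMap", complexId = cx@id, pairs = pairs)
}

#' @describeIn computeContactMap number of contact pairs
#' @param x a ContactMap.
#' @export
setMethod("length", "ContactMap", function(x) nrow(x@pairs))

#' @rdname AbAgComplex-accessors
#' @export
contactPairs <- function(x) x@pairs

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap '", object@complexId, "': ", nrow(object@pairs),
      " antibody-antigen contacts\n", sep = "")
})

#' Define epitope, paratope and per-CDR epitopes
#'
#' Projects the contact map onto the antigen (epitope) and antibody
#' (paratope) sides, and records for each CDR the antigen residues it
#' contacts. Framework (non-CDR) antibody contacts contribute to the
#' paratope but to no CDR epitope.
#'
#' @param cx an \linkS4class{AbAgComplex} with CDRs assigned.
#' @param cm its \linkS4class{ContactMap}.
#' @return An \linkS4class{InterfaceDefinition}.
#' @export
defineInterface <- function(cx, cm) {
  p <- cm@pairs
  cdrEpi <- lapply(CDR_IDS, function(c)
    sort(unique(p$ag[!is.na(p$abCdr) & p$abCdr == c])))
  names(cdrEpi) <- CDR_IDS
  new("InterfaceDefinition",
      epitope = sort(unique(p$ag)), paratope = sort(unique(p$ab)),
      cdrEpitopes = cdrEpi)
}

setMethod("show", "InterfaceDefinition", function(object) {
  cat("InterfaceDefinition: epitope ", length(object@epitope),
      " residues, paratope ", length(object@paratope), " residues\n",
      sep = "")
})

#' @rdname AbAgComplex-accessors
#' @export
epitope <- function(x) x@epitope

#' @rdname AbAgComplex-accessors
#' @export
paratope <- function(x) x@paratope

#' @rdname AbAgComplex-accessors
#' @export
cdrEpitopes <- function(x) x@cdrEpitopes
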