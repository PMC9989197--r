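## Fixture builders and independent oracles shared across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Build a complex from explicit residue specs. Each spec:
## list(chain, resno, aa, ca = c(x,y,z), sc = matrix or NULL)
makeComplex <- function(specs, roles = c(H = "heavy", L = "light",
                                         A = "antigen"),
                        id = "toy", kd = NA_real_) {
  res <- do.call(rbind, lapply(specs, function(s)
    data.frame(chain = s$chain, resno = s$resno, ins = "", aa = s$aa,
               x = s$ca[1], y = s$ca[2], z = s$ca[3],
               stringsAsFactors = FALSE)))
  sc <- lapply(specs, function(s)
    if (is.null(s$sc)) matrix(numeric(0), 0, 3) else s$sc)
  roles <- roles[names(roles) %in% res$chain]
  AbAgComplex(id = id, residues = res, sidechains = sc,
              chainRoles = roles, kd = kd)
}

## residue spec shorthand: single pseudo side-chain atom at distance len
rs <- function(chain, resno, aa, x, y = 0, z = 0, len = 1) {
  list(chain = chain, resno = resno, aa = aa, ca = c(x, y, z),
       sc = if (aa == "G" || len == 0) NULL
            else matrix(c(x, y, z + len), 1, 3))
}

## a minimal paired complex: one residue per CDR region plus antigen
makeAbComplex <- function(id, heavySeq, kd, lightSeq = "ASTK") {
  hs <- strsplit(heavySeq, "")[[1]]
  ls <- strsplit(lightSeq, "")[[1]]
  specs <- c(
    lapply(seq_along(hs), function(i) rs("H", i, hs[i], i * 20, 60)),
    lapply(seq_along(ls), function(i) rs("L", i, ls[i], i * 20, 90)),
    list(rs("A", 1, "A", 0, 0), rs("A", 2, "S", 20, 0)))
  makeComplex(specs, id = id, kd = kd)
}

## Exhaustive O(n^2) contact oracle, recomputing side-chain lengths from
## the raw slots, independent of the package's vectorized path.
bruteContacts <- function(cx, interactionDistance = 4.5) {
  r <- residues(cx)
  roles <- chainRoles(cx)[r$chain]
  sl <- vapply(seq_len(nrow(r)), function(i) {
    s <- cx@sidechains[[i]]
    if (nrow(s) == 0) return(0)
    max(sqrt(colSums((t(s) - c(r$x[i], r$y[i], r$z[i]))^2)))
  }, numeric(1))
  out <- NULL
  for (i in which(roles %in% c("heavy", "light")))
    for (j in which(roles == "antigen")) {
      d <- sqrt((r$x[i] - r$x[j])^2 + (r$y[i] - r$y[j])^2 +
                  (r$z[i] - r$z[j])^2)
      if (d < sl[i] + sl[j] + interactionDistance)
        out <- rbind(out, c(i, j))
    }
  out
}

## Independent Needleman-Wunsch (match 1, mismatch 0, gap -1);
## identity = identical aligned positions / alignment length incl. gaps.
nwIdentity <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + (a[i] == b[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  ## traceback counting matches and alignment length
  i <- n; j <- m; len <- 0; matches <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (a[i] == b[j])) {
      matches <- matches + (a[i] == b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1
  }
  matches / len
}

## Mann-Whitney AUROC, independent of pROC
rankAuc <- function(labels, prob) {
  pos <- prob[labels == "high"]; neg <- prob[labels == "low"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## direct multivalency enumeration over (epitope residue, CDR) incidences
bruteMultivalency <- function(cm, perCdrThreshold = 5) {
  p <- contactPairs(cm)
  p <- p[!is.na(p$abCdr), , drop = FALSE]
  cdrs <- c("H1", "H2", "H3", "L1", "L2", "L3")
  perSite <- lapply(split(p$abCdr, p$ag), unique)
  v <- setNames(numeric(7), c(paste0(cdrs, "_multivalent"),
                              "num_multivalent_CDRs"))
  for (c in cdrs) {
    n <- 0
    for (site in names(perSite))
      if (c %in% perSite[[site]] && length(perSite[[site]]) >= 3)
        n <- n + 1
    v[paste0(c, "_multivalent")] <- n
  }
  v["num_multivalent_CDRs"] <- sum(v[1:6] >= perCdrThreshold)
  v
}
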