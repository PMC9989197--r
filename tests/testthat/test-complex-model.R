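test_that("parseComplex reads a minimal two-chain PDB and drops waters", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1      10.000  10.000  11.500  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      14.000  10.000  10.000  1.00  0.00           C",
    "ATOM      4  CA  TYR A   3      18.000  10.000  10.000  1.00  0.00           C",
    "ATOM      5  CA  SER B   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  LYS B   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  TRP B   3       8.000   0.000   0.000  1.00  0.00           C",
    "END")
  cx <- parseComplex(paste(pdb, collapse = "\n"),
                     roles = c(A = "heavy", B = "antigen"))
  expect_s4_class(cx, "AbAgComplex")
  expect_equal(length(cx), 6L)
  expect_equal(sort(unique(residues(cx)$chain)), c("A", "B"))
  ## alanine keeps its CB as a side-chain heavy atom
  iAla <- which(residues(cx)$aa == "A")
  expect_equal(sidechainLength(cx, iAla), 1.5)

  withWater <- append(pdb, paste0(
    "HETATM    8  O   HOH A   9      50.000  50.000  50.000  1.00  0.00",
    "           O"), after = 7)
  cx2 <- parseComplex(paste(withWater, collapse = "\n"),
                      roles = c(A = "heavy", B = "antigen"))
  expect_equal(length(cx2), 6L)
  expect_equal(residues(cx2), residues(cx))
})

test_that("parseComplex errors and warnings follow the contract", {
  pdb <- paste(c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CA  SER B   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  expect_error(parseComplex(pdb, roles = c(A = "heavy", C = "antigen")),
               "chain role unresolved")
  unk <- paste(c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CA  XYZ A   2      14.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  CA  SER B   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  expect_warning(cx <- parseComplex(unk, roles = c(A = "heavy",
                                                   B = "antigen")),
                 "unknown residue")
  expect_equal(length(cx), 2L)
  noCa <- paste(c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CB  SER B   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  expect_error(parseComplex(noCa, roles = c(A = "heavy", B = "antigen")),
               "incomplete residue")
})

test_that("side-chain length is the furthest heavy atom from CA", {
  gly <- makeComplex(list(rs("H", 1, "G", 0), rs("A", 1, "A", 100)))
  expect_equal(sidechainLength(gly, 1), 0.0)
  one <- makeComplex(list(
    list(chain = "H", resno = 1, aa = "S", ca = c(0, 0, 0),
         sc = matrix(c(3, 0, 0), 1, 3)),
    rs("A", 1, "A", 100)))
  expect_equal(sidechainLength(one, 1), 3.0)
  multi <- makeComplex(list(
    list(chain = "H", resno = 1, aa = "R", ca = c(0, 0, 0),
         sc = rbind(c(1.5, 0, 0), c(0, 2.6, 0), c(0, 0, 4.1))),
    rs("A", 1, "A", 100)))
  expect_equal(sidechainLength(multi, 1), 4.1)
})

test_that("contact criterion uses strict inequality and is symmetric", {
  two <- function(d) makeComplex(list(rs("H", 1, "G", 0),
                                      rs("A", 1, "G", d)))
  cx <- two(3.0)
  expect_true(inContact(cx, 1, 2))
  expect_true(inContact(cx, 2, 1))
  expect_false(inContact(two(4.5), 1, 2))   # boundary: strictly less than
  expect_false(inContact(two(4.6), 1, 2))
})

test_that("contact criterion is invariant under rigid-body motion", {
  set.seed(42)
  cfg <- generatorConfig(seed = 42)
  cx <- generateComplex(cfg, 1)$complex
  cm <- computeContactMap(cx)
  ## rotate about z by 30 degrees then translate
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 12)
  r <- residues(cx)
  xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(R)
  r$x <- xyz[, 1] + shift[1]; r$y <- xyz[, 2] + shift[2]
  r$z <- xyz[, 3] + shift[3]
  sc <- lapply(cx@sidechains, function(s)
    if (nrow(s)) sweep(s %*% t(R), 2, -shift) else s)
  cx2 <- AbAgComplex(id = "rot", residues = r, sidechains = sc,
                     chainRoles = chainRoles(cx))
  cm2 <- computeContactMap(cx2)
  expect_equal(contactPairs(cm2)[, c("ab", "ag")],
               contactPairs(cm)[, c("ab", "ag")])
})

test_that("contact map equals the exhaustive pairwise oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 8
    specs <- c(
      lapply(1:n, function(i) rs("H", i, sample(AA, 1),
                                 runif(1, 0, 15), runif(1, 0, 15),
                                 runif(1, 0, 15), len = runif(1, 0, 3))),
      lapply(1:n, function(i) rs("A", i, sample(AA, 1),
                                 runif(1, 0, 15), runif(1, 0, 15),
                                 runif(1, 0, 15), len = runif(1, 0, 3))))
    cx <- makeComplex(specs)
    got <- contactPairs(computeContactMap(cx))
    want <- bruteContacts(cx)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.matrix(got[, c("ab", "ag")]),
                   want[order(want[, 1], want[, 2]), , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("separated chains give an empty contact map", {
  specs <- c(lapply(1:3, function(i) rs("H", i, "Y", i * 10, 0)),
             lapply(1:3, function(i) rs("A", i, "Y", i * 10, 200)))
  cm <- computeContactMap(makeComplex(specs))
  expect_equal(length(cm), 0L)
  iface <- defineInterface(makeComplex(specs), cm)
  expect_length(epitope(iface), 0)
  expect_length(paratope(iface), 0)
  expect_true(all(lengths(cdrEpitopes(iface)) == 0))
})

test_that("interface projections and per-CDR epitopes are consistent", {
  ## one H3 residue (Chothia 95) in contact with one antigen residue
  specs <- list(rs("H", 95, "Y", 0, 0), rs("H", 1, "A", 100, 0),
                rs("L", 1, "A", 140, 0), rs("A", 1, "S", 0, 3),
                rs("A", 2, "S", 60, 0))
  cx <- makeComplex(specs)
  cm <- computeContactMap(cx)
  iface <- defineInterface(cx, cm)
  expect_equal(length(epitope(iface)), 1L)
  expect_equal(length(cdrEpitopes(iface)$H3), 1L)
  expect_true(all(lengths(cdrEpitopes(iface)[c("H1", "H2", "L1", "L2",
                                               "L3")]) == 0))
  ## projections never exceed the pair count; CDR epitopes nest in epitope
  set.seed(9)
  for (k in 1:10) {
    g <- generateComplex(generatorConfig(seed = k), 1)
    cm <- computeContactMap(g$complex)
    ifc <- defineInterface(g$complex, cm)
    expect_lte(length(epitope(ifc)), length(cm))
    expect_lte(length(paratope(ifc)), length(cm))
    expect_true(all(unlist(cdrEpitopes(ifc)) %in% epitope(ifc)))
  }
})

test_that("framework contacts enter the paratope but no CDR epitope", {
  set.seed(3)
  g <- generateComplex(generatorConfig(seed = 3), 1,
                       plan = list(c("H1", "H2", "H3")),
                       nFrameworkContacts = 2)
  cm <- computeContactMap(g$complex)
  iface <- defineInterface(g$complex, cm)
  expect_equal(length(paratope(iface)), 5L)  # 3 CDR + 2 framework residues
  expect_equal(length(unique(unlist(cdrEpitopes(iface)))), 1L)
  expect_equal(length(epitope(iface)), 3L)   # 1 shared + 2 framework sites
})

test_that("synthetic PDB round-trips within fixed-width precision", {
  set.seed(5)
  g <- generateComplex(generatorConfig(seed = 5), 1)
  cx <- g$complex
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(cx, tf)
  cx2 <- parseComplex(tf, chainRoles(cx))
  expect_equal(length(cx2), length(cx))
  a <- residues(cx)[order(residues(cx)$chain, residues(cx)$resno), ]
  b <- residues(cx2)[order(residues(cx2)$chain, residues(cx2)$resno), ]
  expect_equal(a$aa, b$aa)
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z)), 1e-3)
})
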