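test_that("affinity transforms to -log10(KD) and is monotone", {
  expect_equal(negLog10Kd(1e-9), 9.0)
  expect_equal(negLog10Kd(3e-9), -log10(3e-9))
  expect_equal(round(negLog10Kd(3e-9), 2), 8.52)
  set.seed(61)
  kd <- sort(10^runif(50, -12, -5))
  expect_true(all(diff(negLog10Kd(kd)) < 0))
  expect_error(negLog10Kd(-1))
})

test_that("nanobodies (no light chain) are removed unless enabled", {
  nano <- makeComplex(list(rs("H", 1, "A", 0, 60), rs("A", 1, "S", 0)),
                      roles = c(H = "heavy", A = "antigen"), id = "nano",
                      kd = 1e-8)
  paired <- makeAbComplex("paired", "ACDEF", 1e-8)
  ds <- list(nano, paired)
  kept <- filterNanobodies(ds)
  expect_equal(vapply(kept, complexId, character(1)), "paired")
  all_ <- filterNanobodies(ds, curationConfig(includeNanobodies = TRUE))
  expect_length(all_, 2)
})

test_that("heavy-chain identity matches an independent NW implementation", {
  expect_equal(heavyChainIdentity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  s1 <- sub("Y$", "A", s)
  expect_equal(heavyChainIdentity(s, s1), 0.95)
  set.seed(62)
  for (k in 1:15) {
    a <- paste(sample(AA, sample(8:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA, sample(8:20, 1), replace = TRUE), collapse = "")
    expect_equal(heavyChainIdentity(a, b), nwIdentity(a, b),
                 tolerance = 1e-12)
    expect_equal(heavyChainIdentity(a, b), heavyChainIdentity(b, a))
  }
})

test_that("homology filter keeps the member furthest from the median", {
  seqA <- "ACDEFGHIKLMNPQRSTVWY"
  ds <- list(
    makeAbComplex("dup1", seqA, 1e-9),    # 9.0
    makeAbComplex("dup2", seqA, 1e-12),   # 12.0 (further from median)
    makeAbComplex("d3", "WYACDEGHKMLNPQRSTIVF", 3e-9),
    makeAbComplex("d4", "KLMNPQRSTVWYACDEFGHI", 1e-8),
    makeAbComplex("d5", "QRSTVWYACDEFGHIKLMNP", 1e-7))
  ## dataset median of (9, 12, 8.52, 8, 7) is 8.52
  out <- homologyFilter(ds)
  ids <- vapply(out, complexId, character(1))
  expect_true("dup2" %in% ids)
  expect_false("dup1" %in% ids)
  expect_length(out, 4)
  ## all-distinct set passes unchanged
  distinct <- ds[3:5]
  expect_equal(homologyFilter(distinct), distinct)
  ## idempotence
  expect_equal(homologyFilter(out), out)
})

test_that("homolog families collapse to the per-family brute-force argmax", {
  set.seed(63)
  base <- replicate(4, paste(sample(AA, 30, replace = TRUE),
                             collapse = ""))
  ds <- list(); truth <- character(0)
  nlkAll <- numeric(0)
  for (f in seq_along(base)) {
    nMem <- sample(1:3, 1)
    for (m in seq_len(nMem)) {
      id <- sprintf("f%d_m%d", f, m)
      kd <- 10^-runif(1, 6, 12)
      ds[[id]] <- makeAbComplex(id, base[f], kd)
      nlkAll[id] <- -log10(kd)
    }
  }
  med <- median(nlkAll)
  expected <- vapply(seq_along(base), function(f) {
    members <- grep(sprintf("^f%d_", f), names(nlkAll), value = TRUE)
    d <- abs(nlkAll[members] - med)
    sort(members[d == max(d)])[1]
  }, character(1))
  out <- homologyFilter(unname(ds))
  ids <- vapply(out, complexId, character(1))
  expect_setequal(ids, expected)
  ## retained pairwise identities at or below the threshold
  for (i in seq_along(out)) for (j in seq_len(i - 1))
    expect_lte(heavyChainIdentity(out[[i]], out[[j]]), 0.95)
})

test_that("middle-drop-out removes a one-log band around the median", {
  kds <- c(3e-9, 5e-9, 3e-10, 3e-8, 1e-12, 1e-6, 2.9e-7)
  ds <- lapply(seq_along(kds), function(i)
    makeAbComplex(paste0("c", i), paste(sample(AA, 20, replace = TRUE),
                                        collapse = ""), kds[i]))
  ## median -log10 KD = 8.52 (3 nM); 5 nM is 0.22 logs away -> removed;
  ## 290 nM is 2.01 logs away -> retained
  out <- mdoFilter(ds)
  ids <- vapply(out, complexId, character(1))
  expect_false("c2" %in% ids)
  expect_true("c7" %in% ids)
  med <- median(-log10(kds))
  keepExpected <- which(abs(-log10(kds) - med) >= 1)
  expect_setequal(ids, paste0("c", keepExpected))
  ## survivors are all at least one log from the pre-removal median
  expect_true(all(abs(-log10(vapply(out, kdValue, numeric(1))) - med)
                  >= 1))
})

test_that("binary labeling is strict at the cutoff", {
  expect_equal(binaryLabel(0.5e-9), "high")
  expect_equal(binaryLabel(10e-9), "low")
  expect_equal(binaryLabel(1e-9), "low")   # boundary: strictly below
})

test_that("full curation is ordered, reported, and monotone in its flags", {
  set.seed(64)
  seqs <- replicate(6, paste(sample(AA, 25, replace = TRUE), collapse = ""))
  ds <- c(
    list(makeComplex(list(rs("H", 1, "A", 0, 60), rs("A", 1, "S", 0)),
                     roles = c(H = "heavy", A = "antigen"), id = "nano",
                     kd = 1e-8)),
    lapply(1:6, function(i)
      makeAbComplex(paste0("ab", i), seqs[i], 10^-runif(1, 6, 12))),
    list(makeAbComplex("ab1dup", seqs[1], 1e-6)))
  cur <- curateDataset(ds)
  expect_true("nano" %in% cur$report$id[cur$report$stage == "nanobody"])
  expect_true("ab1dup" %in% cur$report$id[cur$report$stage == "homology"] ||
                "ab1" %in% cur$report$id[cur$report$stage == "homology"])
  expect_equal(length(cur$labels), length(cur$dataset))
  ## disabling filters strictly enlarges the dataset
  bigger <- curateDataset(ds, curationConfig(includeNanobodies = TRUE,
                                             includeHomologs = TRUE))
  expect_gt(length(bigger$dataset), length(cur$dataset))
  ## report round-trips through JSON
  tf <- withr::local_tempfile(fileext = ".json")
  writeCurationReport(cur, tf)
  rep <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_setequal(rep$retained,
                  vapply(cur$dataset, complexId, character(1)))
})

test_that("the synthetic manifest round-trips through PDB parsing", {
  cfg <- generatorConfig(nComplexes = 3, seed = 71)
  ds <- generateDataset(cfg)
  dir <- withr::local_tempdir()
  manifest <- writeDatasetManifest(ds$complexes, dir)
  back <- readDatasetManifest(manifest)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(complexId(back[[i]]), complexId(ds$complexes[[i]]))
    expect_equal(kdValue(back[[i]]), kdValue(ds$complexes[[i]]))
    expect_equal(length(back[[i]]), length(ds$complexes[[i]]))
    ## identical features after the write -> parse round trip
    expect_equal(aaCounts(computeContactMap(back[[i]])),
                 aaCounts(computeContactMap(ds$complexes[[i]])))
  }
})
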