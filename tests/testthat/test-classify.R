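twoClassTable <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("c", 1:n), paste0("f", 1:p)))
  labels <- rep(c("high", "low"), length.out = n)
  x[, 1] <- ifelse(labels == "high", 3, -3) + rnorm(n, sd = 0.1)
  list(x = x, labels = labels)
}

test_that("ANOVA F matches the closed-form via an independent route", {
  set.seed(71)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(c("high", "low"), each = 20)
  f <- anovaFStat(x, labels)
  for (j in 1:6) {
    ref <- stats::oneway.test(x[, j] ~ factor(labels),
                              var.equal = TRUE)$statistic
    expect_equal(unname(f[j]), unname(ref), tolerance = 1e-10)
  }
})

test_that("selection ranks a perfect separator first and is deterministic", {
  d <- twoClassTable()
  expect_equal(anovaFSelect(d$x, d$labels, 1), "f1")
  ## all-constant features: F undefined, order falls back to column order
  xc <- matrix(1, 20, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  labels <- rep(c("high", "low"), 10)
  expect_equal(anovaFSelect(xc, labels, 3), c("a", "b", "c"))
  expect_error(anovaFStat(d$x, rep("high", nrow(d$x))), "two classes")
})

test_that("combined selection takes the top two per set, sixteen in all", {
  set.seed(72)
  labels <- rep(c("high", "low"), each = 20)
  sets <- setNames(lapply(1:8, function(s) {
    m <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("s", s, "_f", 1:5)))
    m
  }), paste0("set", 1:8))
  sel <- combinedSelect(sets, labels)
  expect_length(sel, 16)
  expect_equal(sel[1:2], anovaFSelect(sets[[1]], labels, 2))
  ## per-set brute-force F ranking agrees
  for (s in 1:8) {
    f <- anovaFStat(sets[[s]], labels)
    expect_equal(sel[(2 * s - 1):(2 * s)],
                 names(sort(-f))[1:2])
  }
  ## duplicated names across sets are rejected
  sets$set2 <- sets$set1
  expect_error(combinedSelect(sets, labels), "duplicate")
})

test_that("perfectly separable data reach AUC 1 for every classifier", {
  d <- twoClassTable(n = 40)
  for (clf in c("xgboost", "randomForest", "svm")) {
    rep <- runCV(d$x, d$labels,
                 cvConfig(nRepeats = 1, nFolds = 4, selectorK = 3,
                          seed = 3, classifier = clf))
    expect_equal(medianAUC(rep), 1, tolerance = 1e-9)
  }
})

test_that("cross-validation is deterministic given the seed", {
  d <- twoClassTable(n = 40, seed = 5)
  cfg <- cvConfig(nRepeats = 2, nFolds = 5, selectorK = 4, seed = 11)
  r1 <- runCV(d$x, d$labels, cfg)
  r2 <- runCV(d$x, d$labels, cfg)
  expect_identical(foldMetrics(r1), foldMetrics(r2))
  expect_identical(r1@folds, r2@folds)
  expect_identical(r1@importances, r2@importances)
})

test_that("fold AUCs agree with an independent rank-based AUROC", {
  ## recompute one fold by hand from the stored fold assignment
  d <- twoClassTable(n = 40, seed = 7)
  cfg <- cvConfig(nRepeats = 1, nFolds = 4, selectorK = 8, seed = 13)
  rep <- runCV(d$x, d$labels, cfg)
  fm <- foldMetrics(rep)
  expect_true(all(fm$auc >= 0 & fm$auc <= 1))
  expect_true(all(fm$f1 >= 0 & fm$f1 <= 1))
  ## separable feature: rank AUROC of the raw feature is 1 on each fold
  for (f in 1:4) {
    test <- which(rep@folds[[1]] == f)
    expect_equal(rankAuc(d$labels[test], d$x[test, "f1"]), 1)
  }
})

test_that("stratified folds balance classes within one member", {
  set.seed(14)
  labels <- c(rep("high", 37), rep("low", 63))
  fold <- makeStratifiedFolds(labels, 10)
  for (f in 1:10) {
    nh <- sum(labels[fold == f] == "high")
    nl <- sum(labels[fold == f] == "low")
    expect_lte(abs(nh - 3.7), 1)
    expect_lte(abs(nl - 6.3), 1)
  }
})

test_that("fold-safe selection is computed from training rows only", {
  set.seed(15)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(paste0("c", 1:60), paste0("f", 1:10)))
  labels <- rep(c("high", "low"), 30)
  cfg <- cvConfig(nRepeats = 1, nFolds = 6, selectorK = 3, seed = 16)
  rep <- runCV(x, labels, cfg)
  fold <- rep@folds[[1]]
  manual <- lapply(1:6, function(f)
    anovaFSelect(x[fold != f, , drop = FALSE], labels[fold != f], 3))
  expect_equal(rep@selectedFeatures, manual)
  ## with pure noise the selected sets genuinely differ across folds,
  ## so selection demonstrably depends on the training subset
  expect_gt(length(unique(vapply(manual, paste, character(1),
                                 collapse = ","))), 1)
  ## paper-mode selects once on the full table
  repP <- runCV(x, labels, c4 <- cvConfig(nRepeats = 1, nFolds = 6,
                                          selectorK = 3, seed = 16,
                                          paperModeSelection = TRUE))
  full <- anovaFSelect(x, labels, 3)
  expect_true(all(vapply(repP@selectedFeatures, identical, logical(1),
                         full)))
})

test_that("label randomization nulls out planted signal", {
  tab <- syntheticFeatureTable(80, 10, nInformative = 2, effect = 3,
                               seed = 17)
  cfg <- cvConfig(nRepeats = 5, nFolds = 10, selectorK = 5, seed = 18)
  ctrl <- randomizationControl(tab$x, tab$labels, cfg)
  expect_lt(medianAUC(ctrl), 0.65)
  signal <- runCV(tab$x, tab$labels, cfg)
  expect_gt(medianAUC(signal), medianAUC(ctrl) + 0.15)
  ## identity permutation reproduces runCV exactly
  same <- randomizationControl(tab$x, tab$labels, cfg,
                               identityPermutation = TRUE)
  expect_identical(foldMetrics(same), foldMetrics(signal))
})

test_that("importances are normalized mean gain and find the signal", {
  d <- twoClassTable(n = 60)
  rep <- runCV(d$x, d$labels, cvConfig(nRepeats = 2, nFolds = 5,
                                       selectorK = 4, seed = 19))
  imp <- featureImportances(rep)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "f1")
  expect_gt(imp$importance[1], 0.8)
})

test_that("recurrently misclassified complexes are flagged across sets", {
  mk <- function(rates) {
    new("CVReport", foldMetrics = data.frame(rep = 1, fold = 1, auc = 0.5,
                                             f1 = 0.5, nTest = 2),
        medianAUC = 0.5, medianF1 = 0.5,
        importances = data.frame(feature = character(),
                                 importance = numeric()),
        misclassification = data.frame(id = names(rates),
                                       timesHeldOut = 10L,
                                       timesWrong = as.integer(10 * rates),
                                       rate = rates,
                                       stringsAsFactors = FALSE),
        selectedFeatures = list(), folds = list(), skippedFolds = 0L,
        config = list())
  }
  rates <- c(bad = 1.0, good = 0.0, soso = 0.5)
  reports <- replicate(9, mk(rates), simplify = FALSE)
  expect_equal(trackMisclassified(reports), "bad")
  ## below the set threshold nothing is flagged
  mixed <- c(replicate(6, mk(rates), simplify = FALSE),
             replicate(3, mk(c(bad = 0, good = 0, soso = 0)),
                       simplify = FALSE))
  expect_length(trackMisclassified(mixed), 0)
})

test_that("a planted inverted-label outlier is flagged end to end", {
  tab <- syntheticFeatureTable(60, 6, nInformative = 2, effect = 6,
                               noiseScale = 0.1, seed = 20)
  labels <- tab$labels
  labels[1] <- ifelse(labels[1] == "high", "low", "high")
  cfg <- cvConfig(nRepeats = 5, nFolds = 6, selectorK = 4, seed = 21)
  reports <- replicate(9, runCV(tab$x, labels, cfg), simplify = FALSE)
  flagged <- trackMisclassified(reports)
  expect_true(rownames(tab$x)[1] %in% flagged)
})

test_that("feature-affinity correlations behave as Pearson with flags", {
  set.seed(22)
  n <- 200
  aff <- runif(n, 6, 12)
  x <- cbind(mirror = aff, noise = rnorm(n), flat = rep(1, n))
  r <- featureAffinityCorrelations(x, aff, isNegLog = TRUE)
  expect_equal(r["mirror", "affinity"], 1)
  expect_lt(abs(r["noise", "affinity"]), 0.2)
  expect_equal(unname(r["flat", "affinity"]), 0)
  expect_true("flat" %in% attr(r, "constantColumns"))
  expect_equal(r, t(r), ignore_attr = TRUE)
  expect_true(all(diag(r) == 1))
})

test_that("single-class training folds are skipped with a warning", {
  set.seed(23)
  x <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(paste0("c", 1:12),
                                                    paste0("f", 1:3)))
  labels <- c("high", rep("low", 11))
  ## with a single high-affinity complex, the fold holding it out leaves
  ## a single-class training set
  ws <- capture_warnings(
    rep <- runCV(x, labels, cvConfig(nRepeats = 20, nFolds = 2,
                                     selectorK = 2, seed = 24)))
  expect_true(length(ws) > 0 && all(grepl("single-class", ws)))
  expect_gt(rep@skippedFolds, 0)
})
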