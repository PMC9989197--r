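#' One-way ANOVA F statistics between two classes
#'
#' Closed-form two-group F statistic per feature column: between-group mean
#' square over within-group mean square. Zero-variance features return NA.
#'
#' @param x numeric matrix, complexes x features.
#' @param labels two-level factor/character vector.
#' @return Named numeric vector of F statistics.
#' @export
anovaFStat <- function(x, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("labels must contain two classes")
  g <- split(seq_len(nrow(x)), droplevels(labels))
  n <- nrow(x)
  k <- length(g)
  m <- colMeans(x)
  ssb <- ssw <- numeric(ncol(x))
  for (idx in g) {
    xi <- x[idx, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + length(idx) * (mi - m)^2
    ssw <- ssw + colSums((xi - matrix(mi, nrow(xi), ncol(xi),
                                      byrow = TRUE))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- NA_real_
  setNames(f, colnames(x))
}

#' Select the top-k features by ANOVA F
#'
#' Features are ranked by decreasing F; features with undefined F
#' (zero variance) rank last; ties are broken by feature order in the
#' table, so selection is deterministic.
#'
#' @param x numeric matrix, complexes x features.
#' @param labels two-level labels.
#' @param k number of features to select (capped at the feature count).
#' @return Character vector of k feature names, ranked.
#' @export
anovaFSelect <- function(x, labels, k) {
  f <- anovaFStat(x, labels)
  k <- min(k, ncol(x))
  ord <- order(-f, seq_along(f), na.last = TRUE)
  names(f)[ord][seq_len(k)]
}

#' Combined feature selection: top features from each of the eight sets
#'
#' Selects the top \code{kPerSet} features per feature set via
#' \code{\link{anovaFSelect}} and concatenates them in feature-set order,
#' then rank order. With eight sets and the default \code{kPerSet = 2} this
#' yields 16 features.
#'
#' @param ft a \linkS4class{FeatureTable} (or named list of
#'   complexes-x-features matrices, one per set).
#' @param labels two-level labels.
#' @param kPerSet features per set, default 2.
#' @return Character vector of selected feature names.
#' @export
combinedSelect <- function(ft, labels, kPerSet = 2) {
  mats <- if (is(ft, "FeatureTable")) {
    sets <- featureSetNames(ft)
    setNames(lapply(sets, function(s) getFeatureSet(ft, s)), sets)
  } else ft
  allNames <- unlist(lapply(mats, colnames), use.names = FALSE)
  if (anyDuplicated(allNames))
    stop("duplicate feature names across sets: ",
         paste(unique(allNames[duplicated(allNames)]), collapse = ", "))
  unlist(lapply(mats, function(m) {
    keep <- stats::complete.cases(m)
    anovaFSelect(m[keep, , drop = FALSE],
                 labels[keep], kPerSet)
  }), use.names = FALSE)
}

#' Cross-validation configuration
#'
#' @param nRepeats number of repeats of the fold partition (default 50).
#' @param nFolds folds per repeat (default 10, i.e. 90/10 splits).
#' @param selectorK features selected per fold (default 10).
#' @param seed RNG seed; the whole run is deterministic given it.
#' @param paperModeSelection if TRUE, features are selected once on the
#'   full data before cross-validation (leaks selection information); the
#'   default FALSE selects within each training fold.
#' @param classifier one of \code{"xgboost"} (gradient-boosted trees,
#'   logistic objective), \code{"randomForest"}, \code{"svm"},
#'   \code{"mlp"}. Hyperparameters are library defaults, untuned.
#' @param nrounds boosting rounds for xgboost (default 100).
#' @return list of class \code{"cvConfig"}.
#' @export
cvConfig <- function(nRepeats = 50, nFolds = 10, selectorK = 10, seed = 1,
                     paperModeSelection = FALSE,
                     classifier = c("xgboost", "randomForest", "svm",
                                    "mlp"),
                     nrounds = 100) {
  stopifnot(nRepeats >= 1, nFolds >= 2)
  structure(list(nRepeats = as.integer(nRepeats),
                 nFolds = as.integer(nFolds),
                 selectorK = as.integer(selectorK),
                 seed = as.integer(seed),
                 paperModeSelection = isTRUE(paperModeSelection),
                 classifier = match.arg(classifier),
                 nrounds = as.integer(nrounds)),
            class = "cvConfig")
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (using the current RNG state) and deals
#' its members round-robin over folds, so per-fold class counts differ from
#' proportionality by at most one.
#'
#' @param labels class labels.
#' @param nFolds number of folds.
#' @return integer fold assignment parallel to \code{labels}.
#' @export
makeStratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

.normalizeLabels <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "high", "low")
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("high", "low")))
  labels
}

## Mann-Whitney AUROC check is in the tests; here pROC is authoritative
.auc <- function(labels, prob) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = prob, levels = c("low", "high"),
    direction = "<", quiet = TRUE)))
}

## F1 of the high class at a 0.5 probability threshold
.f1 <- function(labels, prob) {
  pred <- ifelse(prob > 0.5, "high", "low")
  tp <- sum(pred == "high" & labels == "high")
  fp <- sum(pred == "high" & labels == "low")
  fn <- sum(pred == "low" & labels == "high")
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

.fitClassifier <- function(x, y01, cfg) {
  switch(cfg$classifier,
    xgboost = {
      dm <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1),
        data = dm, nrounds = cfg$nrounds, verbose = 0)
    },
    randomForest = {
      requireNamespace("randomForest")
      randomForest::randomForest(x, factor(y01, levels = c(0, 1)))
    },
    svm = {
      requireNamespace("e1071")
      e1071::svm(x, factor(y01, levels = c(0, 1)), probability = TRUE)
    },
    mlp = {
      requireNamespace("nnet")
      nnet::nnet(x, y01, size = 16, decay = 0, maxit = 200, trace = FALSE)
    })
}

.predictProb <- function(model, x, cfg) {
  switch(cfg$classifier,
    xgboost = as.numeric(
      stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))),
    randomForest = as.numeric(
      stats::predict(model, x, type = "prob")[, "1"]),
    svm = {
      p <- stats::predict(model, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    },
    mlp = as.numeric(stats::predict(model, x)))
}

.modelGain <- function(model, featNames, cfg) {
  if (cfg$classifier != "xgboost") return(NULL)
  imp <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  g <- setNames(numeric(length(featNames)), featNames)
  if (!is.null(imp) && nrow(imp)) g[imp$Feature] <- imp$Gain
  g
}

#' Repeated stratified cross-validated classification
#'
#' Runs \code{nRepeats} independent stratified \code{nFolds}-fold
#' partitions (500 fold evaluations at the defaults). In each fold the
#' top-k features are selected by ANOVA F on the training portion only
#' (unless \code{paperModeSelection}), a classifier is fitted with library
#' defaults and scored on the held-out portion. Reports per-fold AUROC and
#' F1, their medians over all evaluated folds, normalized mean-gain feature
#' importances (tree classifier), and per-complex misclassification rates.
#' Folds whose training portion is single-class are skipped with a warning.
#'
#' @param x numeric matrix, complexes x features, rownames = complex ids.
#' @param labels \code{"high"}/\code{"low"} labels (or logical, TRUE =
#'   high), parallel to rows of \code{x}.
#' @param cfg a \code{\link{cvConfig}}.
#' @return A \linkS4class{CVReport}.
#' @export
runCV <- function(x, labels, cfg = cvConfig()) {
  labels <- .normalizeLabels(labels)
  stopifnot(nrow(x) == length(labels))
  if (nrow(x) < 2 * cfg$nFolds)
    stop("need at least 2 x nFolds labeled complexes")
  if (is.null(rownames(x))) rownames(x) <- paste0("cx", seq_len(nrow(x)))
  y01 <- as.integer(labels == "high")
  set.seed(cfg$seed)
  globalSel <- if (cfg$paperModeSelection)
    anovaFSelect(x, labels, cfg$selectorK) else NULL
  metrics <- vector("list", cfg$nRepeats * cfg$nFolds)
  selected <- list()
  folds <- vector("list", cfg$nRepeats)
  gains <- NULL
  nModels <- 0L
  held <- wrong <- setNames(integer(nrow(x)), rownames(x))
  skipped <- 0L
  mi <- 0L
  for (r in seq_len(cfg$nRepeats)) {
    fold <- makeStratifiedFolds(labels, cfg$nFolds)
    folds[[r]] <- fold
    for (f in seq_len(cfg$nFolds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(labels[train])) < 2L) {
        warning("fold ", f, " of repeat ", r,
                " skipped: single-class training set")
        skipped <- skipped + 1L
        next
      }
      sel <- if (cfg$paperModeSelection) globalSel
      else anovaFSelect(x[train, , drop = FALSE], labels[train],
                        cfg$selectorK)
      selected[[length(selected) + 1L]] <- sel
      model <- .fitClassifier(x[train, sel, drop = FALSE], y01[train], cfg)
      prob <- .predictProb(model, x[test, sel, drop = FALSE], cfg)
      mi <- mi + 1L
      metrics[[mi]] <- data.frame(
        rep = r, fold = f, auc = .auc(labels[test], prob),
        f1 = .f1(labels[test], prob), nTest = length(test))
      g <- .modelGain(model, sel, cfg)
      if (!is.null(g)) {
        if (is.null(gains)) gains <- setNames(numeric(0), character(0))
        for (nm in names(g))
          gains[nm] <- (if (nm %in% names(gains)) gains[nm] else 0) + g[nm]
        nModels <- nModels + 1L
      }
      held[test] <- held[test] + 1L
      miss <- (prob > 0.5) != (y01[test] == 1L)
      wrong[test] <- wrong[test] + as.integer(miss)
    }
  }
  metrics <- do.call(rbind, metrics[seq_len(mi)])
  imp <- if (!is.null(gains) && sum(gains) > 0) {
    v <- gains / nModels
    v <- v / sum(v)
    data.frame(feature = names(v), importance = as.numeric(v),
               stringsAsFactors = FALSE)[order(-v), ]
  } else data.frame(feature = character(), importance = numeric(),
                    stringsAsFactors = FALSE)
  rownames(imp) <- NULL
  mis <- data.frame(id = rownames(x), timesHeldOut = as.integer(held),
                    timesWrong = as.integer(wrong),
                    rate = ifelse(held > 0, wrong / held, NA_real_),
                    stringsAsFactors = FALSE)
  new("CVReport",
      foldMetrics = metrics,
      medianAUC = median(metrics$auc, na.rm = TRUE),
      medianF1 = median(metrics$f1, na.rm = TRUE),
      importances = imp, misclassification = mis,
      selectedFeatures = selected, folds = folds,
      skippedFolds = skipped, config = unclass(cfg))
}

setMethod("show", "CVReport", function(object) {
  cat("CVReport: ", nrow(object@foldMetrics), " fold evaluations (",
      object@config$nRepeats, " x ", object@config$nFolds, "-fold, ",
      object@config$classifier, ")\n", sep = "")
  cat(sprintf("  median AUROC %.3f, median F1 %.3f\n",
              object@medianAUC, object@medianF1))
  if (object@skippedFolds)
    cat("  skipped folds:", object@skippedFolds, "\n")
})

#' CVReport accessors
#'
#' @param x a \linkS4class{CVReport}.
#' @return \code{medianAUC}/\code{medianF1} the median fold metrics;
#'   \code{foldMetrics} the per-fold data.frame; \code{misclassification}
#'   the per-complex misclassification table.
#' @name CVReport-accessors
NULL

#' @rdname CVReport-accessors
#' @export
medianAUC <- function(x) x@medianAUC

#' @rdname CVReport-accessors
#' @export
medianF1 <- function(x) x@medianF1

#' @rdname CVReport-accessors
#' @export
foldMetrics <- function(x) x@foldMetrics

#' @rdname CVReport-accessors
#' @export
misclassification <- function(x) x@misclassification

#' Label-randomization control
#'
#' Reruns the cross-validation on label permutations; a healthy pipeline
#' returns a median AUROC of about 0.5, confirming that reported signal
#' comes from feature-label association and not from leakage. By default
#' each repeat draws a fresh permutation, so the pooled fold metrics
#' average over randomizations: a single fixed permutation retains one
#' realized spurious feature-label association that the classifier
#' exploits (or anti-learns) consistently across all folds, giving medians
#' that scatter widely around 0.5.
#'
#' @param x feature matrix as in \code{\link{runCV}}.
#' @param labels true labels.
#' @param cfg a \code{\link{cvConfig}}.
#' @param reshufflePerRepeat draw a fresh permutation for every repeat
#'   (default TRUE); FALSE shuffles once and runs the full CV on it.
#' @param identityPermutation if TRUE the labels are left untouched,
#'   reproducing \code{runCV} exactly.
#' @return A \linkS4class{CVReport} pooled over the shuffled runs.
#' @export
randomizationControl <- function(x, labels, cfg = cvConfig(),
                                 reshufflePerRepeat = TRUE,
                                 identityPermutation = FALSE) {
  labels <- .normalizeLabels(labels)
  if (identityPermutation) return(runCV(x, labels, cfg))
  set.seed(cfg$seed)
  if (!reshufflePerRepeat) {
    labels <- labels[sample.int(length(labels))]
    subSeed <- sample.int(.Machine$integer.max, 1)
    cfg$seed <- subSeed
    return(runCV(x, labels, cfg))
  }
  perms <- replicate(cfg$nRepeats, sample.int(length(labels)),
                     simplify = FALSE)
  subSeeds <- sample.int(.Machine$integer.max, cfg$nRepeats)
  oneCfg <- cfg
  oneCfg$nRepeats <- 1L
  runs <- lapply(seq_len(cfg$nRepeats), function(r) {
    oneCfg$seed <- subSeeds[r]
    runCV(x, labels[perms[[r]]], oneCfg)
  })
  metrics <- do.call(rbind, lapply(seq_along(runs), function(r) {
    m <- foldMetrics(runs[[r]])
    m$rep <- r
    m
  }))
  new("CVReport",
      foldMetrics = metrics,
      medianAUC = median(metrics$auc, na.rm = TRUE),
      medianF1 = median(metrics$f1, na.rm = TRUE),
      importances = data.frame(feature = character(),
                               importance = numeric(),
                               stringsAsFactors = FALSE),
      misclassification = data.frame(id = character(),
                                     timesHeldOut = integer(),
                                     timesWrong = integer(),
                                     rate = numeric(),
                                     stringsAsFactors = FALSE),
      selectedFeatures = list(),
      folds = lapply(runs, function(r) r@folds[[1]]),
      skippedFolds = sum(vapply(runs, function(r) r@skippedFolds,
                                integer(1))),
      config = unclass(cfg))
}

#' Ranked feature importances
#'
#' @param report a \linkS4class{CVReport} from a tree-based classifier.
#' @return data.frame \code{feature}, \code{importance} (normalized mean
#'   gain over all fitted models; sums to 1 when any split occurred),
#'   sorted decreasing.
#' @export
featureImportances <- function(report) {
  if (nrow(report@importances) == 0L)
    stop("importances require a tree-based classifier")
  report@importances
}

#' Track recurrently misclassified complexes
#'
#' Flags complexes misclassified at a rate of at least
#' \code{rateThreshold} by classifiers of at least \code{setThreshold} of
#' the feature sets (the paper's screen uses >= 80 percent in >= 7 of 9
#' sets: the eight single-set classifiers plus the combined one).
#'
#' @param reports named list of \linkS4class{CVReport}, one per feature-set
#'   classifier.
#' @param rateThreshold per-set misclassification rate cutoff (default 0.8).
#' @param setThreshold minimum number of feature sets (default 7).
#' @return Character vector of flagged complex ids.
#' @export
trackMisclassified <- function(reports, rateThreshold = 0.80,
                               setThreshold = 7) {
  rates <- lapply(reports, function(rep) {
    m <- rep@misclassification
    setNames(m$rate, m$id)
  })
  ids <- unique(unlist(lapply(rates, names)))
  nBad <- vapply(ids, function(id) {
    sum(vapply(rates, function(r)
      !is.na(r[id]) && r[id] >= rateThreshold, logical(1)))
  }, numeric(1))
  ids[nBad >= setThreshold]
}

#' Feature-feature and feature-affinity Pearson correlations
#'
#' Appends the affinity (as -log10 KD) to the feature matrix and returns
#' the full Pearson correlation matrix. Constant columns get correlation 0
#' and are listed in the \code{"constantColumns"} attribute.
#'
#' @param x numeric matrix, complexes x features.
#' @param affinities KD values in molar (converted internally) or values
#'   already on the -log10 scale if \code{isNegLog = TRUE}.
#' @param isNegLog interpret \code{affinities} as already -log10(KD).
#' @return Symmetric correlation matrix with unit diagonal and an
#'   \code{"affinity"} column/row.
#' @export
featureAffinityCorrelations <- function(x, affinities, isNegLog = FALSE) {
  stopifnot(nrow(x) >= 3)
  aff <- if (isNegLog) affinities else negLog10Kd(affinities)
  m <- cbind(x, affinity = aff)
  const <- apply(m, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  r <- suppressWarnings(cor(m, method = "pearson"))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  attr(r, "constantColumns") <- colnames(m)[const]
  r
}
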