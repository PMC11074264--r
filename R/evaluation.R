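#' Binary confusion counts
#'
#' Cross-tabulates true against predicted 0/1 labels with class 1 ("high")
#' as positive.
#'
#' @param yTrue,yPred integer 0/1 vectors of equal length `>= 1`.
#' @return a \linkS4class{ConfusionCounts}.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))   # TP=1 FN=1 TN=1 FP=1
#' @export
confusionCounts <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  stopIfNot(length(yTrue) == length(yPred),
            sprintf("length mismatch: %d true vs %d predicted labels",
                    length(yTrue), length(yPred)))
  stopIfNot(length(yTrue) >= 1L, "label vectors must be non-empty")
  stopIfNot(all(yTrue %in% c(0L, 1L)) && all(yPred %in% c(0L, 1L)),
            "labels must be binary (0/1)")
  new("ConfusionCounts",
      tp = sum(yTrue == 1L & yPred == 1L),
      tn = sum(yTrue == 0L & yPred == 0L),
      fp = sum(yTrue == 0L & yPred == 1L),
      fn = sum(yTrue == 1L & yPred == 0L))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). A metric whose denominator is zero is reported as 0 and
#' its name appears in `flags` rather than raising an error.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return list with `accuracy`, `precision`, `recall`, `f1` and the
#'   character vector `flags`.
#' @examples
#' classifierMetrics(confusionCounts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0)))
#' @export
classifierMetrics <- function(counts) {
  stopIfNot(is(counts, "ConfusionCounts"), "counts must be ConfusionCounts")
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  stopIfNot(total > 0L, "no evaluated examples")
  flags <- character()
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  acc <- (tp + tn) / total
  pre <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * pre * rec, pre + rec, "f1")
  list(accuracy = acc, precision = pre, recall = rec, f1 = f1, flags = flags)
}

#' Stratified hold-out split
#'
#' Shuffles within each label class and allocates test members per class by
#' the largest-remainder rule: each class contributes
#' `floor(n_c * testFraction)` members (at least 1, at most `n_c - 1`) and
#' the classes with the largest fractional parts absorb the remainder until
#' the overall test size is `round(n * testFraction)`. Class proportions in
#' the test set therefore match the global ones within one member.
#'
#' @param n number of examples.
#' @param testFraction test share in (0, 1).
#' @param stratifyOn label vector of length `n`.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @examples
#' s <- holdoutSplit(100, 0.25, rep(c(0, 1), 50), seed = 7)
#' lengths(s)   # 75 / 25
#' @export
holdoutSplit <- function(n, testFraction, stratifyOn, seed = 1L) {
  stopIfNot(testFraction > 0 && testFraction < 1,
            "testFraction must lie in (0, 1)")
  stopIfNot(length(stratifyOn) == n, "stratifyOn must have length n")
  classes <- sort(unique(stratifyOn))
  sizes <- vapply(classes, function(cls) sum(stratifyOn == cls), integer(1))
  for (i in seq_along(classes))
    stopIfNot(sizes[i] >= 2L,
              sprintf("class '%s' has %d member(s); need >= 2 for a split",
                      classes[i], sizes[i]))
  exact <- sizes * testFraction
  nTest <- pmin(pmax(floor(exact), 1L), sizes - 1L)
  target <- min(max(round(n * testFraction), length(classes)),
                n - length(classes))
  # largest-remainder top-up toward the overall target size
  for (i in order(exact - floor(exact), decreasing = TRUE)) {
    if (sum(nTest) >= target) break
    if (nTest[i] < sizes[i] - 1L) nTest[i] <- nTest[i] + 1L
  }
  test <- integer()
  withLocalSeed(seed, {
    for (i in seq_along(classes)) {
      members <- which(stratifyOn == classes[i])
      test <- c(test, sample(members)[seq_len(nTest[i])])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Stratified k-fold partition
#'
#' Deals each class's shuffled members round-robin across folds with a
#' rotating offset, so the folds partition `1..n`, differ in size by at
#' most 1, and are stratified within each class up to 1 member.
#'
#' @param n number of examples.
#' @param k number of folds, `2 <= k <= n`.
#' @param stratifyOn label vector of length `n`.
#' @param seed integer seed.
#' @return list of `k` disjoint integer index vectors covering `1..n`.
#' @examples
#' lengths(kFold(11, 5, rep(c(0, 1), length.out = 11), seed = 3))
#' @export
kFold <- function(n, k, stratifyOn, seed = 1L) {
  k <- as.integer(k)
  stopIfNot(k >= 2L, "k must be >= 2")
  stopIfNot(k <= n, sprintf("k (%d) exceeds n (%d)", k, n))
  stopIfNot(length(stratifyOn) == n, "stratifyOn must have length n")
  folds <- vector("list", k)
  offset <- 0L
  withLocalSeed(seed, {
    for (cls in sort(unique(stratifyOn))) {
      members <- sample(which(stratifyOn == cls))
      f <- ((seq_along(members) - 1L + offset) %% k) + 1L
      for (j in seq_len(k))
        folds[[j]] <- c(folds[[j]], members[f == j])
      offset <- (offset + length(members)) %% k
    }
  })
  lapply(folds, sort)
}

#' Normal-approximation binomial confidence interval
#'
#' `pHat +/- z * sqrt(pHat (1 - pHat) / n)`, clipped to `[0, 1]`;
#' `level = 0.95` gives `z = 1.95996...`.
#'
#' @param pHat observed proportion in `[0, 1]`.
#' @param n number of observations, `>= 1`.
#' @param level confidence level in (0, 1).
#' @return numeric `(lo, hi)`.
#' @examples
#' proportionCI(0.9, 100)   # (0.8412, 0.9588)
#' @export
proportionCI <- function(pHat, n, level = 0.95) {
  stopIfNot(level > 0 && level < 1, "level must lie in (0, 1)")
  stopIfNot(pHat >= 0 && pHat <= 1, "pHat must lie in [0, 1]")
  stopIfNot(n >= 1, "n must be >= 1")
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(pHat * (1 - pHat) / n)
  c(max(0, pHat - half), min(1, pHat + half))
}

evalOnSplit <- function(features, dimension, cfg, trainIdx, testIdx,
                        labels = NULL) {
  model <- trainModel(features, dimension, cfg, trainIdx = trainIdx,
                      labels = labels)
  X <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  y <- if (is.null(labels)) featureLabels(features, dimension)
       else as.integer(labels)
  pred <- predictClasses(model, X[testIdx, , drop = FALSE])
  list(model = model, counts = confusionCounts(y[testIdx], pred))
}

#' Run a full train/evaluate experiment
#'
#' Orchestrates the pipeline on a feature matrix (or a raw recording, which
#' is first passed through [extractFeatures()]): stratified split per the
#' protocol, CFNN training on the training side, prediction on the test
#' side, metrics and a binomial confidence interval on accuracy. For k-fold
#' protocols each fold serves as the test set once; reported metrics are
#' unweighted means over folds, the interval uses the pooled test count,
#' and `perFold` holds the fold-level rows.
#'
#' @param x a \linkS4class{FeatureMatrix} or an \linkS4class{EEGRecording}.
#' @param protocol `list(type = "holdout", testFraction = 0.25)` or
#'   `list(type = "kfold", k = 5)`.
#' @param cfg a \linkS4class{CFNNConfig}; its seed is re-derived from
#'   `seed` so one experiment seed controls split and training.
#' @param dimension `"valence"` or `"arousal"`.
#' @param seed integer experiment seed.
#' @param ciLevel confidence level for the accuracy interval.
#' @param extractArgs list of arguments for [extractFeatures()] when `x` is
#'   a raw recording (must include `windowSize`).
#' @return an \linkS4class{EvalReport}.
#' @export
runExperiment <- function(x, protocol = list(type = "holdout", testFraction = 0.25),
                          cfg = cfnnConfig(), dimension = c("valence", "arousal"),
                          seed = 1L, ciLevel = 0.95, extractArgs = list()) {
  dimension <- matchDimension(dimension[1])
  if (is(x, "EEGRecording")) {
    stopIfNot("windowSize" %in% names(extractArgs),
              "extractArgs$windowSize is required for raw recordings")
    x <- do.call(extractFeatures, c(list(rec = x), extractArgs))
  }
  stopIfNot(is(x, "FeatureMatrix"), "x must be a FeatureMatrix or EEGRecording")
  stopIfNot(is.list(protocol) && "type" %in% names(protocol),
            "protocol must be a list with a 'type' element")
  y <- featureLabels(x, dimension)
  n <- length(y)
  cfg@seed <- as.integer(seed %% .Machine$integer.max)
  hash <- hashObject(cfg)

  if (protocol$type == "holdout") {
    stopIfNot("testFraction" %in% names(protocol),
              "holdout protocol needs testFraction")
    sp <- holdoutSplit(n, protocol$testFraction, y, seed = seed)
    res <- evalOnSplit(x, dimension, cfg, sp$train, sp$test)
    met <- classifierMetrics(res$counts)
    ci <- proportionCI(met$accuracy, length(sp$test), ciLevel)
    perFold <- data.frame()
    counts <- res$counts
  } else if (protocol$type == "kfold") {
    stopIfNot("k" %in% names(protocol), "kfold protocol needs k")
    folds <- kFold(n, protocol$k, y, seed = seed)
    rows <- vector("list", length(folds))
    agg <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (j in seq_along(folds)) {
      testIdx <- folds[[j]]
      trainIdx <- setdiff(seq_len(n), testIdx)
      foldCfg <- cfg
      foldCfg@seed <- as.integer((seed + j) %% .Machine$integer.max)
      res <- evalOnSplit(x, dimension, foldCfg, trainIdx, testIdx)
      m <- classifierMetrics(res$counts)
      rows[[j]] <- data.frame(fold = j, accuracy = m$accuracy,
                              precision = m$precision, recall = m$recall,
                              f1 = m$f1, nTest = length(testIdx))
      agg <- agg + c(tp = res$counts@tp, tn = res$counts@tn,
                     fp = res$counts@fp, fn = res$counts@fn)
    }
    perFold <- do.call(rbind, rows)
    met <- list(accuracy = mean(perFold$accuracy),
                precision = mean(perFold$precision),
                recall = mean(perFold$recall),
                f1 = mean(perFold$f1), flags = character())
    ci <- proportionCI(met$accuracy, n, ciLevel)
    counts <- new("ConfusionCounts", tp = agg[["tp"]], tn = agg[["tn"]],
                  fp = agg[["fp"]], fn = agg[["fn"]])
  } else {
    stop("unknown protocol type: ", protocol$type, call. = FALSE)
  }
  new("EvalReport", dimension = dimension, counts = counts,
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1, flags = met$flags,
      ci = ci, ciLevel = ciLevel, protocol = protocol,
      seed = as.integer(seed), configHash = hash, perFold = perFold)
}

setMethod("show", "EvalReport", function(object) {
  proto <- if (object@protocol$type == "holdout")
    sprintf("hold-out %g:%g", 100 * (1 - object@protocol$testFraction),
            100 * object@protocol$testFraction)
  else sprintf("%d-fold CV", object@protocol$k)
  cat(sprintf("EvalReport [%s, %s, seed %d]\n", object@dimension, proto,
              object@seed))
  cat(sprintf("  accuracy %.4f (%.4f-%.4f @ %g%%), precision %.4f, recall %.4f, F1 %.4f\n",
              object@accuracy, object@ci[1], object@ci[2],
              100 * object@ciLevel, object@precision, object@recall,
              object@f1))
  show(object@counts)
})

#' Write an evaluation report to JSON
#'
#' Serializes the full report — counts, metrics, flags, interval, protocol,
#' seed and config hash, plus per-fold rows when present — as pretty JSON.
#' Identical experiments produce byte-identical files.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  stopIfNot(is(report, "EvalReport"), "report must be an EvalReport")
  obj <- list(
    dimension = report@dimension,
    counts = list(tp = report@counts@tp, tn = report@counts@tn,
                  fp = report@counts@fp, fn = report@counts@fn),
    metrics = list(accuracy = report@accuracy, precision = report@precision,
                   recall = report@recall, f1 = report@f1),
    flags = report@flags,
    ci = list(lo = report@ci[1], hi = report@ci[2], level = report@ciLevel),
    protocol = report@protocol,
    seed = report@seed,
    configHash = report@configHash)
  if (nrow(report@perFold)) obj$perFold <- report@perFold
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
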