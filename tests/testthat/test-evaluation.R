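test_that("confusion counts match hand counts and identities", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(c(cc@tp, cc@fn, cc@tn, cc@fp), c(1L, 1L, 1L, 1L))
  y <- c(1, 0, 1, 1, 0)
  same <- confusionCounts(y, y)
  expect_equal(same@fp + same@fn, 0L)
  inv <- confusionCounts(y, 1 - y)
  expect_equal(inv@tp + inv@tn, 0L)
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("metrics reproduce direct evaluation of their formulas", {
  cc <- new("ConfusionCounts", tp = 3L, tn = 2L, fp = 1L, fn = 0L)
  m <- classifierMetrics(cc)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 6 / 7)
  expect_length(m$flags, 0)
})

test_that("metric identities hold on randomized counts", {
  set.seed(13)
  for (i in 1:25) {
    v <- as.integer(rmultinom(1, 40, rep(1 / 4, 4)))
    cc <- new("ConfusionCounts", tp = v[1], tn = v[2], fp = v[3], fn = v[4])
    m <- classifierMetrics(cc)
    expect_equal(m$accuracy, (v[1] + v[2]) / 40)
    if (!length(m$flags)) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
    if (m$precision == m$recall && !length(m$flags))
      expect_equal(m$f1, m$precision)
  }
})

test_that("degenerate denominators are flagged as zero, not errors", {
  cc <- new("ConfusionCounts", tp = 0L, tn = 5L, fp = 0L, fn = 0L)
  m <- classifierMetrics(cc)
  expect_equal(m$precision, 0)
  expect_true(all(c("precision", "recall", "f1") %in% m$flags))
})

test_that("hold-out splits are disjoint, exhaustive, stratified, seeded", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    y <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (min(table(y)) < 2) next
    frac <- runif(1, 0.15, 0.4)
    sp <- holdoutSplit(n, frac, y, seed = i)
    expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0)
    # per-class test counts within 1 of the proportional share
    for (cls in 0:1) {
      want <- sum(y == cls) * frac
      got <- sum(y[sp$test] == cls)
      expect_lte(abs(got - want), 1)
    }
  }
  sp <- holdoutSplit(100, 0.25, rep(c(0, 1), 50), seed = 1)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_identical(sp, holdoutSplit(100, 0.25, rep(c(0, 1), 50), seed = 1))
  expect_error(holdoutSplit(3, 0.5, c(0, 0, 1)), ">= 2")
})

test_that("k-fold partitions are balanced, stratified and seeded", {
  folds <- kFold(10, 5, rep(c(0, 1), 5), seed = 2)
  expect_equal(lengths(folds), rep(2L, 5))
  expect_equal(sort(unlist(folds)), 1:10)
  f11 <- kFold(11, 5, rep_len(c(0, 1), 11), seed = 2)
  expect_equal(sort(lengths(f11), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  expect_equal(sort(unlist(f11)), 1:11)
  expect_identical(kFold(30, 4, rep_len(0:1, 30), seed = 9),
                   kFold(30, 4, rep_len(0:1, 30), seed = 9))
  set.seed(23)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    k <- sample(2:6, 1)
    y <- rbinom(n, 1, 0.5)
    fl <- kFold(n, k, y, seed = i)
    expect_equal(sort(unlist(fl)), seq_len(n))
    expect_lte(diff(range(lengths(fl))), 1)
    # stratification: per-class fold counts within 1
    for (cls in 0:1) {
      perFold <- vapply(fl, function(f) sum(y[f] == cls), integer(1))
      expect_lte(diff(range(perFold)), 1)
    }
  }
  expect_error(kFold(4, 5, rep(0:1, 2)), "exceeds")
})

test_that("binomial confidence intervals follow the normal approximation", {
  ci <- proportionCI(0.9, 100, 0.95)
  expect_equal(ci[1], 0.9 - qnorm(0.975) * sqrt(0.09 / 100), tolerance = 1e-12)
  expect_equal(ci[2], 0.9 + qnorm(0.975) * sqrt(0.09 / 100), tolerance = 1e-12)
  expect_equal(round(ci, 4), c(0.8412, 0.9588))
  # width shrinks with n; boundary clipping
  expect_lt(diff(proportionCI(0.5, 10000)), diff(proportionCI(0.5, 100)))
  expect_equal(proportionCI(1, 50), c(1, 1))
  expect_error(proportionCI(0.5, 10, level = 1.2), "level")
})

test_that("experiments produce consistent, reproducible reports", {
  cfg <- tinyConfig(inputLen = 20L, epochs = 8L)
  spec <- syntheticSpec(nTrials = 8L, nChannels = 4L, duration = 2, seed = 21L)
  rec <- generateDataset(spec)$recording
  rep1 <- runExperiment(rec, protocol = list(type = "holdout", testFraction = 0.25),
                        cfg = cfg, dimension = "valence", seed = 31L,
                        extractArgs = list(windowSize = 128L, step = 64L))
  expect_s4_class(rep1, "EvalReport")
  tot <- rep1@counts@tp + rep1@counts@tn + rep1@counts@fp + rep1@counts@fn
  expect_equal(rep1@accuracy, (rep1@counts@tp + rep1@counts@tn) / tot)
  expect_gte(rep1@accuracy, rep1@ci[1])
  expect_lte(rep1@accuracy, rep1@ci[2])
  # byte-identical reports under the same seed
  rep2 <- runExperiment(rec, protocol = list(type = "holdout", testFraction = 0.25),
                        cfg = cfg, dimension = "valence", seed = 31L,
                        extractArgs = list(windowSize = 128L, step = 64L))
  f1 <- tempfile(); f2 <- tempfile()
  writeReport(rep1, f1); writeReport(rep2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("k-fold experiments use every example as test exactly once", {
  spec <- syntheticSpec(nTrials = 6L, nChannels = 4L, duration = 2, seed = 22L)
  rec <- generateDataset(spec)$recording
  fm <- extractFeatures(rec, windowSize = 128L, step = 128L)
  cfg <- tinyConfig(inputLen = 20L, epochs = 5L)
  repk <- runExperiment(fm, protocol = list(type = "kfold", k = 3L),
                        cfg = cfg, dimension = "valence", seed = 41L)
  n <- length(featureLabels(fm, "valence"))
  tot <- repk@counts@tp + repk@counts@tn + repk@counts@fp + repk@counts@fn
  expect_equal(tot, n)                       # pooled counts cover all examples
  expect_equal(nrow(repk@perFold), 3L)
  expect_equal(sum(repk@perFold$nTest), n)
  expect_equal(repk@accuracy, mean(repk@perFold$accuracy))
})
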