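test_that("the default architecture accounts for every parameter", {
  s <- modelSummary(buildModel(cfnnConfig()))
  r <- s@rows
  expect_equal(r$params[r$layer == "Conv1D"], c(384L, 6176L))
  expect_equal(r$params[r$layer == "Fuzzy"], 4608L)
  expect_equal(r$params[r$layer == "BatchNormalization"], 8L)
  expect_equal(r$nonTrainable[r$layer == "BatchNormalization"], 4L)
  expect_equal(r$params[r$layer == "Dense"], 6L)
  expect_equal(r$params[r$layer == "Defuzzy"], 4L)
  expect_equal(r$outputShape[r$layer == "Flatten"], "(None, 1152)")
  expect_equal(unname(s@totals),
               c(11186, 11182, 4)[match(names(s@totals),
                                        c("total", "trainable", "nonTrainable"))])
  expect_true(validObject(s))
})

test_that("parameter counts track the architecture hyperparameters", {
  cfg <- cfnnConfig(inputLen = 21L, conv1Filters = 6L, conv1Kernel = 3L,
                    conv2Filters = 4L, conv2Kernel = 3L, nRules = 3L)
  s <- modelSummary(buildModel(cfg))
  r <- s@rows
  expect_equal(r$params[1], 6L * 3L + 6L)            # conv1
  expect_equal(r$params[2], 4L * 3L * 6L + 4L)       # conv2
  D <- (21L %/% 2L) * 4L
  expect_equal(r$params[r$layer == "Fuzzy"], D * 3L * 2L)
  expect_equal(r$params[r$layer == "BatchNormalization"], 12L)
  expect_equal(r$params[r$layer == "Dense"], 3L * 2L + 2L)
  expect_equal(r$params[r$layer == "Defuzzy"], 2L * 3L)
})

test_that("forward passes are normalized, finite and deterministic", {
  cfg <- tinyConfig()
  m <- buildModel(cfg)
  set.seed(2)
  X <- matrix(rnorm(7 * 10), 7, 10)
  p1 <- forwardPass(m, X)
  expect_equal(dim(p1), c(7L, 2L))
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 7), tolerance = 1e-6)
  expect_true(all(is.finite(p1)))
  expect_identical(p1, forwardPass(m, X))
  # identical rows give identical outputs
  X2 <- X[c(1, 1, 3), ]
  p2 <- forwardPass(m, X2)
  expect_identical(p2[1, ], p2[2, ])
  # untrained balanced output stays away from collapse
  expect_gt(mean(p1[, 2]), 0.1)
  expect_lt(mean(p1[, 2]), 0.9)
  expect_error(forwardPass(m, matrix(0, 2, 25)), "features")
})

test_that("identical configs build identical models", {
  m1 <- buildModel(tinyConfig())
  m2 <- buildModel(tinyConfig())
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(tinyConfig(seed = 6L))
  expect_false(identical(m1@params, m3@params))
})

test_that("backprop matches finite differences through the whole network", {
  cfg <- cfnnConfig(inputLen = 9L, conv1Filters = 4L, conv1Kernel = 5L,
                    conv2Filters = 3L, conv2Kernel = 3L, poolSize = 2L,
                    nRules = 2L, seed = 3L)
  m <- buildModel(cfg)
  set.seed(9)
  n <- 5L
  X <- matrix(rnorm(n * 9), n, 9)
  y <- c(0L, 1L, 0L, 1L, 1L)
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y + 1L)] <- 1
  fw <- fuzzyEEG:::cfnnForward(m, X, training = TRUE)
  g <- fuzzyEEG:::cfnnBackward(m, fw$caches, fw$probs, Y)
  lossAt <- function(params) {
    m2 <- m; m2@params <- params
    p <- fuzzyEEG:::cfnnForward(m2, X, training = TRUE)$probs
    -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-300)))
  }
  h <- 1e-6
  set.seed(10)
  for (nm in names(m@params)) {
    p0 <- m@params[[nm]]
    for (i in sample(length(p0), min(5L, length(p0)))) {
      pp <- m@params; pp[[nm]][i] <- p0[i] + h
      pm <- m@params; pm[[nm]][i] <- p0[i] - h
      fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      expect_lt(abs(g[[nm]][i] - fd) / max(abs(fd), 1e-4), 1e-3,
                label = sprintf("%s[%d]", nm, i))
    }
  }
  # defuzzification centres all receive gradient on a generic batch
  expect_true(all(g$defuzzC != 0))
})

test_that("training separates blob classes and is seed-reproducible", {
  blob <- makeBlobFeatures()
  cfg <- tinyConfig()
  m1 <- trainModel(blob$X, "valence", cfg, labels = blob$y)
  m2 <- trainModel(blob$X, "valence", cfg, labels = blob$y)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
  expect_equal(nrow(m1@history), cfg@epochs)
  # loss decreases and the training set is learned
  expect_lt(m1@history$loss[cfg@epochs], m1@history$loss[1])
  expect_gt(mean(predictClasses(m1, blob$X) == blob$y), 0.95)
  # moving-average loss decreases over the first 10 epochs
  ma <- stats::filter(m1@history$loss[1:12], rep(1 / 3, 3), sides = 1)
  expect_lt(ma[12], ma[3])
})

test_that("single-class training sets are rejected", {
  blob <- makeBlobFeatures(n = 20L)
  expect_error(trainModel(blob$X, "valence", tinyConfig(),
                          labels = rep(1L, 20L)), "both classes")
})

test_that("feature padding adapts 70-wide tables to the 73-wide default", {
  cfg <- cfnnConfig(epochs = 1L, batchSize = 16L)
  X <- matrix(rnorm(12 * 70), 12, 70)
  y <- rep_len(c(0L, 1L), 12L)
  m <- trainModel(X, "valence", cfg, labels = y)
  expect_equal(dim(forwardPass(m, X)), c(12L, 2L))
  cfgNoPad <- cfnnConfig(epochs = 1L, padFeatures = FALSE)
  expect_error(trainModel(X, "valence", cfgNoPad, labels = y), "padFeatures")
})

test_that("checkpoints round-trip through save/load", {
  blob <- makeBlobFeatures(n = 24L)
  m <- trainModel(blob$X, "valence", tinyConfig(epochs = 3L), labels = blob$y)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f, historyJSON = TRUE)
  back <- loadModel(f)
  expect_identical(back@params, m@params)
  expect_identical(back@history, m@history)
  expect_identical(forwardPass(back, blob$X), forwardPass(m, blob$X))
  expect_true(file.exists(paste0(f, ".history.json")))
  unlink(c(f, paste0(f, ".history.json")))
})

test_that("invalid configurations are rejected", {
  expect_error(cfnnConfig(nClasses = 3L), "nClasses")
  expect_error(cfnnConfig(inputLen = 2L), "kernel")
  expect_error(cfnnConfig(aggregation = "product"), "aggregation")
})
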