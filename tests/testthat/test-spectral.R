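test_that("dft matches the direct-summation oracle on all lengths <= 64", {
  set.seed(11)
  for (N in c(1:8, 13, 16, 31, 32, 48, 64)) {
    x <- rnorm(N)
    got <- spectrumCoefficients(dft(x))
    want <- directDFT(x)
    expect_lt(max(Mod(got - want)) / max(Mod(want), 1), 1e-9)
  }
})

test_that("dft closed forms: constant and impulse", {
  sp <- dft(rep(3, 8))
  co <- spectrumCoefficients(sp)
  expect_equal(co[1], 24 + 0i)
  expect_lt(max(Mod(co[-1])), 1e-12)
  sp2 <- dft(c(1, rep(0, 7)))
  expect_lt(max(Mod(spectrumCoefficients(sp2) - 1)), 1e-12)
})

test_that("inverse transform recovers the input and Parseval holds", {
  set.seed(21)
  for (N in c(5, 16, 33)) {
    x <- rnorm(N)
    sp <- dft(x, fs = 128)
    expect_lt(max(abs(idft(sp) - x)) / max(abs(x)), 1e-9)
    lhs <- sum(x^2)
    rhs <- sum(Mod(spectrumCoefficients(sp))^2) / N
    expect_lt(abs(lhs - rhs) / lhs, 1e-6)
  }
})

test_that("conjugate symmetry holds for real input", {
  set.seed(31)
  x <- rnorm(16)
  co <- spectrumCoefficients(dft(x))
  expect_lt(max(Mod(co[2:16] - Conj(rev(co[2:16])))), 1e-9)
})

test_that("a pure sinusoid concentrates power in its own band", {
  fs <- 128; N <- 256
  x <- sin(2 * pi * 10 * (0:(N - 1)) / fs)
  sp <- dft(x, fs = fs)
  bands <- eegBands()
  p <- vapply(seq_len(nrow(bands)), function(b) bandPower(sp, bands[b, ]),
              numeric(1))
  names(p) <- bands$name
  expect_gt(p[["alpha"]], 100 * max(p[names(p) != "alpha"]))
})

test_that("band power is zero for silence and validates band edges", {
  sp <- dft(numeric(64) + 0, fs = 128)
  expect_equal(bandPower(sp, bandDefinition("alpha", 8, 12)), 0)
  expect_error(bandPower(sp, bandDefinition("bad", 10, 70)), "Nyquist")
  expect_error(dft(numeric(0)), "non-empty")
})

test_that("white-noise band powers are proportional to band bin counts", {
  fs <- 128; N <- 4096
  set.seed(41)
  reps <- 24
  bands <- eegBands()
  acc <- matrix(0, reps, nrow(bands))
  for (r in seq_len(reps)) {
    sp <- dft(rnorm(N), fs = fs)
    acc[r, ] <- vapply(seq_len(nrow(bands)),
                       function(b) bandPower(sp, bands[b, ]), numeric(1))
  }
  # mean |X_k|^2 = N for every bin of unit white noise, in every band
  m <- colMeans(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(m - N) <= 3 * se + 1e-9))
})

test_that("band powers are invariant to time reversal and circular shifts", {
  set.seed(51)
  x <- rnorm(256)
  bands <- eegBands()
  p0 <- vapply(seq_len(nrow(bands)),
               function(b) bandPower(dft(x, fs = 128), bands[b, ]), numeric(1))
  for (variant in list(rev(x), c(x[100:256], x[1:99]))) {
    p1 <- vapply(seq_len(nrow(bands)),
                 function(b) bandPower(dft(variant, fs = 128), bands[b, ]),
                 numeric(1))
    expect_equal(p1, p0, tolerance = 1e-9)
  }
})

test_that("window counting follows the closed-form formula", {
  set.seed(61)
  for (i in 1:6) {
    ns <- sample(64:512, 1)
    w <- sample(16:ns, 1)
    st <- sample(1:64, 1)
    rec <- makeRecording(nTrials = 2L, nChannels = 2L, nSamples = ns)
    fm <- extractFeatures(rec, windowSize = w, step = st, minFFTLen = 64L)
    expect_equal(ncol(SummarizedExperiment::assay(fm, "power")),
                 2L * ((ns - w) %/% st + 1L),
                 label = sprintf("ns=%d w=%d step=%d", ns, w, st))
  }
  # the worked example: 1024 samples, window 256, step 128 -> 7 per trial
  rec <- makeRecording(nTrials = 1L, nSamples = 1024L)
  fm <- extractFeatures(rec, windowSize = 256L, step = 128L)
  expect_equal(ncol(SummarizedExperiment::assay(fm, "power")), 7L)
  # full-length window -> exactly 1 window regardless of step
  fm1 <- extractFeatures(rec, windowSize = 1024L, step = 17L)
  expect_equal(ncol(SummarizedExperiment::assay(fm1, "power")), 1L)
  # window larger than the trial is refused
  expect_error(extractFeatures(rec, windowSize = 2048L), "exceeds")
})

test_that("feature layout is channel-major, band-minor with inherited labels", {
  rec <- makeRecording(nTrials = 2L, nChannels = 3L, nSamples = 256L)
  rec@ratings[, 1] <- c(8, 2)   # valence high, low
  rec@ratings[, 2] <- c(2, 8)   # arousal low, high
  fm <- extractFeatures(rec, windowSize = 128L, step = 64L)
  X <- featureValues(fm)
  expect_equal(ncol(X), 3L * 5L)
  expect_equal(colnames(X)[1:6],
               c("ch1_theta", "ch1_alpha", "ch1_beta_low", "ch1_beta_high",
                 "ch1_gamma", "ch2_theta"))
  expect_true(all(X >= 0))
  y <- featureLabels(fm, "valence")
  a <- featureLabels(fm, "arousal")
  tr <- SummarizedExperiment::colData(fm)$trial
  expect_identical(y, ifelse(tr == 1L, 1L, 0L))
  expect_identical(a, ifelse(tr == 1L, 0L, 1L))
  # 14 channels x 5 bands gives the canonical 70 features
  rec40 <- makeRecording(nTrials = 1L, nChannels = 40L, nSamples = 128L)
  fm70 <- extractFeatures(rec40, windowSize = 128L,
                          channels = defaultChannelSelection())
  expect_equal(nrow(SummarizedExperiment::assay(fm70, "power")), 70L)
})

test_that("ratings binarize with >= threshold as high", {
  r <- matrix(c(7, 3, 5, 4.999, 5, 5, 5, 5), 2, 4)
  expect_identical(binarizeRatings(r, "valence", 5), c(1L, 0L))
  expect_identical(binarizeRatings(r, "arousal", 5), c(1L, 0L))
  expect_error(binarizeRatings(r, "dominance"), "arg")
  expect_error(binarizeRatings(r, "valence", 9.5), "threshold")
})
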