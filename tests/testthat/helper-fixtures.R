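# Shared fixtures, built in code at test time.

# Small deterministic recording with arbitrary signal content.
makeRecording <- function(nTrials = 3L, nChannels = 4L, nSamples = 256L,
                          fs = 128, seed = 101L) {
  set.seed(seed)
  sig <- array(rnorm(nTrials * nChannels * nSamples),
               dim = c(nTrials, nChannels, nSamples))
  rat <- matrix(runif(nTrials * 4, 1, 9), nTrials, 4)
  EEGRecording(sig, rat, fs = fs, subjectID = "fix01",
               channelNames = sprintf("c%02d", seq_len(nChannels)))
}

# Two-class recording with disjoint dominant bands and no noise:
# class 0 = pure 10 Hz alpha, class 1 = pure 30 Hz gamma.
makePureBandRecording <- function(nTrials = 4L, nChannels = 2L,
                                  nSamples = 256L, fs = 128) {
  classes <- rep_len(c(0L, 1L), nTrials)
  tt <- (seq_len(nSamples) - 1L) / fs
  sig <- array(0, c(nTrials, nChannels, nSamples))
  for (tr in seq_len(nTrials)) {
    f <- if (classes[tr] == 0L) 10 else 30
    for (ch in seq_len(nChannels)) sig[tr, ch, ] <- sin(2 * pi * f * tt)
  }
  rat <- matrix(5, nTrials, 4)
  rat[, 1] <- ifelse(classes == 1L, 8, 2)
  rat[, 2] <- rat[, 1]
  list(rec = EEGRecording(sig, rat, fs = fs), classes = classes)
}

# O(N^2) direct summation of the DFT definition — the independent oracle.
directDFT <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * (0:(N - 1)) * kk / N))
  }, complex(1))
}

# Tiny separable feature problem for fast training tests: two Gaussian
# blobs in feature space.
makeBlobFeatures <- function(n = 60L, d = 10L, sep = 4, seed = 7L) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1L, 1:2] <- X[y == 1L, 1:2] + sep
  list(X = X, y = y)
}

tinyConfig <- function(inputLen = 10L, epochs = 30L, seed = 5L, ...) {
  cfnnConfig(inputLen = inputLen, conv1Filters = 8L, conv1Kernel = 5L,
             conv2Filters = 4L, conv2Kernel = 3L, poolSize = 2L,
             nRules = 2L, epochs = epochs, batchSize = 32L, seed = seed, ...)
}
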