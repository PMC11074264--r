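#' Default per-class band gain profiles
#'
#' The "low" class is alpha-dominant and the "high" class gamma-dominant,
#' mirroring the classical observation that high-frequency (gamma) activity
#' is the most discriminative band for affective state while leaving the
#' remaining bands weakly and equally expressed in both classes.
#'
#' @return named list with `low` and `high` amplitude-gain vectors over the
#'   five canonical bands.
#' @export
defaultBandProfiles <- function() {
  list(
    low  = c(theta = 0.3, alpha = 1.5, beta_low = 0.3, beta_high = 0.3, gamma = 0.1),
    high = c(theta = 0.3, alpha = 0.1, beta_low = 0.3, beta_high = 0.3, gamma = 1.5)
  )
}

#' Specify a synthetic affective-EEG dataset
#'
#' Builds a validated \linkS4class{SyntheticSpec}. Defaults describe a small
#' but fully testable recording: 8 trials of 16 channels, 8 s at 128 Hz,
#' balanced alternating classes driving alpha- versus gamma-dominant band
#' profiles over a pink-noise floor.
#'
#' @param nTrials,nChannels block dimensions.
#' @param fs sampling rate (Hz).
#' @param duration trial length (s); `duration * fs` must be an integer.
#' @param classValence,classArousal binary (0/1) per-trial class vectors;
#'   `classValence` defaults to alternating 0/1, `classArousal` to
#'   `classValence`. The valence assignment drives the spectral profile.
#' @param bandProfiles list with `low`/`high` named gain vectors over
#'   [eegBands()] names.
#' @param noiseSd pink-noise standard deviation (a.u.).
#' @param threshold rating cut in (1, 9); generated ratings fall strictly on
#'   the class's side so that [binarizeRatings()] at the same threshold
#'   recovers the assignment exactly.
#' @param sinusoidsPerBand random-frequency sinusoids per band and channel.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nTrials = 8L, nChannels = 16L, fs = 128,
                          duration = 8, classValence = NULL,
                          classArousal = NULL,
                          bandProfiles = defaultBandProfiles(),
                          noiseSd = 0.5, threshold = 5,
                          sinusoidsPerBand = 3L, seed = 1L) {
  nTrials <- as.integer(nTrials)
  if (is.null(classValence))
    classValence <- rep_len(c(0L, 1L), nTrials)
  if (is.null(classArousal))
    classArousal <- classValence
  new("SyntheticSpec",
      nTrials = nTrials, nChannels = as.integer(nChannels),
      fs = as.numeric(fs), duration = as.numeric(duration),
      classValence = as.integer(classValence),
      classArousal = as.integer(classArousal),
      bandProfiles = bandProfiles, noiseSd = as.numeric(noiseSd),
      threshold = as.numeric(threshold),
      sinusoidsPerBand = as.integer(sinusoidsPerBand),
      seed = as.integer(seed))
}

# Pink (1/f-power) noise of length n, unit variance, via spectral shaping of
# white Gaussian noise; deterministic given the ambient RNG state.
pinkNoise <- function(n) {
  w <- rnorm(n)
  if (n < 4L) return(w)
  W <- fft(w)
  k <- seq_len(n) - 1L
  kk <- pmin(k, n - k)           # symmetric bin distance from DC
  s <- ifelse(kk == 0, 0, 1 / sqrt(kk))
  x <- Re(fft(W * s, inverse = TRUE)) / n
  sdx <- stats::sd(x)
  if (sdx > 0) x / sdx else x
}

#' Generate a synthetic recording with class-dependent band power
#'
#' Each trial/channel signal is a sum over the five canonical bands of
#' `sinusoidsPerBand` sinusoids with frequencies drawn uniformly inside the
#' band and uniform random phases, scaled by the trial class's gain for that
#' band, plus pink background noise of scale `noiseSd`. Frequency and phase
#' draws do not depend on the gain values, so increasing one band's gain
#' changes that band's power only. Ratings are drawn uniformly from the open
#' interval on the class's side of `threshold` for each dimension, making
#' the label binarization exactly invertible. A fixed seed yields
#' bit-identical output.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements `recording` (an \linkS4class{EEGRecording})
#'   and `truth` (data.frame `trial`, `valence`, `arousal` of the generating
#'   classes).
#' @examples
#' out <- generateDataset(syntheticSpec(nTrials = 4L, nChannels = 4L,
#'                                      duration = 2))
#' out$truth
#' @export
generateDataset <- function(spec) {
  stopIfNot(is(spec, "SyntheticSpec"), "spec must be a SyntheticSpec")
  validObject(spec)
  bands <- eegBands()
  bandNames <- bands$name
  for (cls in c("low", "high"))
    stopIfNot(all(bandNames %in% names(spec@bandProfiles[[cls]])),
              sprintf("bandProfiles$%s must name every band: %s",
                      cls, paste(bandNames, collapse = ", ")))
  ns <- as.integer(round(spec@duration * spec@fs))
  tt <- (seq_len(ns) - 1L) / spec@fs
  sig <- array(0, c(spec@nTrials, spec@nChannels, ns))
  rat <- matrix(0, spec@nTrials, 4L)
  withLocalSeed(spec@seed, {
    for (tr in seq_len(spec@nTrials)) {
      cls <- if (spec@classValence[tr] == 1L) "high" else "low"
      gains <- spec@bandProfiles[[cls]][bandNames]
      for (ch in seq_len(spec@nChannels)) {
        x <- numeric(ns)
        for (b in seq_len(nrow(bands))) {
          hi <- min(bands$hi[b], spec@fs / 2)
          f <- runif(spec@sinusoidsPerBand, bands$lo[b], hi)
          ph <- runif(spec@sinusoidsPerBand, 0, 2 * pi)
          comp <- colSums(matrix(sin(outer(f, tt, function(fr, t) 2 * pi * fr * t) +
                                       ph), nrow = spec@sinusoidsPerBand))
          x <- x + gains[[b]] / sqrt(spec@sinusoidsPerBand) * comp
        }
        if (spec@noiseSd > 0) x <- x + spec@noiseSd * pinkNoise(ns)
        sig[tr, ch, ] <- x
      }
      th <- spec@threshold
      for (dimIdx in 1:2) {
        clsD <- if (dimIdx == 1L) spec@classValence[tr] else spec@classArousal[tr]
        rat[tr, dimIdx] <- if (clsD == 1L)
          th + (9 - th) * runif(1) else 1 + (th - 1) * runif(1)
      }
      rat[tr, 3:4] <- 1 + 8 * runif(2)   # dominance, liking: uninformative
    }
  })
  rec <- EEGRecording(sig, rat, fs = spec@fs,
                      subjectID = sprintf("synthetic-seed%d", spec@seed),
                      channelNames = sprintf("ch%02d", seq_len(spec@nChannels)))
  list(recording = rec,
       truth = data.frame(trial = seq_len(spec@nTrials),
                          valence = spec@classValence,
                          arousal = spec@classArousal))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d trials x %d channels, %g s @ %g Hz, noiseSd=%g, seed=%d\n",
              object@nTrials, object@nChannels, object@duration, object@fs,
              object@noiseSd, object@seed))
})
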