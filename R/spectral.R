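#' Frequency band definitions
#'
#' `bandDefinition` builds a one-row band table; `eegBands` returns the five
#' canonical analysis bands: theta 4--8, alpha 8--12, lower beta 12--16,
#' upper beta 16--25 and gamma 25--45 Hz. Intervals are half-open
#' `[lo, hi)` so adjacent bands sharing a printed edge never double-count a
#' frequency bin.
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @examples
#' eegBands()
#' @export
bandDefinition <- function(name, lo, hi) {
  stopIfNot(is.numeric(lo) && is.numeric(hi) && lo >= 0 && lo < hi,
            "band edges must satisfy 0 <= lo < hi")
  data.frame(name = as.character(name), lo = as.numeric(lo), hi = as.numeric(hi))
}

#' @rdname bandDefinition
#' @export
eegBands <- function() {
  rbind(
    bandDefinition("theta",     4, 8),
    bandDefinition("alpha",     8, 12),
    bandDefinition("beta_low",  12, 16),
    bandDefinition("beta_high", 16, 25),
    bandDefinition("gamma",     25, 45)
  )
}

#' Discrete Fourier transform of a real window
#'
#' Computes the two-sided DFT
#' \deqn{X_k = \sum_{i=0}^{N-1} x_i e^{-j 2 \pi i k / N}, \quad k = 0..N-1,}
#' optionally after zero padding to `nfft` samples (which refines the bin
#' spacing `fs / nfft` so that narrow bands contain bins even for short
#' windows). The transform itself is evaluated with the fast Fourier
#' algorithm, which is numerically identical to the direct summation.
#'
#' @param x real numeric vector, length `>= 1`.
#' @param fs sampling rate in Hz (default 1, i.e. normalized frequency).
#' @param nfft transform length; `x` is zero-padded up to it. Default
#'   `length(x)`.
#' @return a \linkS4class{Spectrum}.
#' @examples
#' sp <- dft(rep(1, 8))
#' Mod(spectrumCoefficients(sp))[1:3]   # 8, 0, 0
#' @export
dft <- function(x, fs = 1, nfft = length(x)) {
  stopIfNot(length(x) >= 1L, "input signal must be non-empty")
  stopIfNot(is.numeric(x) && all(is.finite(x)), "input signal must be finite numeric")
  nfft <- as.integer(nfft)
  stopIfNot(nfft >= length(x), "nfft must be >= length(x)")
  xp <- c(as.numeric(x), numeric(nfft - length(x)))
  new("Spectrum", coefficients = fft(xp), N = nfft, fs = as.numeric(fs))
}

#' Inverse DFT
#'
#' Recovers the (zero-padded) time-domain window from a
#' \linkS4class{Spectrum}; `idft(dft(x))` equals `x` to machine precision.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @return real numeric vector of length `N`.
#' @export
idft <- function(spectrum) {
  stopIfNot(is(spectrum, "Spectrum"), "spectrum must be a Spectrum")
  Re(fft(spectrum@coefficients, inverse = TRUE)) / spectrum@N
}

#' @rdname Spectrum-accessors
#' @export
spectrumCoefficients <- function(x) x@coefficients

#' Accessors for Spectrum
#' @param x a \linkS4class{Spectrum}.
#' @name Spectrum-accessors
#' @export
spectrumFrequencies <- function(x) (seq_len(x@N) - 1L) * x@fs / x@N

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: N=%d, fs=%g Hz, bin spacing %g Hz\n",
              object@N, object@fs, object@fs / object@N))
})

#' Mean band power of a spectrum
#'
#' The mean of `|X_k|^2` over the bins whose frequency `k * fs / N` lies in
#' the half-open interval `[lo, hi)`. Returns 0 when no bin falls inside the
#' band (zero-pad the transform via `nfft` in [dft()] to avoid empty bands
#' for short windows).
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param band one row of a band table (see [bandDefinition()]).
#' @return nonnegative scalar.
#' @examples
#' sp <- dft(sin(2 * pi * 10 * (0:255) / 128), fs = 128)
#' bandPower(sp, bandDefinition("alpha", 8, 12))
#' @export
bandPower <- function(spectrum, band) {
  stopIfNot(is(spectrum, "Spectrum"), "spectrum must be a Spectrum")
  stopIfNot(all(c("lo", "hi") %in% names(band)), "band must have lo/hi columns")
  lo <- band$lo[1]; hi <- band$hi[1]
  nyquist <- spectrum@fs / 2
  stopIfNot(lo >= 0 && lo < hi && hi <= nyquist,
            sprintf("band [%g, %g) must lie within [0, %g] (Nyquist)", lo, hi, nyquist))
  f <- spectrumFrequencies(spectrum)
  sel <- f >= lo & f < hi & f <= nyquist
  if (!any(sel)) return(0)
  mean(Mod(spectrum@coefficients[sel])^2)
}

#' Binarize 1--9 ratings into high/low labels
#'
#' Label 1 ("high") iff the rating is `>= threshold`, else 0 ("low").
#'
#' @param ratings numeric matrix `[n_trials x 4]` in the column order
#'   (valence, arousal, dominance, liking), or the matrix returned by
#'   [ratings()].
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold cut point in (1, 9); default 5.
#' @return integer 0/1 vector, one label per trial.
#' @examples
#' binarizeRatings(matrix(c(7, 3, 5, 5, 5, 5, 5, 5), 2, 4), "valence")
#' @export
binarizeRatings <- function(ratings, dimension = c("valence", "arousal"),
                            threshold = 5) {
  dimension <- matchDimension(dimension[1])
  stopIfNot(threshold > 1 && threshold < 9, "threshold must lie in (1, 9)")
  ratings <- as.matrix(ratings)
  stopIfNot(ncol(ratings) >= 2L, "ratings must have at least 2 columns")
  col <- if (dimension == "valence") 1L else 2L
  as.integer(ratings[, col] >= threshold)
}

#' Windowed band-power feature extraction
#'
#' Slides a window of `windowSize` samples with stride `step` over every
#' trial (windows start at samples 1, 1+step, ... while the full window
#' fits, giving `floor((n_samples - windowSize)/step) + 1` windows per
#' trial), transforms each channel window with a zero-padded DFT of length
#' `max(windowSize, minFFTLen)`, and records the mean `|X_k|^2` in each band
#' as one feature. Features are ordered channel-major, band-minor. Every
#' window inherits its trial's binarized valence and arousal labels.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param windowSize window length in samples.
#' @param step stride in samples; default `windowSize / 2` (50% overlap),
#'   floored to at least 1.
#' @param channels 1-based channel subset (default: all channels).
#' @param bands band table as from [eegBands()].
#' @param minFFTLen minimum transform length; short windows are zero-padded
#'   up to it so every band contains frequency bins. Default 256.
#' @param threshold rating binarization cut; default 5.
#' @return a \linkS4class{FeatureMatrix}.
#' @examples
#' rec <- generateDataset(syntheticSpec(nTrials = 2L, nChannels = 3L,
#'                                      duration = 2))$recording
#' fm <- extractFeatures(rec, windowSize = 128L)
#' dim(featureValues(fm))   # 3 windows/trial x 2 trials, 3 ch x 5 bands
#' @export
extractFeatures <- function(rec, windowSize, step = NULL,
                            channels = seq_len(nChannels(rec)),
                            bands = eegBands(), minFFTLen = 256L,
                            threshold = 5) {
  stopIfNot(is(rec, "EEGRecording"), "rec must be an EEGRecording")
  windowSize <- as.integer(windowSize)
  stopIfNot(windowSize >= 1L, "windowSize must be >= 1")
  stopIfNot(windowSize <= nSamples(rec),
            sprintf("windowSize (%d) exceeds n_samples (%d)",
                    windowSize, nSamples(rec)))
  if (is.null(step)) step <- max(1L, windowSize %/% 2L)
  step <- as.integer(step)
  stopIfNot(step >= 1L, "step must be >= 1")
  channels <- as.integer(channels)
  stopIfNot(all(channels >= 1L & channels <= nChannels(rec)) &&
              !anyDuplicated(channels), "invalid channel subset")
  nfft <- max(windowSize, as.integer(minFFTLen))
  fs <- samplingRate(rec)
  nyquist <- fs / 2
  stopIfNot(all(bands$lo >= 0 & bands$lo < bands$hi & bands$hi <= nyquist),
            "every band must lie within [0, Nyquist]")

  freq <- (seq_len(nfft) - 1L) * fs / nfft
  nBands <- nrow(bands)
  # averaging operator: bin x band, 1/n_bins inside the band
  M <- matrix(0, nfft, nBands)
  for (b in seq_len(nBands)) {
    sel <- freq >= bands$lo[b] & freq < bands$hi[b] & freq <= nyquist
    if (any(sel)) M[sel, b] <- 1 / sum(sel)
  }

  nWin <- (nSamples(rec) - windowSize) %/% step + 1L
  starts <- 1L + (seq_len(nWin) - 1L) * step
  nCh <- length(channels)
  nFeat <- nCh * nBands
  nRows <- nWin * nTrials(rec)
  values <- matrix(0, nRows, nFeat)
  trialOf <- integer(nRows); startOf <- integer(nRows)
  row <- 0L
  for (tr in seq_len(nTrials(rec))) {
    trialBlock <- rec@signals[tr, channels, , drop = FALSE]
    for (w in seq_len(nWin)) {
      seg <- matrix(0, nfft, nCh)
      seg[seq_len(windowSize), ] <-
        t(trialBlock[1L, , starts[w]:(starts[w] + windowSize - 1L)])
      p <- Mod(mvfft(seg))^2                # nfft x nCh
      pw <- crossprod(p, M)                 # nCh x nBands
      row <- row + 1L
      values[row, ] <- as.vector(t(pw))     # channel-major, band-minor
      trialOf[row] <- tr; startOf[row] <- starts[w]
    }
  }
  lv <- binarizeRatings(ratings(rec), "valence", threshold)
  la <- binarizeRatings(ratings(rec), "arousal", threshold)
  featNames <- as.vector(t(outer(channels, bands$name,
                                 function(ch, b) paste0("ch", ch, "_", b))))
  rowDat <- S4Vectors::DataFrame(
    channel = rep(channels, each = nBands),
    band = rep(bands$name, times = nCh),
    row.names = featNames)
  colDat <- S4Vectors::DataFrame(
    valence = lv[trialOf], arousal = la[trialOf],
    subject = rep(subjectID(rec), nRows),
    trial = trialOf, windowStart = startOf,
    row.names = sprintf("t%03d_w%04d", trialOf, startOf))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power = t(values)), rowData = rowDat, colData = colDat,
    metadata = list(fs = fs, windowSize = windowSize, step = step,
                    nfft = nfft, threshold = threshold))
  new("FeatureMatrix", se)
}

#' Accessors for FeatureMatrix
#'
#' `featureValues` returns the windows x features matrix (the transpose of
#' the `power` assay); `featureLabels` the binary label vector of one
#' emotion dimension.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param dimension `"valence"` or `"arousal"`.
#' @name FeatureMatrix-accessors
NULL

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "power"))
})

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureLabels", "FeatureMatrix", function(x, dimension) {
  dimension <- matchDimension(dimension)
  as.integer(SummarizedExperiment::colData(x)[[dimension]])
})
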