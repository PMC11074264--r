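#' @import methods
#' @importFrom stats fft mvfft qnorm rnorm runif
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Trial-structured multichannel EEG recording
#'
#' Container for one subject's EEG block in the trial x channel x sample
#' layout used by affect-rating experiments: every trial carries the same
#' number of channels and samples, a common sampling rate, and a row of four
#' self-ratings on the 1--9 Likert scale in the fixed column order
#' (valence, arousal, dominance, liking).
#'
#' @slot subjectID single character identifier.
#' @slot signals numeric array `[n_trials x n_channels x n_samples]`,
#'   microvolt-scale arbitrary units.
#' @slot fs sampling rate in Hz (positive).
#' @slot ratings numeric matrix `[n_trials x 4]`, entries in `[1, 9]`.
#' @slot channelNames character vector of length `n_channels` (may be empty).
#'
#' @seealso [EEGRecording()], [loadRecording()], [selectChannels()]
#' @export
setClass("EEGRecording",
  representation(
    subjectID    = "character",
    signals      = "array",
    fs           = "numeric",
    ratings      = "matrix",
    channelNames = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  d <- dim(object@signals)
  if (length(d) != 3L)
    msg <- c(msg, "signals must be a 3-d array [trials x channels x samples]")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(d) == 3L) {
    if (d[3] < 1L)
      msg <- c(msg, "n_samples must be >= 1")
    if (nrow(object@ratings) != d[1])
      msg <- c(msg, sprintf("ratings has %d rows but signals has %d trials",
                            nrow(object@ratings), d[1]))
    if (length(object@channelNames) != 0L &&
        length(object@channelNames) != d[2])
      msg <- c(msg, "channelNames length must match n_channels")
  }
  if (ncol(object@ratings) != 4L)
    msg <- c(msg, sprintf("ratings must have 4 columns (valence, arousal, dominance, liking), got %d",
                          ncol(object@ratings)))
  r <- object@ratings
  if (length(r) && (anyNA(r) || any(r < 1) || any(r > 9)))
    msg <- c(msg, "all ratings must lie in [1, 9]")
  if (anyNA(object@signals) || any(!is.finite(object@signals)))
    msg <- c(msg, "signals must be finite")
  if (length(msg)) msg else TRUE
})

#' Synthetic EEG generation specification
#'
#' Describes a synthetic recording with class-dependent spectral band power:
#' per-trial binary class assignments for the valence and arousal dimensions,
#' a per-class profile of relative band gains, pink (1/f) background noise,
#' and the rating threshold that the generated ratings invert exactly.
#'
#' @slot nTrials,nChannels counts.
#' @slot fs sampling rate (Hz).
#' @slot duration trial length in seconds; `duration * fs` must be an
#'   integer `>= 2`.
#' @slot classValence,classArousal integer 0/1 vectors of length `nTrials`.
#' @slot bandProfiles named list with elements `low` and `high`, each a
#'   named nonnegative numeric vector of per-band amplitude gains.
#' @slot noiseSd standard deviation of the pink-noise background (a.u.).
#' @slot threshold rating cut in (1, 9) used to place generated ratings.
#' @slot sinusoidsPerBand number of random-frequency sinusoids per band.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticSpec()], [generateDataset()]
#' @export
setClass("SyntheticSpec",
  representation(
    nTrials        = "integer",
    nChannels      = "integer",
    fs             = "numeric",
    duration       = "numeric",
    classValence   = "integer",
    classArousal   = "integer",
    bandProfiles   = "list",
    noiseSd        = "numeric",
    threshold      = "numeric",
    sinusoidsPerBand = "integer",
    seed           = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  ns <- object@duration * object@fs
  if (abs(ns - round(ns)) > 1e-8 || round(ns) < 2)
    msg <- c(msg, "duration * fs must be an integer >= 2")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (length(object@classValence) != object@nTrials ||
      length(object@classArousal) != object@nTrials)
    msg <- c(msg, "class assignments must have one entry per trial")
  if (!all(object@classValence %in% c(0L, 1L)) ||
      !all(object@classArousal %in% c(0L, 1L)))
    msg <- c(msg, "class assignments must be binary (0/1)")
  if (!all(c("low", "high") %in% names(object@bandProfiles)))
    msg <- c(msg, "bandProfiles must have elements 'low' and 'high'")
  gains <- unlist(object@bandProfiles)
  if (length(gains) && any(gains < 0))
    msg <- c(msg, "band power gains must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@threshold <= 1 || object@threshold >= 9)
    msg <- c(msg, "threshold must lie in (1, 9)")
  if (length(msg)) msg else TRUE
})

#' Discrete Fourier spectrum of a real window
#'
#' Two-sided DFT coefficients `X_k = sum_i x_i exp(-j 2 pi i k / N)`,
#' `k = 0..N-1`, together with the transform length and the sampling rate
#' that maps bin `k` to frequency `k * fs / N` Hz.
#'
#' @slot coefficients complex vector of length `N`.
#' @slot N transform length in samples (after any zero padding).
#' @slot fs sampling rate in Hz.
#'
#' @seealso [dft()], [bandPower()]
#' @export
setClass("Spectrum",
  representation(coefficients = "complex", N = "integer", fs = "numeric")
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@coefficients) != object@N)
    msg <- c(msg, "coefficients length must equal N")
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Windowed band-power feature matrix
#'
#' A \linkS4class{SummarizedExperiment} whose assay `power` holds band-power
#' features (rows, channel-major / band-minor) by analysis windows (columns).
#' `colData` carries the binarized `valence`/`arousal` labels inherited from
#' the window's trial plus provenance (`subject`, `trial`, `windowStart`,
#' 1-based start sample). `metadata` records the extraction configuration.
#'
#' @seealso [extractFeatures()], [featureValues()], [featureLabels()]
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"power" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'power' is required")
  else if (any(SummarizedExperiment::assay(object, "power") < 0))
    msg <- c(msg, "band powers must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  need <- c("valence", "arousal", "subject", "trial", "windowStart")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Gaussian fuzzy rule bank
#'
#' Per-(input, rule) Gaussian membership parameters of a zero-order
#' Takagi--Sugeno--Kang rule base: means `m[i, j]` and standard deviations
#' `sigma[i, j]` for input `i` under rule `j`, plus optional constant
#' consequent weights, one per rule.
#'
#' @slot means numeric matrix `[n_inputs x n_rules]`.
#' @slot sigmas positive numeric matrix, same shape as `means`; every entry
#'   must be `>= sigmaMin`.
#' @slot consequents numeric vector of length `n_rules`, or empty.
#' @slot sigmaMin positive floor on the standard deviations.
#'
#' @seealso [fuzzyRuleBank()], [fuzzify()]
#' @export
setClass("FuzzyRuleBank",
  representation(
    means       = "matrix",
    sigmas      = "matrix",
    consequents = "numeric",
    sigmaMin    = "numeric"
  )
)

setValidity("FuzzyRuleBank", function(object) {
  msg <- character()
  if (!identical(dim(object@means), dim(object@sigmas)))
    msg <- c(msg, "means and sigmas must have identical shapes")
  if (object@sigmaMin <= 0)
    msg <- c(msg, "sigmaMin must be positive")
  if (length(object@sigmas) && any(object@sigmas < object@sigmaMin))
    msg <- c(msg, "all sigmas must be >= sigmaMin")
  if (length(object@consequents) &&
      length(object@consequents) != ncol(object@means))
    msg <- c(msg, "consequents must have one entry per rule")
  if (length(msg)) msg else TRUE
})

#' CFNN architecture and training configuration
#'
#' Hyperparameters of the convolutional fuzzy neural network: two 1-D
#' convolutions (same padding), one max-pool, a Gaussian fuzzification layer
#' with `nRules` rules over the flattened conv features, batch normalization,
#' a dense layer, a centre-of-gravity defuzzification layer and a softmax
#' head; trained with Adam.
#'
#' @slot inputLen feature-vector length fed to the first convolution.
#' @slot conv1Filters,conv1Kernel,conv2Filters,conv2Kernel conv shapes.
#' @slot poolSize max-pool width (floor division on the length axis).
#' @slot nRules number of fuzzy rules.
#' @slot nClasses number of output classes (2).
#' @slot learningRate,batchSize,epochs Adam training schedule.
#' @slot aggregation rule-strength aggregation: `"geometric-mean"` or
#'   `"product-log"`.
#' @slot sigmaMin floor on membership standard deviations.
#' @slot eps defuzzification denominator guard.
#' @slot bnMomentum,bnEps batch-norm moving-average momentum and variance
#'   guard.
#' @slot clipNorm global gradient-norm clip (`Inf` disables).
#' @slot padFeatures zero-pad narrower feature tables up to `inputLen`.
#' @slot seed integer seed for weight initialization and batch shuffling.
#'
#' @seealso [cfnnConfig()], [buildModel()]
#' @export
setClass("CFNNConfig",
  representation(
    inputLen     = "integer",
    conv1Filters = "integer",
    conv1Kernel  = "integer",
    conv2Filters = "integer",
    conv2Kernel  = "integer",
    poolSize     = "integer",
    nRules       = "integer",
    nClasses     = "integer",
    learningRate = "numeric",
    batchSize    = "integer",
    epochs       = "integer",
    aggregation  = "character",
    sigmaMin     = "numeric",
    eps          = "numeric",
    bnMomentum   = "numeric",
    bnEps        = "numeric",
    clipNorm     = "numeric",
    padFeatures  = "logical",
    seed         = "integer"
  )
)

setValidity("CFNNConfig", function(object) {
  msg <- character()
  if (object@inputLen < max(object@conv1Kernel, object@conv2Kernel))
    msg <- c(msg, "inputLen must be >= both kernel sizes")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (object@nClasses != 2L) msg <- c(msg, "nClasses must be 2")
  if (object@nRules < 1L) msg <- c(msg, "nRules must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (!object@aggregation %in% c("geometric-mean", "product-log"))
    msg <- c(msg, "aggregation must be 'geometric-mean' or 'product-log'")
  if (object@sigmaMin <= 0) msg <- c(msg, "sigmaMin must be positive")
  if (object@eps <= 0) msg <- c(msg, "eps must be positive")
  if (length(msg)) msg else TRUE
})

#' Assembled CFNN model
#'
#' Holds the configuration, all trainable parameter blocks, the
#' non-trainable batch-norm moving statistics, the input standardization
#' learned from the training split, and the per-epoch training history.
#' Build with [buildModel()]; never manipulate slots directly.
#'
#' @slot config a \linkS4class{CFNNConfig}.
#' @slot params named list of parameter matrices/vectors.
#' @slot state named list: batch-norm moving mean/variance, feature
#'   standardization (`mu`, `sd`), `trained` flag.
#' @slot history data.frame with per-epoch `loss` and `accuracy` (empty
#'   before training).
#'
#' @seealso [buildModel()], [trainModel()], [modelSummary()]
#' @export
setClass("CFNNModel",
  representation(
    config  = "CFNNConfig",
    params  = "list",
    state   = "list",
    history = "data.frame"
  )
)

#' Per-layer parameter accounting of a CFNN
#'
#' One row per layer with its output shape, parameter count and trainable
#' flag, plus the (total, trainable, non-trainable) totals.
#'
#' @slot rows data.frame with columns `layer`, `outputShape`, `params`
#'   (all parameters of the layer) and `nonTrainable` (the subset that is
#'   not updated by gradient descent, e.g. batch-norm moving statistics).
#' @slot totals named numeric: `total`, `trainable`, `nonTrainable`.
#' @seealso [modelSummary()]
#' @export
setClass("ModelSummary",
  representation(rows = "data.frame", totals = "numeric")
)

setValidity("ModelSummary", function(object) {
  msg <- character()
  tot <- sum(object@rows$params)
  nt <- sum(object@rows$nonTrainable)
  if (object@totals[["total"]] != tot ||
      object@totals[["trainable"]] != tot - nt ||
      object@totals[["nonTrainable"]] != nt)
    msg <- c(msg, "totals must equal the column sums of rows")
  if (length(msg)) msg else TRUE
})

#' Binary confusion counts
#'
#' Cell counts of a 2 x 2 confusion table with the "high" class (label 1)
#' as positive.
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @seealso [confusionCounts()], [classifierMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0L)) "counts must be nonnegative" else TRUE
})

#' Evaluation report for one emotion dimension
#'
#' Confusion counts, the four headline metrics, a binomial confidence
#' interval on accuracy, and full provenance (protocol, seed, config hash).
#' For k-fold protocols the metrics are unweighted means over folds and
#' `perFold` holds the per-fold rows.
#'
#' @slot dimension `"valence"` or `"arousal"`.
#' @slot counts a \linkS4class{ConfusionCounts} (pooled over folds).
#' @slot accuracy,precision,recall,f1 proportions in `[0, 1]`.
#' @slot flags names of metrics whose denominator was zero (reported as 0).
#' @slot ci numeric `(lo, hi)`; @slot ciLevel its level.
#' @slot protocol list describing the split protocol.
#' @slot seed integer seed; @slot configHash md5 of the model config.
#' @slot perFold data.frame of per-fold metrics (empty for hold-out).
#' @seealso [runExperiment()], [writeReport()]
#' @export
setClass("EvalReport",
  representation(
    dimension  = "character",
    counts     = "ConfusionCounts",
    accuracy   = "numeric",
    precision  = "numeric",
    recall     = "numeric",
    f1         = "numeric",
    flags      = "character",
    ci         = "numeric",
    ciLevel    = "numeric",
    protocol   = "list",
    seed       = "integer",
    configHash = "character",
    perFold    = "data.frame"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!object@dimension %in% c("valence", "arousal"))
    msg <- c(msg, "dimension must be 'valence' or 'arousal'")
  if (length(object@ci) == 2L &&
      (object@ci[1] > object@accuracy + 1e-12 ||
       object@ci[2] < object@accuracy - 1e-12))
    msg <- c(msg, "accuracy must lie inside its confidence interval")
  if (length(msg)) msg else TRUE
})
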