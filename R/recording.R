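#' Construct an EEG recording
#'
#' @param signals numeric array `[n_trials x n_channels x n_samples]`.
#' @param ratings numeric matrix `[n_trials x 4]` of 1--9 self-ratings in the
#'   column order (valence, arousal, dominance, liking).
#' @param fs sampling rate in Hz.
#' @param subjectID subject identifier.
#' @param channelNames optional channel names (length `n_channels`).
#' @return a validated \linkS4class{EEGRecording}.
#' @examples
#' sig <- array(rnorm(2 * 3 * 64), dim = c(2, 3, 64))
#' rat <- matrix(5, 2, 4)
#' rec <- EEGRecording(sig, rat, fs = 128)
#' nSamples(rec)
#' @export
EEGRecording <- function(signals, ratings, fs = 128,
                         subjectID = "s01", channelNames = character()) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stop("signals must be a 3-d array [trials x channels x samples]", call. = FALSE)
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  storage.mode(signals) <- "double"
  dimnames(ratings) <- NULL
  dimnames(signals) <- NULL
  new("EEGRecording",
      subjectID = as.character(subjectID),
      signals = signals, fs = as.numeric(fs),
      ratings = ratings, channelNames = as.character(channelNames))
}

#' Accessors for EEGRecording
#'
#' `nTrials`/`nChannels`/`nSamples` return the block dimensions;
#' `samplingRate` the rate in Hz; `signals` the raw 3-d array; `ratings`
#' the trial x 4 rating matrix; `subjectID` and `channelNames` the metadata.
#'
#' @param x an \linkS4class{EEGRecording}.
#' @return dimension accessors return a single integer; `signals` an array;
#'   `ratings` a matrix; the rest character.
#' @name EEGRecording-accessors
NULL

#' @rdname EEGRecording-accessors
#' @export
setMethod("nTrials", "EEGRecording", function(x) dim(x@signals)[1L])
#' @rdname EEGRecording-accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) dim(x@signals)[2L])
#' @rdname EEGRecording-accessors
#' @export
setMethod("nSamples", "EEGRecording", function(x) dim(x@signals)[3L])
#' @rdname EEGRecording-accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname EEGRecording-accessors
#' @export
setMethod("signals", "EEGRecording", function(x) x@signals)
#' @rdname EEGRecording-accessors
#' @export
setMethod("ratings", "EEGRecording", function(x) x@ratings)
#' @rdname EEGRecording-accessors
#' @export
setMethod("subjectID", "EEGRecording", function(x) x@subjectID)
#' @rdname EEGRecording-accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d trials x %d channels x %d samples @ %g Hz\n",
              object@subjectID, nTrials(object), nChannels(object),
              nSamples(object), object@fs))
  cat(sprintf("  ratings: %d x 4 (valence, arousal, dominance, liking) in [%g, %g]\n",
              nrow(object@ratings),
              if (length(object@ratings)) min(object@ratings) else NA,
              if (length(object@ratings)) max(object@ratings) else NA))
})

#' @rdname selectChannels
#' @export
setMethod("selectChannels", "EEGRecording", function(x, indices) {
  indices <- as.integer(indices)
  nc <- nChannels(x)
  stopIfNot(length(indices) >= 1L, "indices must be non-empty")
  stopIfNot(all(indices >= 1L & indices <= nc),
            sprintf("channel indices must lie in [1, %d]", nc))
  stopIfNot(!anyDuplicated(indices), "duplicate channel indices")
  nm <- if (length(x@channelNames)) x@channelNames[indices] else character()
  EEGRecording(x@signals[, indices, , drop = FALSE], x@ratings,
               fs = x@fs, subjectID = x@subjectID, channelNames = nm)
})

#' The standard 14-channel analysis subset
#'
#' The 1-based channel indices conventionally retained for band-power
#' analysis of 32+ channel affective-EEG montages.
#'
#' @return integer vector of length 14.
#' @export
defaultChannelSelection <- function() {
  c(1L, 2L, 3L, 4L, 6L, 11L, 13L, 17L, 19L, 20L, 21L, 25L, 29L, 31L)
}
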