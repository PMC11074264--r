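#' @rdname EEGRecording-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname EEGRecording-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Subset and reorder the channels of a recording
#'
#' @param x an \linkS4class{EEGRecording}.
#' @param indices 1-based channel indices, no duplicates, each in
#'   `[1, nChannels(x)]`.
#' @return an \linkS4class{EEGRecording} with `length(indices)` channels in
#'   the given order; trials, samples and ratings unchanged.
#' @examples
#' rec <- generateDataset(syntheticSpec(nTrials = 2L, nChannels = 6L,
#'                                      duration = 1))$recording
#' nChannels(selectChannels(rec, c(2L, 5L)))
#' @export
setGeneric("selectChannels", function(x, indices) standardGeneric("selectChannels"))

#' Per-layer parameter accounting
#'
#' @param model a built \linkS4class{CFNNModel}.
#' @return a \linkS4class{ModelSummary}.
#' @export
setGeneric("modelSummary", function(model) standardGeneric("modelSummary"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureLabels", function(x, dimension) standardGeneric("featureLabels"))
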