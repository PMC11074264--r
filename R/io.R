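#' Read and write trial-structured EEG recordings
#'
#' Two on-disk dialects are supported. `"deap"` serializes the canonical
#' per-subject mapping of the preprocessed affective-EEG distribution — a
#' list with elements `data` (trials x channels x samples) and `labels`
#' (trials x 4 ratings), plus optional `fs`, `subject_id`, `channel_names` —
#' using R's native serialization (bit-exact round-trip). `"text"` is a
#' portable plain-text directory: `header.json` with the scalar metadata and
#' shapes, `signals.csv` in long (trial, channel, sample columns) layout and
#' `ratings.csv`, all numbers printed with 17 significant digits so doubles
#' round-trip exactly.
#'
#' When the `"deap"` mapping omits `fs`, the sampling rate defaults to
#' 128 Hz, the rate of the preprocessed distribution.
#'
#' @param path file (`"deap"`) or directory (`"text"`) path.
#' @param dialect `"deap"` or `"text"`.
#' @param rec an \linkS4class{EEGRecording}.
#' @return `loadRecording` returns an \linkS4class{EEGRecording};
#'   `saveRecording` invisibly returns `path`.
#' @examples
#' rec <- generateDataset(syntheticSpec(nTrials = 2L, nChannels = 3L,
#'                                      duration = 1))$recording
#' f <- tempfile(fileext = ".rds")
#' saveRecording(rec, f)
#' identical(signals(loadRecording(f)), signals(rec))
#' @name recording-io
NULL

#' @rdname recording-io
#' @export
loadRecording <- function(path, dialect = c("deap", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "deap") loadRecordingDeap(path) else loadRecordingText(path)
}

#' @rdname recording-io
#' @export
saveRecording <- function(rec, path, dialect = c("deap", "text")) {
  stopIfNot(is(rec, "EEGRecording"), "rec must be an EEGRecording")
  validObject(rec)
  stopIfNot(nSamples(rec) >= 1L, "recording has zero samples")
  dialect <- match.arg(dialect)
  if (dialect == "deap") saveRecordingDeap(rec, path) else saveRecordingText(rec, path)
  invisible(path)
}

loadRecordingDeap <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  stopIfNot(is.list(obj), "malformed recording: top level is not a mapping")
  for (key in c("data", "labels"))
    stopIfNot(key %in% names(obj),
              sprintf("malformed recording: missing key '%s'", key))
  data <- obj$data
  labels <- obj$labels
  stopIfNot(is.array(data) && length(dim(data)) == 3L,
            sprintf("malformed recording: 'data' must be a 3-d array, got shape (%s)",
                    paste(dim(data), collapse = ", ")))
  labels <- as.matrix(labels)
  stopIfNot(ncol(labels) == 4L,
            sprintf("malformed recording: 'labels' must be trials x 4, got %d x %d",
                    nrow(labels), ncol(labels)))
  stopIfNot(nrow(labels) == dim(data)[1L],
            sprintf("malformed recording: 'labels' has %d rows for %d trials",
                    nrow(labels), dim(data)[1L]))
  fs <- if (!is.null(obj$fs)) obj$fs else 128
  EEGRecording(data, labels, fs = fs,
               subjectID = if (!is.null(obj$subject_id)) obj$subject_id else "s01",
               channelNames = if (!is.null(obj$channel_names))
                 obj$channel_names else character())
}

saveRecordingDeap <- function(rec, path) {
  obj <- list(data = rec@signals, labels = rec@ratings, fs = rec@fs,
              subject_id = rec@subjectID, channel_names = rec@channelNames)
  ok <- tryCatch({ saveRDS(obj, path, version = 2L); TRUE },
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(ok)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

loadRecordingText <- function(path) {
  stopIfNot(dir.exists(path), sprintf("directory not found: %s", path))
  hf <- file.path(path, "header.json")
  stopIfNot(file.exists(hf), "malformed recording: missing header.json")
  hdr <- jsonlite::read_json(hf, simplifyVector = TRUE)
  for (key in c("n_trials", "n_channels", "n_samples", "fs"))
    stopIfNot(key %in% names(hdr),
              sprintf("malformed recording: header missing '%s'", key))
  sg <- utils::read.csv(file.path(path, "signals.csv"))
  stopIfNot(nrow(sg) == hdr$n_trials * hdr$n_channels,
            sprintf("malformed recording: signals.csv has %d rows, expected %d",
                    nrow(sg), hdr$n_trials * hdr$n_channels))
  stopIfNot(ncol(sg) == hdr$n_samples + 2L,
            sprintf("malformed recording: signals.csv has %d sample columns, expected %d",
                    ncol(sg) - 2L, hdr$n_samples))
  arr <- array(0, c(hdr$n_trials, hdr$n_channels, hdr$n_samples))
  vals <- as.matrix(sg[, -(1:2), drop = FALSE])
  arr[cbind(rep(sg$trial, hdr$n_samples),
            rep(sg$channel, hdr$n_samples),
            rep(seq_len(hdr$n_samples), each = nrow(sg)))] <- as.vector(vals)
  rt <- as.matrix(utils::read.csv(file.path(path, "ratings.csv")))
  EEGRecording(arr, rt, fs = hdr$fs,
               subjectID = if (!is.null(hdr$subject_id)) hdr$subject_id else "s01",
               channelNames = if (!is.null(hdr$channel_names) &&
                                  length(hdr$channel_names))
                 hdr$channel_names else character())
}

saveRecordingText <- function(rec, path) {
  if (!dir.exists(path))
    stopIfNot(dir.create(path, recursive = TRUE, showWarnings = FALSE),
              sprintf("cannot create directory: %s", path))
  hdr <- list(subject_id = rec@subjectID, fs = rec@fs,
              n_trials = nTrials(rec), n_channels = nChannels(rec),
              n_samples = nSamples(rec), channel_names = rec@channelNames)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  nt <- nTrials(rec); nc <- nChannels(rec); ns <- nSamples(rec)
  idx <- expand.grid(channel = seq_len(nc), trial = seq_len(nt))
  mat <- matrix(aperm(rec@signals, c(2, 1, 3)), nrow = nt * nc, ncol = ns)
  df <- data.frame(trial = idx$trial, channel = idx$channel)
  sampleCols <- as.data.frame(apply(mat, 2, fmt17))
  if (nrow(df) == 1L) sampleCols <- as.data.frame(t(as.matrix(sampleCols)))
  names(sampleCols) <- paste0("s", seq_len(ns))
  utils::write.csv(cbind(df, sampleCols), file.path(path, "signals.csv"),
                   row.names = FALSE, quote = FALSE)
  rt <- as.data.frame(apply(rec@ratings, 2, fmt17))
  if (nTrials(rec) == 1L) rt <- as.data.frame(t(as.matrix(rt)))
  names(rt) <- c("valence", "arousal", "dominance", "liking")
  utils::write.csv(rt, file.path(path, "ratings.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
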