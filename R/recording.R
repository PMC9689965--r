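#' EEG recording container
#'
#' A single subject/run of multi-channel EEG: a channels x samples matrix in
#' microvolts, sampling rate, canonical channel labels, run state and event
#' annotations (in samples, not seconds, to avoid float drift).
#'
#' @param data Numeric matrix, channels x samples.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per data row.
#' @param subject_id,run_id Identifiers.
#' @param state One of `"eyes_open"`, `"eyes_closed"`, `"mi_run"`.
#' @param annotations Data frame with columns `onset` (sample index, 1-based),
#'   `duration` (samples) and `label`, or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_labels,
                          subject_id = "S000", run_id = "R00",
                          state = c("eyes_open", "eyes_closed", "mi_run"),
                          annotations = NULL) {
  state <- match.arg(state)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording data contains NA/Inf values")
  if (length(channel_labels) != nrow(data))
    stop("channel label count (", length(channel_labels),
         ") does not match data rows (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (is.null(annotations)) {
    annotations <- data.frame(onset = integer(), duration = integer(),
                              label = character(), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
    if (nrow(annotations) &&
        (any(annotations$onset < 1) || any(annotations$onset > ncol(data))))
      stop("annotation onsets outside the recorded data")
  }
  rownames(data) <- channel_labels
  structure(
    list(subject_id = subject_id, run_id = run_id, state = state,
         sample_rate = sample_rate, channel_labels = channel_labels,
         data = data, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s  state=%s  %d ch x %d samples @ %g Hz, %d annotations\n",
              x$subject_id, x$run_id, x$state, nrow(x$data), ncol(x$data),
              x$sample_rate, nrow(x$annotations)))
  invisible(x)
}

is_recording <- function(x) inherits(x, "eeg_recording")

# Reorder the channels of a recording to the canonical montage order.
# Channels absent from the canonical list keep their relative order at the end.
align_to_montage <- function(rec, montage = eegmmidb_channels()) {
  present <- montage[montage %in% rec$channel_labels]
  extra <- setdiff(rec$channel_labels, montage)
  ord <- match(c(present, extra), rec$channel_labels)
  rec$data <- rec$data[ord, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[ord]
  rec
}
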