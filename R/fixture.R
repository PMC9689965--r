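# Internal fixture container: a versioned, lossless on-disk form of an
# eeg_recording.  Serialized with R's native format; the version string is
# checked on read so stale fixtures fail loudly rather than silently.

FIXTURE_VERSION <- "restalpha-fixture-1"

#' Write / read a recording in the internal fixture format
#'
#' Lossless round-trip of every field of an [eeg_recording()] (unlike EDF,
#' which quantizes to 16 bits).  The container embeds a format version that
#' is verified on read.
#'
#' @param rec An [eeg_recording()].
#' @param path File path (conventionally `.rafx`).
#' @return `write_fixture()` returns `path` invisibly; `read_fixture()`
#'   returns the recording.
#' @export
write_fixture <- function(rec, path) {
  stopifnot(is_recording(rec))
  saveRDS(list(version = FIXTURE_VERSION, recording = unclass(rec)),
          path, version = 2)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("fixture integrity error: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$version))
    stop("fixture integrity error: not a restalpha fixture")
  if (!identical(obj$version, FIXTURE_VERSION))
    stop("fixture version mismatch: file is '", obj$version,
         "', reader expects '", FIXTURE_VERSION, "'")
  r <- obj$recording
  eeg_recording(r$data, r$sample_rate, r$channel_labels, r$subject_id,
                r$run_id, r$state, r$annotations)
}
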