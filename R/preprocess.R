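#' Standard EEG frequency bands
#'
#' The four analysis bands: theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz)
#' and gamma (30–50 Hz).  Together they partition the 4–50 Hz range over
#' which total power is defined.
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low = c(4, 8, 13, 30), high = c(8, 13, 30, 50),
             stringsAsFactors = FALSE)
}

validate_band <- function(low, high, sample_rate) {
  if (!(low > 0 && high > low)) stop("band must satisfy 0 < low < high")
  if (high >= sample_rate / 2)
    stop("band edge ", high, " Hz is at or above Nyquist (",
         sample_rate / 2, " Hz)")
  invisible(TRUE)
}

# --- filter design -----------------------------------------------------------

# Steady-state initial conditions for a direct-form-II-transposed filter,
# so that forward-backward filtering has minimal edge transients.
lfilter_zi <- function(b, a) {
  m <- max(length(b), length(a))
  b <- c(b, numeric(m - length(b))) / a[1]
  a <- c(a, numeric(m - length(a))) / a[1]
  n <- m - 1L
  comp <- matrix(0, n, n)                     # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

.filter_cache <- new.env(parent = emptyenv())

butter_bandpass <- function(low, high, order, sample_rate) {
  key <- paste(low, high, order, sample_rate, sep = "|")
  f <- .filter_cache[[key]]
  if (is.null(f)) {
    bw <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
    f <- list(b = as.numeric(bw$b), a = as.numeric(bw$a))
    f$zi <- lfilter_zi(f$b, f$a)
    .filter_cache[[key]] <- f
  }
  f
}

# Zero-phase Butterworth band-pass of a samples x channels matrix.
filtfilt_matrix <- function(x, low, high, order, sample_rate) {
  f <- butter_bandpass(low, high, order, sample_rate)
  padlen <- min(nrow(x) - 1L, 3L * (max(length(f$a), length(f$b)) - 1L))
  filtfilt_cols(f$b, f$a, x, f$zi, padlen)
}

# --- common average reference ------------------------------------------------

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels.  After
#' CAR the per-sample channel mean is zero; the operation is idempotent.
#'
#' @param x An [eeg_recording()] or a channels x samples numeric matrix.
#' @return Same type as the input.
#' @export
apply_car <- function(x) {
  if (is_recording(x)) {
    x$data <- apply_car(x$data)
    return(x)
  }
  if (!is.matrix(x)) stop("`x` must be a recording or a matrix")
  if (nrow(x) < 2) stop("common average reference needs at least 2 channels")
  sweep(x, 2, colMeans(x), "-")
}

# --- band-pass filtering -----------------------------------------------------

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with an order-`order` Butterworth band-pass applied
#' forward and backward (zero phase; the magnitude response is squared, so
#' the effective attenuation order doubles).
#'
#' @param x An [eeg_recording()], an `epoch_set`, a `trial_set`, or a
#'   channels x samples matrix.
#' @param low,high Band edges in Hz.
#' @param order Filter order (default 4).
#' @param sample_rate Required when `x` is a bare matrix.
#' @return Same type as the input.
#' @export
bandpass <- function(x, low, high, order = 4, sample_rate = NULL) {
  if (is_recording(x)) {
    validate_band(low, high, x$sample_rate)
    x$data <- t(filtfilt_matrix(t(x$data), low, high, order, x$sample_rate))
    return(x)
  }
  if (inherits(x, "epoch_set") || inherits(x, "trial_set")) {
    validate_band(low, high, x$sample_rate)
    d <- dim(x$data)
    if (d[3] > 0) {
      dn <- dimnames(x$data)
      # stack trials as columns of one samples x (channels*trials) matrix so
      # the whole set is filtered in a single pass
      m <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2])
      m <- filtfilt_matrix(m, low, high, order, x$sample_rate)
      x$data <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
      dimnames(x$data) <- dn
    }
    return(x)
  }
  if (is.matrix(x)) {
    if (is.null(sample_rate)) stop("`sample_rate` required for matrix input")
    validate_band(low, high, sample_rate)
    return(t(filtfilt_matrix(t(x), low, high, order, sample_rate)))
  }
  stop("unsupported input type for bandpass()")
}

# --- segmentation ------------------------------------------------------------

new_epoch_set <- function(data, sample_rate, subject_id, state) {
  structure(list(data = data, sample_rate = sample_rate,
                 subject_id = subject_id, state = state),
            class = "epoch_set")
}

#' Segment a resting recording into fixed-length epochs
#'
#' Cuts consecutive, non-overlapping windows of `epoch_len` samples starting
#' at the first sample; any remainder is discarded.  A one-minute run at
#' 160 Hz (9600 samples) yields six 1500-sample epochs.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len Epoch length in samples (default 1500).
#' @return An `epoch_set`: channels x epoch_len x n_epochs array plus
#'   metadata.
#' @export
epoch_rest <- function(rec, epoch_len = 1500) {
  stopifnot(is_recording(rec))
  n <- ncol(rec$data)
  if (n < epoch_len)
    stop("recording has ", n, " samples, shorter than one epoch (",
         epoch_len, ")")
  k <- n %/% epoch_len
  a <- array(rec$data[, seq_len(k * epoch_len), drop = FALSE],
             dim = c(nrow(rec$data), epoch_len, k),
             dimnames = list(rec$channel_labels, NULL, NULL))
  new_epoch_set(a, rec$sample_rate, rec$subject_id, rec$state)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s/%s: %d epochs x %d ch x %d samples\n",
              x$subject_id, x$state, d[3], d[1], d[2]))
  invisible(x)
}

MI_CLASSES <- c("left_hand", "right_hand", "both_hands", "feet")

new_trial_set <- function(data, labels, sample_rate, subject_id) {
  labels <- factor(labels, levels = MI_CLASSES)
  if (anyNA(labels)) stop("trial labels must be one of: ",
                          paste(MI_CLASSES, collapse = ", "))
  structure(list(data = data, labels = labels, sample_rate = sample_rate,
                 subject_id = subject_id),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %s: %d trials x %d ch x %d samples (%s)\n",
              x$subject_id, d[3], d[1], d[2],
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Cut labeled motor-imagery trials out of an annotated run
#'
#' Takes one `window`-sample trial per non-rest annotation, starting at the
#' annotation onset.  Events whose window would run past the end of the data
#' are dropped with a warning.
#'
#' @param rec An [eeg_recording()] with annotations.
#' @param window Trial length in samples (default 640 = 4 s at 160 Hz).
#' @return A `trial_set`: channels x window x n_trials array with a factor of
#'   class labels.
#' @export
extract_mi_trials <- function(rec, window = 640) {
  stopifnot(is_recording(rec))
  ann <- rec$annotations
  ev <- ann[ann$label %in% MI_CLASSES, , drop = FALSE]
  if (nrow(ev) == 0) {
    warning("no motor-imagery annotations in ", rec$run_id,
            "; returning empty trial set")
    return(new_trial_set(array(0, c(nrow(rec$data), window, 0)),
                         character(), rec$sample_rate, rec$subject_id))
  }
  fits <- ev$onset + window - 1L <= ncol(rec$data)
  if (any(!fits)) {
    warning(sum(!fits), " trial(s) extend past the end of ", rec$run_id,
            " and were dropped")
    ev <- ev[fits, , drop = FALSE]
  }
  a <- array(0, c(nrow(rec$data), window, nrow(ev)),
             dimnames = list(rec$channel_labels, NULL, NULL))
  for (i in seq_len(nrow(ev)))
    a[, , i] <- rec$data[, ev$onset[i]:(ev$onset[i] + window - 1L)]
  new_trial_set(a, ev$label, rec$sample_rate, rec$subject_id)
}
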