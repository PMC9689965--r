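#' Mean-square band power of a signal
#'
#' Power defined as the mean squared amplitude, `(1/N) * sum(x^2)`.
#'
#' @param x Numeric vector (one channel, one epoch).
#' @return Non-negative scalar.
#' @export
#' @examples
#' band_power(rep(2, 100))  # == 4
band_power <- function(x) {
  if (length(x) == 0) stop("empty signal")
  mean(x^2)
}

#' Relative power level (RPL) per band
#'
#' Band-pass filters the epoch into each analysis band, computes the
#' mean-square power of each, and normalizes by the total power `P_all` over
#' 4–50 Hz.  With the default `p_all = "band_sum"` the total is the sum of
#' the four band powers (the bands partition 4–50 Hz), so the RPLs sum to 1
#' exactly; `p_all = "broadband"` instead uses the power of a single 4–50 Hz
#' filtered signal.
#'
#' @param epoch Numeric vector, one channel.
#' @param sample_rate Sampling rate in Hz.
#' @param bands Band table as from [eeg_bands()].
#' @param order Butterworth order (default 4, applied zero-phase).
#' @param p_all How the total power is computed (see above).
#' @return Named numeric vector of RPL values in `[0, 1]`, one per band.
#' @export
relative_power_level <- function(epoch, sample_rate, bands = eeg_bands(),
                                 order = 4,
                                 p_all = c("band_sum", "broadband")) {
  p_all <- match.arg(p_all)
  x <- matrix(as.numeric(epoch), ncol = 1)
  p <- vapply(seq_len(nrow(bands)), function(i) {
    validate_band(bands$low[i], bands$high[i], sample_rate)
    band_power(filtfilt_matrix(x, bands$low[i], bands$high[i], order,
                               sample_rate))
  }, numeric(1))
  total <- if (p_all == "band_sum") sum(p) else
    band_power(filtfilt_matrix(x, min(bands$low), max(bands$high), order,
                               sample_rate))
  if (total <= 0) stop("total 4-50 Hz power is zero; RPL undefined")
  setNames(p / total, bands$name)
}

# Plain (rectangular-window) periodogram: PSD_i = |X_i|^2 / N on the
# frequency grid k * fs / N, k = 0..floor(N/2).
periodogram <- function(x, sample_rate) {
  n <- length(x)
  X <- fft(x)
  k <- 0:(n %/% 2)
  list(frequencies = k * sample_rate / n, psd = (Mod(X[k + 1])^2) / n)
}

#' Power spectral entropy (PSE) of a band
#'
#' Band-pass filters the epoch, computes its plain periodogram, restricts the
#' bins to the band, normalizes them to sum to one, and returns the Shannon
#' entropy in nats.  PSE lies in `[0, ln(n_bins)]`; the bound is reached only
#' for a flat in-band spectrum.
#'
#' @inheritParams relative_power_level
#' @param band Length-2 numeric `c(low, high)` in Hz.
#' @param filter If `FALSE`, skip the band-pass and only restrict the
#'   periodogram bins (useful when the input is already band-filtered).
#' @return Entropy in nats.
#' @export
power_spectral_entropy <- function(epoch, sample_rate, band = c(8, 13),
                                   order = 4, filter = TRUE) {
  validate_band(band[1], band[2], sample_rate)
  x <- as.numeric(epoch)
  if (filter)
    x <- filtfilt_matrix(matrix(x, ncol = 1), band[1], band[2], order,
                         sample_rate)[, 1]
  pg <- periodogram(x, sample_rate)
  keep <- pg$frequencies >= band[1] & pg$frequencies <= band[2]
  if (sum(keep) < 2) stop("band contains fewer than 2 periodogram bins")
  spectral_entropy(pg$psd[keep])
}

spectral_entropy <- function(psd) {
  total <- sum(psd)
  if (total <= 0) stop("zero band power; PSE undefined")
  p <- psd / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Binarize an epoch around its median
#'
#' Symbols are 1 where the sample is at or above the epoch median and 0
#' below it (ties map to 1, so a constant epoch gives an all-ones sequence).
#' `threshold = "mean"` uses the epoch mean instead.
#'
#' @param x Numeric vector.
#' @param threshold `"median"` (default) or `"mean"`.
#' @return Integer vector of 0/1 symbols, same length as `x`.
#' @export
binarize_epoch <- function(x, threshold = c("median", "mean")) {
  threshold <- match.arg(threshold)
  th <- if (threshold == "median") median(x) else mean(x)
  as.integer(x >= th)
}

#' Normalized Lempel–Ziv complexity of a symbol sequence
#'
#' Counts the LZ76 patterns `C(n)` of a 0/1 sequence (counter initialized at
#' 1) and normalizes by the random-sequence asymptote `n / log2(n)`, i.e.
#' returns `C(n) * log2(n) / n`.  Random binary sequences approach 1 as `n`
#' grows; a constant sequence of length 1500 gives `2 * log2(1500) / 1500`.
#'
#' @param symbols Integer/logical vector of 0/1 symbols.
#' @return List with `count` (integer `C(n)`) and `value` (normalized LZC).
#' @export
lz76_complexity <- function(symbols) {
  s <- as.integer(symbols)
  if (length(s) < 2) stop("sequence too short (n >= 2 required)")
  cn <- lz76_count(s)
  list(count = cn, value = cn * log2(length(s)) / length(s))
}

#' Lempel–Ziv complexity (LZC) of a band-filtered epoch
#'
#' Band-pass filters the epoch (optional), binarizes it around its median and
#' returns the normalized LZ76 complexity (see [lz76_complexity()]).  Median
#' binarization makes the feature invariant to positive amplitude scaling.
#'
#' @inheritParams power_spectral_entropy
#' @param band Length-2 numeric band in Hz, or `NULL` for no filtering.
#' @param threshold Binarization rule, see [binarize_epoch()].
#' @return Normalized LZC (non-negative scalar).
#' @export
lempel_ziv_complexity <- function(epoch, sample_rate = NULL, band = NULL,
                                  order = 4,
                                  threshold = c("median", "mean")) {
  x <- as.numeric(epoch)
  if (!is.null(band)) {
    if (is.null(sample_rate)) stop("`sample_rate` required when filtering")
    validate_band(band[1], band[2], sample_rate)
    x <- filtfilt_matrix(matrix(x, ncol = 1), band[1], band[2], order,
                         sample_rate)[, 1]
  }
  lz76_complexity(binarize_epoch(x, match.arg(threshold)))$value
}

# --- feature table -----------------------------------------------------------

# Per-band, per-channel, per-epoch features of one (already CAR'd) recording.
# Filtering is done on the continuous record; epochs are cut afterwards, so
# no per-epoch transient handling is needed.
subject_state_features <- function(rec, bands, features, epoch_len, order) {
  n_ch <- nrow(rec$data)
  chans <- rec$channel_labels
  nb <- nrow(bands)
  filt <- lapply(seq_len(nb), function(i)
    epoch_rest(bandpass(rec, bands$low[i], bands$high[i], order), epoch_len))
  n_ep <- dim(filt[[1]]$data)[3]

  out <- list()
  # band powers (always needed for RPL)
  if ("RPL" %in% features) {
    P <- array(0, c(nb, n_ch, n_ep))
    for (b in seq_len(nb)) for (e in seq_len(n_ep))
      P[b, , e] <- rowMeans(filt[[b]]$data[, , e]^2)
    tot <- apply(P, c(2, 3), sum)
    if (any(tot <= 0)) stop("epoch with zero 4-50 Hz power; RPL undefined")
    rpl <- P
    for (b in seq_len(nb)) rpl[b, , ] <- P[b, , ] / tot
    m <- apply(rpl, c(1, 2), mean)
    out$RPL <- data.frame(band = rep(bands$name, n_ch),
                          channel = rep(chans, each = nb),
                          feature = "RPL", value = as.vector(m))
  }
  if ("PSE" %in% features) {
    m <- matrix(0, nb, n_ch)
    for (b in seq_len(nb)) {
      freq <- (0:(epoch_len %/% 2)) * rec$sample_rate / epoch_len
      keep <- freq >= bands$low[b] & freq <= bands$high[b]
      acc <- matrix(0, n_ep, n_ch)
      for (e in seq_len(n_ep)) {
        X <- mvfft(t(filt[[b]]$data[, , e]))          # samples x channels
        psd <- (Mod(X[seq_len(epoch_len %/% 2 + 1), , drop = FALSE])^2) / epoch_len
        acc[e, ] <- apply(psd[keep, , drop = FALSE], 2, spectral_entropy)
      }
      m[b, ] <- colMeans(acc)
    }
    out$PSE <- data.frame(band = rep(bands$name, n_ch),
                          channel = rep(chans, each = nb),
                          feature = "PSE", value = as.vector(m))
  }
  if ("LZC" %in% features) {
    m <- matrix(0, nb, n_ch)
    for (b in seq_len(nb)) {
      acc <- matrix(0, n_ep, n_ch)
      for (e in seq_len(n_ep)) for (ch in seq_len(n_ch)) {
        s <- binarize_epoch(filt[[b]]$data[ch, , e])
        acc[e, ch] <- lz76_count(s) * log2(epoch_len) / epoch_len
      }
      m[b, ] <- colMeans(acc)
    }
    out$LZC <- data.frame(band = rep(bands$name, n_ch),
                          channel = rep(chans, each = nb),
                          feature = "LZC", value = as.vector(m))
  }
  res <- do.call(rbind, out)
  res$subject <- rec$subject_id
  res$state <- rec$state
  rownames(res) <- NULL
  res[, c("subject", "state", "band", "channel", "feature", "value")]
}

#' Build the resting-state feature table
#'
#' Computes RPL, PSE and LZC per subject, state, band and channel.  For each
#' recording the continuous signal is (optionally) common-average referenced,
#' band-pass filtered per band, segmented into fixed-length epochs, features
#' are computed per epoch and channel, and the per-channel feature is the
#' arithmetic mean over epochs.
#'
#' @param recordings List of [eeg_recording()]s (resting runs; both states
#'   per subject).  Subjects missing one of the requested states are dropped
#'   with a warning.
#' @param bands Band table as from [eeg_bands()].
#' @param features Subset of `c("RPL", "PSE", "LZC")`.
#' @param epoch_len Epoch length in samples (default 1500).
#' @param order Butterworth filter order.
#' @param car Apply common average reference first (default `TRUE`).
#' @param states States a subject must have to be included.
#' @param channels Optional channel subset to compute features for (the CAR
#'   always uses every recorded channel).
#' @return Tidy data frame: `subject`, `state`, `band`, `channel`,
#'   `feature`, `value`.
#' @export
build_feature_table <- function(recordings, bands = eeg_bands(),
                                features = c("RPL", "PSE", "LZC"),
                                epoch_len = 1500, order = 4, car = TRUE,
                                states = c("eyes_open", "eyes_closed"),
                                channels = NULL) {
  features <- match.arg(features, c("RPL", "PSE", "LZC"), several.ok = TRUE)
  subj <- vapply(recordings, function(r) r$subject_id, "")
  st <- vapply(recordings, function(r) r$state, "")
  keep_subj <- names(which(tapply(st, subj, function(s) all(states %in% s))))
  dropped <- setdiff(unique(subj), keep_subj)
  if (length(dropped))
    warning("dropping subject(s) missing a resting state: ",
            paste(dropped, collapse = ", "))
  rows <- lapply(recordings, function(r) {
    if (!(r$subject_id %in% keep_subj) || !(r$state %in% states)) return(NULL)
    if (car) r <- apply_car(r)
    if (!is.null(channels)) {
      miss <- setdiff(channels, r$channel_labels)
      if (length(miss)) stop("channel(s) not recorded: ",
                             paste(miss, collapse = ", "))
      r$data <- r$data[match(channels, r$channel_labels), , drop = FALSE]
      r$channel_labels <- channels
    }
    subject_state_features(r, bands, features, epoch_len, order)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
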