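# Independent brute-force LZ76 parser: scans left to right; each phrase is
# the longest substring reproducible from the prefix (overlap allowed) plus
# one symbol; the final, possibly incomplete, phrase counts too.  Written
# against the definition, independently of the package's counter.
brute_lz76 <- function(s) {
  n <- length(s)
  str <- paste(s, collapse = "")
  count <- 0L
  i <- 1L
  while (i <= n) {
    L <- 0L
    while (i + L <= n) {
      phrase <- substr(str, i, i + L)
      prefix <- substr(str, 1, i + L - 1)
      if (grepl(phrase, prefix, fixed = TRUE)) L <- L + 1L else break
    }
    count <- count + 1L
    i <- i + L + 1L
  }
  count
}

# Pearson r from the definition (covariance over product of SDs).
pearson_formula <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sd(x) * sd(y))
}

# Pure sinusoid sampled at fs.
make_sine <- function(freq, n = 1500, fs = 160, phase = 0) {
  sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Deterministically flat in-band spectrum: equal-amplitude random-phase
# sinusoids on every periodogram grid frequency inside the band.
make_flat_band_signal <- function(band, n = 1500, fs = 160, seed = 1) {
  freqs <- (0:(n %/% 2)) * fs / n
  inband <- freqs[freqs >= band[1] & freqs <= band[2]]
  set.seed(seed)
  phases <- runif(length(inband), 0, 2 * pi)
  rowSums(vapply(seq_along(inband),
                 function(i) make_sine(inband[i], n, fs, phases[i]),
                 numeric(n)))
}

# Brute-force one-vs-rest CSP filters via the plain (non-symmetric)
# generalized eigendecomposition, normalized like the package's filters.
brute_csp_ovr <- function(a, labels, n_per_class = 2) {
  labels <- droplevels(factor(labels))
  covs <- lapply(seq_len(dim(a)[3]), function(i) {
    C <- tcrossprod(a[, , i]) / dim(a)[2]
    C / sum(diag(C))
  })
  out <- NULL
  for (cl in levels(labels)) {
    Sc <- Reduce(`+`, covs[labels == cl]) / sum(labels == cl)
    Sr <- Reduce(`+`, covs[labels != cl]) / sum(labels != cl)
    ev <- eigen(solve(Sc + Sr) %*% Sc)
    w <- Re(ev$vectors[, seq_len(n_per_class), drop = FALSE])
    for (j in seq_len(ncol(w))) {
      w[, j] <- w[, j] / sqrt(sum(w[, j]^2))
      if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
    }
    colnames(w) <- paste0(cl, "_", seq_len(n_per_class))
    out <- cbind(out, w)
  }
  out
}

# Small montage subset (includes the sensorimotor groups) for fast cohorts.
test_channels <- function() demo_channels()

# Random labeled trial array with no class signal.
null_trials <- function(nc = 8, len = 80, per_class = 20,
                        classes = c("left_hand", "right_hand",
                                    "both_hands", "feet")) {
  n <- per_class * length(classes)
  list(a = array(rnorm(nc * len * n), c(nc, len, n)),
       labels = factor(rep(classes, each = per_class), levels = classes))
}
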