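fs <- 160

test_that("band power is the mean squared amplitude", {
  expect_equal(band_power(rep(2.5, 77)), 6.25)
  expect_equal(band_power(numeric(10)), 0)
  # sinusoid with an integer number of cycles: A^2 / 2
  s <- 3 * make_sine(8, n = 1600)
  expect_equal(band_power(s), 9 / 2, tolerance = 1e-9)
  expect_error(band_power(numeric(0)), "empty")
})

test_that("RPL concentrates on the band of a pure tone and sums to one", {
  rpl <- relative_power_level(make_sine(10), fs)
  expect_gte(rpl[["alpha"]], 0.95)
  expect_equal(sum(rpl), 1)
  expect_true(all(rpl >= 0 & rpl <= 1))
})

test_that("RPL is exactly scale-invariant and simplex-normalized", {
  set.seed(1)
  x <- rnorm(1500)
  r1 <- relative_power_level(x, fs)
  expect_equal(sum(r1), 1)
  expect_equal(relative_power_level(10 * x, fs), r1, tolerance = 1e-9)
  expect_error(relative_power_level(numeric(1500), fs), "zero")
})

test_that("broadband total-power variant stays close to the band sum", {
  set.seed(2)
  x <- rnorm(1500)
  r_sum <- relative_power_level(x, fs)
  r_broad <- relative_power_level(x, fs, p_all = "broadband")
  expect_equal(unname(r_broad), unname(r_sum), tolerance = 0.1)
})

test_that("PSE reaches the log-bin-count bound only for a flat spectrum", {
  n <- 1500
  freqs <- (0:(n %/% 2)) * fs / n
  n_bins <- sum(freqs >= 8 & freqs <= 13)
  flat <- make_flat_band_signal(c(8, 13), seed = 3)
  pse_flat <- power_spectral_entropy(flat, fs, c(8, 13))
  expect_lte(pse_flat, log(n_bins))
  expect_gte(pse_flat, 0.95 * log(n_bins))
  # a single on-grid tone concentrates the spectrum
  pse_tone <- power_spectral_entropy(make_sine(10), fs, c(8, 13))
  expect_lt(pse_tone, 0.25 * log(n_bins))
  # scale invariance
  expect_equal(power_spectral_entropy(5.5 * flat, fs, c(8, 13)), pse_flat,
               tolerance = 1e-12)
})

test_that("PSE of band noise sits below the bound by the periodogram bias", {
  # single-epoch periodograms of Gaussian noise have exponential bin power,
  # which costs about (1 - Euler gamma) nats relative to ln(n_bins)
  n_bins <- sum((0:750) * fs / 1500 >= 8 & (0:750) * fs / 1500 <= 13)
  set.seed(4)
  vals <- replicate(20, power_spectral_entropy(rnorm(1500), fs, c(8, 13)))
  expect_true(all(vals > log(n_bins) - 0.8 & vals < log(n_bins)))
})

test_that("LZ76 counter matches the brute-force parser", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(10:400, 1)
    s <- rbinom(n, 1, runif(1, 0.2, 0.8))
    expect_equal(lz76_complexity(s)$count, brute_lz76(s))
  }
})

test_that("LZC hits the hand-traced values on degenerate sequences", {
  const <- lz76_complexity(rep(1L, 1500))
  expect_equal(const$count, 2)
  expect_equal(const$value, 2 * log2(1500) / 1500)
  expect_lt(lz76_complexity(rep(c(0L, 1L), 750))$value, 0.05)
})

test_that("LZC of iid random binary sequences approaches 1", {
  set.seed(6)
  vals <- replicate(20, lz76_complexity(rbinom(1500, 1, 0.5))$value)
  expect_gt(mean(vals), 0.9)
  expect_lt(mean(vals), 1.1)
})

test_that("median binarization makes LZC scale-invariant; constant epochs are defined", {
  set.seed(7)
  x <- rnorm(1500)
  expect_equal(lempel_ziv_complexity(x), lempel_ziv_complexity(100 * x))
  expect_equal(binarize_epoch(rep(3, 10)), rep(1L, 10))
  expect_equal(lempel_ziv_complexity(rep(3, 1500)), 2 * log2(1500) / 1500)
  # ties at the median binarize to 1
  expect_equal(binarize_epoch(c(1, 2, 2, 3)), c(0L, 1L, 1L, 1L))
})

test_that("wider in-band noise does not reduce median PSE or LZC", {
  set.seed(8)
  narrow <- replicate(20, {
    x <- bandpass(matrix(rnorm(2000), 1), 9.5, 11.5, sample_rate = fs)[1, ]
    c(power_spectral_entropy(x[251:1750], fs, c(8, 13), filter = FALSE),
      lempel_ziv_complexity(x[251:1750]))
  })
  wide <- replicate(20, {
    x <- bandpass(matrix(rnorm(2000), 1), 8, 13, sample_rate = fs)[1, ]
    c(power_spectral_entropy(x[251:1750], fs, c(8, 13), filter = FALSE),
      lempel_ziv_complexity(x[251:1750]))
  })
  expect_gte(median(wide[1, ]), median(narrow[1, ]))
  expect_gte(median(wide[2, ]), median(narrow[2, ]))
})

test_that("feature table cells are epoch means with full axes", {
  set.seed(9)
  chans <- c("C3", "C4", "Cz")
  recs <- list(
    eeg_recording(matrix(rnorm(3 * 4500), 3), fs, chans, subject_id = "S001",
                  state = "eyes_open"),
    eeg_recording(matrix(rnorm(3 * 4500), 3), fs, chans, subject_id = "S001",
                  state = "eyes_closed"))
  ft <- build_feature_table(recs, car = FALSE)
  expect_equal(nrow(ft), 2 * 4 * 3 * 3)   # states x bands x channels x features
  expect_false(anyNA(ft$value))
  # cell = mean over the three epochs, cross-checked per feature
  filt <- bandpass(recs[[1]], 8, 13)
  eps <- epoch_rest(filt)
  pse_epochs <- vapply(1:3, function(e)
    power_spectral_entropy(eps$data["C3", , e], fs, c(8, 13), filter = FALSE),
    numeric(1))
  cell <- ft$value[ft$subject == "S001" & ft$state == "eyes_open" &
                   ft$band == "alpha" & ft$channel == "C3" &
                   ft$feature == "PSE"]
  expect_equal(cell, mean(pse_epochs), tolerance = 1e-10)
})

test_that("subjects missing a resting state are dropped with a warning", {
  chans <- c("C3", "C4")
  recs <- list(
    eeg_recording(matrix(rnorm(2 * 3000), 2), fs, chans, subject_id = "S001",
                  state = "eyes_open"),
    eeg_recording(matrix(rnorm(2 * 3000), 2), fs, chans, subject_id = "S001",
                  state = "eyes_closed"),
    eeg_recording(matrix(rnorm(2 * 3000), 2), fs, chans, subject_id = "S002",
                  state = "eyes_open"))
  expect_warning(ft <- build_feature_table(recs, features = "RPL"), "S002")
  expect_equal(unique(ft$subject), "S001")
})
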