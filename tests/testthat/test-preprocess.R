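fs <- 160

test_that("common average reference zeroes the per-sample channel mean", {
  set.seed(1)
  x <- matrix(rnorm(64 * 500), 64)
  y <- apply_car(x)
  expect_lt(max(abs(colMeans(y))) / stats::sd(x), 1e-12)
  # two antisymmetric channels are already zero-mean: unchanged
  a <- matrix(rnorm(300), 1)
  expect_equal(apply_car(rbind(a, -a)), rbind(a, -a))
  # a common offset is removed exactly
  expect_equal(apply_car(x + 7), y)
  # idempotent
  expect_equal(apply_car(y), y)
  expect_error(apply_car(x[1, , drop = FALSE]), "at least 2 channels")
})

test_that("band-pass response passes in-band and rejects out-of-band tones", {
  s10 <- make_sine(10); s3 <- make_sine(3)
  in_band <- bandpass(matrix(s10, 1), 8, 13, sample_rate = fs)
  out_band <- bandpass(matrix(s3, 1), 8, 13, sample_rate = fs)
  expect_gte(band_power(in_band) / band_power(s10), 0.9)
  expect_lt(band_power(out_band) / band_power(s3), 0.01)
})

test_that("band-pass filtering is linear and scale-equivariant", {
  set.seed(2)
  x <- matrix(rnorm(2 * 2000), 2)
  y <- matrix(rnorm(2 * 2000), 2)
  fx <- bandpass(x, 8, 13, sample_rate = fs)
  fy <- bandpass(y, 8, 13, sample_rate = fs)
  expect_lt(max(abs(bandpass(3.7 * x, 8, 13, sample_rate = fs) - 3.7 * fx)),
            1e-8 * sd(x))
  expect_lt(max(abs(bandpass(x + y, 8, 13, sample_rate = fs) - (fx + fy))),
            1e-8 * sd(x))
})

test_that("the four bands partition broadband 4-50 Hz power for white noise", {
  set.seed(3)
  x <- matrix(rnorm(4 * 8000), 4)
  bands <- eeg_bands()
  band_sum <- Reduce(`+`, lapply(seq_len(nrow(bands)), function(i)
    rowMeans(bandpass(x, bands$low[i], bands$high[i], sample_rate = fs)^2)))
  broad <- rowMeans(bandpass(x, 4, 50, sample_rate = fs)^2)
  expect_true(all(abs(band_sum / broad - 1) < 0.1))
})

test_that("band-filtered outputs of white noise are near-orthogonal", {
  set.seed(4)
  x <- matrix(rnorm(6000), 1)
  bands <- eeg_bands()
  filtered <- lapply(seq_len(nrow(bands)), function(i)
    as.numeric(bandpass(x, bands$low[i], bands$high[i], sample_rate = fs)))
  for (i in 1:3) for (j in (i + 1):4) {
    xp <- mean(filtered[[i]] * filtered[[j]]) /
      sqrt(band_power(filtered[[i]]) * band_power(filtered[[j]]))
    # adjacent bands deliberately share their common edge frequency, where
    # both zero-phase filters pass ~1/4 power, so allow a small systematic
    # cross-power there; non-adjacent bands are essentially orthogonal
    expect_lt(abs(xp), if (j == i + 1) 0.15 else 0.05)
  }
})

test_that("band edges at or above Nyquist are rejected", {
  expect_error(bandpass(matrix(rnorm(100), 1), 30, 80, sample_rate = fs),
               "Nyquist")
  expect_error(bandpass(matrix(rnorm(100), 1), 13, 8, sample_rate = fs),
               "low < high")
})

test_that("resting epochs are consecutive, non-overlapping and complete", {
  rec <- eeg_recording(matrix(seq_len(2 * 9600), 2, byrow = TRUE), fs,
                       c("C3", "C4"))
  ep <- epoch_rest(rec)
  expect_equal(dim(ep$data), c(2, 1500, 6))
  expect_equal(ep$data[1, , 1], as.numeric(1:1500))
  expect_equal(ep$data[1, , 2], as.numeric(1501:3000))
  one <- epoch_rest(eeg_recording(matrix(0, 2, 1500), fs, c("C3", "C4")))
  expect_equal(dim(one$data)[3], 1)
  expect_error(
    epoch_rest(eeg_recording(matrix(0, 2, 1499), fs, c("C3", "C4"))),
    "shorter than one epoch")
})

test_that("trial extraction honours annotations and window bounds", {
  n <- 8000
  onsets <- as.integer(seq(1, 7000, length.out = 25))
  rec <- eeg_recording(matrix(rnorm(2 * n), 2), fs, c("C3", "C4"),
                       state = "mi_run",
                       annotations = data.frame(
                         onset = onsets, duration = 640L,
                         label = rep(c("left_hand", "right_hand"),
                                     length.out = 25)))
  ts <- extract_mi_trials(rec, window = 640)
  expect_equal(dim(ts$data)[3], 25)
  expect_equal(ts$data[, , 1], rec$data[, 1:640])
  # event too close to the end is dropped with a warning
  rec$annotations <- rbind(rec$annotations,
                           data.frame(onset = n, duration = 1L,
                                      label = "feet"))
  expect_warning(ts2 <- extract_mi_trials(rec, window = 640), "dropped")
  expect_equal(dim(ts2$data)[3], 25)
  # no MI events at all -> empty set plus warning
  rec$annotations <- data.frame(onset = 1L, duration = 1L, label = "rest")
  expect_warning(empty <- extract_mi_trials(rec, 640), "no motor-imagery")
  expect_equal(dim(empty$data)[3], 0)
})
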