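test_that("cohort specs are validated", {
  expect_error(cohort_spec(1), "n_subjects")
  expect_error(cohort_spec(5, rest_duration = 5), ">= 1500")
  expect_error(cohort_spec(5, planted_rho = 1.2), "planted_rho")
  expect_error(cohort_spec(5, band_power_profile = c(theta = -0.1, alpha = 1,
                                                     beta = 0, gamma = 0)),
               "non-negative")
  expect_error(cohort_spec(5, alpha_range = NULL, planted_rho = 0.5),
               "alpha_range is NULL")
})

test_that("resting recordings have the specified geometry", {
  spec <- cohort_spec(2, channels = test_channels(), seed = 4)
  rec <- make_resting_recording(spec, 1, "eyes_open")
  expect_equal(ncol(rec$data), 9600)     # one minute at 160 Hz
  expect_equal(nrow(rec$data), length(test_channels()))
  expect_equal(rec$state, "eyes_open")
  expect_error(make_resting_recording(spec, 1, "nap"), "arg")
})

test_that("a pure-alpha profile with no background yields alpha RPL near 1", {
  spec <- cohort_spec(2, channels = test_channels()[1:4],
                      rest_duration = 15, planted_rho = 0,
                      band_power_profile = c(theta = 0, alpha = 1, beta = 0,
                                             gamma = 0),
                      alpha_range = NULL, band_jitter_sd = 0,
                      background_fraction = 0, seed = 5)
  rec <- make_resting_recording(spec, 1, "eyes_open")
  rpl <- relative_power_level(rec$data[1, 1:1500], spec$sample_rate)
  expect_gte(rpl[["alpha"]], 0.95)
})

test_that("generated band fractions match the planted profile (Monte-Carlo)", {
  # 50 realizations of an equal-power four-band profile, no background
  vals <- sapply(1:50, function(s) {
    spec <- cohort_spec(2, channels = test_channels()[1:2],
                        rest_duration = 10, planted_rho = 0,
                        band_power_profile = c(theta = .25, alpha = .25,
                                               beta = .25, gamma = .25),
                        alpha_range = NULL, band_jitter_sd = 0,
                        background_fraction = 0, seed = 1000 + s)
    rec <- make_resting_recording(spec, 1, "eyes_open")
    relative_power_level(rec$data[1, 1:1500], spec$sample_rate)
  })
  expect_true(all(abs(rowMeans(vals) - 0.25) < 0.05))
})

test_that("same seed gives a bit-identical cohort; different seeds differ", {
  spec <- cohort_spec(3, channels = test_channels(), rest_duration = 10,
                      trials_per_class = 5, seed = 9)
  r1 <- make_resting_recording(spec, 2, "eyes_closed")
  r2 <- make_resting_recording(spec, 2, "eyes_closed")
  expect_identical(r1$data, r2$data)
  t1 <- make_mi_trials(spec, 2)
  t2 <- make_mi_trials(spec, 2)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$labels, t2$labels)
  spec2 <- cohort_spec(3, channels = test_channels(), rest_duration = 10,
                       trials_per_class = 5, seed = 10)
  expect_false(identical(make_mi_trials(spec2, 2)$data, t1$data))
  expect_false(identical(
    make_resting_recording(spec2, 2, "eyes_closed")$data, r1$data))
})

test_that("ground truth plants the requested correlation and cohort size", {
  spec <- cohort_spec(105, planted_rho = 0.5, seed = 12)
  gt <- ground_truth(spec)
  expect_equal(nrow(gt), 105)
  expect_lt(abs(cor(gt$alpha_frac, gt$separability) - 0.5), 0.2)
  gt0 <- ground_truth(cohort_spec(100, planted_rho = 0, seed = 13))
  expect_lt(abs(cor(gt0$alpha_frac, gt0$separability)), 0.2)
  expect_true(all(gt$separability >= 0 & gt$separability <= 1))
  expect_true(all(gt$alpha_frac >= 0.15 & gt$alpha_frac <= 0.55))
})

test_that("class covariance contrast vanishes at zero separability", {
  class_spread <- function(s, seed) {
    spec <- cohort_spec(2, channels = test_channels(), trials_per_class = 40,
                        separability_range = c(s, s), planted_rho = 0,
                        seed = seed)
    ts <- make_mi_trials(spec, 1)
    cv <- restalpha:::trial_covariances(bandpass(ts, 8, 30)$data)
    cms <- sapply(levels(ts$labels), function(cl)
      rowMeans(cv$norm[, ts$labels == cl, drop = FALSE]))
    # largest between-class difference of the channel variances
    diag_idx <- which(as.vector(diag(length(spec$channels))) == 1)
    max(apply(cms[diag_idx, ], 1, function(z) diff(range(z))))
  }
  # at separability 0 only sampling noise remains; at 0.8 the planted
  # ERD-like contrast dominates it by a wide margin
  expect_gt(class_spread(0.8, 14), 3 * class_spread(0, 14))
})

test_that("CSP accuracy increases monotonically with planted separability", {
  levels_s <- c(0, 0.25, 0.5, 0.75, 1)
  acc <- sapply(levels_s, function(s) {
    sapply(1:3, function(k) {
      spec <- cohort_spec(2, channels = test_channels(),
                          trials_per_class = 30,
                          separability_range = c(s, s), planted_rho = 0,
                          seed = 500 + k)
      mi_performance(make_mi_trials(spec, 1), folds = 10, reps = 2,
                     seed = 600 + k, two_class = FALSE)$acc4_mean
    })
  })
  rho <- cor(rep(levels_s, each = 3), as.vector(acc), method = "spearman")
  expect_gt(rho, 0.9)
  expect_lt(mean(acc[, 1]), 35)     # chance at zero separability
  expect_gt(mean(acc[, 5]), 80)     # strong at the range maximum
})

test_that("make_cohort returns aligned recordings, trials and ground truth", {
  spec <- cohort_spec(3, channels = test_channels(), rest_duration = 10,
                      trials_per_class = 5, seed = 21)
  coh <- make_cohort(spec)
  expect_equal(nrow(coh$ground_truth), 3)
  expect_length(coh$recordings, 6)
  expect_length(coh$trials, 3)
  expect_equal(vapply(coh$recordings, function(r) r$state, "")[1:2],
               c("eyes_open", "eyes_closed"))
  expect_equal(coh$trials[[2]]$subject_id, "S002")
  expect_equal(table(coh$trials[[1]]$labels)[["feet"]], 5)
  # per-subject streams: subject 2 is identical in a larger cohort
  spec5 <- cohort_spec(5, channels = test_channels(), rest_duration = 10,
                       trials_per_class = 5, seed = 21)
  expect_identical(make_mi_trials(spec5, 2)$data, coh$trials[[2]]$data)
})

test_that("eyes-closed recordings carry extra occipital alpha power", {
  spec <- cohort_spec(2, channels = test_channels(), seed = 22)
  eo <- make_resting_recording(spec, 1, "eyes_open")
  ec <- make_resting_recording(spec, 1, "eyes_closed")
  occ_alpha <- function(rec) {
    occ <- rec$data[c("O1", "O2"), 1:3000]
    mean(bandpass(occ, 8, 13, sample_rate = 160)^2) / mean(occ^2)
  }
  expect_gt(occ_alpha(ec), occ_alpha(eo))
})
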