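# minimal feature table for correlation tests
toy_features <- function(values, subjects, state = "eyes_open",
                         band = "alpha", channel = "C3", feature = "RPL") {
  data.frame(subject = subjects, state = state, band = band,
             channel = channel, feature = feature, value = values,
             stringsAsFactors = FALSE)
}

test_that("correlation map recovers exact +/-1 and matches the formula oracle", {
  subj <- sprintf("S%03d", 1:20)
  perf <- data.frame(subject = subj, acc4_mean = seq(20, 90, length.out = 20))
  up <- toy_features(perf$acc4_mean, subj)
  cm <- correlation_map(up, perf)
  expect_equal(cm$r, 1)
  down <- toy_features(-perf$acc4_mean, subj)
  expect_equal(correlation_map(down, perf)$r, -1)
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(20)
    cm <- correlation_map(toy_features(v, subj), perf)
    expect_equal(cm$r, pearson_formula(v, perf$acc4_mean), tolerance = 1e-12)
    expect_equal(cm$p, cor.test(v, perf$acc4_mean)$p.value, tolerance = 1e-12)
  }
})

test_that("correlating feature with performance is symmetric in its arguments", {
  set.seed(2)
  subj <- sprintf("S%03d", 1:15)
  v <- rnorm(15); p <- rnorm(15)
  a <- correlation_map(toy_features(v, subj),
                       data.frame(subject = subj, acc4_mean = p))$r
  b <- correlation_map(toy_features(p, subj),
                       data.frame(subject = subj, acc4_mean = v))$r
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("zero-variance cells are NA, misaligned subjects are dropped listwise", {
  subj <- sprintf("S%03d", 1:10)
  perf <- data.frame(subject = subj, acc4_mean = rnorm(10))
  cm <- correlation_map(toy_features(rep(1, 10), subj), perf)
  expect_true(is.na(cm$r) && is.na(cm$p))
  # subject missing from performance: n drops, no error
  cm2 <- correlation_map(toy_features(rnorm(10), subj), perf[-1, ])
  expect_equal(cm2$n, 9)
  expect_error(correlation_map(toy_features(rnorm(10), subj),
                               data.frame(subject = "S099", acc4_mean = 1)),
               "common subjects")
})

# a correlation map with a planted band profile of |r| across 64 channels
planted_cmap <- function(level = c(theta = .1, alpha = .5, beta = .15,
                                   gamma = .12), noise = 0.03, seed = 3) {
  set.seed(seed)
  ch <- eegmmidb_channels()
  do.call(rbind, lapply(names(level), function(b)
    data.frame(state = "eyes_open", band = b, channel = ch, feature = "RPL",
               measure = "acc4_mean",
               r = pmin(pmax(level[[b]] + rnorm(64, 0, noise), -1), 1),
               p = 0.01, n = 100)))
}

test_that("band contrast flags a planted alpha-dominant profile", {
  cm <- planted_cmap()
  bc <- band_contrast(cm, "eyes_open", "RPL")
  expect_equal(bc$n_channels, 64)
  expect_lt(bc$gg_p, 0.001)
  expect_true(bc$gg_epsilon > 0 && bc$gg_epsilon <= 1)
  alpha_rows <- bc$pairwise[bc$pairwise$band1 == "alpha" |
                            bc$pairwise$band2 == "alpha", ]
  expect_true(all(alpha_rows$p < 0.05))
})

test_that("near-identical band profiles yield non-significant contrasts", {
  cm <- planted_cmap(level = c(theta = .3, alpha = .3, beta = .3, gamma = .3),
                     noise = 0.02, seed = 4)
  bc <- band_contrast(cm, "eyes_open", "RPL")
  expect_gt(bc$gg_p, 0.05)
  expect_true(all(abs(bc$pairwise$t) < 3))
  # exactly identical |r|: paired t defined as 0, p = 1
  cm$r <- 0.25
  bc0 <- band_contrast(cm, "eyes_open", "RPL")
  expect_true(all(bc0$pairwise$t == 0) && all(bc0$pairwise$p == 1))
})

test_that("permuting band labels per channel destroys the band effect", {
  cm <- planted_cmap()
  wide <- matrix(abs(cm$r), nrow = 64)  # channels x bands (band-major input)
  wide <- sapply(split(abs(cm$r), cm$band)[unique(cm$band)], identity)
  set.seed(5)
  destroyed <- replicate(100, {
    perm <- t(apply(wide, 1, sample))
    colnames(perm) <- colnames(wide)
    cmp <- cm
    for (j in seq_along(colnames(perm)))
      cmp$r[cmp$band == colnames(perm)[j]] <- perm[, j]
    band_contrast(cmp, "eyes_open", "RPL")$gg_p
  })
  expect_gte(mean(destroyed > 0.05), 0.9)
})

test_that("channel-pair averages are exact two-channel means", {
  subj <- c("S001", "S002")
  rows <- expand.grid(subject = subj, channel = c("C3", "C4", "Cp4"),
                      feature = c("RPL", "PSE", "LZC"),
                      stringsAsFactors = FALSE)
  rows$state <- "eyes_open"; rows$band <- "alpha"
  rows$value <- seq_len(nrow(rows))
  pf <- channel_pair_average(rows)
  expect_equal(names(pf), c("subject", "RPL", "PSE", "LZC"))
  v <- function(ch, ft, s) rows$value[rows$channel == ch &
                                      rows$feature == ft & rows$subject == s]
  expect_equal(pf$RPL[1], (v("C3", "RPL", "S001") + v("C4", "RPL", "S001")) / 2)
  expect_equal(pf$PSE[2], (v("C4", "PSE", "S002") + v("Cp4", "PSE", "S002")) / 2)
  expect_equal(pf$LZC[1], (v("C3", "LZC", "S001") + v("Cp4", "LZC", "S001")) / 2)
  expect_error(channel_pair_average(rows, pairs = list(RPL = c("C3", "Oz"))),
               "Oz")
})

test_that("group contrasts: null p-values are uniform, separation is detected", {
  set.seed(6)
  pvals <- replicate(200, {
    pf <- data.frame(subject = sprintf("S%03d", 1:80), RPL = rnorm(80))
    gr <- data.frame(subject = pf$subject,
                     group = rep(c("H", "L"), each = 40))
    suppressWarnings(group_contrasts(pf, gr))$p[1]  # only H-L can run
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # 3 pooled SDs apart, n = 20 each -> overwhelming evidence
  pf <- data.frame(subject = sprintf("S%03d", 1:40),
                   RPL = c(rnorm(20), rnorm(20) + 3))
  gr <- data.frame(subject = pf$subject, group = rep(c("H", "L"), each = 20))
  expect_lt(suppressWarnings(group_contrasts(pf, gr))$p[1], 0.001)
  # identical groups -> t exactly 0
  pf2 <- data.frame(subject = sprintf("S%03d", 1:8),
                    RPL = rep(c(1, 2, 3, 4), 2))
  gr2 <- data.frame(subject = pf2$subject, group = rep(c("H", "L"), each = 4))
  expect_equal(suppressWarnings(group_contrasts(pf2, gr2))$t[1], 0)
  # undersized group: every affected comparison is skipped with a warning
  gr3 <- gr2; gr3$group <- c("H", rep("L", 7))
  w <- capture_warnings(res <- group_contrasts(pf2, gr3))
  expect_true(all(grepl("fewer than 2", w)))
  expect_length(w, 3)   # H-M, H-L and M-L all involve the 1-subject H group
})
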