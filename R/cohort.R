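#' Specification of a synthetic EEG cohort
#'
#' Defines the statistical structure of a simulated resting + motor-imagery
#' cohort: per-subject resting runs (eyes open and closed) built from 1/f
#' background plus band-limited Gaussian components, and four-class MI trial
#' sets whose class-specific spatial covariance contrast (alpha-band variance
#' decrease over class-specific sensorimotor channel groups, i.e. an ERD-like
#' signature) scales with the subject's latent class separability.  Subject
#' (alpha fraction, separability) pairs are drawn from a Gaussian copula with
#' correlation `planted_rho`, so the population correlation between resting
#' alpha power and MI separability is controllable.
#'
#' The alpha fraction is mapped from its copula quantile through a power
#' function (`alpha_link_gamma`); with the default exponent > 1 the mapping is
#' convex, so only clearly high-separability subjects show distinctly elevated
#' alpha — low and medium performers remain similar, mirroring the group
#' geometry the analysis is designed to detect.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sample_rate Sampling rate in Hz (default 160).
#' @param channels Channel labels (default: the canonical 64-channel montage).
#' @param rest_duration Resting run length in seconds (default 60).
#' @param trials_per_class MI trials per class (default 75 = 25 x 3 runs).
#' @param mi_window MI trial length in seconds (default 4).
#' @param planted_rho Target cross-subject correlation (Gaussian copula)
#'   between resting alpha fraction and MI separability, in `[-1, 1]`.
#' @param separability_range Range the uniform separability marginal is
#'   mapped to (default `c(0, 1)`).
#' @param band_power_profile Named power fractions for theta/alpha/beta/gamma
#'   band components (non-negative; normalized internally).
#' @param alpha_range Range of the per-subject alpha power fraction; `NULL`
#'   freezes alpha at the profile value (then `planted_rho` must be 0).
#' @param alpha_link_gamma Exponent of the quantile -> alpha-fraction mapping.
#' @param band_jitter_sd Log-normal sd of per-subject jitter on the non-alpha
#'   band shares (0 disables).
#' @param background_fraction Fraction of 4-50 Hz power contributed by the
#'   1/f background (0 disables).
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^exp).
#' @param ec_alpha_boost Range of the multiplicative extra occipital alpha
#'   power in the eyes-closed state (`NULL` disables the boost).
#' @param erd_depth Maximum fractional alpha-variance decrease on a class's
#'   channel group at separability 1 (generator calibration constant).
#' @param mu_power Alpha (mu-rhythm) component variance in MI trials relative
#'   to unit broadband background (generator calibration constant).
#' @param seed Master seed; every subject derives an independent stream.
#' @return A `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(n_subjects,
                        sample_rate = 160,
                        channels = eegmmidb_channels(),
                        rest_duration = 60,
                        trials_per_class = 75,
                        mi_window = 4,
                        planted_rho = 0.5,
                        separability_range = c(0, 1),
                        band_power_profile = c(theta = 0.25, alpha = 0.35,
                                               beta = 0.25, gamma = 0.15),
                        alpha_range = c(0.15, 0.55),
                        alpha_link_gamma = 3,
                        band_jitter_sd = 0.3,
                        background_fraction = 0.25,
                        noise_exponent = 1,
                        ec_alpha_boost = c(0.5, 2.5),
                        erd_depth = 0.6,
                        mu_power = 0.6,
                        seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (rest_duration * sample_rate < 1500)
    stop("rest_duration x sample_rate must be >= 1500 (one epoch)")
  if (abs(planted_rho) > 1) stop("|planted_rho| must be <= 1")
  if (any(band_power_profile < 0)) stop("power fractions must be non-negative")
  if (!all(c("theta", "alpha", "beta", "gamma") %in% names(band_power_profile)))
    stop("band_power_profile must name theta, alpha, beta and gamma")
  if (is.null(alpha_range) && planted_rho != 0)
    stop("planted_rho must be 0 when alpha_range is NULL (alpha frozen)")
  if (!is.null(alpha_range) && (diff(alpha_range) < 0 ||
      any(alpha_range < 0) || any(alpha_range > 1)))
    stop("alpha_range must be increasing within [0, 1]")
  if (diff(separability_range) < 0 || any(separability_range < 0) ||
      any(separability_range > 1))
    stop("separability_range must be increasing within [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), sample_rate = sample_rate,
    channels = channels, rest_duration = rest_duration,
    trials_per_class = as.integer(trials_per_class), mi_window = mi_window,
    planted_rho = planted_rho, separability_range = separability_range,
    band_power_profile = band_power_profile[c("theta", "alpha", "beta", "gamma")],
    alpha_range = alpha_range, alpha_link_gamma = alpha_link_gamma,
    band_jitter_sd = band_jitter_sd,
    background_fraction = background_fraction,
    noise_exponent = noise_exponent, ec_alpha_boost = ec_alpha_boost,
    erd_depth = erd_depth, mu_power = mu_power, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d subjects, %d ch @ %g Hz, %g s rest, ",
                     "%d trials/class, rho=%g, seed=%d\n"),
              x$n_subjects, length(x$channels), x$sample_rate,
              x$rest_duration, x$trials_per_class, x$planted_rho, x$seed))
  invisible(x)
}

subject_ids <- function(spec) sprintf("S%03d", seq_len(spec$n_subjects))

prof_alpha <- function(spec) {
  p <- spec$band_power_profile / sum(spec$band_power_profile)
  p[["alpha"]]
}

#' Ground truth of a synthetic cohort
#'
#' The per-subject latent parameters the generator plants: true alpha power
#' fraction, true MI class separability, the per-subject band-share jitter,
#' alpha spectral concentration, occipital eyes-closed boost, and the group
#' the subject is intended to land in (from the generator's nominal
#' separability-to-accuracy calibration).  Fully determined by the spec and
#' its seed; used as the recovery target in tests.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame, one row per subject.
#' @export
ground_truth <- function(spec) {
  n <- spec$n_subjects
  prof <- spec$band_power_profile / sum(spec$band_power_profile)
  with_seed(derive_seed(spec$seed, "ground-truth"), {
    z1 <- rnorm(n)
    z2 <- spec$planted_rho * z1 +
      sqrt(1 - spec$planted_rho^2) * rnorm(n)
    u <- pnorm(z1); v <- pnorm(z2)
    sep <- spec$separability_range[1] + diff(spec$separability_range) * u
    if (is.null(spec$alpha_range)) {
      alpha <- rep(prof[["alpha"]], n)
      conc <- rep(0.5, n)
    } else {
      alpha <- spec$alpha_range[1] +
        diff(spec$alpha_range) * v^spec$alpha_link_gamma
      conc <- v
    }
    other <- prof[c("theta", "beta", "gamma")]
    shares <- matrix(rep(other, each = n), n, 3) *
      exp(matrix(rnorm(3 * n, 0, spec$band_jitter_sd), n, 3))
    shares <- shares / pmax(rowSums(shares), .Machine$double.eps)
    boost <- if (is.null(spec$ec_alpha_boost)) rep(0, n) else
      runif(n, spec$ec_alpha_boost[1], spec$ec_alpha_boost[2])
    # nominal separability -> 4-class accuracy map (logistic fit to the
    # generator's Monte-Carlo calibration curve); informational only
    acc_nominal <- 25 + 67 / (1 + exp(-(sep - 0.66) / 0.14))
    data.frame(subject = subject_ids(spec),
               alpha_frac = alpha, separability = sep,
               alpha_concentration = conc,
               theta_share = shares[, 1], beta_share = shares[, 2],
               gamma_share = shares[, 3], ec_boost = boost,
               intended_group = assign_group(acc_nominal),
               planted_rho = spec$planted_rho, seed = spec$seed,
               stringsAsFactors = FALSE)
  })
}

# Bulk white noise drawn from a C++ stream whose seed comes from the current
# (seeded) R RNG -- fast, and reproducible through the usual seed chain.
white_noise <- function(n, p) rnorm_mat(n, p, sample.int(2147483647L, 1))

# 1/f^exp background noise, n x p, generated by spectral shaping of white
# noise; column variances are approximately 1 before scaling.
one_over_f_noise <- function(n, p, exponent, sample_rate) {
  w <- white_noise(n, p)
  X <- mvfft(w)
  f <- seq(0, sample_rate, length.out = n + 1)[1:n]
  f[f > sample_rate / 2] <- sample_rate - f[f > sample_rate / 2]
  shape <- c(0, 1 / pmax(f[-1], f[2])^(exponent / 2))
  y <- Re(mvfft(X * shape, inverse = TRUE)) / n
  scale(y, center = FALSE, scale = apply(y, 2, sd))
}

# Band-limited unit-variance Gaussian component (filtered white noise).
band_component <- function(n, p, low, high, order, sample_rate) {
  y <- filtfilt_matrix(white_noise(n, p), low, high, order, sample_rate)
  scale(y, center = FALSE, scale = apply(y, 2, sd))
}

#' Simulate one resting run
#'
#' Generates the eyes-open or eyes-closed resting recording of one subject:
#' 1/f background plus independent band-limited Gaussian components whose
#' expected 4-50 Hz power fractions follow the subject's planted band
#' profile (the alpha fraction comes from the cohort ground truth).  The
#' subject's alpha component is centred at 10.5 Hz with a bandwidth that
#' narrows as the subject's alpha concentration rises.  In the eyes-closed
#' state, occipital channels receive extra alpha power (the classic
#' eyes-closed occipital alpha increase), with a per-subject random
#' magnitude independent of MI separability.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index (1-based).
#' @param state `"eyes_open"` or `"eyes_closed"`.
#' @param gt Optional precomputed [ground_truth()] (avoids recomputation).
#' @return An [eeg_recording()].
#' @export
make_resting_recording <- function(spec, subject,
                                   state = c("eyes_open", "eyes_closed"),
                                   gt = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(spec, "cohort_spec"),
            subject >= 1, subject <= spec$n_subjects)
  if (is.null(gt)) gt <- ground_truth(spec)
  pars <- gt[subject, ]
  fs <- spec$sample_rate
  n <- round(spec$rest_duration * fs)
  nc <- length(spec$channels)
  bands <- eeg_bands()
  order <- 4

  frac <- c(theta = pars$theta_share * (1 - pars$alpha_frac),
            alpha = pars$alpha_frac,
            beta = pars$beta_share * (1 - pars$alpha_frac),
            gamma = pars$gamma_share * (1 - pars$alpha_frac))

  with_seed(derive_seed(spec$seed, "rest", subject, state), {
    x <- matrix(0, n, nc)
    for (b in seq_len(nrow(bands))) {
      nm <- bands$name[b]
      if (frac[[nm]] <= 0) next
      if (nm == "alpha") {
        bw <- 5 - 3.5 * pars$alpha_concentration   # 8-13 Hz down to ~1.5 Hz
        lo <- 10.5 - bw / 2; hi <- 10.5 + bw / 2
      } else {
        lo <- bands$low[b]; hi <- bands$high[b]
      }
      comp <- band_component(n, nc, lo, hi, order, fs)
      x <- x + comp * sqrt(frac[[nm]])
    }
    if (state == "eyes_closed" && !is.null(spec$ec_alpha_boost)) {
      # posterior-dominant but widespread eyes-closed alpha increase whose
      # magnitude is a per-subject trait independent of MI separability;
      # additive relative to the cohort's typical alpha level, so it masks
      # (rather than amplifies) between-subject alpha differences
      w <- ifelse(spec$channels %in% occipital_channels(), 1.2, 0.6)
      a_typ <- if (is.null(spec$alpha_range)) prof_alpha(spec) else
        mean(spec$alpha_range)
      extra <- band_component(n, nc, 8, 13, order, fs)
      x <- x + extra %*% diag(sqrt(w * pars$ec_boost * a_typ))
    }
    if (spec$background_fraction > 0) {
      bg <- one_over_f_noise(n, nc, spec$noise_exponent, fs)
      inband <- filtfilt_matrix(bg, 4, 50, order, fs)
      pw <- colMeans(inband^2)
      target <- spec$background_fraction / (1 - spec$background_fraction)
      bg <- sweep(bg, 2, sqrt(target / pw), "*")
      x <- x + bg
    }
    eeg_recording(t(x) * 20, fs, spec$channels,
                  subject_id = pars$subject,
                  run_id = if (state == "eyes_open") "R01" else "R02",
                  state = state)
  })
}

# class -> channel group for the ERD-like covariance contrast
mi_class_channels <- function() {
  list(right_hand = c("C3", "C5", "Cp3", "Cp5"),
       left_hand  = c("C4", "C6", "Cp4", "Cp6"),
       both_hands = c("C3", "C5", "Cp3", "Cp5", "C4", "C6", "Cp4", "Cp6"),
       feet       = c("Cz", "Cpz", "Fz"))
}

#' Simulate one subject's motor-imagery trials
#'
#' Draws labeled four-class trials: unit-variance broadband Gaussian noise
#' plus a dominant alpha-band (mu-rhythm) component whose variance is
#' reduced, on the class-specific sensorimotor channel group, by
#' `erd_depth * separability` — an event-related-desynchronization-like
#' covariance contrast.  At separability 0 the four class covariances are
#' identical (chance-level classes); classification accuracy rises
#' monotonically with separability.
#'
#' @inheritParams make_resting_recording
#' @return A `trial_set` (channels x samples x trials array plus labels).
#' @export
make_mi_trials <- function(spec, subject, gt = NULL) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject >= 1, subject <= spec$n_subjects)
  if (is.null(gt)) gt <- ground_truth(spec)
  pars <- gt[subject, ]
  fs <- spec$sample_rate
  win <- round(spec$mi_window * fs)
  nc <- length(spec$channels)
  k <- spec$trials_per_class
  groups <- mi_class_channels()
  miss <- setdiff(unique(unlist(groups)), spec$channels)
  if (length(miss))
    stop("spec channels lack sensorimotor channels needed for MI classes: ",
         paste(miss, collapse = ", "))
  n_tr <- 4L * k
  labels <- rep(MI_CLASSES, each = k)

  with_seed(derive_seed(spec$seed, "mi", subject), {
    labels <- sample(labels)
    # one long alpha-band noise stream, sliced per trial
    mu <- band_component(win * n_tr, nc, 8, 13, 4, fs)
    d <- spec$erd_depth * pars$separability
    # per-class channel scaling of the mu component (ERD-like contrast)
    fac <- matrix(spec$mu_power, 4, nc,
                  dimnames = list(MI_CLASSES, spec$channels))
    for (cl in MI_CLASSES)
      fac[cl, match(groups[[cl]], spec$channels)] <- spec$mu_power * (1 - d)
    a <- assemble_trials(mu, white_noise(win * n_tr, nc),
                         sqrt(fac[match(labels, MI_CLASSES), , drop = FALSE]),
                         win)
    dimnames(a) <- list(spec$channels, NULL, NULL)
    new_trial_set(a, labels, fs, pars$subject)
  })
}

#' Simulate a full cohort
#'
#' Generates every subject's eyes-open and eyes-closed resting recordings and
#' MI trial set, together with the ground truth.  All draws are reproducible
#' from the spec seed, with one independent stream per subject and run, so
#' the same subject is bit-identical regardless of cohort size.  For large
#' cohorts prefer the per-subject generators (memory: a 64-channel trial set
#' is ~100 MB per subject).
#'
#' @param spec A [cohort_spec()].
#' @return List with `ground_truth` (data frame), `recordings` (list of
#'   [eeg_recording()], two per subject) and `trials` (list of `trial_set`).
#' @export
make_cohort <- function(spec) {
  gt <- ground_truth(spec)
  recs <- list(); tri <- list()
  for (i in seq_len(spec$n_subjects)) {
    recs[[2 * i - 1]] <- make_resting_recording(spec, i, "eyes_open", gt)
    recs[[2 * i]] <- make_resting_recording(spec, i, "eyes_closed", gt)
    tri[[i]] <- make_mi_trials(spec, i, gt)
  }
  list(ground_truth = gt, recordings = recs, trials = tri)
}
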