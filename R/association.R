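P_FLOOR <- 1e-300  # p-values below double underflow are reported as this floor

pearson_cell <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = max(ct$p.value, P_FLOOR), n = n)
}

#' Channel-wise Pearson correlation map
#'
#' Correlates every feature cell (state x band x channel x feature) with a
#' per-subject performance measure across subjects.  Subjects are aligned by
#' id; subjects missing from either table are excluded listwise.  Cells with
#' zero variance are returned as `NA`, never silently as 0, and p-values
#' below double-precision underflow are floored at `1e-300`.
#'
#' @param features Tidy feature table from [build_feature_table()].
#' @param performance Data frame with a `subject` column and the performance
#'   measure column, as from [mi_performance()].
#' @param measure Name of the performance column (default `"acc4_mean"`).
#' @return Data frame (`correlation_map`): `state`, `band`, `channel`,
#'   `feature`, `measure`, `r`, `p`, `n`.
#' @export
correlation_map <- function(features, performance, measure = "acc4_mean") {
  if (!measure %in% names(performance))
    stop("performance table has no column '", measure, "'")
  common <- intersect(unique(features$subject), performance$subject)
  if (length(common) < 3) stop("need at least 3 common subjects")
  perf <- setNames(performance[[measure]], performance$subject)[common]
  f <- features[features$subject %in% common, ]
  cells <- unique(f[, c("state", "band", "channel", "feature")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- f$state == cells$state[i] & f$band == cells$band[i] &
      f$channel == cells$channel[i] & f$feature == cells$feature[i]
    v <- setNames(f$value[sel], f$subject[sel])[common]
    as.data.frame(as.list(pearson_cell(v, perf)))
  }))
  out <- cbind(cells, measure = measure, res)
  rownames(out) <- NULL
  class(out) <- c("correlation_map", class(out))
  out
}

# Greenhouse-Geisser epsilon: tr(E)^2 / ((k-1) tr(E^2)) with E the sample
# covariance of the within-factor responses projected on an orthonormal
# contrast basis.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  E <- crossprod(C, stats::cov(Y) %*% C)
  sum(diag(E))^2 / ((k - 1) * sum(E * E))
}

# Paired t-test that tolerates identical columns (zero-variance differences
# are reported as t = 0, p = 1 rather than NaN).
paired_t <- function(x, y) {
  d <- x - y
  if (sd(d) == 0) return(c(t = 0, p = 1))
  tt <- t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), p = max(tt$p.value, P_FLOOR))
}

#' Repeated-measures contrast of |r| across frequency bands
#'
#' Treats channels as the repeated-measures units and the band as the
#' within-unit factor, with the absolute correlation coefficient as the
#' response.  Runs Mauchly's sphericity test, the Greenhouse–Geisser
#' corrected F-test, and all pairwise paired t-tests between bands.
#'
#' @param cmap A [correlation_map()].
#' @param state,feature Which slice of the map to contrast.
#' @return List: `mauchly_p`, `gg_epsilon`, `gg_p`, `uncorrected_p`,
#'   `pairwise` (data frame of band pairs with t and p), `n_channels`.
#' @export
band_contrast <- function(cmap, state = "eyes_open", feature = "RPL") {
  m <- cmap[cmap$state == state & cmap$feature == feature, ]
  bands <- unique(m$band)
  if (length(bands) < 2) stop("need at least 2 bands")
  wide <- sapply(bands, function(b) {
    v <- m[m$band == b, ]
    abs(setNames(v$r, v$channel)[unique(m$channel)])
  })
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3) stop("need at least 3 channels")
  idata <- data.frame(band = factor(bands, levels = bands))
  fit <- lm(wide ~ 1)
  mau <- tryCatch(
    mauchly.test(fit, M = ~ band, X = ~ 1, idata = idata)$p.value,
    error = function(e) NA_real_)
  av <- anova(fit, M = ~ band, X = ~ 1, idata = idata, test = "Spherical")
  gg_eps <- gg_epsilon(wide)
  gg_p <- max(av[["G-G Pr"]][1], P_FLOOR)
  raw_p <- max(av[["Pr(>F)"]][1], P_FLOOR)
  pairs <- utils::combn(bands, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    st <- paired_t(wide[, pairs[1, j]], wide[, pairs[2, j]])
    data.frame(band1 = pairs[1, j], band2 = pairs[2, j],
               mean1 = mean(wide[, pairs[1, j]]),
               mean2 = mean(wide[, pairs[2, j]]),
               t = st["t"], p = st["p"], row.names = NULL)
  }))
  list(state = state, feature = feature,
       mauchly_p = mau, gg_epsilon = gg_eps, gg_p = gg_p,
       uncorrected_p = raw_p, pairwise = pw, n_channels = nrow(wide))
}

#' Default channel pairs for the per-subject scalar features
#'
#' The channel pairs whose eyes-open alpha values are averaged into one
#' scalar per subject and feature: C3/C4 for RPL, C4/Cp4 for PSE, C3/Cp4 for
#' LZC (the channels with the strongest correlations over the motor cortex).
#'
#' @return Named list of channel pairs.
#' @export
default_feature_pairs <- function() {
  list(RPL = c("C3", "C4"), PSE = c("C4", "Cp4"), LZC = c("C3", "Cp4"))
}

#' Per-subject channel-pair feature averages
#'
#' For each feature, averages the two named channels' values (eyes-open alpha
#' band by default), giving one scalar per subject and feature — the inputs
#' of the screening classifiers.
#'
#' @param features Tidy feature table from [build_feature_table()].
#' @param pairs Named list of channel pairs, see [default_feature_pairs()].
#' @param state,band Which slice to average.
#' @return Data frame: `subject` plus one column per feature.
#' @export
channel_pair_average <- function(features, pairs = default_feature_pairs(),
                                 state = "eyes_open", band = "alpha") {
  f <- features[features$state == state & features$band == band, ]
  subjects <- unique(f$subject)
  out <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (feat in names(pairs)) {
    if (!feat %in% f$feature) next
    chans <- pairs[[feat]]
    missing <- setdiff(chans, unique(f$channel))
    if (length(missing))
      stop("channel(s) not in feature table: ", paste(missing, collapse = ", "))
    sel <- f[f$feature == feat & f$channel %in% chans, ]
    agg <- tapply(sel$value, sel$subject, mean)
    out[[feat]] <- as.numeric(agg[subjects])
  }
  out
}

#' Independent-group contrasts of the pair-averaged features
#'
#' Welch two-sample t-tests between the H/M/L groups (H–M, H–L, M–L) for each
#' scalar feature.  Comparisons involving a group with fewer than two
#' subjects are skipped with a warning.
#'
#' @param pair_features Output of [channel_pair_average()].
#' @param groups Data frame with `subject` and `group` columns (H/M/L), as
#'   from [mi_performance()].
#' @return Data frame: `feature`, `group1`, `group2`, `mean1`, `mean2`,
#'   `t`, `p`.
#' @export
group_contrasts <- function(pair_features, groups) {
  g <- setNames(as.character(groups$group), groups$subject)
  gl <- g[pair_features$subject]
  feats <- setdiff(names(pair_features), "subject")
  combos <- list(c("H", "M"), c("H", "L"), c("M", "L"))
  rows <- list()
  for (feat in feats) {
    for (cmb in combos) {
      x <- pair_features[[feat]][gl == cmb[1] & !is.na(gl)]
      y <- pair_features[[feat]][gl == cmb[2] & !is.na(gl)]
      if (length(x) < 2 || length(y) < 2) {
        warning("skipping ", feat, " ", cmb[1], "-", cmb[2],
                ": a group has fewer than 2 subjects")
        next
      }
      if (sd(c(x, y)) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- t.test(x, y, var.equal = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, group1 = cmb[1], group2 = cmb[2],
        mean1 = mean(x), mean2 = mean(y),
        t = unname(tt$statistic), p = max(tt$p.value, P_FLOOR))
    }
  }
  do.call(rbind, rows)
}
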