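# Stratified fold assignment: within each class, shuffle and deal round-robin.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated cross-validated CSP + linear SVM accuracy
#'
#' Scores a (band-pass filtered) trial set with `reps` repetitions of
#' stratified `folds`-fold cross-validation.  Within every training fold a
#' fresh one-vs-rest CSP model is fitted (no leakage into the test fold),
#' log-variance features are extracted, and a linear SVM with penalty `cost`
#' is trained; the repetition's accuracy is the mean over its folds, and the
#' function returns the mean and standard deviation over repetitions, in
#' percent.  Fold shuffling is seeded (`seed + repetition index`), so results
#' are reproducible.
#'
#' @param x A `trial_set` or channels x samples x trials array (already
#'   filtered to the classification band).
#' @param labels Trial labels (ignored for a `trial_set`).
#' @param folds,reps Cross-validation folds and repetitions (default 10 x 10).
#' @param cost SVM penalty parameter C (default 1).
#' @param seed Base seed for fold shuffling.
#' @param n_per_class CSP filters per class.
#' @param fit_once If `TRUE`, fit the CSP model once on all trials and
#'   cross-validate only the SVM (a replication mode; the default refits CSP
#'   inside each training fold).
#' @param details If `TRUE`, also return per-fold models' filters (used by
#'   leakage tests).
#' @return List with `mean`, `sd` (percent) and `per_rep`; with
#'   `details = TRUE` also `fold_filters`.
#' @export
crossval_accuracy <- function(x, labels = NULL, folds = 10, reps = 10,
                              cost = 1, seed = 1, n_per_class = 2,
                              fit_once = FALSE, details = FALSE) {
  if (is.list(x) && !inherits(x, "trial_set") &&
      all(c("raw", "norm", "nc") %in% names(x))) {
    cv <- x                                # precomputed trial covariances
    labs <- droplevels(factor(labels))
  } else {
    inp <- as_trial_array(x, labels)
    labs <- droplevels(factor(inp$labels))
    cv <- trial_covariances(inp$a)
  }
  if (min(table(labs)) < folds)
    stop("every class needs at least `folds` trials (have ",
         min(table(labs)), ", need ", folds, ")")
  raw_t <- t(cv$raw)                       # trials x nc^2, for features
  classes <- levels(labs)
  cls_ind <- outer(labs, classes, "==") * 1     # trials x classes
  cls_sum <- cv$norm %*% cls_ind                # per-class covariance sums
  full_model <- if (fit_once)
    fit_csp_from_covs(cv$norm, labs, cv$nc, n_per_class) else NULL

  per_rep <- numeric(reps)
  fold_filters <- list()
  K <- length(classes)
  for (r in seq_len(reps)) {
    assign <- with_seed(seed + r, stratified_folds(labs, folds))
    fold_ind <- outer(assign, seq_len(folds), "==") * 1
    # per-(fold, class) covariance sums and counts, one matmul per repetition
    ind_fc <- fold_ind[, rep(seq_len(folds), each = K), drop = FALSE] *
      cls_ind[, rep(seq_len(K), folds), drop = FALSE]
    FC <- cv$norm %*% ind_fc
    cnt_fc <- colSums(ind_fc)
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- fold_ind[, f] == 1
      model <- if (fit_once) full_model else {
        # training-fold class means = (total sums - test-fold sums) / counts
        cols <- ((f - 1) * K + 1):(f * K)
        fsum <- FC[, cols, drop = FALSE]
        ncnt <- colSums(cls_ind) - cnt_fc[cols]
        cm <- lapply(seq_along(classes), function(k)
          matrix((cls_sum[, k] - fsum[, k]) / ncnt[k], cv$nc, cv$nc))
        names(cm) <- classes
        fit_csp_from_class_means(cm, setNames(ncnt, classes), n_per_class)
      }
      WW <- apply(model$filters, 2, function(w) as.vector(tcrossprod(w)))
      V <- raw_t %*% WW
      if (any(V <= 0)) stop("zero-variance trial; CSP features undefined")
      F_all <- log(V / rowSums(V))
      fit <- e1071::svm(F_all[!te, , drop = FALSE], labs[!te],
                        kernel = "linear", cost = cost, scale = TRUE)
      pred <- predict(fit, F_all[te, , drop = FALSE])
      acc[f] <- mean(pred == labs[te])
      if (details && r == 1) fold_filters[[f]] <- model$filters
    }
    per_rep[r] <- mean(acc) * 100
  }
  out <- list(mean = mean(per_rep), sd = sd(per_rep), per_rep = per_rep)
  if (details) out$fold_filters <- fold_filters
  out
}

#' Assign H/M/L performance group
#'
#' High (H) for a mean four-class accuracy of 60% or more, medium (M) for
#' 40% up to (but excluding) 60%, low (L) below 40%.
#'
#' @param acc Accuracy in percent (vectorized).
#' @param thresholds Lower bounds of the M and H intervals (default 40, 60).
#' @return Factor with levels H, M, L.
#' @export
#' @examples
#' assign_group(c(65, 40, 39.9))  # H M L
assign_group <- function(acc, thresholds = c(40, 60)) {
  if (any(acc < 0 | acc > 100)) stop("accuracy must be within [0, 100]")
  factor(ifelse(acc >= thresholds[2], "H",
                ifelse(acc >= thresholds[1], "M", "L")),
         levels = c("H", "M", "L"))
}

#' Score one subject's MI performance
#'
#' The full per-subject scoring protocol: band-pass the trials to 8–30 Hz,
#' run repeated cross-validated multiclass CSP + linear SVM on the four-class
#' problem (mean accuracy = the subject's MI performance), on left vs. right
#' hand, and on both-hands vs. feet, then assign the H/M/L group from the
#' four-class mean.
#'
#' @param trials A `trial_set` with the four MI classes (unfiltered).
#' @param folds,reps,cost,seed,n_per_class,fit_once See [crossval_accuracy()].
#' @param band,order Classification band (default 8–30 Hz Butterworth).
#' @param thresholds Group thresholds, see [assign_group()].
#' @param two_class Also score the two 2-class problems (default `TRUE`;
#'   `FALSE` returns `NA` for them and saves about a third of the runtime).
#' @return One-row data frame: `subject`, `acc4_mean`, `acc4_sd`, `acc_lr`,
#'   `acc_hf`, `group`.
#' @export
mi_performance <- function(trials, folds = 10, reps = 10, cost = 1, seed = 1,
                           n_per_class = 2, fit_once = FALSE,
                           band = c(8, 30), order = 4,
                           thresholds = c(40, 60), two_class = TRUE) {
  stopifnot(inherits(trials, "trial_set"))
  filt <- bandpass(trials, band[1], band[2], order)
  cv <- trial_covariances(filt$data)
  res4 <- crossval_accuracy(cv, filt$labels, folds = folds, reps = reps,
                            cost = cost, seed = seed,
                            n_per_class = n_per_class, fit_once = fit_once)
  score2 <- function(keep) {
    if (!two_class) return(NA_real_)
    idx <- filt$labels %in% keep
    sub <- list(raw = cv$raw[, idx, drop = FALSE],
                norm = cv$norm[, idx, drop = FALSE], nc = cv$nc)
    crossval_accuracy(sub, droplevels(filt$labels[idx]),
                      folds = folds, reps = reps, cost = cost, seed = seed,
                      n_per_class = n_per_class, fit_once = fit_once)$mean
  }
  data.frame(subject = trials$subject_id,
             acc4_mean = res4$mean, acc4_sd = res4$sd,
             acc_lr = score2(c("left_hand", "right_hand")),
             acc_hf = score2(c("both_hands", "feet")),
             group = assign_group(res4$mean, thresholds),
             stringsAsFactors = FALSE)
}
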