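# One stratified k-fold CV run of a linear SVM on per-subject scalar
# features, with z-scoring fitted on the training folds only.
svm_cv <- function(X, y, folds, seed, cost) {
  y <- droplevels(factor(y))
  n <- length(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest group (", min_class, ") below fold count; reducing ",
            "folds to ", min_class)
    folds <- min_class
  }
  assign <- with_seed(seed, stratified_folds(y, folds))
  pred <- factor(rep(NA, n), levels = levels(y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    Ztr <- scale(X[tr, , drop = FALSE], mu, sdev)
    Zte <- scale(X[!tr, , drop = FALSE], mu, sdev)
    fit <- e1071::svm(Ztr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[!tr] <- predict(fit, Zte)
    fold_acc[f] <- mean(pred[!tr] == y[!tr])
  }
  confusion <- table(predicted = pred, true = y)
  list(accuracy = 100 * sum(diag(confusion)) / n,
       fold_accuracy = 100 * fold_acc,
       confusion = confusion, folds = folds,
       predictions = pred, fold_assignment = assign)
}

new_screening_result <- function(feature_set, cv, seed) {
  structure(list(feature_set = feature_set, cv_accuracy = cv$accuracy,
                 fold_accuracy = cv$fold_accuracy, confusion = cv$confusion,
                 folds = cv$folds, seed = seed, predictions = cv$predictions,
                 fold_assignment = cv$fold_assignment),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %s: %.2f%% (%d-fold CV)\n",
              x$feature_set, x$cv_accuracy, x$folds))
  print(x$confusion)
  invisible(x)
}

#' Screen high vs. low MI performers from resting alpha features
#'
#' Classifies group H against group L subjects from the eyes-open alpha
#' channel-pair features with a linear SVM (C = 1) under stratified k-fold
#' cross-validation, with features standardized inside each training fold.
#' A model is built for every single feature (a 1-D SVM, i.e. a threshold)
#' and for the combined feature vector.
#'
#' @param pair_features Data frame from [channel_pair_average()]: `subject`
#'   plus one column per scalar feature.
#' @param groups Data frame with `subject` and `group` (H/M/L) columns.
#' @param folds Cross-validation folds (default 10; reduced with a warning if
#'   a group is smaller).
#' @param seed Seed for the fold shuffle.
#' @param cost Linear SVM penalty.
#' @return Named list of `screening_result` objects: one per feature plus
#'   `"combined"`, each with the pooled CV accuracy (percent), per-fold
#'   accuracies and the predicted x true confusion matrix.
#' @export
screen_binary <- function(pair_features, groups, folds = 10, seed = 1,
                          cost = 1) {
  g <- setNames(as.character(groups$group), groups$subject)
  gl <- g[pair_features$subject]
  keep <- gl %in% c("H", "L")
  if (sum(gl[keep] == "H") == 0 || sum(gl[keep] == "L") == 0)
    stop("both groups H and L must be non-empty")
  y <- factor(gl[keep], levels = c("H", "L"))
  feats <- setdiff(names(pair_features), "subject")
  X <- as.matrix(pair_features[keep, feats, drop = FALSE])
  sets <- c(as.list(feats), list(feats))
  names(sets) <- c(feats, "combined")
  lapply(names(sets), function(nm) {
    cv <- svm_cv(X[, sets[[nm]], drop = FALSE], y, folds, seed, cost)
    new_screening_result(nm, cv, seed)
  }) |> setNames(names(sets))
}

#' Three-class screening model of MI performance
#'
#' Multiclass linear SVM separating H, M and L from the combined channel-pair
#' features under stratified cross-validation.  Besides the accuracy and
#' confusion matrix, returns the prediction distribution per true group
#' (columns of the confusion normalized to proportions), which exposes which
#' groups get confused with which.
#'
#' @inheritParams screen_binary
#' @return A `screening_result` with an extra `prediction_distribution`
#'   element (predicted x true proportions by true group).
#' @export
screen_three_class <- function(pair_features, groups, folds = 10, seed = 1,
                               cost = 1) {
  g <- setNames(as.character(groups$group), groups$subject)
  gl <- g[pair_features$subject]
  keep <- gl %in% c("H", "M", "L")
  y <- factor(gl[keep], levels = c("H", "M", "L"))
  if (any(table(y) == 0)) stop("all three groups must be non-empty")
  feats <- setdiff(names(pair_features), "subject")
  X <- as.matrix(pair_features[keep, feats, drop = FALSE])
  cv <- svm_cv(X, y, folds, seed, cost)
  res <- new_screening_result("combined", cv, seed)
  res$prediction_distribution <- sweep(cv$confusion, 2,
                                       pmax(colSums(cv$confusion), 1), "/")
  res
}
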