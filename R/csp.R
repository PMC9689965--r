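# --- covariance utilities ----------------------------------------------------

# Per-trial covariances of a channels x samples x trials array, returned as
# an (nc*nc) x n matrix of vectorized covariances: `raw` for feature
# variances, `norm` trace-normalized for filter fitting.
trial_covariances <- function(a) {
  d <- dim(a)
  nc <- d[1]; n <- d[3]
  raw <- matrix(0, nc * nc, n)
  for (i in seq_len(n)) {
    C <- tcrossprod(a[, , i]) / d[2]
    raw[, i] <- as.vector(C)
  }
  tr <- raw[as.vector(diag(nc) == 1), , drop = FALSE]
  norm <- sweep(raw, 2, colSums(tr), "/")
  list(raw = raw, norm = norm, nc = nc)
}

as_trial_array <- function(x, labels) {
  if (inherits(x, "trial_set")) list(a = x$data, labels = x$labels)
  else list(a = x, labels = labels)
}

# unit norm, sign fixed by making the largest-magnitude coefficient positive
fix_filter_signs <- function(w) {
  for (j in seq_len(ncol(w))) {
    w[, j] <- w[, j] / sqrt(sum(w[, j]^2))
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  w
}

# Generalized eigenproblem Sc w = lambda S w via Cholesky whitening of S
# (S = R'R, eigen of R^-T Sc R^-1); shrinks S and Sc towards a scaled
# identity if S is not safely positive definite.  Returns all eigenpairs,
# eigenvalues decreasing, vectors back-transformed to filter space.
geigen_whitened <- function(Sc, S) {
  nc <- nrow(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < max(diag(R)) * 1e-7) {
    warning("ill-conditioned composite covariance; applying shrinkage")
    g <- 0.05
    S <- (1 - g) * S + g * mean(diag(S)) * diag(nc)
    Sc <- (1 - g) * Sc + g * mean(diag(Sc)) * diag(nc)
    R <- tryCatch(chol(S), error = function(e)
      stop("composite covariance singular even after shrinkage"))
  }
  Ri <- backsolve(R, diag(nc))            # R^-1
  M <- crossprod(Ri, Sc %*% Ri)           # R^-T Sc R^-1, symmetric
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(values = ev$values, vectors = Ri %*% ev$vectors)
}

# One-vs-rest CSP fit given the per-class MEAN normalized covariances
# (list of nc x nc matrices) and trial counts; the "rest" covariance pools
# the other classes' trials (count-weighted mean).
fit_csp_from_class_means <- function(class_means, class_counts,
                                     n_per_class = 2) {
  classes <- names(class_means)
  if (length(classes) < 2) stop("CSP needs at least 2 classes")
  nc <- nrow(class_means[[1]])
  filters <- NULL; eigvals <- NULL
  if (length(classes) == 2) {
    # two-class shortcut: the second class's one-vs-rest problem is the
    # mirror image of the first (eigenvalues 1 - lambda, same eigenvectors)
    ev <- geigen_whitened(class_means[[1]],
                          class_means[[1]] + class_means[[2]])
    pick <- cbind(seq_len(n_per_class), nc + 1 - seq_len(n_per_class))
    for (j in 1:2) {
      w <- fix_filter_signs(ev$vectors[, pick[, j], drop = FALSE])
      lam <- ev$values[pick[, j]]
      if (j == 2) lam <- 1 - lam
      colnames(w) <- paste0(classes[j], "_", seq_len(n_per_class))
      filters <- cbind(filters, w)
      eigvals <- c(eigvals, setNames(lam, colnames(w)))
    }
  } else {
    for (cl in classes) {
      Sc <- class_means[[cl]]
      oth <- setdiff(classes, cl)
      Sr <- Reduce(`+`, Map(function(m, w) m * w, class_means[oth],
                            class_counts[oth])) / sum(class_counts[oth])
      ev <- geigen_whitened(Sc, Sc + Sr)
      w <- fix_filter_signs(ev$vectors[, seq_len(n_per_class), drop = FALSE])
      colnames(w) <- paste0(cl, "_", seq_len(n_per_class))
      filters <- cbind(filters, w)
      eigvals <- c(eigvals, setNames(ev$values[seq_len(n_per_class)],
                                     colnames(w)))
    }
  }
  structure(list(filters = filters, classes = classes,
                 n_per_class = n_per_class, eigenvalues = eigvals),
            class = "csp_model")
}

# Convenience wrapper: fit from vectorized normalized covariances + labels.
fit_csp_from_covs <- function(covs_norm, labels, nc, n_per_class = 2) {
  labels <- droplevels(factor(labels))
  cm <- lapply(levels(labels), function(cl)
    matrix(rowMeans(covs_norm[, labels == cl, drop = FALSE]), nc, nc))
  names(cm) <- levels(labels)
  fit_csp_from_class_means(cm, table(labels), n_per_class)
}

#' Fit one-vs-rest multiclass CSP filters
#'
#' For each class, solves the generalized eigenproblem of the class's mean
#' trace-normalized trial covariance against the composite (class + pooled
#' rest) covariance and keeps the eigenvectors of the `n_per_class` largest
#' eigenvalues.  Under this normalization the eigenvalues lie in (0, 1) and
#' equal 0.5 when a class is indistinguishable from the rest.  Filters are
#' unit-norm with the largest-magnitude coefficient positive, so the fit is
#' deterministic.  Trials are expected to be band-pass filtered (8–30 Hz for
#' the MI problem) beforehand.
#'
#' @param x A `trial_set` or a channels x samples x trials array.
#' @param labels Trial labels (ignored for a `trial_set`).
#' @param n_per_class Filters kept per class (default 2).
#' @return A `csp_model` with a channels x (n_per_class * n_classes) filter
#'   matrix.
#' @export
fit_csp_ovr <- function(x, labels = NULL, n_per_class = 2) {
  inp <- as_trial_array(x, labels)
  labs <- droplevels(factor(inp$labels))
  if (min(table(labs)) < dim(inp$a)[1])
    warning("fewer trials than channels in some class; ",
            "covariance estimates may be poor")
  cv <- trial_covariances(inp$a)
  fit_csp_from_covs(cv$norm, labs, cv$nc, n_per_class)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d classes x %d filters/class over %d channels\n",
              length(x$classes), x$n_per_class, nrow(x$filters)))
  invisible(x)
}

# Log-variance features from vectorized raw covariances: for filter w_j,
# var_j = w' C w = <vec(C), vec(w w')>; features are log of the variance
# normalized by the total variance across the model's filters.
csp_features_from_covs <- function(covs_raw, model) {
  W <- model$filters
  WW <- apply(W, 2, function(w) as.vector(tcrossprod(w)))
  V <- t(covs_raw) %*% WW
  if (any(V <= 0)) stop("zero-variance trial; CSP features undefined")
  F <- log(V / rowSums(V))
  colnames(F) <- colnames(W)
  F
}

#' Log-variance CSP features
#'
#' Projects each trial through the model's spatial filters and returns, per
#' filter, the log of the filtered-trial variance normalized by the total
#' variance across all the model's filters.  The normalization makes the
#' features invariant to positive amplitude scaling of the trial.
#'
#' @param x A `trial_set`, a channels x samples x trials array, or a single
#'   channels x samples trial matrix.
#' @param model A `csp_model` from [fit_csp_ovr()].
#' @return Numeric matrix, trials x (n_per_class * n_classes).
#' @export
csp_features <- function(x, model) {
  if (inherits(x, "trial_set")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] != nrow(model$filters))
    stop("trial channel count does not match the CSP model")
  cv <- trial_covariances(x)
  csp_features_from_covs(cv$raw, model)
}
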