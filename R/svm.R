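#' Classifier hyperparameters
#'
#' Penalty and kernel width of the soft-margin SVM with Gaussian radial
#' basis kernel K(u, v) = exp(-gamma * ||u - v||^2).
#'
#' @param C Soft-margin penalty, > 0.
#' @param gamma RBF kernel width, > 0.
#' @return An object of class `ClassifierSpec`.
#' @export
classifier_spec <- function(C, gamma) {
  C <- as.numeric(C); gamma <- as.numeric(gamma)
  stopifnot(length(C) == 1L, length(gamma) == 1L, is.finite(C), is.finite(gamma),
            C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma), class = "ClassifierSpec")
}

#' @export
print.ClassifierSpec <- function(x, ...) {
  cat(sprintf("<ClassifierSpec> C = %g, gamma = %g\n", x$C, x$gamma))
  invisible(x)
}

#' Train the RBF-kernel soft-margin SVM
#'
#' Solves the C-SVC dual by sequential minimal optimization (compiled
#' in-package; no external SVM library). Positive rows are labelled +1
#' ("HKG"), negative rows -1.
#'
#' @param pos Numeric matrix of positive-class feature rows.
#' @param neg Numeric matrix of negative-class feature rows.
#' @param spec A [classifier_spec()].
#' @param standardize Standardise each feature to zero mean / unit
#'   variance using statistics of the training rows (default TRUE; RBF
#'   kernels are scale-sensitive and raw powers span orders of magnitude).
#' @return An object of class `rbf_svm` with a [predict][predict.rbf_svm]
#'   method.
#' @export
train_classifier <- function(pos, neg, spec, standardize = TRUE) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) == 0L || nrow(neg) == 0L) stop("both classes must be non-empty")
  stopifnot(inherits(spec, "ClassifierSpec"), ncol(pos) == ncol(neg))
  X <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  }
  K <- .rbf_cross_kernel(X, X, spec$gamma)
  fit <- .smo_solve(K, y, spec$C)
  sv <- fit$alpha > 1e-8
  structure(list(X_sv = X[sv, , drop = FALSE],
                 coef = (fit$alpha * y)[sv],
                 b = fit$b, spec = spec,
                 center = center, scale = scale,
                 standardize = standardize,
                 converged = fit$converged),
            class = "rbf_svm")
}

#' Decision values and class predictions
#'
#' @param object A model from [train_classifier()].
#' @param newdata Numeric matrix of feature rows (on the raw feature
#'   scale; the training standardisation is re-applied).
#' @param type `"class"` for logical HKG calls (decision value > 0) or
#'   `"decision"` for the raw decision function.
#' @param ... Unused.
#' @return Logical vector (`type = "class"`) or numeric decision values.
#' @export
predict.rbf_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$center))
  if (object$standardize) {
    newdata <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, `/`)
  }
  K <- .rbf_cross_kernel(newdata, object$X_sv, object$spec$gamma)
  dec <- drop(K %*% object$coef) + object$b
  if (type == "class") dec > 0 else dec
}

#' Grid search for (C, gamma) by k-fold cross-validation
#'
#' Evaluates every grid point by stratified k-fold cross-validated
#' accuracy and returns the best; ties are broken by the smallest C, then
#' the smallest gamma.
#'
#' @param features Numeric feature matrix.
#' @param labels Logical (or 0/1) vector, TRUE = positive class.
#' @param grid Data frame with columns `C` and `gamma`, or a list of
#'   [classifier_spec()]s. Default: C in 2^(-3..7), gamma in 2^(-9..1).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param standardize Passed to [train_classifier()].
#' @return The winning [classifier_spec()], with the CV accuracy table in
#'   attribute `"cv"`.
#' @export
select_hyperparameters <- function(features, labels, grid = default_grid(),
                                   folds = 5L, seed = 1L, standardize = TRUE) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (sum(labels) < 2L || sum(!labels) < 2L) stop("need >= 2 examples per class")
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  if (is.list(grid) && !is.data.frame(grid)) {
    grid <- data.frame(C = vapply(grid, `[[`, numeric(1), "C"),
                       gamma = vapply(grid, `[[`, numeric(1), "gamma"))
  }
  fold_id <- withr::with_seed(seed, {
    id <- integer(length(labels))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- classifier_spec(grid$C[g], grid$gamma[g])
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(labels[tr]) == 0L || sum(!labels[tr]) == 0L) next
      model <- train_classifier(features[tr & labels, , drop = FALSE],
                                features[tr & !labels, , drop = FALSE],
                                spec, standardize = standardize)
      pred <- predict(model, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    acc[g] <- correct / length(labels)
  }
  ord <- order(-acc, grid$C, grid$gamma)
  best <- ord[1L]
  out <- classifier_spec(grid$C[best], grid$gamma[best])
  attr(out, "cv") <- cbind(grid, accuracy = acc)
  out
}

#' Default (C, gamma) search grid
#'
#' Powers of two: C in 2^-3..2^7, gamma in 2^-9..2^1.
#' @return Data frame with columns `C` and `gamma`.
#' @export
default_grid <- function() {
  expand.grid(C = 2^seq(-3L, 7L, by = 2L), gamma = 2^seq(-9L, 1L, by = 2L))
}
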