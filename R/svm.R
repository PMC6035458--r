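#' Fit an RBF-kernel C-SVC
#'
#' Features are z-scored with training statistics; the Gaussian kernel width
#' defaults to `1 / n_features` on the scaled data (unit feature variance).
#' The dual problem is solved by a deterministic SMO routine, so refitting on
#' identical data is bit-identical.
#'
#' @param X training matrix (n x p).
#' @param y binary labels (0/1 or -1/+1).
#' @param C soft-margin cost (default 1).
#' @param gamma RBF width; default `1 / ncol(X)` after scaling.
#' @param scale z-score features with training statistics (default TRUE).
#' @return an `svm_model`.
#' @export
svm_fit <- function(X, y, C = 1, gamma = NULL, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  y[y == 0] <- -1
  if (!all(y %in% c(-1, 1))) stopf("labels must be binary")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  if (nrow(X) != length(y)) stopf("X / y size mismatch")
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl < 1e-12] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- exp(-gamma * cross_dist2(Xs, Xs))
  sol <- .smo_solve(K, y, C = C)
  structure(list(X = Xs, y = y, alpha = sol$alpha, b = sol$b, gamma = gamma,
                 C = C, center = ctr, scale = scl),
            class = "svm_model")
}

#' Decision values of a fitted SVM
#'
#' Positive values predict the positive (toxicity) class; the value itself is
#' the ROC score.
#'
#' @param model an `svm_model`.
#' @param newX matrix of cases to score.
#' @return numeric decision values.
#' @export
svm_decision <- function(model, newX) {
  stopifnot(inherits(model, "svm_model"))
  newX <- as.matrix(newX)
  Xs <- sweep(sweep(newX, 2, model$center), 2, model$scale, "/")
  Kte <- exp(-model$gamma * cross_dist2(Xs, model$X))
  as.numeric(Kte %*% (model$alpha * model$y) + model$b)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF C-SVC, n = %d, p = %d, %d SV, gamma = %.4g\n",
              nrow(x$X), ncol(x$X), sum(x$alpha > 1e-8), x$gamma))
  invisible(x)
}
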