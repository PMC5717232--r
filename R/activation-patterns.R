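#' Project classifier weights into activation space
#'
#' Classifier weights are not directly interpretable as neural sources: a
#' sensor can receive a large weight merely for noise cancellation. The
#' activation pattern `a = Cov(X) %*% w` (per class) re-expresses the weights
#' as the signal pattern the classifier responds to. The covariance is
#' computed in the normalized feature space in which the weights live (the
#' classifier's stored z-scoring), pooled over all supplied trials, and the
#' result is mapped back to raw sensor units via the stored per-sensor scale.
#'
#' @param clf a [fit_timepoint()] classifier, or a plain sensors x classes
#'   weight matrix (in which case `X` is used as-is, unnormalized).
#' @param X trials x sensors data matrix from the classifier's training time.
#' @return matrix sensors x classes of class `activation_pattern`.
#' @export
activation_pattern <- function(clf, X) {
  X <- as.matrix(X)
  if (inherits(clf, "timepoint_classifier")) {
    if (ncol(X) != length(clf$center)) stop("sensor dimension mismatch")
    Xz <- sweep(sweep(X, 2, clf$center), 2, clf$scale_sd, "/")
    a <- cov(Xz) %*% clf$W
    a <- a * clf$scale_sd          # back to raw sensor units
    colnames(a) <- clf$classes
  } else {
    W <- as.matrix(clf)
    if (ncol(X) != nrow(W)) stop("sensor dimension mismatch")
    a <- cov(X) %*% W
  }
  structure(a, class = c("activation_pattern", "matrix", "array"))
}

#' Average activation patterns over a training-time window
#'
#' @param patterns list of `activation_pattern` matrices, one per training
#'   time.
#' @param train_times matching training times, ms.
#' @param window closed-open `[t0, t1)` training window, ms.
#' @return the element-wise mean `activation_pattern`.
#' @export
window_average_pattern <- function(patterns, train_times, window) {
  idx <- window_index(train_times, window)
  out <- Reduce(`+`, patterns[idx]) / length(idx)
  structure(out, class = c("activation_pattern", "matrix", "array"))
}
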