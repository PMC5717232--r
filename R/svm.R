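# Linear hinge-loss SVM (C-classification) solved by dual coordinate
# descent, with class-balanced sample costs and Platt-style sigmoid
# calibration of the decision values.

linsvm_binary <- function(X, y01, C = 1, tol = 0.01, max_iter = 1000) {
  y <- ifelse(y01, 1L, -1L)
  n <- length(y)
  npos <- sum(y01)
  # balanced weighting: each class contributes equally to the hinge term
  wts <- ifelse(y01, n / (2 * npos), n / (2 * (n - npos)))
  fit <- .linsvm_fit_cpp(t(X), y, C * wts, bias = 1, tol = tol,
                         max_iter = as.integer(max_iter))
  list(w = fit$w, b = fit$b, n_iter = fit$n_iter)
}

# Platt (1999) sigmoid P(y=1|f) = 1 / (1 + exp(A f + B)) fitted by Newton
# iterations with the smoothed targets of Lin, Lin & Weng (2007).
platt_fit <- function(f, y01, max_iter = 100) {
  n1 <- sum(y01); n0 <- sum(!y01)
  t <- ifelse(y01, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                       # dL/dz
    d2 <- p * (1 - p)
    gA <- sum(d1 * f); gB <- sum(d1)
    hAA <- sum(d2 * f * f) + 1e-12
    hAB <- sum(d2 * f)
    hBB <- sum(d2) + 1e-12
    det <- hAA * hBB - hAB^2
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(-hAB * gA + hAA * gB) / det
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newval <- obj(newA, newB)
      if (newval < val + 1e-10 || step < 1e-10) break
      step <- step / 2
    }
    if (abs(val - newval) < 1e-10 && max(abs(gA), abs(gB)) < 1e-6) {
      A <- newA; B <- newB; break
    }
    A <- newA; B <- newB; val <- newval
  }
  # calibrated probability must increase with the decision value
  c(A = min(A, -1e-8), B = B)
}

#' Fit a per-timepoint multiclass classifier
#'
#' Trains, for one time sample, a one-vs-rest bank of linear hinge-loss SVMs
#' (penalty C = 1 by default) on z-scored sensor features, with class
#' weighting that equalizes each class's contribution to the hyperplane, and
#' sigmoid (Platt) calibration of each binary decision value fitted on the
#' same training data. The z-scoring parameters are estimated from the
#' training trials only and stored with the classifier.
#'
#' @param X numeric matrix, trials x sensors.
#' @param y factor or character vector of class labels (>= 2 classes, >= 2
#'   trials per class).
#' @param C SVM penalty parameter.
#' @param classes optional fixed class order.
#' @param scale z-score features before fitting (default TRUE).
#' @param tol,max_iter dual coordinate-descent stopping rule.
#' @return an object of class `timepoint_classifier` with fields `classes`,
#'   `W` (sensors x classes weight matrix), `b`, `platt` (2 x classes),
#'   `center`, `scale_sd`, `C`.
#' @export
fit_timepoint <- function(X, y, C = 1, classes = NULL, scale = TRUE,
                          tol = 0.01, max_iter = 1000) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features")
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (any(table(factor(y, classes)) < 2L))
    stop("need at least 2 trials per class")
  if (scale) {
    ctr <- colMeans(X)
    sds <- apply(X, 2, sd)
    sds[sds < 1e-12] <- 1
  } else {
    ctr <- rep(0, ncol(X)); sds <- rep(1, ncol(X))
  }
  Xz <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  K <- length(classes)
  W <- matrix(0, ncol(X), K, dimnames = list(NULL, classes))
  b <- numeric(K)
  platt <- matrix(0, 2, K, dimnames = list(c("A", "B"), classes))
  for (k in seq_len(K)) {
    y01 <- y == classes[k]
    fit <- linsvm_binary(Xz, y01, C = C, tol = tol, max_iter = max_iter)
    W[, k] <- fit$w
    b[k] <- fit$b
    f <- drop(Xz %*% fit$w) + fit$b
    platt[, k] <- platt_fit(f, y01)
  }
  structure(list(classes = classes, W = W, b = b, platt = platt,
                 center = ctr, scale_sd = sds, C = C),
            class = "timepoint_classifier")
}

#' Class-probability predictions of a timepoint classifier
#'
#' Applies the stored normalization, evaluates the one-vs-rest decision
#' values, passes each through its calibrated sigmoid, and normalizes across
#' classes so each trial's probabilities sum to 1.
#'
#' @param clf a `timepoint_classifier`.
#' @param X numeric matrix, trials x sensors (same sensor dimension as
#'   training).
#' @return matrix trials x classes of probabilities.
#' @export
predict_proba <- function(clf, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(clf$center)) stop("sensor dimension mismatch")
  Xz <- sweep(sweep(X, 2, clf$center), 2, clf$scale_sd, "/")
  f <- sweep(Xz %*% clf$W, 2, clf$b, "+")
  p <- 1 / (1 + exp(sweep(f, 2, clf$platt["A", ], "*") +
                      rep(clf$platt["B", ], each = nrow(f))))
  p / rowSums(p)
}

#' Hard class labels (secondary metric)
#'
#' Argmax of the calibrated probabilities; exact ties resolve to the first
#' class in the classifier's fixed class order. Mean correct-class
#' probability, not accuracy, is the pipeline's primary performance
#' measure; hard labels feed confusion matrices.
#'
#' @param clf a `timepoint_classifier`.
#' @param X trials x sensors matrix.
#' @return character vector of predicted class labels.
#' @export
predict_classes <- function(clf, X) {
  p <- predict_proba(clf, X)
  clf$classes[max.col(p, ties.method = "first")]
}

#' Uncalibrated decision values
#' @param clf a `timepoint_classifier`.
#' @param X trials x sensors matrix.
#' @return matrix trials x classes of signed margins.
#' @export
decision_values <- function(clf, X) {
  X <- as.matrix(X)
  Xz <- sweep(sweep(X, 2, clf$center), 2, clf$scale_sd, "/")
  sweep(Xz %*% clf$W, 2, clf$b, "+")
}
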