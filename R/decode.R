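stratified_folds <- function(y, n_folds, seed = 1) {
  y <- as.character(y)
  if (any(table(y) < n_folds))
    stop("every class needs at least n_folds trials for stratification")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated temporal generalization decoding
#'
#' For each fold of a stratified K-fold split and each training time `t`, a
#' [fit_timepoint()] classifier (z-scoring refit per fold from the training
#' trials at `t`) is trained on the held-in trials and applied to the
#' held-out trials at every testing time `t'`, so that train- and test-time
#' data always come from independent trials. Classification performance is
#' the mean probability assigned to the correct class (chance `1/K_classes`).
#'
#' @param ep an [epochs] object.
#' @param labels per-trial class labels (default `info(ep)$category`).
#' @param n_folds number of stratified folds (default 5).
#' @param C SVM penalty parameter.
#' @param train_times training times to use (ms; default all samples).
#' @param seed seed of the fold assignment.
#' @param keep_probs keep the full per-trial, per-class probability array
#'   (train x test x trials x classes)? Default FALSE; the per-trial
#'   correct-class probability array is always kept.
#' @return an object of class `generalization_matrix`: list with `values`
#'   (train x test mean correct-class probability), `train_times`,
#'   `test_times`, `chance`, `classes`, `folds`, and optionally `probs` and
#'   `correct_prob` (train x test x trials).
#' @export
cv_temporal_generalization <- function(ep, labels = NULL, n_folds = 5, C = 1,
                                       train_times = NULL, seed = 1,
                                       keep_probs = FALSE) {
  stopifnot(inherits(ep, "epochs"))
  if (is.null(labels)) labels <- ep$info$category
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  K <- length(classes)
  fold <- stratified_folds(labels, n_folds, seed = seed)
  tr_idx <- if (is.null(train_times)) seq_along(ep$times) else
    vapply(train_times, function(t) time_index(ep$times, t), integer(1))
  n_tr <- length(tr_idx)
  n_te <- length(ep$times)
  n <- n_trials(ep)
  cls_idx <- match(labels, classes)
  correct <- array(NA_real_, c(n_tr, n_te, n))
  probs <- if (keep_probs) array(NA_real_, c(n_tr, n_te, n, K)) else NULL
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    clfs <- lapply(seq_len(n_tr), function(a)
      fit_timepoint(ep$data[train, , tr_idx[a]], labels[train], C = C,
                    classes = classes))
    pre <- precompute_bank(clfs)
    ep_test <- subset_trials(ep, test)
    correct[, , test] <- bank_correct_prob(pre, ep_test, cls_idx[test])
    if (keep_probs) {
      for (b in seq_len(n_te)) {
        pb <- predict_bank(pre, matrix(ep$data[test, , b], length(test)))
        probs[, b, test, ] <- aperm(pb, c(3, 1, 2))
      }
    }
  }
  values <- rowMeans(correct, dims = 2)
  out <- list(values = values, train_times = ep$times[tr_idx],
              test_times = ep$times, chance = 1 / K, classes = classes,
              folds = fold, correct_prob = correct)
  if (keep_probs) out$probs <- probs
  structure(out, class = "generalization_matrix")
}

#' Diagonal of a generalization matrix
#' @param gm a `generalization_matrix`.
#' @return numeric vector of train = test performance over time.
#' @export
gm_diagonal <- function(gm) {
  idx <- vapply(gm$train_times, function(t) time_index(gm$test_times, t),
                integer(1))
  gm$values[cbind(seq_along(gm$train_times), idx)]
}

#' Train a bank of classifiers over all training times
#'
#' Fits one [fit_timepoint()] classifier per training time on all trials
#' (used for localizer-to-stream transfer, where the test data come from a
#' different task and no cross-validation is required).
#'
#' @param ep an [epochs] object (e.g. the localizer).
#' @param labels per-trial labels (default `info(ep)$category`).
#' @param train_times training times in ms (default all samples).
#' @param C SVM penalty parameter.
#' @return an object of class `classifier_bank`: list of classifiers plus
#'   `train_times` and `classes`.
#' @export
train_timepoint_classifiers <- function(ep, labels = NULL,
                                        train_times = NULL, C = 1) {
  stopifnot(inherits(ep, "epochs"))
  if (is.null(labels)) labels <- ep$info$category
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(train_times)) train_times <- ep$times
  idx <- vapply(train_times, function(t) time_index(ep$times, t), integer(1))
  clfs <- lapply(idx, function(ti)
    fit_timepoint(ep$data[, , ti], labels, C = C, classes = classes))
  structure(list(classifiers = clfs, train_times = ep$times[idx],
                 classes = classes), class = "classifier_bank")
}

# Stack a list of timepoint classifiers into one weight matrix so that a
# whole bank is applied to a data matrix with a single BLAS call.  The
# per-classifier z-scoring is folded into the weights:
#   f = ((x - mu)/s) W + b  =  x (W/s) + (b - (mu/s) W)
precompute_bank <- function(clfs) {
  K <- length(clfs[[1]]$classes)
  Wall <- do.call(cbind, lapply(clfs, function(cl) cl$W / cl$scale_sd))
  ball <- unlist(lapply(clfs, function(cl)
    cl$b - drop(crossprod(cl$center / cl$scale_sd, cl$W))))
  A <- unlist(lapply(clfs, function(cl) cl$platt["A", ]))
  B <- unlist(lapply(clfs, function(cl) cl$platt["B", ]))
  list(Wall = Wall, ball = ball, A = A, B = B, K = K,
       n_clf = length(clfs))
}

# probabilities of every classifier in a precomputed bank on one data
# matrix; returns trials x K x n_clf
predict_bank <- function(pre, X) {
  f <- X %*% pre$Wall
  f <- sweep(f, 2, pre$ball, "+")
  p <- 1 / (1 + exp(sweep(f, 2, pre$A, "*") + rep(pre$B, each = nrow(f))))
  dim(p) <- c(nrow(X), pre$K, pre$n_clf)
  q <- aperm(p, c(2, 1, 3))                  # K x n x n_clf
  tot <- colSums(q)                          # n x n_clf sums over classes
  q <- q / rep(tot, each = pre$K)
  aperm(q, c(2, 1, 3))
}

# Correct-class probabilities of a stacked bank over all test times,
# without materializing the full per-class array.  cls_idx gives each
# trial's correct class (index into the class order).  Returns
# n_clf x n_test x n_trials.
bank_correct_prob <- function(pre, ep, cls_idx, test_idx = NULL) {
  n <- n_trials(ep)
  if (is.null(test_idx)) test_idx <- seq_along(ep$times)
  A <- pre$n_clf; K <- pre$K
  # f columns are classifier-major, class-minor
  sum_mat <- kronecker(diag(A), rep(1, K))
  pick <- cbind(rep(seq_len(n), A),
                as.vector(outer(cls_idx, (seq_len(A) - 1L) * K, "+")))
  cp <- array(NA_real_, c(A, length(test_idx), n))
  for (bi in seq_along(test_idx)) {
    f <- matrix(ep$data[, , test_idx[bi]], nrow = n) %*% pre$Wall
    f <- sweep(f, 2, pre$ball, "+")
    p <- 1 / (1 + exp(sweep(f, 2, pre$A, "*") + rep(pre$B, each = n)))
    num <- matrix(p[pick], n, A)
    cp[, bi, ] <- t(num / (p %*% sum_mat))
  }
  cp
}

#' Apply a classifier bank to new epochs at every testing time
#'
#' Localizer-trained classifiers are applied, without refitting, to every
#' time sample of the test epochs (each classifier's stored normalization is
#' reused), yielding the train-time x test-time x trials x classes
#' probability array.
#'
#' @param bank a `classifier_bank` from [train_timepoint_classifiers()].
#' @param ep test [epochs] (e.g. per-stimulus re-epoched stream data).
#' @return array train x test x trials x classes, with `train_times` /
#'   `test_times` / `classes` attributes.
#' @export
transfer_decode <- function(bank, ep) {
  stopifnot(inherits(bank, "classifier_bank"), inherits(ep, "epochs"))
  if (dim(ep$data)[2] != length(bank$classifiers[[1]]$center))
    stop("sensor dimension mismatch between bank and test epochs")
  n_tr <- length(bank$train_times)
  n_te <- length(ep$times)
  n <- n_trials(ep)
  K <- length(bank$classes)
  out <- array(NA_real_, c(n_tr, n_te, n, K))
  pre <- precompute_bank(bank$classifiers)
  for (b in seq_len(n_te)) {
    Xb <- matrix(ep$data[, , b], nrow = n)
    pb <- predict_bank(pre, Xb)              # n x K x n_tr
    out[, b, , ] <- aperm(pb, c(3, 1, 2))
  }
  attr(out, "train_times") <- bank$train_times
  attr(out, "test_times") <- ep$times
  attr(out, "classes") <- bank$classes
  out
}

#' Per-stimulus correct-class probability matrices
#'
#' Reduces transfer probability arrays to, per stream position, the
#' train x test x trials array of probabilities assigned to that position's
#' own category, plus its trial-mean matrix.
#'
#' @param transfer_list named list of [transfer_decode()] outputs, one per
#'   stream position (as produced by applying the bank to [epoch_stream()]
#'   output).
#' @param info TrialInfo data.frame with `cat_pos<k>` columns.
#' @return object of class `per_stimulus_matrices`: per position a list with
#'   `correct_prob` (train x test x trials) and `values` (train x test mean);
#'   common `train_times`, `test_times`, `chance`.
#' @export
per_stimulus_matrix <- function(transfer_list, info) {
  positions <- as.integer(sub("^pos", "", names(transfer_list)))
  out <- list()
  for (j in seq_along(positions)) {
    p <- positions[j]
    pr <- transfer_list[[j]]
    classes <- attr(pr, "classes")
    cats <- info[[paste0("cat_pos", p)]]
    cls_idx <- match(as.character(cats), classes)
    if (anyNA(cls_idx)) stop("unknown category label at position ", p)
    n <- dim(pr)[3]
    cp <- array(NA_real_, dim(pr)[1:3])
    for (i in seq_len(n)) cp[, , i] <- pr[, , i, cls_idx[i]]
    out[[paste0("pos", p)]] <-
      list(position = p, correct_prob = cp, values = apply(cp, c(1, 2), mean))
  }
  structure(list(positions = positions, matrices = out,
                 train_times = attr(transfer_list[[1]], "train_times"),
                 test_times = attr(transfer_list[[1]], "test_times"),
                 chance = 1 / length(attr(transfer_list[[1]], "classes"))),
            class = "per_stimulus_matrices")
}

#' Long-format export of generalization matrices
#'
#' Flattens one or more train x test performance matrices into the tidy
#' (train_ms, test_ms, position, condition, subject, value) layout used
#' for CSV export.
#'
#' @param values matrix train x test.
#' @param train_times,test_times time axes, ms.
#' @param position,condition,subject identifying columns (recycled).
#' @return data.frame in long format.
#' @export
matrix_long <- function(values, train_times, test_times, position = NA,
                        condition = NA, subject = NA) {
  data.frame(train_ms = rep(train_times, times = length(test_times)),
             test_ms = rep(test_times, each = length(train_times)),
             position = position, condition = condition, subject = subject,
             value = as.vector(values))
}

#' Window-mean classification performance
#'
#' Mean of one training-time row of a generalization matrix over a testing
#' window (closed-open `[t0, t1)`).
#'
#' @param values matrix train x test (or train x test x trials array, in
#'   which case a per-trial vector is returned).
#' @param train_times,test_times time axes of `values`, ms.
#' @param train_time training time of interest (nearest sample used).
#' @param test_window testing window in ms, default `c(400, 550)`.
#' @return scalar (or per-trial vector) mean performance.
#' @export
mean_window <- function(values, train_times, test_times, train_time,
                        test_window = c(400, 550)) {
  a <- time_index(train_times, train_time)
  idx <- window_index(test_times, test_window)
  if (length(dim(values)) == 3L)
    return(apply(values[a, idx, , drop = FALSE], 3, mean))
  mean(values[a, idx])
}

#' Onset and offset of a decodable timecourse
#'
#' The median-threshold rule: threshold = 50th percentile of the timecourse's
#' values; onset = first time strictly above it, offset = last.
#'
#' @param timecourse numeric vector (group-averaged performance over time).
#' @param times matching time axis in ms.
#' @return named numeric `c(onset, offset)`; both `NA` (with a warning) if
#'   nothing exceeds the threshold.
#' @export
onset_offset <- function(timecourse, times) {
  stopifnot(length(timecourse) == length(times))
  thr <- median(timecourse)
  above <- which(timecourse > thr)
  if (!length(above)) {
    warning("no sample strictly exceeds the median; onset/offset undefined")
    return(c(onset = NA_real_, offset = NA_real_))
  }
  c(onset = times[min(above)], offset = times[max(above)])
}

#' Null calibration of the decoder by label permutation
#'
#' Permutes the trial labels of an epochs object and reruns the full
#' cross-validated diagonal decoding, returning the grand-mean correct-class
#' probability per permutation. With four balanced classes this distribution
#' must concentrate at chance 0.25.
#'
#' @param ep an [epochs] object.
#' @param labels trial labels (default `info(ep)$category`).
#' @param n_perm number of label permutations.
#' @param n_folds stratified folds per run.
#' @param seed seed for permutations and fold splits.
#' @return numeric vector of length `n_perm` of grand-mean performances.
#' @export
null_calibration <- function(ep, labels = NULL, n_perm = 100, n_folds = 5,
                             seed = 1) {
  stopifnot(inherits(ep, "epochs"))
  if (is.null(labels)) labels <- ep$info$category
  labels <- as.character(labels)
  perms <- with_seed(seed, replicate(n_perm, sample(labels),
                                     simplify = FALSE))
  vapply(seq_len(n_perm), function(i) {
    gm <- cv_diagonal(ep, perms[[i]], n_folds = n_folds, seed = seed + i)
    mean(gm$values)
  }, numeric(1))
}

# diagonal-only CV decoding (train time = test time), used where the full
# generalization matrix is not needed
cv_diagonal <- function(ep, labels, n_folds = 5, C = 1, seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, n_folds, seed = seed)
  n_t <- length(ep$times)
  n <- n_trials(ep)
  correct <- matrix(NA_real_, n_t, n)
  cls_idx <- match(labels, classes)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    for (a in seq_len(n_t)) {
      clf <- fit_timepoint(ep$data[train, , a], labels[train], C = C,
                           classes = classes)
      p <- predict_proba(clf, ep$data[test, , a])
      correct[a, test] <- p[cbind(seq_along(test), cls_idx[test])]
    }
  }
  list(values = rowMeans(correct), times = ep$times, chance = 1 / length(classes))
}
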