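test_that("separable classes are fit perfectly with calibrated output", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
             matrix(rnorm(40, mean = -2), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  clf <- fit_timepoint(X, y)
  p <- predict_proba(clf, X)
  expect_equal(max(abs(rowSums(p) - 1)), 0, tolerance = 1e-9)
  expect_equal(mean(clf$classes[max.col(p)] == y), 1)
  expect_error(fit_timepoint(X, rep("a", 40)), "2 classes")
  expect_error(fit_timepoint(X, c("b", rep("a", 39))), "2 trials")
  Xbad <- X; Xbad[1] <- Inf
  expect_error(fit_timepoint(Xbad, y), "non-finite")
})

test_that("class-permutation-symmetric input yields uniform probabilities", {
  # four classes built as cyclic shifts of one base set: the learning
  # problem is invariant under class rotation, so a shift-invariant probe
  # point must receive probability 1/4 from every class
  base <- matrix(c(3, 0.3, -0.2, 0.1,
                   2.5, -0.4, 0.3, 0.2,
                   3.2, 0.2, 0.1, -0.3,
                   2.8, -0.1, -0.3, 0.4,
                   3.1, 0.4, 0.2, 0.3), ncol = 4, byrow = TRUE)
  shift <- function(M, k) M[, ((seq_len(4) - 1 + k) %% 4) + 1, drop = FALSE]
  X <- do.call(rbind, lapply(0:3, function(k) shift(base, -k)))
  y <- rep(letters[1:4], each = nrow(base))
  clf <- fit_timepoint(X, y, tol = 1e-8, max_iter = 1e5)
  probe <- matrix(1, 1, 4)                 # invariant under rotation
  expect_equal(drop(predict_proba(clf, probe)), rep(0.25, 4),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("probability ranking follows the calibrated decision values", {
  set.seed(2)
  td <- toy_multiclass(n_per = 25, sep = 1.5, seed = 2)
  clf <- fit_timepoint(td$X, td$y)
  Xn <- matrix(rnorm(30 * 12), 30, 12)
  f <- decision_values(clf, Xn)
  p_raw <- 1 / (1 + exp(sweep(f, 2, clf$platt["A", ], "*") +
                          rep(clf$platt["B", ], each = 30)))
  for (k in 1:4) {
    expect_equal(order(p_raw[, k]), order(f[, k]))  # A < 0: monotone
  }
  expect_true(all(clf$platt["A", ] < 0))
})

test_that("duplicating a class's trials leaves a separable boundary fixed", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, mean = 3, sd = 0.3), 30, 2),
             matrix(rnorm(40, mean = -3, sd = 0.3), 20, 2))
  y <- rep(c("a", "b"), c(30, 20))
  w1 <- fit_timepoint(X, y, scale = FALSE, tol = 1e-6, max_iter = 20000)
  Xd <- rbind(X, X[y == "a", ]); yd <- c(y, rep("a", 30))
  w2 <- fit_timepoint(Xd, yd, scale = FALSE, tol = 1e-6, max_iter = 20000)
  expect_equal(w1$W, w2$W, tolerance = 1e-5)
  expect_equal(w1$b, w2$b, tolerance = 1e-5)
})

test_that("the dual solver matches a brute-force primal minimizer", {
  # identical objective: 0.5(||w||^2 + b^2) + sum_i C_i hinge_i with the
  # regularized augmented bias, solved directly with Nelder-Mead restarts
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y01 <- rep(c(TRUE, FALSE), each = 10)
  X[y01, 1] <- X[y01, 1] + 1.5
  n <- 20
  Ci <- ifelse(y01, n / (2 * 10), n / (2 * 10))
  obj <- function(th) {
    w <- th[1:3]; b <- th[4]
    marg <- ifelse(y01, 1, -1) * (drop(X %*% w) + b)
    0.5 * sum(th^2) + sum(Ci * pmax(0, 1 - marg))
  }
  fit <- tgdecode:::linsvm_binary(X, y01, C = 1, tol = 1e-7,
                                  max_iter = 50000)
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- optim(rnorm(4, sd = 0.5), obj,
               control = list(maxit = 5000, reltol = 1e-12))
    o <- optim(o$par, obj, control = list(maxit = 5000, reltol = 1e-12))
    if (o$value < best) { best <- o$value; par <- o$par }
  }
  expect_equal(obj(c(fit$w, fit$b)), best, tolerance = 1e-4)
  cs <- sum(fit$w * par[1:3]) / sqrt(sum(fit$w^2) * sum(par[1:3]^2))
  expect_gt(cs, 0.999)
  expect_equal(fit$b, par[4], tolerance = 0.01)
})

test_that("the fitted hyperplane agrees with e1071's direction", {
  set.seed(5)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y01 <- rep(c(TRUE, FALSE), each = 40)
  X[y01, 2] <- X[y01, 2] + 2
  fit <- tgdecode:::linsvm_binary(X, y01, C = 1, tol = 1e-6,
                                  max_iter = 50000)
  m <- e1071::svm(X, factor(y01, c(TRUE, FALSE)), kernel = "linear",
                  cost = 1, scale = FALSE)
  w_e <- drop(t(m$coefs) %*% m$SV)
  cs <- sum(fit$w * w_e) / sqrt(sum(fit$w^2) * sum(w_e^2))
  expect_gt(cs, 0.99)
})

test_that("normalization parameters come from training data only", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), each = 20)
  clf <- fit_timepoint(X, y)
  expect_equal(clf$center, colMeans(X))
  expect_equal(clf$scale_sd, apply(X, 2, sd))
  # the classifier is a pure function of the training trials: predictions
  # on wildly shifted test data use the stored, frozen scaler
  p1 <- predict_proba(clf, X[1:5, ])
  clf2 <- fit_timepoint(X, y)                 # refit, nothing changed
  expect_identical(p1, predict_proba(clf2, X[1:5, ]))
})

test_that("cross-validated scaling beats full-data scaling at null calibration", {
  # z-scoring with statistics from all trials (the classic leakage bug)
  # must not be what the pipeline does: its CV null is centered at chance
  set.seed(7)
  loc <- epochs(array(rnorm(40 * 16 * 21), c(40, 16, 21)),
                seq(-50, 150, 10), 100,
                info = data.frame(category = sample(rep(letters[1:4], 10))))
  gm <- cv_temporal_generalization(loc, train_times = c(0, 100, 200),
                                   seed = 1)
  expect_lt(abs(mean(gm$values) - 0.25), 0.02)
})

test_that("generalization matrix diagonal equals train-and-test-at-t decoding", {
  td <- toy_multiclass(n_per = 15, p = 8, sep = 2, seed = 8)
  dat <- array(0, c(60, 8, 3))
  dat[, , 1] <- matrix(rnorm(60 * 8), 60, 8)
  dat[, , 2] <- td$X
  dat[, , 3] <- td$X + 0.5
  ep <- epochs(dat, c(0, 10, 20), 100,
               info = data.frame(category = td$y))
  gm <- cv_temporal_generalization(ep, seed = 3)
  di <- cv_diagonal(ep, td$y, seed = 3)
  expect_equal(gm_diagonal(gm), di$values, tolerance = 1e-12)
  expect_true(all(gm$values >= 0 & gm$values <= 1))
  # informative timepoint decodes above chance, noise timepoint does not
  expect_gt(gm$values[2, 2], 0.4)
  expect_lt(abs(gm$values[1, 1] - 0.25), 0.08)
  expect_error(cv_temporal_generalization(ep, labels = rep(c("a", "b"), 30),
                                          n_folds = 40), "n_folds")
})

test_that("noise-free generalization matches the kernel-overlap structure", {
  # stages share a pattern iff: early~early, early~sustain, mid~mid,
  # late~late; the matrix must be above chance exactly where train- and
  # test-time codes overlap in pattern space
  cfg <- tiny_config(noise_sd = 0, n_localizer_trials = 24, rng_seed = 2)
  pr <- tiny_primitives(24, seed = 2)
  loc <- with_seed(2, simulate_localizer(cfg, pr$patterns, pr$kernels))
  gm <- cv_temporal_generalization(loc, train_times = c(-30, 160, 300, 510),
                                   seed = 1)
  tt <- gm$test_times
  v <- gm$values
  # strong diagonal codes
  expect_gt(v[2, tt == 160], 0.5)
  expect_gt(v[3, tt == 300], 0.5)
  expect_gt(v[4, tt == 510], 0.5)
  # early <-> sustain reactivation (shared topography), both directions
  expect_gt(v[2, tt == 510], 0.35)
  expect_gt(v[4, tt == 160], 0.35)
  # pre-onset training time has no code: flat at chance everywhere
  expect_lt(max(abs(v[1, ] - 0.25)), 0.05)
  # early code is absent at mid-stage-only test times and vice versa is
  # covered by the mid/late rows; early classifier at 300 ms sees only
  # mid + late patterns, which it was not trained on
  expect_lt(v[2, tt == 300], 0.45)
})

test_that("a localizer trial embedded in a stream transfers identically", {
  td <- toy_multiclass(n_per = 15, p = 8, sep = 2, seed = 9)
  n_t <- 5
  dat <- array(rnorm(60 * 8 * n_t, sd = 0.1), c(60, 8, n_t))
  dat[, , 2] <- td$X
  loc <- epochs(dat, seq(0, by = 10, length.out = n_t), 100,
                info = data.frame(category = td$y))
  bank <- train_timepoint_classifiers(loc)
  # "stream" epochs that are literally the localizer data
  pr <- transfer_decode(bank, loc)
  expect_equal(dim(pr), c(n_t, n_t, 60, 4))
  for (i in c(1, 30)) {
    expect_equal(pr[2, 2, i, ], unname(predict_proba(bank$classifiers[[2]],
                                                     td$X[i, , drop = FALSE])[1, ]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # probabilities stay normalized everywhere
  expect_equal(range(apply(pr, 1:3, sum)), c(1, 1), tolerance = 1e-9)
  expect_error(transfer_decode(bank, epochs(dat[, 1:3, , drop = FALSE],
                                            loc$times, 100)),
               "dimension")
})

test_that("per-stimulus extraction follows each position's own labels", {
  td <- toy_multiclass(n_per = 10, p = 6, sep = 3, seed = 10)
  n <- 40
  dat <- array(td$X, c(n, 6, 1))
  ep <- epochs(dat, 0, 100, info = data.frame(category = td$y))
  bank <- train_timepoint_classifiers(ep)
  tr <- transfer_decode(bank, ep)
  info <- data.frame(cat_pos1 = td$y, cat_pos2 = sample(td$y))
  psm <- per_stimulus_matrix(list(pos1 = tr, pos2 = tr), info)
  # position 1 uses the true labels: high correct-class probability
  expect_gt(psm$matrices$pos1$values[1, 1], 0.5)
  # position 2 uses shuffled labels: near chance
  expect_lt(psm$matrices$pos2$values[1, 1], 0.4)
  # bookkeeping: swapping two labels swaps the extracted probabilities
  info2 <- info
  info2$cat_pos1 <- replace(info$cat_pos1, 1:2, info$cat_pos1[2:1])
  psm2 <- per_stimulus_matrix(list(pos1 = tr), info2)
  expect_equal(psm2$matrices$pos1$correct_prob[1, 1, 1],
               tr[1, 1, 1, match(info$cat_pos1[2], bank$classes)])
})

test_that("hard labels follow calibrated probabilities; long export round-trips", {
  td <- toy_multiclass(n_per = 12, p = 6, sep = 3, seed = 12)
  clf <- fit_timepoint(td$X, td$y)
  cls <- predict_classes(clf, td$X)
  p <- predict_proba(clf, td$X)
  expect_equal(cls, clf$classes[max.col(p, ties.method = "first")])
  expect_gt(mean(cls == td$y), 0.9)
  vals <- matrix(runif(6), 2, 3)
  lg <- matrix_long(vals, c(100, 110), c(0, 10, 20), position = 3,
                    condition = "target", subject = 1)
  expect_equal(nrow(lg), 6)
  expect_equal(lg$value[lg$train_ms == 110 & lg$test_ms == 20], vals[2, 3])
  expect_equal(matrix(lg$value, 2, 3), vals)
})

test_that("window means use the closed-open sample convention", {
  vals <- matrix(0.3, 4, 91)
  trt <- c(120, 170, 220, 370)
  tet <- seq(0, 900, 10)
  expect_equal(mean_window(vals, trt, tet, 170), 0.3)
  expect_equal(length(window_index(tet, c(400, 550))), 15)
  vals[2, ] <- seq_len(91) / 100
  got <- mean_window(vals, trt, tet, 170, c(400, 550))
  expect_equal(got, mean((41:55) / 100))
  expect_error(mean_window(vals, trt, tet, 170, c(550, 400)), "window")
})

test_that("onset/offset follow the median-threshold rule", {
  tc <- c(0.25, 0.25, 0.30, 0.40, 0.30, 0.25, 0.25)
  times <- seq(0, 60, 10)
  expect_equal(onset_offset(tc, times), c(onset = 20, offset = 40))
  inc <- seq(0.2, 0.5, length.out = 7)
  expect_equal(onset_offset(inc, times)[["offset"]], 60)
  expect_warning(oo <- onset_offset(rep(0.3, 7), times), "undefined")
  expect_true(all(is.na(oo)))
})
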