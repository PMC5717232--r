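test_that("category topographies are unit norm, quasi-orthogonal, reproducible", {
  ps <- make_category_patterns(100, rng_seed = 1, max_cosine = 0.3)
  expect_equal(dim(ps$patterns), c(100, 12))
  expect_equal(unname(sqrt(colSums(ps$patterns^2))), rep(1, 12),
               tolerance = 1e-12)
  G <- crossprod(ps$patterns)
  expect_lt(max(abs(G[upper.tri(G)])), 0.3)
  ps2 <- make_category_patterns(100, rng_seed = 1, max_cosine = 0.3)
  expect_identical(ps$patterns, ps2$patterns)
  expect_error(make_category_patterns(4, rng_seed = 1, max_cosine = 0.01))
  expect_error(make_category_patterns(24, rng_seed = 1, max_cosine = 1e-4),
               "1000")
})

test_that("response kernels have the documented shape and support", {
  ks <- make_response_kernels()
  expect_true(all(ks$sampled >= 0))
  # the continuous envelopes peak at 1 (at the window midpoint for bumps);
  # the sampled grid may sit just off an off-grid peak
  for (st in names(ks$stage_windows))
    expect_equal(eval_kernel(ks, st, mean(ks$stage_windows[[st]])), 1)
  expect_gt(min(apply(ks$sampled, 2, max)), 0.99)
  expect_equal(ks$tau[which.max(ks$sampled[, "early"])], (90 + 230) / 2)
  # support rule: window (90, 230) with 50 ms skirts covers the 0-900 ms
  # grid samples at 40..280 ms and nothing else
  nz <- which(ks$sampled[, "early"] > 0)
  expect_true(all(ks$tau[nz] > 40 - 1e-9 & ks$tau[nz] < 280 + 1e-9))
  expect_true(all(ks$sampled[ks$tau > 50 & ks$tau < 270, "early"] > 0))
  # sustained stages plateau at 1 inside the window
  expect_equal(unname(ks$sampled[ks$tau >= 400 & ks$tau <= 670, "late"]),
               rep(1, sum(ks$tau >= 400 & ks$tau <= 670)))
  expect_error(make_response_kernels(list(early = c(230, 90))), "onset")
  expect_error(make_response_kernels(list(early = c(700, 1000))), "900")
})

test_that("localizer trials are exact stage superpositions when noise-free", {
  cfg <- tiny_config(noise_sd = 0, n_localizer_trials = 8)
  pr <- tiny_primitives()
  suppressWarnings(loc <- simulate_localizer(cfg, pr$patterns, pr$kernels))
  amp <- cfg$stage_amplitudes
  for (i in 1:2) {
    cc <- loc$info$category[i]
    expected <- Reduce(`+`, lapply(names(amp), function(st) {
      topo <- pattern_of(pr$patterns, cc, if (st == "sustain") "early" else st)
      amp[[st]] * outer(topo, eval_kernel(pr$kernels, st, loc$times))
    }))
    expect_equal(loc$data[i, , ], expected, tolerance = 1e-12)
  }
  # pre-onset samples carry no signal (kernel supports start at 40 ms)
  expect_equal(max(abs(loc$data[, , loc$times <= 0])), 0)
})

test_that("localizer labels are balanced, with rounding to a balanced count", {
  cfg <- tiny_config(n_localizer_trials = 300, noise_sd = 0)
  pr <- tiny_primitives()
  loc <- simulate_localizer(cfg, pr$patterns, pr$kernels)
  expect_equal(as.integer(table(loc$info$category)), rep(75L, 4))
  cfg2 <- tiny_config(n_localizer_trials = 10, noise_sd = 0)
  expect_warning(loc2 <- simulate_localizer(cfg2, pr$patterns, pr$kernels),
                 "balanced")
  expect_equal(n_trials(loc2), 8)
})

test_that("stream trials superpose single-stimulus responses linearly", {
  cfg <- tiny_config(noise_sd = 0)
  pr <- tiny_primitives()
  m <- selection_model("gradual")
  set.seed(1)
  tr <- simulate_rsvp_trial(cfg, pr$patterns, pr$kernels, m, lag = 7)
  onsets <- stream_onsets(cfg)
  gains <- selection_gains(m, tr$info$target_pos, tr$info$lag,
                           unlist(tr$info[c("guess1", "guess2", "guess3")]))
  gains <- sweep(gains, 2, cfg$stage_amplitudes[colnames(gains)], "*")
  expected <- matrix(0, cfg$n_sensors, length(tr$times))
  for (i in 1:12) {
    cc <- tr$info[[paste0("cat_pos", i)]]
    expected <- expected + stim_template(pr$patterns, pr$kernels, cc,
                                         tr$times - onsets[i],
                                         as.list(gains[i, ]))
  }
  expect_equal(tr$data, expected, tolerance = 1e-12)
})

test_that("overlapping stage codes coexist at a single stream time", {
  # at ~1.19 s after stream onset: stimulus 9 is in its early stage,
  # stimulus 8 in its mid stage, stimulus 7 (if gated) in its late stage
  cfg <- tiny_config(noise_sd = 0)
  ks <- make_response_kernels()
  onsets <- stream_onsets(cfg)
  t_probe <- 1190
  tau <- t_probe - onsets[c("9", "8", "7")]
  expect_gt(eval_kernel(ks, "early", tau[["9"]]), 0)
  expect_gt(eval_kernel(ks, "mid", tau[["8"]]), 0)
  expect_gt(eval_kernel(ks, "late", tau[["7"]]), 0)
  expect_equal(eval_kernel(ks, "early", tau[["7"]]), 0)
})

test_that("discrete gating zeroes the late stage of unreported stimuli", {
  m <- selection_model("discrete")
  g <- selection_gains(m, target_position = 7, lag = 7, guesses = c(7, 6, 9))
  expect_true(all(g[c(7, 6, 9), "late"] > 0))
  expect_equal(unname(g[-c(7, 6, 9), "late"]), rep(0, 9))
  expect_equal(unname(g[, "sustain"]), rep(0, 12))
  # graded by guess order
  expect_true(g[7, "late"] > g[6, "late"] && g[6, "late"] > g[9, "late"])
})

test_that("gradual profile collapses onto the target as sigma -> 0", {
  m <- selection_model("gradual", gradual_sigma = 1e-9,
                       gradual_asymmetry = 1)
  g <- gradual_gain_profile(m, 7)
  expect_equal(g[7], 1)
  expect_equal(max(g[-7]), 0)
  # asymmetric default: preceding neighbor enhanced more than following
  m2 <- selection_model("gradual")
  g2 <- gradual_gain_profile(m2, 7)
  expect_gt(g2[6], g2[8])
})

test_that("datasets are deterministic and balanced over lags", {
  cfg <- tiny_config(n_rsvp_trials = 60, n_subjects = 2, rng_seed = 5)
  m <- selection_model("gradual")
  ds1 <- simulate_dataset(cfg, m)
  ds2 <- simulate_dataset(cfg, m)
  expect_identical(ds1$subjects[[2]]$rsvp$data, ds2$subjects[[2]]$rsvp$data)
  expect_identical(ds1$subjects[[1]]$info, ds2$subjects[[1]]$info)
  expect_equal(as.integer(table(ds1$subjects[[1]]$info$lag)), rep(15L, 4))
  # target position equals the lag
  expect_true(all(ds1$subjects[[1]]$info$target_pos ==
                    ds1$subjects[[1]]$info$lag))
  # guesses pairwise distinct
  gg <- ds1$subjects[[1]]$info[, c("guess1", "guess2", "guess3")]
  expect_true(all(apply(gg, 1, function(r) length(unique(r)) == 3)))
})

test_that("projection onto a topography recovers gain times kernel", {
  # one category per stage, no noise: projecting x(t) onto a_{c,s}
  # recovers g_s k_s(t - onset) exactly
  cfg <- tiny_config(noise_sd = 0)
  pr <- tiny_primitives()
  m <- selection_model("discrete", guess_floor = 0)
  set.seed(2)
  tr <- simulate_rsvp_trial(cfg, pr$patterns, pr$kernels, m, lag = 7)
  onsets <- stream_onsets(cfg)
  # position 3 is a pure distractor here unless reported; project on its
  # early topography and subtract every other stimulus's contribution
  i <- 3
  cc <- tr$info[[paste0("cat_pos", i)]]
  a <- pattern_of(pr$patterns, cc, "early")
  proj <- drop(crossprod(a, tr$data))
  gains <- selection_gains(m, tr$info$target_pos, tr$info$lag,
                           unlist(tr$info[c("guess1", "guess2", "guess3")]))
  gains <- sweep(gains, 2, cfg$stage_amplitudes[colnames(gains)], "*")
  other <- matrix(0, cfg$n_sensors, length(tr$times))
  for (j in setdiff(1:12, i)) {
    other <- other + stim_template(pr$patterns, pr$kernels,
                                   tr$info[[paste0("cat_pos", j)]],
                                   tr$times - onsets[j],
                                   as.list(gains[j, ]))
  }
  own_mid <- gains[i, "mid"] *
    outer(pattern_of(pr$patterns, cc, "mid"),
          eval_kernel(pr$kernels, "mid", tr$times - onsets[i]))
  own_late <- gains[i, "late"] *
    outer(pattern_of(pr$patterns, cc, "late"),
          eval_kernel(pr$kernels, "late", tr$times - onsets[i]))
  resid <- proj - drop(crossprod(a, other + own_mid + own_late))
  expect_equal(resid,
               gains[i, "early"] *
                 eval_kernel(pr$kernels, "early", tr$times - onsets[i]),
               tolerance = 1e-10)
})

test_that("behavioral guess distribution matches the stated model", {
  m <- selection_model("gradual")
  set.seed(6)
  n <- 10000
  g1 <- replicate(n, simulate_behavior(m, 7, lag = 9)[1])
  w <- report_weights(m, 7, 9)
  tv <- 0.5 * sum(abs(tabulate(g1, 12) / n - w))
  expect_lt(tv, 0.02)
})
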