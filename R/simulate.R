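#' Simulation configuration
#'
#' Bundles the constants of the simulated experiment. Defaults reproduce the
#' reference study design: a 13-stimulus stream at SOA 116 ms (8.6 Hz,
#' stimulus duration 84 ms), a color T1 at position 0 followed by 12
#' category images, a cued target T2 at lag 1, 3, 7 or 9, 300 localizer and
#' 300 RSVP trials per subject, 15 subjects, and signals sampled at 100 Hz.
#'
#' @param n_sensors number of sensors (homogeneous synthetic sensor set).
#' @param sfreq sampling frequency, Hz.
#' @param soa_ms stimulus onset asynchrony, ms. Stimulus onsets `i * soa_ms`
#'   are rounded to the nearest sample of the `sfreq` grid; the rounded
#'   onsets are what every downstream step uses.
#' @param stim_duration_ms nominal stimulus duration, ms (metadata only; the
#'   response envelopes, not the stimulus, carry the dynamics).
#' @param n_stream number of stimuli per RSVP trial including T1.
#' @param lags possible inter-target lags (T2 position relative to T1).
#' @param n_localizer_trials localizer trials per subject (balanced over the
#'   4 categories; rounded to the nearest balanced count if needed).
#' @param n_rsvp_trials RSVP trials per subject (balanced over lags).
#' @param noise_sd sd of the i.i.d. Gaussian sensor noise, in units of a
#'   unit-norm topography peak.
#' @param stage_amplitudes named peak amplitudes of the response stages
#'   relative to the early transient; later stages are weaker, mirroring the
#'   decline of decodability beyond ~300 ms in evoked responses.
#' @param ar1_phi optional AR(1) coefficient for temporally correlated noise
#'   (0 = white, the default).
#' @param n_subjects number of simulated subjects.
#' @param rng_seed master seed; one seed reproduces the whole dataset.
#' @param max_cosine topography quasi-orthogonality bound.
#' @param stage_windows stage timing windows passed to
#'   [make_response_kernels()].
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_sensors = 102, sfreq = 100, soa_ms = 116,
                       stim_duration_ms = 84, n_stream = 13,
                       lags = c(1, 3, 7, 9), n_localizer_trials = 300,
                       n_rsvp_trials = 300, noise_sd = 1.5, ar1_phi = 0,
                       n_subjects = 15, rng_seed = 1, max_cosine = 0.3,
                       stage_windows = default_stage_windows(),
                       stage_amplitudes = c(early = 1, mid = 0.7,
                                            late = 0.5, sustain = 0.8)) {
  stopifnot(n_sensors >= 2, sfreq > 0, soa_ms > 0, n_stream >= 2,
            all(lags >= 1), noise_sd >= 0, abs(ar1_phi) < 1,
            n_subjects >= 1, all(stage_amplitudes >= 0))
  structure(list(n_sensors = n_sensors, sfreq = sfreq, soa_ms = soa_ms,
                 stim_duration_ms = stim_duration_ms, n_stream = n_stream,
                 lags = lags, n_localizer_trials = n_localizer_trials,
                 n_rsvp_trials = n_rsvp_trials, noise_sd = noise_sd,
                 ar1_phi = ar1_phi, n_subjects = n_subjects,
                 rng_seed = rng_seed, max_cosine = max_cosine,
                 stage_windows = stage_windows,
                 stage_amplitudes = stage_amplitudes),
            class = "sim_config")
}

#' Rounded stimulus onsets of the stream
#'
#' Onset of stream position `i` (T1 = position 0) is `i * soa_ms` rounded to
#' the nearest sample of the acquisition grid.
#'
#' @param config a `sim_config`.
#' @param positions stream positions (default 1..12, the category images).
#' @return named numeric vector of onsets in ms.
#' @export
stream_onsets <- function(config, positions = seq_len(config$n_stream - 1L)) {
  dt <- 1000 / config$sfreq
  on <- round(positions * config$soa_ms / dt) * dt
  names(on) <- positions
  on
}

sensor_noise <- function(n_sensors, n_times, noise_sd, ar1_phi = 0) {
  e <- matrix(rnorm(n_sensors * n_times, sd = noise_sd), n_sensors, n_times)
  if (ar1_phi != 0) {
    scale <- sqrt(1 - ar1_phi^2)   # keep marginal sd = noise_sd
    for (t in 2:n_times) e[, t] <- ar1_phi * e[, t - 1] + scale * e[, t]
  }
  e
}

# sensors x time noise-free template for one stimulus with stage gains
stim_template <- function(patterns, kernels, category, tau, gains) {
  out <- matrix(0, patterns$n_sensors, length(tau))
  for (stage in names(kernels$stage_windows)) {
    g <- gains[[stage]]
    if (g == 0) next
    topo_stage <- if (stage == "sustain") "early" else stage
    k <- eval_kernel(kernels, stage, tau)
    if (any(k != 0))
      out <- out + g * outer(pattern_of(patterns, category, topo_stage), k)
  }
  out
}

#' Simulate a localizer session
#'
#' One stimulus per trial, all four response stages at unit gain (a single
#' attended stimulus also carries the sustained prolongation of its early
#' response). Epochs span -50..550 ms around stimulus onset. Labels are
#' balanced across the four categories and shuffled.
#'
#' @param config a `sim_config`.
#' @param patterns a `category_patterns` set.
#' @param kernels a `response_kernels` set.
#' @return an [epochs] object; `info(ep)$category` holds the labels.
#' @export
simulate_localizer <- function(config, patterns, kernels) {
  n <- config$n_localizer_trials
  k <- length(patterns$categories)
  n_bal <- max(k, round(n / k) * k)
  if (n_bal != n)
    warning("n_localizer_trials = ", n, " not divisible by ", k,
            "; using nearest balanced count ", n_bal)
  times <- seq(-50, 550, by = 1000 / config$sfreq)
  labels <- sample(rep(patterns$categories, n_bal / k))
  amp <- config$stage_amplitudes
  templates <- lapply(patterns$categories, function(cc)
    stim_template(patterns, kernels, cc, times, as.list(amp)))
  names(templates) <- patterns$categories
  dat <- array(0, c(n_bal, config$n_sensors, length(times)))
  for (i in seq_len(n_bal)) {
    x <- templates[[labels[i]]]
    if (config$noise_sd > 0)
      x <- x + sensor_noise(config$n_sensors, length(times),
                            config$noise_sd, config$ar1_phi)
    dat[i, , ] <- x
  }
  epochs(dat, times, config$sfreq,
         info = data.frame(trial = seq_len(n_bal), category = labels,
                           stringsAsFactors = FALSE))
}

#' Simulate the behavioral guesses of one trial
#'
#' Three distinct stream positions are drawn without replacement from a
#' report distribution over positions 1..12: a discretized Gaussian centered
#' on the target mixed with a uniform guessing floor in the gradual model, or
#' a target point mass mixed with the floor in the discrete model. Shorter
#' lags raise the effective floor via the model's `lag_modulation`.
#'
#' @param model a `selection_model`.
#' @param target_position target stream position (1..12).
#' @param lag inter-target lag (`NULL` for no lag modulation).
#' @param n_positions number of stream positions (12).
#' @param n_guesses number of guesses (3).
#' @return integer vector of distinct reported positions, by preference.
#' @export
simulate_behavior <- function(model, target_position, lag = NULL,
                              n_positions = 12L, n_guesses = 3L) {
  stopifnot(target_position >= 1, target_position <= n_positions)
  w <- report_weights(model, target_position, lag, n_positions)
  g <- integer(n_guesses)
  avail <- rep(TRUE, n_positions)
  for (k in seq_len(n_guesses)) {
    p <- w * avail
    if (sum(p) <= 0) p <- as.numeric(avail)  # point mass exhausted: uniform
    g[k] <- sample.int(n_positions, 1L, prob = p / sum(p))
    avail[g[k]] <- FALSE
  }
  g
}

# report distribution over positions (before without-replacement truncation)
report_weights <- function(model, target_position, lag = NULL,
                           n_positions = 12L) {
  floor_eff <- 1 - (1 - model$guess_floor) *
    (if (is.null(lag)) 1 else lag_mod(model, lag))
  pos <- seq_len(n_positions)
  core <- if (model$mode == "gradual" && model$behavior_sigma > 1e-8) {
    d <- exp(-(pos - target_position)^2 / (2 * model$behavior_sigma^2))
    d / sum(d)
  } else {
    as.numeric(pos == target_position)
  }
  (1 - floor_eff) * core + floor_eff / n_positions
}

#' Simulate one RSVP trial
#'
#' The sensor signal is the linear superposition of the per-stimulus
#' responses: `x(t) = sum_i sum_s g_{i,s} a_{c_i,s} k_s(t - onset_i)` plus
#' Gaussian noise. T1 (position 0) contributes no category signal and serves
#' only as the timing anchor. Behavior is sampled first; in the discrete
#' model the late-stage gains are then conditioned on the sampled guesses.
#'
#' @param config a `sim_config`.
#' @param patterns,kernels simulation primitives.
#' @param model a `selection_model`.
#' @param lag inter-target lag; must be one of `config$lags`.
#' @param categories optional integer/character vector of categories at
#'   positions 1..12 (random if `NULL`).
#' @return list with `data` (sensors x time matrix), `times` (ms, T1 onset at
#'   0), and `info` (one-row data.frame: lag, target_pos, guesses,
#'   categories per position).
#' @export
simulate_rsvp_trial <- function(config, patterns, kernels, model, lag,
                                categories = NULL) {
  if (!lag %in% config$lags) stop("lag must be one of config$lags")
  n_img <- config$n_stream - 1L
  dt <- 1000 / config$sfreq
  times <- seq(-200, 2300, by = dt)
  onsets <- stream_onsets(config)
  if (is.null(categories))
    categories <- sample(patterns$categories, n_img, replace = TRUE)
  target <- lag
  guesses <- simulate_behavior(model, target, lag, n_positions = n_img)
  gmat <- selection_gains(model, target, lag, guesses, n_img)
  gmat <- sweep(gmat, 2, config$stage_amplitudes[colnames(gmat)], "*")
  x <- matrix(0, config$n_sensors, length(times))
  for (i in seq_len(n_img)) {
    x <- x + stim_template(patterns, kernels, categories[i],
                           times - onsets[i], as.list(gmat[i, ]))
  }
  if (config$noise_sd > 0)
    x <- x + sensor_noise(config$n_sensors, length(times), config$noise_sd,
                          config$ar1_phi)
  info <- data.frame(lag = lag, target_pos = target,
                     guess1 = guesses[1], guess2 = guesses[2],
                     guess3 = guesses[3], stringsAsFactors = FALSE)
  info[paste0("cat_pos", seq_len(n_img))] <- as.list(categories)
  list(data = x, times = times, info = info)
}

#' Simulate a full multi-subject dataset
#'
#' Generates, per subject, a localizer session, an RSVP session with lags
#' balanced across trials, and the trial metadata table. Category
#' topographies are drawn independently per subject (real subjects differ
#' in head geometry, so pattern geometry must not act as a dataset-level
#' random effect); kernels are shared. The entire dataset is a
#' deterministic function of `config$rng_seed`.
#'
#' @param config a `sim_config`.
#' @param model a `selection_model`.
#' @return an object of class `sim_dataset`: list with `patterns` (one
#'   `category_patterns` set per subject), `kernels`, `config`, `model`,
#'   and `subjects` (per subject: `localizer` epochs, `rsvp` epochs of
#'   full stream trials, `info` TrialInfo data.frame).
#' @export
simulate_dataset <- function(config, model) {
  with_seed(config$rng_seed, {
    kernels <- make_response_kernels(config$stage_windows, config$sfreq)
    n_lag <- length(config$lags)
    n_bal <- max(n_lag, round(config$n_rsvp_trials / n_lag) * n_lag)
    if (n_bal != config$n_rsvp_trials)
      warning("n_rsvp_trials rounded to nearest lag-balanced count ", n_bal)
    pattern_seeds <- sample.int(2^30, config$n_subjects)
    all_patterns <- lapply(pattern_seeds, function(ps)
      make_category_patterns(config$n_sensors, rng_seed = ps,
                             max_cosine = config$max_cosine))
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      patterns <- all_patterns[[s]]
      loc <- simulate_localizer(config, patterns, kernels)
      lag_seq <- sample(rep(config$lags, n_bal / n_lag))
      trials <- lapply(lag_seq, function(lg)
        simulate_rsvp_trial(config, patterns, kernels, model, lg))
      dat <- array(0, c(n_bal, config$n_sensors, length(trials[[1]]$times)))
      for (i in seq_len(n_bal)) dat[i, , ] <- trials[[i]]$data
      info <- do.call(rbind, lapply(trials, `[[`, "info"))
      info <- cbind(subject = s, trial = seq_len(n_bal), info)
      rsvp <- epochs(dat, trials[[1]]$times, config$sfreq, info = info)
      attr(rsvp, "onsets") <- stream_onsets(config)
      loc$info$subject <- s
      list(localizer = loc, rsvp = rsvp, info = info)
    })
    structure(list(patterns = all_patterns, kernels = kernels,
                   config = config, model = model, subjects = subjects),
              class = "sim_dataset")
  })
}
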