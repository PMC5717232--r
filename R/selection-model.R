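#' Attentional selection model for the RSVP stream
#'
#' Parameterizes how attention modulates the per-stimulus response stages.
#' Two hypotheses are implemented in pure form:
#'
#' * `gradual`: attention simultaneously amplifies several stimuli around the
#'   target. The early-stage response of stimulus at stream position `i`
#'   acquires a sustained prolongation (the `sustain` envelope, sharing the
#'   early-stage topography) whose gain follows an asymmetric Gaussian profile
#'   of the positional distance to the target,
#'   `g_i = amplitude * exp(-d^2 / (2 * sigma_side^2))` with
#'   `sigma_left = gradual_sigma * gradual_asymmetry` for stimuli preceding
#'   the target and `sigma_right = gradual_sigma` for stimuli following it.
#'   No stimulus receives the late stage.
#' * `discrete`: attention is all-or-none. Only the stimuli the subject
#'   eventually reports receive the late processing stage (350-720 ms), with
#'   gain `discrete_gain * guess_gains[k]` for the stimulus reported as guess
#'   `k`; every non-reported stimulus has late-stage gain exactly 0, and no
#'   stimulus receives the sustain prolongation.
#'
#' `lag_modulation` scales all attentional gains (and degrades behavioral
#' precision) per inter-target lag, emulating the attentional blink.
#'
#' @param mode `"gradual"` or `"discrete"`.
#' @param gradual_sigma width (in stream positions) of the gain profile on
#'   the post-target side.
#' @param gradual_amplitude peak gain multiplier at the target position.
#' @param gradual_asymmetry ratio of pre-target to post-target widths
#'   (> 1 means stimuli preceding the target are enhanced more).
#' @param discrete_gain gain applied to the late-stage envelope of reported
#'   stimuli (scaled further by `guess_gains`).
#' @param guess_gains length-3 multipliers for guesses 1..3.
#' @param lag_modulation named per-lag multiplier on attentional gains.
#' @param behavior_sigma width (positions) of the report distribution.
#' @param guess_floor baseline probability mass spread uniformly over all 12
#'   positions (pure-guessing floor) at the least demanding lag.
#' @return an object of class `selection_model`.
#' @examples
#' selection_model("gradual")
#' selection_model("discrete", guess_gains = c(1, 0.5, 0.25))
#' @export
selection_model <- function(mode = c("gradual", "discrete"),
                            gradual_sigma = 0.4,
                            gradual_amplitude = 1,
                            gradual_asymmetry = 3.5,
                            discrete_gain = 1,
                            guess_gains = c(1, 0.6, 0.35),
                            lag_modulation = c("1" = 0.8, "3" = 0.5,
                                               "7" = 0.9, "9" = 1),
                            behavior_sigma = 1.2,
                            guess_floor = 0.15) {
  mode <- match.arg(mode)
  stopifnot(gradual_sigma >= 0, gradual_amplitude >= 0, discrete_gain >= 0,
            all(guess_gains >= 0), length(guess_gains) == 3L,
            all(lag_modulation >= 0), guess_floor >= 0, guess_floor <= 1)
  structure(list(mode = mode, gradual_sigma = gradual_sigma,
                 gradual_amplitude = gradual_amplitude,
                 gradual_asymmetry = gradual_asymmetry,
                 discrete_gain = discrete_gain, guess_gains = guess_gains,
                 lag_modulation = lag_modulation,
                 behavior_sigma = behavior_sigma, guess_floor = guess_floor),
            class = "selection_model")
}

#' Gradual-selection gain profile over stream positions
#'
#' Ground-truth attentional gain for each stream position given the target
#' position, before lag modulation.
#'
#' @param model a `selection_model` (mode `"gradual"`).
#' @param target_position target stream position (1..12).
#' @param positions positions at which to evaluate (default 1..12).
#' @return numeric vector of gains.
#' @export
gradual_gain_profile <- function(model, target_position,
                                 positions = 1:12) {
  d <- positions - target_position
  sig <- ifelse(d < 0, model$gradual_sigma * model$gradual_asymmetry,
                model$gradual_sigma)
  g <- ifelse(sig <= 0, as.numeric(d == 0),
              exp(-d^2 / (2 * pmax(sig, 1e-12)^2)))
  model$gradual_amplitude * g
}

# per-trial stage gains: positions 1..12 x stages (early, mid, late, sustain)
selection_gains <- function(model, target_position, lag, guesses,
                            n_positions = 12L) {
  lm <- lag_mod(model, lag)
  g <- matrix(0, n_positions, 4,
              dimnames = list(NULL, c("early", "mid", "late", "sustain")))
  g[, "early"] <- 1
  g[, "mid"] <- 1
  if (model$mode == "gradual") {
    g[, "sustain"] <- lm * gradual_gain_profile(model, target_position,
                                                seq_len(n_positions))
  } else {
    for (k in seq_along(guesses))
      g[guesses[k], "late"] <- lm * model$discrete_gain * model$guess_gains[k]
  }
  g
}

lag_mod <- function(model, lag) {
  m <- model$lag_modulation[as.character(lag)]
  if (is.na(m)) 1 else unname(m)
}
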