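guess_chance <- function(guess_index, n_positions = 12L,
                         convention = c("without_replacement", "flat")) {
  convention <- match.arg(convention)
  if (convention == "flat") return(1 / n_positions)
  1 / (n_positions - guess_index + 1L)
}

#' Empirical report distribution per guess and lag
#'
#' Per-subject proportions of trials on which each stream position was
#' reported as guess `guess_index`, at a given inter-target lag, together
#' with the chance level. Under uniform without-replacement guessing, chance
#' for guess k over 12 positions is `1/(12 - k + 1)` (1/12, 1/11, 1/10); the
#' flat `1/12` convention is available via `chance_convention`.
#'
#' @param info TrialInfo data.frame (columns `subject`, `lag`,
#'   `guess1..guess3`).
#' @param lag inter-target lag to select.
#' @param guess_index which guess (1, 2 or 3).
#' @param n_positions number of stream positions.
#' @param chance_convention `"without_replacement"` (default) or `"flat"`.
#' @return data.frame (subject, lag, guess, position, proportion, chance);
#'   proportions sum to 1 over positions within subject.
#' @export
report_distribution <- function(info, lag, guess_index, n_positions = 12L,
                                chance_convention = "without_replacement") {
  sel <- info[info$lag == lag, , drop = FALSE]
  if (!nrow(sel)) stop("no trials at lag ", lag)
  g <- sel[[paste0("guess", guess_index)]]
  ch <- guess_chance(guess_index, n_positions, chance_convention)
  out <- lapply(unique(sel$subject), function(s) {
    gi <- g[sel$subject == s]
    prop <- tabulate(gi, nbins = n_positions) / length(gi)
    data.frame(subject = s, lag = lag, guess = guess_index,
               position = seq_len(n_positions), proportion = prop,
               chance = ch)
  })
  do.call(rbind, out)
}

#' Mode and variance of a report distribution
#'
#' Mode is the position of maximum proportion (ties resolved to the earliest
#' position, with a message); variance uses positions as an integer scale:
#' `sum p_i (i - mu)^2` with `mu = sum p_i i`.
#'
#' @param p numeric vector of proportions over positions 1..length(p).
#' @return named numeric `c(mode, variance)`.
#' @export
distribution_mode_variance <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  pos <- seq_along(p)
  mx <- which(p == max(p))
  if (length(mx) > 1L) message("tied mode; earliest position reported")
  mu <- sum(p * pos)
  c(mode = pos[mx[1]], variance = sum(p * (pos - mu)^2))
}

#' Distribution of later guesses conditioned on Guess 1
#'
#' Restricts trials to those where Guess 1 fell at a given offset from the
#' target, then computes the distribution of guess 2 (or 3) over the
#' remaining positions: the conditioned position is removed from the support
#' and proportions are renormalized over the rest.
#'
#' @param info TrialInfo data.frame.
#' @param guess1_offset offset of Guess 1 relative to the target (e.g. -1
#'   for T-1, +1 for T+1, 0 for the target itself).
#' @param lag inter-target lag to select.
#' @param guess_index which later guess to analyze (2 or 3).
#' @param n_positions number of stream positions.
#' @return data.frame (subject, lag, guess, position, proportion) with `NA`
#'   proportion at the conditioned position; empty cells are flagged with an
#'   error.
#' @export
conditional_distribution <- function(info, guess1_offset, lag,
                                     guess_index = 2L, n_positions = 12L) {
  stopifnot(guess_index %in% 2:3)
  sel <- info[info$lag == lag &
                info$guess1 == info$target_pos + guess1_offset, ,
              drop = FALSE]
  if (!nrow(sel)) stop("no trials with Guess 1 at offset ", guess1_offset,
                       " for lag ", lag)
  cond_pos <- unique(sel$target_pos + guess1_offset)
  g <- sel[[paste0("guess", guess_index)]]
  out <- lapply(unique(sel$subject), function(s) {
    gi <- g[sel$subject == s]
    prop <- tabulate(gi, nbins = n_positions)
    prop[cond_pos] <- NA              # removed from the support
    prop <- prop / sum(prop, na.rm = TRUE)
    data.frame(subject = s, lag = lag, guess = guess_index,
               position = seq_len(n_positions), proportion = prop)
  })
  do.call(rbind, out)
}

#' Report accuracy (attentional blink curve)
#'
#' Per subject and lag, the fraction of trials on which any of the three
#' guesses matched the target. A uniform without-replacement guesser scores
#' `1 - (11/12)(10/11)(9/10) = 1/4` in expectation.
#'
#' @param info TrialInfo data.frame.
#' @return data.frame (subject, lag, accuracy).
#' @export
blink_accuracy <- function(info) {
  hit <- with(info, target_pos == guess1 | target_pos == guess2 |
                target_pos == guess3)
  agg <- aggregate(hit, by = list(subject = info$subject, lag = info$lag),
                   FUN = mean)
  names(agg)[3] <- "accuracy"
  agg[order(agg$subject, agg$lag), ]
}
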