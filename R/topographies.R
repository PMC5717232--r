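CATEGORIES <- c("face", "place", "body", "object")
STAGES <- c("early", "mid", "late")

#' Draw quasi-orthogonal category sensor topographies
#'
#' Generates one unit-norm sensor topography per (category, stage) pair.
#' Topographies stand in for the category-specific field maps a real
#' experiment would measure; they are drawn from an isotropic Gaussian and
#' accepted only if the absolute cosine similarity with every previously
#' accepted topography stays below `max_cosine`, so that every stage of every
#' category occupies a distinct direction of sensor space.
#'
#' @param n_sensors number of sensors; must be at least twice the number of
#'   (category, stage) pairs so the cosine bound is attainable.
#' @param rng_seed integer seed; the same seed always yields the same set.
#' @param max_cosine upper bound on pairwise |cosine similarity|
#'   (default 0.3).
#' @param categories,stages names of the categories and response stages.
#' @return an object of class `category_patterns`: a list with `patterns`
#'   (matrix n_sensors x (categories*stages), columns named
#'   `<category>.<stage>`), `categories`, `stages`, `n_sensors`,
#'   `max_cosine`.
#' @examples
#' ps <- make_category_patterns(100, rng_seed = 1)
#' round(crossprod(ps$patterns)[1:3, 1:3], 2)
#' @export
make_category_patterns <- function(n_sensors, rng_seed = 1, max_cosine = 0.3,
                                   categories = CATEGORIES, stages = STAGES) {
  n_pat <- length(categories) * length(stages)
  if (n_sensors < 2L * n_pat)
    stop("n_sensors must be >= ", 2L * n_pat, " (2 x number of patterns)")
  pats <- with_seed(rng_seed, {
    out <- matrix(NA_real_, n_sensors, n_pat)
    for (k in seq_len(n_pat)) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        v <- rnorm(n_sensors)
        v <- v / sqrt(sum(v^2))
        if (k == 1L || all(abs(crossprod(out[, seq_len(k - 1L), drop = FALSE],
                                         v)) < max_cosine)) {
          out[, k] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not satisfy max_cosine = ", max_cosine, " in 1000 ",
             "attempts; increase n_sensors or relax the bound")
    }
    out
  })
  colnames(pats) <- paste(rep(categories, each = length(stages)),
                          rep(stages, length(categories)), sep = ".")
  structure(list(patterns = pats, categories = categories, stages = stages,
                 n_sensors = n_sensors, max_cosine = max_cosine),
            class = "category_patterns")
}

#' Look up the topography of one (category, stage) pair
#' @param x a `category_patterns` object.
#' @param category,stage names of the pair.
#' @return unit-norm numeric vector of length `n_sensors`.
#' @export
pattern_of <- function(x, category, stage) {
  stopifnot(inherits(x, "category_patterns"))
  x$patterns[, paste(category, stage, sep = ".")]
}

default_stage_windows <- function() {
  list(early = c(90, 230), mid = c(220, 330), late = c(350, 720),
       sustain = c(440, 720))
}

#' Build smooth response-stage time envelopes
#'
#' Each processing stage of the evoked response is modelled as a smooth,
#' non-negative envelope with peak amplitude 1 and compact support
#' `[onset - 50, offset + 50]` ms. Transient stages (`early`, `mid`) are
#' raised-cosine bumps peaking at the window midpoint; sustained stages
#' (`late`, `sustain`) are plateaus with 100-ms raised-cosine ramps. The
#' `sustain` envelope is the optional attention-dependent prolongation of the
#' early-stage response (it reuses the early-stage topography when simulated).
#'
#' @param stage_windows named list of `(onset_ms, offset_ms)` windows;
#'   defaults to early (90, 230), mid (220, 330), late (350, 720) and
#'   sustain (440, 720).
#' @param sfreq sampling frequency in Hz used for the sampled representation.
#' @return an object of class `response_kernels`: list with `stage_windows`,
#'   `sfreq`, `tau` (sample grid 0..900 ms) and `sampled` (matrix
#'   length(tau) x stages).
#' @examples
#' ks <- make_response_kernels()
#' ks$tau[which.max(ks$sampled[, "early"])]  # peak at the window midpoint
#' @export
make_response_kernels <- function(stage_windows = default_stage_windows(),
                                  sfreq = 100) {
  for (nm in names(stage_windows)) {
    w <- stage_windows[[nm]]
    if (length(w) != 2L || w[2] <= w[1])
      stop("stage window '", nm, "' must satisfy onset < offset")
    if (w[1] < 0 || w[2] > 900)
      stop("stage window '", nm, "' must lie within [0, 900] ms")
  }
  tau <- seq(0, 900, by = 1000 / sfreq)
  shapes <- vapply(names(stage_windows), function(nm) {
    kernel_eval(stage_windows[[nm]], tau,
                sustained = nm %in% c("late", "sustain"))
  }, numeric(length(tau)))
  structure(list(stage_windows = stage_windows, sfreq = sfreq, tau = tau,
                 sampled = shapes), class = "response_kernels")
}

# closed-form envelope; skirt = 50 ms on each side of the stage window
kernel_eval <- function(window, tau, sustained = FALSE, skirt = 50) {
  a <- window[1] - skirt
  b <- window[2] + skirt
  k <- numeric(length(tau))
  inside <- tau >= a & tau <= b
  if (!sustained) {
    k[inside] <- 0.5 * (1 - cos(2 * pi * (tau[inside] - a) / (b - a)))
  } else {
    ramp <- 2 * skirt
    up <- inside & tau < a + ramp
    dn <- inside & tau > b - ramp
    flat <- inside & !up & !dn
    k[up] <- 0.5 * (1 - cos(pi * (tau[up] - a) / ramp))
    k[dn] <- 0.5 * (1 - cos(pi * (b - tau[dn]) / ramp))
    k[flat] <- 1
  }
  k
}

#' Evaluate a stage envelope at arbitrary post-onset lags
#' @param kernels a `response_kernels` object.
#' @param stage stage name.
#' @param tau numeric vector of post-onset lags in ms.
#' @return numeric vector of envelope values.
#' @export
eval_kernel <- function(kernels, stage, tau) {
  stopifnot(inherits(kernels, "response_kernels"))
  kernel_eval(kernels$stage_windows[[stage]], tau,
              sustained = stage %in% c("late", "sustain"))
}
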