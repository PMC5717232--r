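#' Epoched multi-sensor time series
#'
#' The universal container of the package: a trials x sensors x time array
#' with a uniform time axis (ms) and optional per-trial metadata.
#'
#' @param data numeric array, trials x sensors x time; must be finite.
#' @param times numeric vector of sample times in ms, strictly increasing
#'   with uniform spacing `1000 / sfreq`.
#' @param sfreq sampling frequency, Hz.
#' @param info optional data.frame of per-trial metadata (one row per trial).
#' @return an object of class `epochs`.
#' @export
epochs <- function(data, times, sfreq, info = NULL) {
  if (length(dim(data)) != 3L) stop("data must be trials x sensors x time")
  if (dim(data)[3] != length(times))
    stop("length(times) must match dim(data)[3]")
  if (!all(is.finite(data))) stop("data must be finite everywhere")
  dt <- 1000 / sfreq
  if (length(times) > 1L &&
      max(abs(diff(times) - dt)) > 1e-6 * dt)
    stop("times must be uniformly spaced at 1000/sfreq")
  if (!is.null(info) && nrow(info) != dim(data)[1])
    stop("info must have one row per trial")
  structure(list(data = data, times = times, sfreq = sfreq, info = info),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d trials x %d sensors x %d samples, %g-%g ms @ %g Hz\n",
              d[1], d[2], d[3], min(x$times), max(x$times), x$sfreq))
  invisible(x)
}

#' @export
dim.epochs <- function(x) dim(x$data)

#' Number of trials in an epochs object
#' @param ep an `epochs` object.
#' @return integer count.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' Subset trials of an epochs object (data and metadata together)
#' @param ep an `epochs` object.
#' @param idx trial indices or logical mask.
#' @return an `epochs` object.
#' @export
subset_trials <- function(ep, idx) {
  epochs(ep$data[idx, , , drop = FALSE], ep$times, ep$sfreq,
         info = if (is.null(ep$info)) NULL else ep$info[idx, , drop = FALSE])
}

#' Baseline-correct each trial and sensor
#'
#' Subtracts, per trial and sensor, the mean over a pre-onset window
#' (closed-open `[t0, t1)`).
#'
#' @param ep an `epochs` object.
#' @param window baseline window in ms; must end at or before 0. Default:
#'   everything before stimulus onset.
#' @return a baseline-corrected `epochs` object.
#' @export
baseline_correct <- function(ep, window = c(min(ep$times), 0)) {
  stopifnot(inherits(ep, "epochs"))
  if (window[2] > 0) stop("baseline window must end at or before 0 ms")
  idx <- window_index(ep$times, window)
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim(ep$data))
  ep
}

#' Low-pass filter and decimate epochs
#'
#' Applies a zero-phase FIR anti-alias low-pass (via [signal::filtfilt()])
#' then keeps every `sfreq / target_sfreq`-th sample. The default cutoff is
#' 30 Hz when down-sampling to 100 Hz (0.6 x the target Nyquist).
#'
#' @param ep an `epochs` object.
#' @param target_sfreq new sampling frequency; must divide `ep$sfreq`.
#' @param cutoff_hz low-pass cutoff in Hz (default `0.3 * target_sfreq`).
#' @param order FIR order (default 64, reduced if epochs are short).
#' @return a decimated `epochs` object.
#' @export
downsample <- function(ep, target_sfreq, cutoff_hz = 0.3 * target_sfreq,
                       order = 64) {
  stopifnot(inherits(ep, "epochs"))
  r <- ep$sfreq / target_sfreq
  if (abs(r - round(r)) > 1e-9) stop("target_sfreq must divide sfreq")
  r <- as.integer(round(r))
  if (r == 1L) return(ep)
  n_t <- dim(ep$data)[3]
  order <- min(order, (n_t - 1) %/% 3 - 1)
  flt <- as.numeric(signal::fir1(order, cutoff_hz / (ep$sfreq / 2)))
  flt <- flt / sum(flt)                     # exact unit DC gain
  d <- dim(ep$data)
  flat <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = n_t)  # time x (trial*sensor)
  pad <- min(order, n_t - 1L)               # reflect edges to tame transients
  flat <- apply(flat, 2, function(v) {
    vp <- c(rev(v[2:(pad + 1L)]), v, rev(v[(n_t - pad):(n_t - 1L)]))
    signal::filtfilt(flt, 1, vp)[(pad + 1L):(pad + n_t)]
  })
  keep <- seq(1L, n_t, by = r)
  out <- aperm(array(flat[keep, ], c(length(keep), d[1], d[2])), c(2, 3, 1))
  epochs(out, ep$times[keep], target_sfreq, info = ep$info)
}

#' Re-epoch stream trials around each stimulus onset
#'
#' Cuts, for each requested stream position, a per-stimulus epoch with time
#' zero at that stimulus's (rounded) onset, using the closed-open window
#' convention. Each per-stimulus epochs object inherits the trial metadata
#' plus a `category` column for that position, so downstream decoding treats
#' it like a localizer epoch.
#'
#' @param ep stream `epochs` (time zero = T1 onset); needs either an
#'   `onsets` attribute or an explicit `onsets` vector.
#' @param onsets named vector of stimulus onsets in ms (names = positions).
#' @param window per-stimulus window `[t0, t1)` in ms, default `c(0, 900)`.
#' @param positions which stream positions to cut (default all).
#' @return named list of `epochs`, one per position (`"pos<k>"`). Positions
#'   whose window exceeds the recorded trial span are dropped with a warning.
#' @export
epoch_stream <- function(ep, onsets = attr(ep, "onsets"),
                         window = c(0, 900), positions = NULL) {
  stopifnot(inherits(ep, "epochs"))
  if (is.null(onsets)) stop("stimulus onsets are required")
  if (is.null(positions)) positions <- as.integer(names(onsets))
  dt <- 1000 / ep$sfreq
  out <- list()
  for (p in positions) {
    on <- onsets[[as.character(p)]]
    lo <- on + window[1]
    hi <- on + window[2]
    if (lo < min(ep$times) - 1e-9 || hi - dt > max(ep$times) + 1e-9) {
      warning("position ", p, ": window exceeds trial span; epoch dropped")
      next
    }
    idx <- which(ep$times >= lo - 1e-9 & ep$times < hi - 1e-9)
    info <- ep$info
    if (!is.null(info)) {
      catcol <- paste0("cat_pos", p)
      if (catcol %in% names(info)) info$category <- info[[catcol]]
      info$position <- p
    }
    sub <- epochs(ep$data[, , idx, drop = FALSE],
                  ep$times[idx] - on, ep$sfreq, info = info)
    attr(sub, "position") <- p
    out[[paste0("pos", p)]] <- sub
  }
  out
}

#' Centered moving average for display
#'
#' Smooths a timecourse with a centered moving average; edges use truncated
#' windows so the length is preserved. For presentation of exported
#' timecourses only — statistics are always computed on unsmoothed data.
#'
#' @param x numeric vector, or matrix (smoothed along columns).
#' @param window odd window length in samples (default 3).
#' @return smoothed object of the same shape.
#' @export
moving_average <- function(x, window = 3L) {
  if (window %% 2L != 1L) stop("window must be odd")
  if (is.matrix(x)) return(apply(x, 2, moving_average, window = window))
  n <- length(x)
  if (window > n) stop("window longer than series")
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}
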