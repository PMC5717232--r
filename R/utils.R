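#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# nearest index on a time grid
time_index <- function(times, t) which.min(abs(times - t))

# closed-open [t0, t1) sample selection on a time grid
window_index <- function(times, window) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be (t0, t1) with t1 > t0")
  idx <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  if (!length(idx)) stop("empty window: no samples in [", window[1], ", ",
                         window[2], ")")
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
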