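# independent statistical oracles used by both the unit and the
# acceptance suites

# brute-force enumeration of the signed-rank null: all 2^n sign
# assignments of the observed (possibly tied) ranks
enum_signed_rank <- function(x, tail) {
  d <- x[x != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wdist <- drop(signs %*% r)
  W <- sum(r[d > 0])
  pg <- mean(Wdist >= W - 1e-12)
  pl <- mean(Wdist <= W + 1e-12)
  p <- switch(tail, greater = pg, less = pl,
              two.sided = min(1, 2 * min(pg, pl)))
  list(W = W, p = p)
}

# Benjamini-Hochberg step-up, written directly from the formula
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  out <- numeric(m)
  out[o] <- rev(cummin(rev(pmin(p[o] * m / seq_len(m), 1))))
  out
}
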