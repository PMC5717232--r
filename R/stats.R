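stat_result <- function(test, statistic, p_raw, n, tail,
                        df1 = NA_real_, df2 = NA_real_, effect = NA_character_,
                        family = NA_character_) {
  data.frame(test = test, effect = effect, statistic = statistic,
             df1 = df1, df2 = df2, p_raw = p_raw, p_fdr = NA_real_,
             family = family, n = n, tail = tail,
             stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' Tests whether paired differences (or values minus chance) are symmetric
#' about zero. Exact zeros are dropped (Wilcoxon's rule), absolute values are
#' mid-ranked under ties, and the statistic is `W`, the sum of ranks of
#' positive differences. For `n <= 15` retained differences the p-value is
#' exact, computed by enumerating all `2^n` sign assignments of the observed
#' (possibly tied) ranks; for larger `n` a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x numeric vector of differences (or values), `mu` is subtracted.
#' @param mu null center (default 0; use the chance level for performance
#'   values).
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max largest `n` for which enumeration is used.
#' @return a one-row `data.frame` (see internal `stat_result`): statistic
#'   `W`, raw p, effective `n`, tail.
#' @examples
#' signed_rank_test(c(1, 2, 3), tail = "greater")  # W = 6, p = 1/8
#' @export
signed_rank_test <- function(x, mu = 0,
                             tail = c("two.sided", "greater", "less"),
                             exact_max = 15L) {
  tail <- match.arg(tail)
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, W, tail)
  } else {
    tie_tab <- table(r)
    e <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p_greater <- pnorm((W - e - 0.5) / sqrt(v), lower.tail = FALSE)
    p_less <- pnorm((W - e + 0.5) / sqrt(v))
    p <- switch(tail, greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
  }
  stat_result("signed_rank", W, p, n, tail)
}

# exact null distribution of W by dynamic programming over doubled ranks
signed_rank_exact_p <- function(ranks, W, tail) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  counts <- numeric(tot + 1L)        # counts[w + 1] = #assignments with 2W = w
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(tot + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  p_greater <- sum(probs[(w2 + 1L):(tot + 1L)])
  p_less <- sum(probs[seq_len(w2 + 1L)])
  switch(tail, greater = p_greater, less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

#' Benjamini-Hochberg FDR adjustment over a declared family
#'
#' Step-up adjustment `p_(i) -> min_(j >= i) min(1, p_(j) * m / j)` applied
#' to a family of raw p-values declared in advance.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @seealso [fdr_family()] to adjust a table of test results in place.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) stop("empty family")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Adjust a table of test results within FDR families
#'
#' Fills the `p_fdr` column of a results table (rows = tests), adjusting
#' within each level of `family`. Family membership is an explicit input,
#' declared before any p-value is inspected.
#'
#' @param results data.frame with columns `p_raw` and (optionally) `family`.
#' @param family family label(s); recycled over rows if length 1.
#' @return the table with `p_fdr` and `family` filled.
#' @export
fdr_family <- function(results, family = "family1") {
  stopifnot("p_raw" %in% names(results))
  results$family <- rep_len(family, nrow(results))
  for (f in unique(results$family)) {
    idx <- results$family == f
    results$p_fdr[idx] <- fdr_adjust(results$p_raw[idx])
  }
  results
}

#' Repeated-measures ANOVA on aligned-rank-transformed data
#'
#' Nonparametric factorial analysis for fully-crossed within-subject designs
#' with one observation per subject and cell. For each effect the responses
#' are aligned (cell mean removed, the estimated contribution of the effect
#' of interest added back), mid-ranked across the whole dataset, and a
#' standard balanced within-subject ANOVA is computed on the ranks, with the
#' effect-by-subject interaction as the error term.
#'
#' @param data data.frame in long format.
#' @param dv name of the response column.
#' @param factors character vector of 1 or 2 within-subject factor columns.
#' @param subject name of the subject identifier column.
#' @return data.frame with one `stat_result` row per main effect and (for 2
#'   factors) the interaction: F statistic, df, raw p.
#' @export
art_rm_anova <- function(data, dv, factors, subject = "subject") {
  stopifnot(length(factors) %in% 1:2,
            all(c(dv, factors, subject) %in% names(data)))
  y <- data[[dv]]
  S <- factor(data[[subject]])
  fs <- lapply(factors, function(f) factor(data[[f]]))
  cells <- interaction(as.data.frame(fs), drop = FALSE)
  cnt <- table(S, cells)
  if (any(cnt != 1L))
    stop("design must be complete and balanced: one observation per ",
         "subject per cell")
  mu <- mean(y)
  cell_mean <- ave(y, cells)
  effects <- list()
  if (length(factors) == 1L) {
    mA <- ave(y, fs[[1]])
    effects[[factors[1]]] <- mA - mu
  } else {
    mA <- ave(y, fs[[1]]); mB <- ave(y, fs[[2]])
    effects[[factors[1]]] <- mA - mu
    effects[[factors[2]]] <- mB - mu
    effects[[paste(factors, collapse = ":")]] <- cell_mean - mA - mB + mu
  }
  res <- lapply(names(effects), function(eff) {
    aligned <- y - cell_mean + effects[[eff]]
    r <- rank(aligned)
    rm_anova_F(r, fs, S, eff, factors)
  })
  do.call(rbind, res)
}

# balanced within-subject ANOVA on (rank-transformed) responses; returns the
# F test of one effect with its effect-by-subject error stratum
rm_anova_F <- function(r, fs, S, eff, factors) {
  n <- nlevels(S)
  mu <- mean(r)
  mS <- ave(r, S)
  if (eff %in% factors) {
    f1 <- fs[[match(eff, factors)]]
    a <- nlevels(f1)
    reps <- length(r) / (a * n)           # cells of the other factor(s)
    mA <- tapply(r, f1, mean)
    mS <- tapply(r, S, mean)
    mAS <- tapply(r, list(f1, S), mean)   # a x n
    ss_eff <- n * reps * sum((mA - mu)^2)
    resid_as <- sweep(sweep(mAS, 1, mA), 2, mS) + mu
    ss_err <- reps * sum(resid_as^2)
    df1 <- a - 1
    df2 <- (a - 1) * (n - 1)
  } else {
    f1 <- fs[[1]]; f2 <- fs[[2]]
    a <- nlevels(f1); b <- nlevels(f2)
    mA <- tapply(r, f1, mean); mB <- tapply(r, f2, mean)
    mAB <- tapply(r, list(f1, f2), mean)
    ss_eff <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + mu)^2)
    fit <- ave(r, interaction(f1, f2)) + ave(r, interaction(f1, S)) +
      ave(r, interaction(f2, S)) - ave(r, f1) - ave(r, f2) - mS + mu
    ss_err <- sum((r - fit)^2)
    df1 <- (a - 1) * (b - 1)
    df2 <- (a - 1) * (b - 1) * (n - 1)
  }
  Fv <- (ss_eff / df1) / (ss_err / df2)
  out <- stat_result("art_rm_anova", Fv, pf(Fv, df1, df2, lower.tail = FALSE),
                     n, "two.sided", df1 = df1, df2 = df2, effect = eff)
  out
}

#' One-sample t-test
#'
#' Classical t statistic against a fixed null mean; used for behavioral
#' report proportions against their chance level.
#'
#' @param x numeric sample (`n >= 2`, non-constant).
#' @param mu null mean.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return one-row `stat_result` data.frame with `t`, df, raw p.
#' @export
one_sample_ttest <- function(x, mu = 0,
                             tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) < 2L) stop("need at least 2 observations")
  if (sd(x) < 1e-14)
    stop("zero variance: t statistic undefined")
  tt <- t.test(x, mu = mu,
               alternative = switch(tail, two.sided = "two.sided",
                                    greater = "greater", less = "less"))
  stat_result("one_sample_t", unname(tt$statistic), tt$p.value, length(x),
              tail, df1 = unname(tt$parameter))
}

#' Per-subject linear trend over ordered levels
#'
#' Fits, per subject, the least-squares slope of the response over the level
#' index (e.g. Guess 1, 2, 3, unreported), and tests the slopes against zero
#' across subjects with a signed-rank test.
#'
#' @param values numeric matrix, subjects x ordered levels (>= 3 levels).
#' @param tail tail of the group test on slopes.
#' @return list with `slopes` (per subject), `mean_slope`, and `test`
#'   (signed-rank `stat_result`).
#' @export
linear_trend_slope <- function(values,
                               tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  values <- as.matrix(values)
  if (ncol(values) < 3L) stop("need at least 3 ordered levels")
  idx <- seq_len(ncol(values))
  xc <- idx - mean(idx)
  slopes <- drop(values %*% xc) / sum(xc^2)
  mean_slope <- mean(slopes)
  test <- if (all(slopes == 0)) NULL else signed_rank_test(slopes, tail = tail)
  list(slopes = slopes, mean_slope = mean_slope, test = test)
}
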