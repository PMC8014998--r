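# Core statistical primitives: Mann-Whitney U with an exact tied-data null,
# two-sided exact binomial enrichment p-values, and Tukey HSD pair tests on
# a shared one-way ANOVA fit.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test of two independent samples. For small
#' groups (`min(n) <= exact_max` and `n1 + n2 <= 20`) the null distribution
#' of U is computed by exhaustive enumeration of all group labelings of the
#' pooled midranks, which remains exact in the presence of ties; otherwise
#' the normal approximation with tie and continuity correction is used.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest `min(n1, n2)` for which enumeration is used.
#'
#' @return List with `u` (U statistic of `x`), `p` (two-sided p-value) and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- sqrt(.Machine$double.eps)

  if (min(n1, n2) <= exact_max && n1 + n2 <= 20) {
    idx <- combn(n1 + n2, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - eps)
    return(list(u = u, p = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal_approx"))
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction toward the null
  p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
  list(u = u, p = p, method = "normal_approx")
}

#' Two-sided exact binomial p-value by tail doubling
#'
#' Probability of observing a count as extreme as `k` successes in `n`
#' trials under success probability `p0`, two-sided by doubling the smaller
#' tail (capped at 1). Deterministic replacement for sampled-reference logo
#' significance tests.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @return p-value in (0, 1].
#' @export
binom_twosided_p <- function(k, n, p0) {
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# One-way ANOVA from a groups list (numeric vectors). Degenerate convention:
# no between- and no within-group variance -> F = 0, p = 1; between-group
# signal with exactly zero residual variance -> p = 0.
oneway_anova_stats <- function(groups) {
  ns <- lengths(groups)
  n <- sum(ns)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  if (ssw <= 0) {
    if (ssb <= 0) return(list(f = 0, p = 1, mse = 0, df2 = df2, means = means, ns = ns))
    return(list(f = Inf, p = 0, mse = 0, df2 = df2, means = means, ns = ns))
  }
  msb <- ssb / df1
  mse <- ssw / df2
  f <- msb / mse
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE), mse = mse,
       df2 = df2, means = means, ns = ns)
}

# Tukey HSD p-values for all pairs, using the pooled MSE of the same fit.
tukey_pair_p <- function(fit) {
  k <- length(fit$means)
  pairs <- combn(k, 2)
  p <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(fit$mse / 2 * (1 / fit$ns[a] + 1 / fit$ns[b]))
    if (se == 0) {
      return(if (abs(fit$means[a] - fit$means[b]) > 0) 0 else 1)
    }
    q <- abs(fit$means[a] - fit$means[b]) / se
    ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
  }, numeric(1))
  nm <- names(fit$means)
  setNames(p, paste0(nm[pairs[2, ]], "-", nm[pairs[1, ]]))
}
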