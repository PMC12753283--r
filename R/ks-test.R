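# Exact finite-sample Kolmogorov-Smirnov machinery.
#
# P(D_n < d) is evaluated exactly with the Marsaglia-Tsang-Wang matrix-power
# construction: with k = ceil(nd), h = k - nd and m = 2k - 1, build the m x m
# matrix H of the (i-j+1)!-scaled unit lower Hessenberg pattern with boundary
# corrections in powers of h, then P(D_n < d) = (n!/n^n) [H^n]_{k,k}.  The
# matrix power uses repeated squaring with explicit base-10 exponent carrying
# so that n in the thousands stays inside double range.

ks_cdf_exact <- function(d, n) {
  stopifnot(length(d) == 1L, length(n) == 1L, n >= 1)
  if (d <= 0) return(0)
  if (d >= 1) return(1)
  k <- ceiling(n * d)
  h <- k - n * d
  m <- 2L * k - 1L
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) if (i - j + 1 >= 0) H[i, j] <- 1
  }
  for (i in seq_len(m)) {
    H[i, 1] <- H[i, 1] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1)
  }
  if (2 * h - 1 > 0) H[m, 1] <- H[m, 1] + (2 * h - 1)^m
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1 > 0) H[i, j] <- H[i, j] / factorial(i - j + 1)
    }
  }
  # H^n with overflow guard on the pivot entry
  pow <- function(A, eA, p) {
    if (p == 1L) return(list(A = A, e = eA))
    half <- pow(A, eA, p %/% 2L)
    B <- half$A %*% half$A
    eB <- 2 * half$e
    if (p %% 2L == 1L) {
      B <- B %*% A
      eB <- eB + eA
    }
    if (B[k, k] > 1e140) {
      B <- B * 1e-140
      eB <- eB + 140
    }
    list(A = B, e = eB)
  }
  r <- pow(H, 0, as.integer(n))
  s <- r$A[k, k]
  e <- r$e
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) {
      s <- s * 1e140
      e <- e - 140
    }
  }
  min(max(s * 10^e, 0), 1)
}

#' Exact finite-sample Kolmogorov-Smirnov critical value
#'
#' Computes the two-sided critical value \eqn{d_{n,\alpha}} solving
#' \eqn{P(D_n > d) = \alpha} from the exact finite-\eqn{n} Kolmogorov
#' distribution (not the asymptotic \eqn{1.36/\sqrt n} rule), by bisection on
#' the Marsaglia-Tsang-Wang evaluation of \eqn{P(D_n < d)}. Small-sample
#' tables are reproduced to their printed precision, e.g.
#' \eqn{d_{21,0.05} = 0.287}.
#'
#' @param n Sample size (positive integer).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical value, a number in (0, 1).
#' @examples
#' ks_critical_value(21, 0.05) # 0.2872
#' ks_critical_value(1, 0.05) # 0.975 exactly
#' @export
ks_critical_value <- function(n, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_validation("`n` must be a positive integer.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must lie strictly between 0 and 1.")
  }
  f <- function(d) ks_cdf_exact(d, n) - (1 - alpha)
  # bracket near the asymptotic scale to keep the matrix order k = ceil(nd)
  # small; widen to (0, 1) only if the cheap bracket misses
  lower <- max(1e-8, 0.2 / sqrt(n))
  upper <- min(1 - 1e-12, 6 / sqrt(n))
  if (f(lower) > 0) lower <- 1e-8
  if (f(upper) < 0) upper <- 1 - 1e-12
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

#' One-sample Kolmogorov-Smirnov test against a fitted Weibull
#'
#' Computes the two-sided KS statistic
#' \eqn{D=\max_i\max(|F(y_{(i)})-i/n|,\,|F(y_{(i)})-(i-1)/n|)} of the sample
#' against the CDF of a fitted scale-shape Weibull, and compares it with the
#' exact finite-sample critical value from [ks_critical_value()]. The fitted
#' parameters are treated as known (no Lilliefors-style correction), so with
#' estimated parameters the test is conservative.
#'
#' @param values Positive sample values (typically the event observations
#'   only; censored values carry no exact empirical-CDF position).
#' @param params A [weibull_params()] object, e.g. from
#'   [fit_weibull_univariate()].
#' @param alpha Significance level.
#' @return A tibble with one row: `statistic`, `critical_value`, `n`, `alpha`
#'   and `reject`.
#' @examples
#' set.seed(1)
#' p <- weibull_params(shape = 4, scale = 5)
#' ks_test_weibull(weibull_rng(50, p), p)
#' @export
ks_test_weibull <- function(values, params, alpha = 0.05) {
  if (length(values) == 0) stop_validation("`values` must be nonempty.")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_validation("`values` must be positive.")
  }
  n <- length(values)
  fy <- weibull_cdf(sort(values), params)
  i <- seq_len(n)
  d <- max(pmax(abs(fy - i / n), abs(fy - (i - 1) / n)))
  crit <- ks_critical_value(n, alpha)
  tibble::tibble(
    statistic = d,
    critical_value = crit,
    n = n,
    alpha = alpha,
    reject = d > crit
  )
}
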