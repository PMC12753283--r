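# Scale-shape Weibull distribution.
#
# The package works throughout in the rate-style parametrization
#   f(y) = lambda * gamma * y^(gamma-1) * exp(-lambda * y^gamma),
# where gamma > 0 is the shape and lambda > 0 a rate-like scale.  The classic
# scale tau of stats::dweibull relates to lambda by lambda = tau^(-gamma).

#' Scale-shape Weibull parameter set
#'
#' Bundles the shape \eqn{\gamma} and the rate-style scale \eqn{\lambda} of the
#' Weibull distribution \eqn{f(y)=\lambda\gamma y^{\gamma-1}e^{-\lambda
#' y^\gamma}} together with the derived classic scale
#' \eqn{\tau=\lambda^{-1/\gamma}}. Exactly one of `rate` and `scale` must be
#' given.
#'
#' @param shape Positive shape \eqn{\gamma}.
#' @param rate Positive rate-style scale \eqn{\lambda}.
#' @param scale Positive classic scale \eqn{\tau} (as in [stats::dweibull()]).
#' @return A `weibull_params` list with fields `shape`, `rate` and `scale`.
#' @examples
#' weibull_params(shape = 2, rate = 0.5)
#' weibull_params(shape = 2, scale = 2^(1 / 2))
#' @export
weibull_params <- function(shape, rate = NULL, scale = NULL) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
    stop_validation("`shape` must be a single positive number.")
  }
  if (is.null(rate) == is.null(scale)) {
    stop_validation("supply exactly one of `rate` and `scale`.")
  }
  if (is.null(rate)) {
    if (!is.numeric(scale) || scale <= 0) stop_validation("`scale` must be positive.")
    rate <- scale^(-shape)
  } else {
    if (!is.numeric(rate) || rate <= 0) stop_validation("`rate` must be positive.")
    scale <- rate^(-1 / shape)
  }
  structure(list(shape = shape, rate = rate, scale = scale),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(shape = %g, rate = %g, classic scale = %g)\n",
              x$shape, x$rate, x$scale))
  invisible(x)
}

check_nonneg_y <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0)) {
    stop_validation("`y` must be finite and nonnegative.")
  }
}

#' Weibull density, distribution, survival, hazard and mean
#'
#' Vectorized evaluations of the scale-shape Weibull density
#' \eqn{f(y)=\lambda\gamma y^{\gamma-1}e^{-\lambda y^\gamma}}, its CDF
#' \eqn{F(y)=1-e^{-\lambda y^\gamma}}, survival \eqn{S(y)=e^{-\lambda
#' y^\gamma}}, hazard \eqn{h(y)=\lambda\gamma y^{\gamma-1}} and mean
#' \eqn{\lambda^{-1/\gamma}\Gamma(1+1/\gamma)}.
#'
#' For shape < 1 the density diverges at the origin; `weibull_pdf(0, ...)`
#' returns `Inf` there, matching the limit of the density.
#'
#' @param y Nonnegative evaluation points (hazard requires `y > 0` when
#'   shape < 1).
#' @param params A [weibull_params()] object.
#' @return Numeric vector.
#' @examples
#' p <- weibull_params(shape = 2, rate = 1)
#' weibull_pdf(1, p)
#' weibull_cdf(1, p) + weibull_survival(1, p) # = 1
#' weibull_hazard(2, p) # = 4
#' weibull_mean(p) # = sqrt(pi)/2
#' @export
weibull_pdf <- function(y, params) {
  check_nonneg_y(y)
  g <- params$shape; l <- params$rate
  out <- l * g * y^(g - 1) * exp(-l * y^g)
  if (g < 1) out[y == 0] <- Inf
  if (g == 1) out[y == 0] <- l
  out
}

#' @rdname weibull_pdf
#' @export
weibull_cdf <- function(y, params) {
  check_nonneg_y(y)
  -expm1(-params$rate * y^params$shape)
}

#' @rdname weibull_pdf
#' @export
weibull_survival <- function(y, params) {
  check_nonneg_y(y)
  exp(-params$rate * y^params$shape)
}

#' @rdname weibull_pdf
#' @export
weibull_hazard <- function(y, params) {
  g <- params$shape; l <- params$rate
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      (g < 1 && any(y <= 0))) {
    stop_validation("hazard requires y > 0 (y >= 0 when shape >= 1).")
  }
  l * g * y^(g - 1)
}

#' @rdname weibull_pdf
#' @export
weibull_mean <- function(params) {
  params$rate^(-1 / params$shape) * gamma(1 + 1 / params$shape)
}

#' Draw from the scale-shape Weibull by inverse CDF
#'
#' @param n Number of draws.
#' @param params A [weibull_params()] object.
#' @return Numeric vector of length `n`.
#' @export
weibull_rng <- function(n, params) {
  u <- runif(n)
  (-log1p(-u) / params$rate)^(1 / params$shape)
}

#' Univariate censored Weibull maximum likelihood
#'
#' Maximizes the right-censored Weibull log-likelihood
#' \eqn{\sum_i \delta_i[\log\gamma+(\gamma-1)\log y_i + \log\lambda] -
#' \lambda y_i^\gamma} by damped Newton-Raphson. This is the
#' intercept-only special case of [wr_fit()] (with \eqn{\lambda=e^{b_0}}).
#'
#' @param values Positive observed values (already censored at the threshold,
#'   if any).
#' @param censored Logical vector; `TRUE` marks a right-censored value. The
#'   default treats every value as an event.
#' @return A list with `params` ([weibull_params()]), `loglik`, `gradient`,
#'   `iterations` and `converged`.
#' @examples
#' set.seed(1)
#' y <- weibull_rng(200, weibull_params(shape = 3, rate = 0.1))
#' fit_weibull_univariate(y)$params
#' @export
fit_weibull_univariate <- function(values, censored = rep(FALSE, length(values))) {
  if (length(values) != length(censored)) {
    stop_validation("`values` and `censored` must have the same length.")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_validation("`values` must be positive.")
  }
  delta <- as.numeric(!censored)
  if (sum(delta) < 2) {
    stop_convergence("need at least 2 uncensored values to fit a Weibull.")
  }
  X <- matrix(1, length(values), 1)
  fit <- newton_wr(values, delta, X, weights = rep(1, length(values)),
                   init = c(1, log(sum(delta) / sum(values))))
  if (!fit$converged) {
    stop_convergence("univariate censored Weibull fit did not converge.")
  }
  list(
    params = weibull_params(shape = fit$par[1], rate = exp(fit$par[2])),
    loglik = fit$loglik,
    gradient = fit$gradient,
    iterations = fit$iterations,
    converged = fit$converged
  )
}
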