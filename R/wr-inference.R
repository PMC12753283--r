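# Global-model inference: Wilks simultaneous test and Wald partial tests.

test_result <- function(name, statistic, df, p_value, alpha, method) {
  tibble::tibble(
    name = name,
    statistic = statistic,
    df = df,
    p_value = p_value,
    alpha = alpha,
    reject = p_value < alpha,
    method = method
  )
}

#' Wilks simultaneous likelihood-ratio test for the global model
#'
#' Tests \eqn{H_0: b_1=\dots=b_p=0} with \eqn{W = 2(\ell(\hat\phi) -
#' \ell(\hat\phi_0))} against a chi-square reference with df = p (the number
#' of covariates). `method = "quadratic_form"` uses the asymptotically
#' equivalent \eqn{W \approx \hat B^\top [I_{F22}]^{-1}\hat B}, where
#' \eqn{\hat B} stacks the slope estimates and \eqn{I_{F22}} is the variance
#' matrix with the shape and intercept rows/columns removed.
#'
#' @param full A converged `wr_fit` with p >= 1 covariates.
#' @param null The nested null fit from [wr_null_fit()] (computed on demand
#'   when omitted; ignored by the quadratic-form method).
#' @param alpha Significance level.
#' @param method `"likelihood"` (default) or `"quadratic_form"`.
#' @return One-row tibble: `name`, `statistic`, `df`, `p_value`, `alpha`,
#'   `reject`, `method`.
#' @export
wilks_test <- function(full, null = NULL, alpha = 0.05,
                       method = c("likelihood", "quadratic_form")) {
  method <- match.arg(method)
  p <- length(full$covariate_names)
  if (p < 1) stop_validation("the full model has no covariates to test.")
  if (method == "likelihood") {
    if (is.null(null)) null <- wr_null_fit(full$sample, weights = full$weights)
    W <- 2 * (full$loglik - null$loglik)
    if (W < -1e-6) {
      stop_convergence("full-model log-likelihood below null: optimizer failure.")
    }
    W <- max(W, 0)
  } else {
    B <- full$coef[-1]
    V22 <- full$varcov[-(1:2), -(1:2), drop = FALSE]
    W <- drop(t(B) %*% solve(V22, B))
  }
  test_result("simultaneous (Wilks)", W, p, pchisq(W, df = p, lower.tail = FALSE),
              alpha, method)
}

#' Wald partial tests of the global regression coefficients
#'
#' For each coefficient, \eqn{Q_k = \hat b_k / \mathrm{se}(\hat b_k)} with
#' \eqn{\mathrm{se} = \sqrt{\mathrm{var}(\hat b_k)}} taken from the inverse
#' observed information, compared two-sided against the standard normal:
#' \eqn{p = 2(1-\Phi(|Q_k|))}.
#'
#' @param fit A converged `wr_fit`.
#' @param alpha Significance level.
#' @param include_intercept Include the intercept row (default `TRUE`)?
#' @return Tibble with one row per tested coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (\eqn{|Q_k|} signed), `p_value`, `reject`.
#' @export
wald_tests <- function(fit, alpha = 0.05, include_intercept = TRUE) {
  if (is.null(fit$varcov)) stop_convergence("fit has no variance matrix.")
  v <- diag(fit$varcov)[-1] # drop shape
  if (any(v <= 0)) stop_convergence("nonpositive coefficient variance.")
  est <- fit$coef
  se <- sqrt(v)
  q <- est / se
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(q),
    p_value = unname(2 * pnorm(-abs(q))),
    reject = unname(2 * pnorm(-abs(q)) < alpha)
  )
  if (!include_intercept) out <- out[out$term != "(Intercept)", ]
  out
}

#' @rdname wald_tests
#' @param k Coefficient index: 0 for the intercept, 1..p for the covariates.
#' @export
wald_partial <- function(fit, k, alpha = 0.05) {
  tab <- wald_tests(fit, alpha = alpha)
  if (k < 0 || k > length(fit$covariate_names)) {
    stop_validation("`k` must lie in 0..p.")
  }
  tab[k + 1L, ]
}
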