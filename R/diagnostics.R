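# Pre-fit screening (VIF, Glejser), post-fit goodness-of-fit, and backward
# covariate elimination.

#' Variance inflation factors
#'
#' Each covariate is regressed by least squares (with intercept) on the
#' remaining covariates; \eqn{VIF_k = 1/(1-R_k^2)}. Values above
#' `flag_threshold` (conventionally 10) flag multicollinearity.
#'
#' @param x A [spatial_sample()] object, or a data frame / matrix of
#'   covariate columns.
#' @param flag_threshold Flagging cutoff (default 10).
#' @return Tibble with one row per covariate: `term`, `r_squared`, `vif`,
#'   `flagged`.
#' @export
vif <- function(x, flag_threshold = 10) {
  X <- if (inherits(x, "spatial_sample")) {
    as.matrix(x$data[x$covariate_names])
  } else {
    as.matrix(as.data.frame(x))
  }
  p <- ncol(X)
  if (p < 2) stop_validation("VIF needs at least two covariates.")
  if (nrow(X) <= p) stop_validation("VIF needs n > p observations.")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    stop_validation(paste0("constant covariate column(s): ",
                           paste(colnames(X)[const], collapse = ", ")))
  }
  r2 <- vapply(seq_len(p), function(k) {
    fit <- lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
  }, numeric(1))
  tibble::tibble(
    term = colnames(X),
    r_squared = r2,
    vif = 1 / (1 - r2),
    flagged = 1 / (1 - r2) > flag_threshold
  )
}

#' Glejser test for spatial heterogeneity
#'
#' Regresses the response on the covariates by ordinary least squares, takes
#' the absolute residuals \eqn{e_i = |y_i - \hat y_i|}, and tests whether
#' the covariates explain them through the overall F statistic of the
#' auxiliary least-squares regression of \eqn{|e|} on the covariates,
#' \deqn{F_g = \frac{(\hat\beta^\top X^\top e - n\bar e^2)/p}
#' {(e^\top e - \hat\beta^\top X^\top e)/(n-p-1)} \sim F(p,\; n-p-1).}
#' Rejection indicates heteroskedastic (spatially heterogeneous) response
#' variability, the screen that motivates geographically weighted modelling.
#'
#' @param sample A [spatial_sample()] object.
#' @param alpha Significance level.
#' @param covariates Covariate subset (default all).
#' @param residuals `"ols"` (default; the auxiliary construction is ordinary
#'   least-squares algebra) or `"wr_mean"` to take residuals from the fitted
#'   censored-Weibull mean model instead.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`, `alpha`,
#'   `reject`.
#' @export
glejser_test <- function(sample, alpha = 0.05, covariates = NULL,
                         residuals = c("ols", "wr_mean")) {
  residuals <- match.arg(residuals)
  if (is.null(covariates)) covariates <- sample$covariate_names
  X <- as.matrix(sample$data[covariates])
  y <- sample$data$response
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop_validation("Glejser test needs n > p + 1.")
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop_validation("rank-deficient design.")
  if (residuals == "ols") {
    e_raw <- lm.fit(Xd, y)$residuals
  } else {
    fit <- wr_fit(sample, covariates = covariates)
    e_raw <- y - predict(fit)$mean
  }
  e <- abs(e_raw)
  aux <- lm.fit(Xd, e)
  fitted <- e - aux$residuals
  ssr <- sum((fitted - mean(e))^2)
  sse <- sum(aux$residuals^2)
  Fg <- (ssr / p) / (sse / (n - p - 1))
  tibble::tibble(
    statistic = Fg, df1 = p, df2 = n - p - 1,
    p_value = pf(Fg, p, n - p - 1, lower.tail = FALSE),
    alpha = alpha,
    reject = pf(Fg, p, n - p - 1, lower.tail = FALSE) < alpha
  )
}

#' Goodness-of-fit report for global and geographically weighted fits
#'
#' Computes four model-level measures:
#' * `bic`: \eqn{-2\ell + K\log n} with K = p + 2. For a geographically
#'   weighted fit, \eqn{\ell} is the sum over sites of each observation's
#'   own-site contribution \eqn{\delta_i\log h(y_i,x_i;\hat\phi(u_i)) +
#'   \log S(y_i,x_i;\hat\phi(u_i))} — the minimal single-number extension of
#'   the global likelihood; see the methods vignette.
#' * `mcfadden_r2`: \eqn{1-\ell/\ell_0} against the intercept-plus-shape
#'   null (per-site nulls for the geographically weighted model).
#' * `mape_percent`: \eqn{(100/n)\sum|y_i-\hat\mu_i|/y_i} with \eqn{\hat\mu}
#'   from the mean-regression function, against the raw responses by default
#'   (the response is fully observed; censoring is an analysis construct).
#' * `gcv`: \eqn{n\sum(y_i-\hat\mu_i)^2/(n-K)^2} on the same residuals.
#'
#' @param fit A `wr_fit` or `gwwr_fit`.
#' @param events_only Restrict MAPE/GCV to event rows? Default `FALSE`.
#' @return One-row tibble: `bic`, `gcv`, `mcfadden_r2`, `mape_percent`, `K`,
#'   `n`.
#' @export
gof_report <- function(fit, events_only = FALSE) {
  if (inherits(fit, "wr_fit")) {
    sample <- fit$sample
    ll <- fit$loglik
    ll0 <- wr_null_fit(sample)$loglik
    mu <- predict(fit)$mean
    K <- length(fit$par)
  } else if (inherits(fit, "gwwr_fit")) {
    sample <- fit$sample
    pc <- sample_pieces(sample, fit$covariate_names)
    ok <- which(!vapply(fit$locals, is.null, logical(1)))
    own <- function(i, par) {
      # single observation's own-site censored log-likelihood contribution
      wr_core(par, pc$y[i], pc$delta[i], pc$X[i, , drop = FALSE], 1)$loglik
    }
    ll <- sum(vapply(ok, function(i) own(i, unname(fit$locals[[i]]$par)),
                     numeric(1)))
    ll0 <- sum(vapply(ok, function(i) {
      nf <- local_null_fit(fit, i)
      wr_core(nf$par, pc$y[i], pc$delta[i],
              matrix(1, 1, 1), 1)$loglik
    }, numeric(1)))
    mu <- vapply(ok, function(i) {
      lf <- fit$locals[[i]]
      gamma(1 + 1 / lf$shape) *
        exp(-drop(pc$X[i, ] %*% lf$coef) / lf$shape)
    }, numeric(1))
    sample <- list(data = sample$data[ok, ])
    K <- length(fit$covariate_names) + 2L
  } else {
    stop_validation("`fit` must be a wr_fit or gwwr_fit.")
  }
  y <- sample$data$response
  delta <- sample$data$delta
  if (events_only) {
    keep <- delta == 1
    y <- y[keep]
    mu <- mu[keep]
  }
  n <- length(y)
  tibble::tibble(
    bic = -2 * ll + K * log(n),
    gcv = n * sum((y - mu)^2) / (n - K)^2,
    mcfadden_r2 = 1 - ll / ll0,
    mape_percent = 100 * mean(abs(y - mu) / y),
    K = K,
    n = n
  )
}

#' Backward covariate elimination for the global model
#'
#' Starting from the full model, iteratively refits after dropping the
#' covariate with the largest partial Wald p-value exceeding `alpha_stay`,
#' recording the BIC of every visited model. The selected model is the
#' visited model with minimum BIC among those whose retained covariates all
#' meet the stay rule (the final model of the sequence always qualifies).
#'
#' @param sample A [spatial_sample()] object.
#' @param alpha_stay Stay threshold for the partial p-values (default 0.10,
#'   so borderline covariates significant at the 10% level are retained).
#' @param covariates Starting covariate set (default all).
#' @return List with `fit` (the selected `wr_fit`), `covariates` (retained
#'   names) and `trace` (tibble: step, covariates, dropped, bic, max p-value).
#' @export
backward_eliminate <- function(sample, alpha_stay = 0.10, covariates = NULL) {
  if (is.null(covariates)) covariates <- sample$covariate_names
  current <- covariates
  step <- 0L
  rows <- list()
  visited <- list()
  repeat {
    fit <- wr_fit(sample, covariates = current)
    gof <- gof_report(fit)
    wt <- if (length(current) > 0) {
      wald_tests(fit, include_intercept = FALSE)
    } else NULL
    maxp <- if (is.null(wt) || nrow(wt) == 0) NA_real_ else max(wt$p_value)
    qualifies <- is.na(maxp) || maxp <= alpha_stay
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = step,
      covariates = paste(current, collapse = ","),
      n_covariates = length(current),
      bic = gof$bic,
      max_p_value = maxp,
      qualifies = qualifies
    )
    visited[[length(visited) + 1]] <- list(fit = fit, covariates = current,
                                           bic = gof$bic, qualifies = qualifies)
    if (qualifies) break
    drop_term <- wt$term[which.max(wt$p_value)]
    current <- setdiff(current, drop_term)
    step <- step + 1L
    if (length(current) == 0) {
      fit <- wr_fit(sample, covariates = character(0))
      gof <- gof_report(fit)
      rows[[length(rows) + 1]] <- tibble::tibble(
        step = step, covariates = "", n_covariates = 0L, bic = gof$bic,
        max_p_value = NA_real_, qualifies = TRUE)
      visited[[length(visited) + 1]] <- list(fit = fit,
                                             covariates = character(0),
                                             bic = gof$bic, qualifies = TRUE)
      warn("backward elimination removed every covariate; returning intercept-only model.")
      break
    }
  }
  trace <- dplyr::bind_rows(rows)
  qual <- visited[vapply(visited, function(v) v$qualifies, logical(1))]
  best <- qual[[which.min(vapply(qual, function(v) v$bic, numeric(1)))]]
  list(fit = best$fit, covariates = best$covariates, trace = trace)
}
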