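# Global censored Weibull regression.
#
# Model: y_i ~ Weibull(gamma, lambda_i) with lambda_i = exp(b' x_i), right
# censored at y* with event flag delta_i.  Parameters are packed shape-first,
# phi = (gamma, b0, ..., bp).  The weighted versions of the likelihood and
# its derivatives below are shared with the geographically weighted model
# (unit weights give the global quantities exactly).

# log-likelihood, gradient and Hessian at phi = c(gamma, b)
wr_core <- function(phi, y, delta, X, weights) {
  g <- phi[1]
  b <- phi[-1]
  ylg <- log(y)
  eta <- drop(X %*% b)
  # A_i = y_i^gamma exp(b'x_i), accumulated in log space to dodge overflow
  logA <- g * ylg + eta
  A <- exp(logA)
  w <- weights
  ll <- sum(w * (delta * (log(g) + (g - 1) * ylg + eta) - A))
  gg <- sum(w * (delta * (1 / g + ylg) - A * ylg))
  gb <- drop(crossprod(X, w * (delta - A)))
  h_gg <- -sum(w * (delta / g^2 + A * ylg^2))
  h_gb <- -drop(crossprod(X, w * A * ylg))
  h_bb <- -crossprod(X, X * (w * A))
  H <- rbind(c(h_gg, h_gb), cbind(h_gb, h_bb))
  list(loglik = ll, gradient = c(gg, gb), hessian = H)
}

# Damped Newton-Raphson with step halving and escalating ridge fallback.
newton_wr <- function(y, delta, X, weights, init,
                      tol_grad = 1e-6, tol_step = 1e-8, max_iter = 100L,
                      max_halvings = 30L) {
  phi <- init
  cur <- wr_core(phi, y, delta, X, weights)
  iterations <- 0L
  halvings_total <- 0L
  converged <- FALSE
  for (m in seq_len(max_iter)) {
    iterations <- m
    if (max(abs(cur$gradient)) < tol_grad) {
      converged <- TRUE
      break
    }
    H <- cur$hessian
    step <- NULL
    ridge <- 0
    repeat {
      Hr <- if (ridge == 0) H else H - ridge * diag(nrow(H))
      step <- tryCatch(solve(Hr, cur$gradient), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) break
      ridge <- if (ridge == 0) 1e-8 else ridge * 10
      if (ridge > 1e-2) break
    }
    if (is.null(step) || !all(is.finite(step))) break
    # line search: halve until gamma stays positive and loglik increases
    lam <- 1
    improved <- FALSE
    for (h in seq_len(max_halvings + 1L)) {
      cand <- phi - lam * step
      if (cand[1] > 0) {
        nxt <- tryCatch(wr_core(cand, y, delta, X, weights),
                        error = function(e) NULL)
        if (!is.null(nxt) && is.finite(nxt$loglik) &&
            nxt$loglik >= cur$loglik - 1e-12) {
          improved <- TRUE
          break
        }
      }
      lam <- lam / 2
      halvings_total <- halvings_total + 1L
    }
    if (!improved) break
    delta_phi <- cand - phi
    phi <- cand
    cur <- nxt
    if (max(abs(delta_phi)) < tol_step) {
      converged <- max(abs(cur$gradient)) < tol_grad ||
        max(abs(delta_phi)) < tol_step
      break
    }
  }
  if (!converged && max(abs(cur$gradient)) < tol_grad) converged <- TRUE
  list(par = phi, loglik = cur$loglik, gradient = cur$gradient,
       hessian = cur$hessian, iterations = iterations,
       step_halvings = halvings_total, converged = converged)
}

sample_pieces <- function(sample, use_covariates = NULL) {
  if (is.null(use_covariates)) use_covariates <- sample$covariate_names
  X <- sample$design[, c("(Intercept)", use_covariates), drop = FALSE]
  list(y = sample$data$censored_response, delta = sample$data$delta, X = X,
       covariate_names = use_covariates)
}

# Internal weighted fit on a (possibly standardized) design; returns results
# on the original covariate scale.
fit_wr_weighted <- function(y, delta, X, weights, init = NULL,
                            standardize = TRUE) {
  n <- length(y)
  p1 <- ncol(X) # p + 1 including intercept
  if (sum(weights * delta) <= 0) {
    stop_convergence("no (weighted) events: censored Weibull likelihood is unbounded.")
  }
  ctr <- rep(0, p1)
  scl <- rep(1, p1)
  if (standardize && p1 > 1) {
    for (j in 2:p1) {
      s <- stats::sd(X[, j])
      if (is.finite(s) && s > 0) {
        ctr[j] <- mean(X[, j])
        scl[j] <- s
      }
    }
  }
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  to_std <- function(phi) {
    b <- phi[-1]
    bz <- b * scl
    bz[1] <- b[1] + sum(b[-1] * ctr[-1])
    c(phi[1], bz)
  }
  from_std <- function(phi) {
    bz <- phi[-1]
    b <- bz / scl
    b[1] <- bz[1] - sum((bz[-1] / scl[-1]) * ctr[-1])
    c(phi[1], b)
  }
  if (is.null(init)) {
    b0 <- log(sum(weights * delta) / sum(weights * y))
    init <- c(1, b0, rep(0, p1 - 1L))
  }
  res <- newton_wr(y, delta, Z, weights, to_std(init))
  if (!res$converged) {
    # retry from a univariate censored Weibull warm start
    uni <- tryCatch(
      newton_wr(y, delta, matrix(1, n, 1), weights,
                c(1, log(sum(weights * delta) / sum(weights * y)))),
      error = function(e) NULL)
    if (!is.null(uni) && uni$converged) {
      init2 <- c(uni$par[1], uni$par[2], rep(0, p1 - 1L))
      res2 <- newton_wr(y, delta, Z, weights, init2)
      if (res2$converged || res2$loglik > res$loglik) res <- res2
    }
  }
  phi <- from_std(res$par)
  final <- wr_core(phi, y, delta, X, weights)
  H <- (final$hessian + t(final$hessian)) / 2
  varcov <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(varcov)) {
    ridge <- 1e-8
    while (is.null(varcov) && ridge <= 1e-2) {
      varcov <- tryCatch(solve(-(H - ridge * diag(nrow(H)))),
                         error = function(e) NULL)
      ridge <- ridge * 10
    }
  }
  list(par = phi, loglik = final$loglik, gradient = final$gradient,
       hessian = H, varcov = varcov, iterations = res$iterations,
       step_halvings = res$step_halvings, converged = res$converged)
}

phi_names <- function(covariate_names) {
  c("shape", "(Intercept)", covariate_names)
}

#' Censored Weibull regression log-likelihood, gradient and Hessian
#'
#' Evaluates the right-censored Weibull regression log-likelihood
#' \deqn{\ell(\phi)=\sum_i w_i\left(\delta_i[\log\gamma+(\gamma-1)\log y_i +
#' b^\top x_i] - y_i^\gamma e^{b^\top x_i}\right)}
#' and its analytic gradient and Hessian with respect to the shape-first
#' parameter packing \eqn{\phi=(\gamma, b_0,\dots,b_p)}. Unit weights give
#' the global model; kernel weights give the local likelihood of the
#' geographically weighted model.
#'
#' @param shape Positive shape \eqn{\gamma}.
#' @param coef Coefficient vector \eqn{b} of length p + 1 (intercept first).
#' @param sample A [spatial_sample()] object.
#' @param weights Optional nonnegative weights (default all 1).
#' @return `wr_loglik()` a scalar; `wr_gradient()` a vector of length p + 2;
#'   `wr_hessian()` a symmetric (p + 2) x (p + 2) matrix.
#' @examples
#' s <- simulate_sites(sim_config(n_sites = 30, p = 1, seed = 7))$sample
#' wr_loglik(1, c(0, 0), s)
#' wr_gradient(1, c(0, 0), s)
#' @export
wr_loglik <- function(shape, coef, sample, weights = NULL) {
  pc <- sample_pieces(sample)
  if (length(coef) != ncol(pc$X)) stop_validation("`coef` has the wrong length.")
  if (is.null(weights)) weights <- rep(1, length(pc$y))
  wr_core(c(shape, coef), pc$y, pc$delta, pc$X, weights)$loglik
}

#' @rdname wr_loglik
#' @export
wr_gradient <- function(shape, coef, sample, weights = NULL) {
  pc <- sample_pieces(sample)
  if (length(coef) != ncol(pc$X)) stop_validation("`coef` has the wrong length.")
  if (is.null(weights)) weights <- rep(1, length(pc$y))
  setNames(wr_core(c(shape, coef), pc$y, pc$delta, pc$X, weights)$gradient,
           phi_names(pc$covariate_names))
}

#' @rdname wr_loglik
#' @export
wr_hessian <- function(shape, coef, sample, weights = NULL) {
  pc <- sample_pieces(sample)
  if (length(coef) != ncol(pc$X)) stop_validation("`coef` has the wrong length.")
  if (is.null(weights)) weights <- rep(1, length(pc$y))
  H <- wr_core(c(shape, coef), pc$y, pc$delta, pc$X, weights)$hessian
  dimnames(H) <- list(phi_names(pc$covariate_names),
                      phi_names(pc$covariate_names))
  (H + t(H)) / 2
}

#' Fit the global censored Weibull regression model
#'
#' Maximum likelihood by damped Newton-Raphson with step-halving line search
#' (the step is halved until the log-likelihood increases and the shape stays
#' positive) and an escalating ridge fallback for indefinite Hessians.
#' Covariates are standardized internally for conditioning and estimates
#' back-transformed; reported likelihood, derivatives and the variance matrix
#' \eqn{\mathrm{var}(\hat\phi)=-H(\hat\phi)^{-1}} are on the original scale.
#'
#' @param sample A [spatial_sample()] object.
#' @param covariates Covariate names to include (default all).
#' @param init Optional start vector \eqn{(\gamma, b_0,\dots,b_p)}; default
#'   shape 1, intercept \eqn{\log(\sum\delta_i/\sum y_i)}, slopes 0.
#' @param weights Optional observation weights (used by the geographically
#'   weighted fit; default all 1).
#' @param standardize Standardize covariates internally? Affects conditioning
#'   only, not the reported estimates.
#' @return A `wr_fit` object: list with `shape`, `coef`, `par` (packed
#'   \eqn{\phi}), `loglik`, `gradient`, `hessian`, `varcov`, `iterations`,
#'   `step_halvings`, `converged`, `covariate_names`, `n`, `n_events` and the
#'   originating `sample`. Methods: [tidy()], [glance()], `print()`,
#'   [predict.wr_fit()].
#' @examples
#' s <- simulate_sites(sim_config(n_sites = 120, p = 2, seed = 3))$sample
#' fit <- wr_fit(s)
#' tidy(fit)
#' glance(fit)
#' @export
wr_fit <- function(sample, covariates = NULL, init = NULL, weights = NULL,
                   standardize = TRUE) {
  pc <- sample_pieces(sample, covariates)
  if (is.null(weights)) weights <- rep(1, length(pc$y))
  if (sum(pc$delta) < 1) {
    stop_convergence("all observations censored: cannot fit the model.")
  }
  res <- fit_wr_weighted(pc$y, pc$delta, pc$X, weights, init = init,
                         standardize = standardize)
  nm <- phi_names(pc$covariate_names)
  par <- setNames(res$par, nm)
  dimnames(res$hessian) <- list(nm, nm)
  if (!is.null(res$varcov)) dimnames(res$varcov) <- list(nm, nm)
  structure(
    list(
      shape = par[[1]],
      coef = par[-1],
      par = par,
      loglik = res$loglik,
      gradient = setNames(res$gradient, nm),
      hessian = res$hessian,
      varcov = res$varcov,
      iterations = res$iterations,
      step_halvings = res$step_halvings,
      converged = res$converged,
      covariate_names = pc$covariate_names,
      n = length(pc$y),
      n_events = sum(pc$delta),
      weights = weights,
      sample = sample
    ),
    class = "wr_fit"
  )
}

#' Intercept-plus-shape-only (null) censored Weibull fit
#'
#' The nested null model with every slope zero, used by the Wilks
#' simultaneous test and McFadden's R-squared.
#'
#' @inheritParams wr_fit
#' @return A `wr_fit` object with zero covariates.
#' @export
wr_null_fit <- function(sample, weights = NULL) {
  wr_fit(sample, covariates = character(0), weights = weights)
}

#' @export
print.wr_fit <- function(x, ...) {
  cat(sprintf("Censored Weibull regression (n = %d, events = %d)\n",
              x$n, x$n_events))
  cat(sprintf("  shape = %.4f, loglik = %.4f, converged = %s (%d iter)\n",
              x$shape, x$loglik, x$converged, x$iterations))
  print(round(x$coef, 4))
  invisible(x)
}

#' Tidy method for censored Weibull regression fits
#'
#' @param x A `wr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (shape first): `term`,
#'   `estimate`, `std.error`, `statistic` (Wald z), `p.value`.
#' @method tidy wr_fit
#' @export
tidy.wr_fit <- function(x, ...) {
  se <- if (is.null(x$varcov)) rep(NA_real_, length(x$par)) else
    sqrt(pmax(diag(x$varcov), 0))
  stat <- x$par / se
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pnorm(-abs(stat)))
  )
}

#' Glance method for censored Weibull regression fits
#'
#' @param x A `wr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `logLik`, `BIC` (\eqn{-2\ell + K
#'   \log n}), `df` (number of parameters K), `iterations`, `converged`.
#' @method glance wr_fit
#' @export
glance.wr_fit <- function(x, ...) {
  K <- length(x$par)
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    logLik = x$loglik,
    BIC = -2 * x$loglik + K * log(x$n),
    df = K,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Predicted regression functions of a Weibull regression model
#'
#' Evaluates the four regression functions of the fitted model at new
#' covariate rows and response values: survival
#' \eqn{S(y,x)=\exp[-y^\gamma e^{b^\top x}]}, distribution \eqn{F=1-S},
#' hazard \eqn{h(y,x)=\gamma y^{\gamma-1}e^{b^\top x}}, density
#' \eqn{f = h\,S} and mean \eqn{\mu(x)=\Gamma(1+1/\gamma)
#' \exp(-b^\top x/\gamma)}.
#'
#' @param object A `wr_fit` object (or any list with `shape` and `coef`).
#' @param newdata Data frame or matrix of covariate rows (the intercept is
#'   added automatically); default: the training covariates.
#' @param y Response values at which to evaluate (recycled against rows);
#'   default: the training censored responses.
#' @param ... Unused.
#' @return Tibble with columns `y`, `survival`, `cdf`, `hazard`, `density`,
#'   `mean`. `survival + cdf = 1` rowwise.
#' @export
predict.wr_fit <- function(object, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$sample$design[, c("(Intercept)", object$covariate_names),
                             drop = FALSE]
  } else {
    newdata <- as.data.frame(newdata)
    miss <- setdiff(object$covariate_names, names(newdata))
    if (length(miss) > 0) {
      stop_validation(paste0("newdata lacks covariate(s): ",
                             paste(miss, collapse = ", ")))
    }
    X <- cbind(1, as.matrix(newdata[object$covariate_names]))
  }
  if (is.null(y)) y <- object$sample$data$censored_response
  if (length(y) == 1L) y <- rep(y, nrow(X))
  if (length(y) != nrow(X)) stop_validation("`y` and `newdata` lengths differ.")
  wr_regression_functions(object$shape, object$coef, X, y)
}

# shared evaluator used by predict, site measures and curve export
wr_regression_functions <- function(shape, coef, X, y) {
  eta <- drop(X %*% coef)
  S <- exp(-y^shape * exp(eta))
  h <- shape * y^(shape - 1) * exp(eta)
  tibble::tibble(
    y = y,
    survival = S,
    cdf = 1 - S,
    hazard = h,
    density = h * S,
    mean = gamma(1 + 1 / shape) * exp(-eta / shape)
  )
}
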