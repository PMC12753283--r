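# Effect-ratio interpretation measures, mean-model linearization, per-site
# water-quality measures, and before/after covariate curves.

#' Effect ratios for a one-unit covariate increase
#'
#' Given a fitted (local or global) parameter set and an observation row,
#' computes the ratio of each regression function after versus before a
#' one-unit increase in covariate `k`, evaluated at the row's own (y, x):
#' \eqn{R_S} and \eqn{R_F} by direct evaluation of the survival and
#' distribution functions, the hazard ratio \eqn{R_h = e^{\hat b_k}}
#' (y-free, the proportional-hazards property), and the mean ratio
#' \eqn{R_\mu = e^{-\hat b_k/\hat\gamma}}.
#'
#' @param shape,coef Fitted shape and coefficient vector (intercept first),
#'   e.g. from a `wr_fit` or one element of `gwwr_fit$locals`.
#' @param x Covariate row (named, or ordered as `coef[-1]`).
#' @param y Response value at which \eqn{R_S, R_F} are evaluated.
#' @param k Covariate index (1..p) or name.
#' @param delta Size of the covariate increase (default 1 unit).
#' @return One-row tibble: `term`, `R_S`, `R_F`, `R_h`, `R_mu`.
#' @examples
#' effect_ratios(19.8865, c(-72.7466, 2.0556), x = c(0.3), y = 5, k = 1)
#' @export
effect_ratios <- function(shape, coef, x, y, k, delta = 1) {
  p <- length(coef) - 1L
  if (is.character(k)) k <- match(k, names(coef[-1]))
  if (is.na(k) || k < 1 || k > p) stop_validation("`k` must index a covariate.")
  x <- as.numeric(x)
  if (length(x) != p) stop_validation("`x` must have one value per covariate.")
  x1 <- x
  x1[k] <- x1[k] + delta
  X <- rbind(c(1, x), c(1, x1))
  fns <- wr_regression_functions(shape, coef, X, rep(y, 2))
  if (any(!is.finite(unlist(fns[c("survival", "cdf", "hazard", "mean")])))) {
    stop_validation("non-finite regression-function evaluation.")
  }
  bk <- coef[k + 1L]
  tibble::tibble(
    term = if (!is.null(names(coef))) names(coef)[k + 1L] else paste0("x", k),
    R_S = fns$survival[2] / fns$survival[1],
    R_F = fns$cdf[2] / fns$cdf[1],
    R_h = exp(delta * bk),
    R_mu = exp(-delta * bk / shape)
  )
}

#' Linearized mean-model coefficients
#'
#' The Weibull mean regression \eqn{\mu(x) = \Gamma(1+1/\gamma)
#' \exp(-b^\top x/\gamma)} factors into the constant
#' \eqn{\Gamma(1+1/\gamma)} and the exponent coefficient vector
#' \eqn{-b/\gamma}, the scale on which covariate effects on the expected
#' response read off directly.
#'
#' @param shape Fitted shape \eqn{\gamma}.
#' @param coef Fitted coefficient vector (intercept first).
#' @return List with `factor` (\eqn{\Gamma(1+1/\gamma)}) and `exponent_coef`
#'   (\eqn{-b/\gamma}, same names as `coef`).
#' @examples
#' mean_model_coefficients(19.8865, c(-72.7466, 2.0556, 30.1975, 0.8769, 2.5021))
#' @export
mean_model_coefficients <- function(shape, coef) {
  list(factor = gamma(1 + 1 / shape), exponent_coef = -coef / shape)
}

#' Per-site water-quality measures from a geographically weighted fit
#'
#' Evaluates the four local regression functions at each site's own
#' censored response and covariate row: improvement probability
#' \eqn{\hat S(y_i,x_i)}, degradation probability \eqn{\hat F = 1-\hat S},
#' degradation rate \eqn{\hat h(y_i,x_i)} and mean response
#' \eqn{\hat\mu(x_i)}; the regional summary row holds the arithmetic means
#' over sites.
#'
#' @param gwwr A `gwwr_fit` (failed sites are skipped with a warning).
#' @return Tibble with one row per converged site plus a final
#'   `site_id = "(regional average)"` row; columns `site_index`, `site_id`,
#'   `improvement_prob`, `degradation_prob`, `degradation_rate`,
#'   `mean_response`.
#' @export
site_measures <- function(gwwr) {
  pc <- sample_pieces(gwwr$sample, gwwr$covariate_names)
  ok <- which(!vapply(gwwr$locals, is.null, logical(1)))
  if (length(ok) < length(gwwr$locals)) {
    warn(sprintf("%d site(s) without a converged local fit skipped.",
                 length(gwwr$locals) - length(ok)))
  }
  rows <- purrr::map_dfr(ok, function(i) {
    lf <- gwwr$locals[[i]]
    fns <- wr_regression_functions(lf$shape, lf$coef,
                                   pc$X[i, , drop = FALSE], pc$y[i])
    tibble::tibble(
      site_index = i,
      site_id = gwwr$sample$data$site_id[i],
      improvement_prob = fns$survival,
      degradation_prob = fns$cdf,
      degradation_rate = fns$hazard,
      mean_response = fns$mean
    )
  })
  avg <- tibble::tibble(
    site_index = NA_integer_, site_id = "(regional average)",
    improvement_prob = mean(rows$improvement_prob),
    degradation_prob = mean(rows$degradation_prob),
    degradation_rate = mean(rows$degradation_rate),
    mean_response = mean(rows$mean_response)
  )
  dplyr::bind_rows(rows, avg)
}

#' Before/after covariate-increase curves
#'
#' Exports, over a grid of response values, the survival, distribution,
#' hazard and mean curves of a fitted (local or global) model before and
#' after a `delta`-unit increase in covariate `k` at a fixed covariate row —
#' the curves behind before/after effect displays.
#'
#' @inheritParams effect_ratios
#' @param y_grid Positive response grid.
#' @return Tibble with columns `y`, `when` ("before"/"after"), `survival`,
#'   `cdf`, `hazard`, `mean`.
#' @export
covariate_curves <- function(shape, coef, x, k, y_grid, delta = 1) {
  if (any(y_grid <= 0)) stop_validation("`y_grid` must be positive.")
  p <- length(coef) - 1L
  if (is.character(k)) k <- match(k, names(coef[-1]))
  if (is.na(k) || k < 1 || k > p) stop_validation("`k` must index a covariate.")
  x <- as.numeric(x)
  x1 <- x
  x1[k] <- x1[k] + delta
  one <- function(xrow, lab) {
    X <- matrix(rep(c(1, xrow), each = length(y_grid)), nrow = length(y_grid))
    fns <- wr_regression_functions(shape, coef, X, y_grid)
    dplyr::mutate(fns[, c("y", "survival", "cdf", "hazard", "mean")],
                  when = lab, .after = "y")
  }
  dplyr::bind_rows(one(x, "before"), one(x1, "after"))
}

#' Plot before/after covariate-increase curves
#'
#' @param curves Output of [covariate_curves()].
#' @param measure Which curve to draw: `"cdf"` (degradation probability),
#'   `"survival"`, `"hazard"` or `"mean"`.
#' @return A ggplot object.
#' @export
plot_covariate_curves <- function(curves,
                                  measure = c("cdf", "survival", "hazard", "mean")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$y, y = .data[[measure]],
                               colour = .data$when)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "response", y = measure, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Map of local coefficient estimates
#'
#' Draws the per-site estimates of a geographically weighted fit at their
#' coordinates, one facet per parameter.
#'
#' @param object A `gwwr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwwr_fit
#' @export
autoplot.gwwr_fit <- function(object, ...) {
  td <- tidy(object)
  xy <- tibble::tibble(site_index = seq_len(nrow(object$sample$data)),
                       u = object$sample$data$u, v = object$sample$data$v)
  td <- dplyr::left_join(td, xy, by = "site_index")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = "Local parameter estimates") +
    ggplot2::theme_minimal()
}
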