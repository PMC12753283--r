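# Local-model inference: similarity with the global model, simultaneous
# local-parameter test, per-site partial Wald tests, and factor grouping.

# local null (shape + intercept only) fit under the same weights
local_null_fit <- function(gwwr, i) {
  lf <- gwwr$locals[[i]]
  pc <- sample_pieces(gwwr$sample, character(0))
  fit_wr_weighted(pc$y, pc$delta, pc$X, lf$weights)
}

#' Similarity test: geographically weighted versus global model
#'
#' Tests whether location-varying coefficients improve on the single global
#' coefficient vector. The likelihood method uses \eqn{G = 2\sum_i
#' (\ell_{w_i}(\hat\phi(u_i)) - \ell_{w_i}(\hat\phi))}, where both
#' log-likelihoods at site i are evaluated under that site's kernel weights
#' (so each per-site gap compares nested parameterizations of the same
#' weighted likelihood). The quadratic-form method uses \eqn{G \approx
#' \sum_i C(u_i)} with \eqn{C(u_i) = [\hat B(u_i)-\hat B]^\top
#' [I_{F22}(u_i)]^{-1} [\hat B(u_i)-\hat B]} over the slope vectors. The
#' reference distribution is chi-square with df = n p.
#'
#' @param gwwr A `gwwr_fit`.
#' @param alpha Significance level.
#' @param method `"quadratic_form"` (default; its ingredients are the
#'   tabulated per-site estimates and variances) or `"likelihood"`.
#' @return One-row test tibble as in [wilks_test()].
#' @export
similarity_test <- function(gwwr, alpha = 0.05,
                            method = c("quadratic_form", "likelihood")) {
  method <- match.arg(method)
  p <- length(gwwr$covariate_names)
  if (p < 1) stop_validation("the fitted model has no covariates to test.")
  ok <- which(!vapply(gwwr$locals, is.null, logical(1)))
  if (method == "likelihood") {
    pc <- sample_pieces(gwwr$sample, gwwr$covariate_names)
    G <- sum(vapply(ok, function(i) {
      lf <- gwwr$locals[[i]]
      lg <- wr_core(unname(gwwr$global$par), pc$y, pc$delta, pc$X,
                    lf$weights)$loglik
      2 * (lf$loglik - lg)
    }, numeric(1)))
  } else {
    B <- gwwr$global$coef[-1]
    G <- sum(vapply(ok, function(i) {
      lf <- gwwr$locals[[i]]
      Bi <- lf$coef[-1]
      V22 <- lf$varcov[-(1:2), -(1:2), drop = FALSE]
      drop(t(Bi - B) %*% solve(V22, Bi - B))
    }, numeric(1)))
  }
  df <- length(ok) * p
  test_result("similarity (GWWR vs WR)", G, df,
              pchisq(G, df = df, lower.tail = FALSE), alpha, method)
}

#' Simultaneous test of the local regression coefficients
#'
#' Tests \eqn{H_0: b_k(u_i) = 0} for all k and i. The likelihood method sums
#' per-site Wilks statistics \eqn{2(\ell_{w_i}(\hat\phi(u_i)) -
#' \ell_{w_i}(\hat\phi_0(u_i)))} against the site-specific null fit (shape
#' and intercept only, same weights); the quadratic-form method sums
#' \eqn{C_w(u_i) = \hat B^\top(u_i) [I_{F22}(u_i)]^{-1} \hat B(u_i)}.
#' Chi-square reference with df = n p.
#'
#' @inheritParams similarity_test
#' @return One-row test tibble.
#' @export
simultaneous_test <- function(gwwr, alpha = 0.05,
                              method = c("quadratic_form", "likelihood")) {
  method <- match.arg(method)
  p <- length(gwwr$covariate_names)
  if (p < 1) stop_validation("the fitted model has no covariates to test.")
  ok <- which(!vapply(gwwr$locals, is.null, logical(1)))
  if (method == "likelihood") {
    G <- sum(vapply(ok, function(i) {
      lf <- gwwr$locals[[i]]
      nf <- local_null_fit(gwwr, i)
      max(2 * (lf$loglik - nf$loglik), 0)
    }, numeric(1)))
  } else {
    G <- sum(vapply(ok, function(i) {
      lf <- gwwr$locals[[i]]
      Bi <- lf$coef[-1]
      V22 <- lf$varcov[-(1:2), -(1:2), drop = FALSE]
      drop(t(Bi) %*% solve(V22, Bi))
    }, numeric(1)))
  }
  df <- length(ok) * p
  test_result("simultaneous (local)", G, df,
              pchisq(G, df = df, lower.tail = FALSE), alpha, method)
}

#' Per-site partial Wald tests of the local coefficients
#'
#' For every site and covariate, \eqn{W_k(u_i) = \hat b_k(u_i) /
#' \sqrt{\mathrm{var}(\hat b_k(u_i))}} with the variance from the local
#' inverse observed information, compared two-sided against the standard
#' normal.
#'
#' @param gwwr A `gwwr_fit`.
#' @param alpha Significance level.
#' @param include_intercept Include intercept rows? Default `FALSE`: the
#'   per-site significant-covariate sets are defined over the covariates.
#' @return Tibble with one row per (site, term): `site_index`, `site_id`,
#'   `term`, `estimate`, `std.error`, `statistic`, `p_value`, `significant`.
#' @export
local_wald_tests <- function(gwwr, alpha = 0.05, include_intercept = FALSE) {
  out <- purrr::map_dfr(seq_along(gwwr$locals), function(i) {
    lf <- gwwr$locals[[i]]
    if (is.null(lf)) return(NULL)
    est <- lf$coef
    v <- diag(lf$varcov)[-1]
    bad <- v <= 0
    se <- sqrt(ifelse(bad, NA_real_, v))
    q <- est / se
    tibble::tibble(
      site_index = i, site_id = gwwr$sample$data$site_id[i],
      term = names(est), estimate = unname(est), std.error = unname(se),
      statistic = unname(q), p_value = unname(2 * pnorm(-abs(q))),
      significant = unname(2 * pnorm(-abs(q)) < alpha)
    )
  })
  if (!include_intercept) out <- out[out$term != "(Intercept)", ]
  out
}

#' Group sites by their significant-covariate sets
#'
#' Partitions the sites of a [local_wald_tests()] table by identical sets of
#' significant covariates, the basis for mapping locally influential factors.
#'
#' @param table Output of [local_wald_tests()] (intercept rows ignored).
#' @return List with `sites` (tibble: site_index, site_id, significant_set)
#'   and `groups` (tibble: group, significant_set, n_sites, site_ids), both
#'   deterministically ordered (groups by decreasing size, then set label).
#' @export
factor_groups <- function(table) {
  tab <- table[table$term != "(Intercept)", ]
  sets <- tab |>
    dplyr::group_by(.data$site_index, .data$site_id) |>
    dplyr::summarise(
      significant_set = paste(sort(.data$term[.data$significant %in% TRUE]),
                              collapse = ","),
      .groups = "drop") |>
    dplyr::arrange(.data$site_index)
  groups <- sets |>
    dplyr::count(.data$significant_set, name = "n_sites") |>
    dplyr::arrange(dplyr::desc(.data$n_sites), .data$significant_set)
  groups$group <- seq_len(nrow(groups))
  groups <- dplyr::left_join(
    groups,
    sets |>
      dplyr::group_by(.data$significant_set) |>
      dplyr::summarise(site_ids = list(.data$site_id), .groups = "drop"),
    by = "significant_set")
  list(sites = sets,
       groups = groups[, c("group", "significant_set", "n_sites", "site_ids")])
}
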