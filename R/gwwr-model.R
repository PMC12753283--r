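# Geographically weighted censored Weibull regression: kernels, per-site
# adaptive bandwidth search by BIC, and locally weighted Newton fits.

#' Pairwise distances between sites
#'
#' Euclidean by default. The `"greatcircle"` mode treats the columns as
#' longitude/latitude degrees and returns haversine distances in kilometres
#' (via the geosphere package); it exists for analysts whose coordinates are
#' geographic, but the default everywhere in the package is planar.
#'
#' @param coords n x 2 matrix of coordinates.
#' @param method `"euclidean"` (default) or `"greatcircle"`.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords, method = c("euclidean", "greatcircle")) {
  method <- match.arg(method)
  if (any(!is.finite(coords))) stop_validation("coordinates must be finite.")
  if (method == "euclidean") return(as.matrix(stats::dist(coords)))
  if (!requireNamespace("geosphere", quietly = TRUE)) {
    stop_validation("the greatcircle mode needs the geosphere package.")
  }
  geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
}

#' Spatial kernel weights
#'
#' Adaptive Gaussian kernel \eqn{w_{ij} = \exp[-\tfrac12 (d_{ij}/a_i)^2]} or
#' compact-support bi-square kernel \eqn{w_{ij} = [1-(d_{ij}/a_i)^2]^2} for
#' \eqn{d_{ij}\le a_i}, else 0. An infinite bandwidth gives unit weights for
#' both kernels, reducing the local model to the global one.
#'
#' @param distances Nonnegative distances from the focal site.
#' @param bandwidth Positive bandwidth \eqn{a_i}, possibly `Inf`.
#' @param kind `"gaussian"` or `"bisquare"`.
#' @return Weights in \[0, 1\], 1 at distance 0.
#' @examples
#' kernel_weights(c(0, 1, 2), bandwidth = 1, kind = "gaussian")
#' kernel_weights(c(0, 0.5, 2), bandwidth = 1, kind = "bisquare")
#' @export
kernel_weights <- function(distances, bandwidth, kind = c("gaussian", "bisquare")) {
  kind <- match.arg(kind)
  if (any(distances < 0)) stop_validation("distances must be nonnegative.")
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop_validation("`bandwidth` must be positive (possibly Inf).")
  }
  if (is.infinite(bandwidth)) return(rep(1, length(distances)))
  r <- distances / bandwidth
  if (kind == "gaussian") exp(-0.5 * r^2) else ifelse(r <= 1, (1 - r^2)^2, 0)
}

#' Kernel and bandwidth-search configuration
#'
#' @param kind Kernel family, `"gaussian"` (default) or `"bisquare"`.
#' @param bandwidth_mode `"per_site_bic"` (default: each site searches its
#'   own bandwidth grid for the minimum-BIC candidate) or `"fixed"`.
#' @param fixed_bandwidth Bandwidth used when `bandwidth_mode = "fixed"`
#'   (possibly `Inf`, which reproduces the global fit at every site).
#' @param n_candidates Number of log-spaced finite candidates per site
#'   when no explicit grid is given.
#' @param candidate_grid Optional explicit vector of positive candidate
#'   bandwidths (sorted internally).
#' @param include_infinite Add the infinite (all-weights-1) candidate to the
#'   grid? Default `TRUE`: a site whose likelihood prefers pooling all
#'   observations can select the global fit.
#' @param bic_n Sample size entering the local BIC penalty: `"full"`
#'   (default; the full n, the criterion as published) or `"effective"`
#'   (the kernel mass \eqn{\sum_j w_{ij}}).
#' @param distance Distance mode passed to [pairwise_distances()].
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(kind = c("gaussian", "bisquare"),
                          bandwidth_mode = c("per_site_bic", "fixed"),
                          fixed_bandwidth = Inf,
                          n_candidates = 40L,
                          candidate_grid = NULL,
                          include_infinite = TRUE,
                          bic_n = c("full", "effective"),
                          distance = c("euclidean", "greatcircle")) {
  kind <- match.arg(kind)
  bandwidth_mode <- match.arg(bandwidth_mode)
  bic_n <- match.arg(bic_n)
  distance <- match.arg(distance)
  if (!is.null(candidate_grid)) {
    if (any(candidate_grid <= 0)) stop_validation("candidate bandwidths must be positive.")
    candidate_grid <- sort(unique(candidate_grid))
  }
  structure(list(kind = kind, bandwidth_mode = bandwidth_mode,
                 fixed_bandwidth = fixed_bandwidth,
                 n_candidates = as.integer(n_candidates),
                 candidate_grid = candidate_grid,
                 include_infinite = include_infinite,
                 bic_n = bic_n, distance = distance),
            class = "kernel_config")
}

# Default per-site grid: log-spaced from the (p+2)-th nearest-neighbour
# distance to twice the max pairwise distance, plus Inf when configured.
site_bandwidth_grid <- function(dist_row, p, config, dmax) {
  if (!is.null(config$candidate_grid)) {
    grid <- config$candidate_grid
  } else {
    nn <- sort(dist_row)
    lo <- nn[min(length(nn), p + 2L)]
    if (!is.finite(lo) || lo <= 0) lo <- max(dmax * 1e-3, 1e-8)
    hi <- 2 * dmax
    grid <- exp(seq(log(lo), log(hi), length.out = config$n_candidates))
  }
  if (config$include_infinite) grid <- c(grid, Inf)
  grid
}

#' Locally weighted censored Weibull fit at one site
#'
#' Maximizes the kernel-weighted local log-likelihood (the global likelihood
#' with weights \eqn{w_{ij}}) by the same damped Newton-Raphson as
#' [wr_fit()], warm-started from the global estimate. The local BIC is
#' \eqn{-2\ell(\hat\phi(u_i)) + K\log n} with K = p + 2 and n the full
#' sample size.
#'
#' @param sample A [spatial_sample()] object.
#' @param site_index Focal site (1..n).
#' @param bandwidth Positive bandwidth, possibly `Inf`.
#' @param config A [kernel_config()].
#' @param global A `wr_fit` used as warm start (fit on demand if omitted).
#' @param covariates Covariate subset (default all).
#' @return A `local_fit` list: `site_index`, `bandwidth`, `weights`, `par`,
#'   `shape`, `coef`, `loglik`, `varcov`, `bic`, `converged`, `iterations`.
#' @export
local_fit <- function(sample, site_index, bandwidth, config = kernel_config(),
                      global = NULL, covariates = NULL) {
  pc <- sample_pieces(sample, covariates)
  n <- length(pc$y)
  D <- pairwise_distances(sample$coords, config$distance)
  w <- kernel_weights(D[site_index, ], bandwidth, config$kind)
  p <- length(pc$covariate_names)
  if (sum(w * pc$delta) < p + 2) {
    stop_convergence(sprintf(
      "site %d: bandwidth %g under-identified (weighted events %.2f < %d).",
      site_index, bandwidth, sum(w * pc$delta), p + 2L))
  }
  if (is.null(global)) global <- wr_fit(sample, covariates = covariates)
  res <- fit_wr_weighted(pc$y, pc$delta, pc$X, w, init = unname(global$par))
  nm <- phi_names(pc$covariate_names)
  par <- setNames(res$par, nm)
  if (!is.null(res$varcov)) dimnames(res$varcov) <- list(nm, nm)
  structure(
    list(site_index = site_index, bandwidth = bandwidth, weights = w,
         par = par, shape = par[[1]], coef = par[-1], loglik = res$loglik,
         gradient = setNames(res$gradient, nm), varcov = res$varcov,
         bic = -2 * res$loglik +
           (p + 2) * log(if (config$bic_n == "effective") sum(w) else n),
         converged = res$converged, iterations = res$iterations),
    class = "local_fit"
  )
}

#' Per-site adaptive bandwidth search by BIC
#'
#' Evaluates every candidate bandwidth of the site's grid, fitting the local
#' model at each eligible candidate, and returns the bandwidth minimizing the
#' local BIC \eqn{-2\ell(\hat\phi(u_i)) + K\log n}. Ties break toward the
#' larger bandwidth. Candidates whose weighted event mass falls below p + 2
#' are under-identified and skipped.
#'
#' @inheritParams local_fit
#' @return List with `bandwidth` (the argmin) and `trace`, a tibble of
#'   (bandwidth, bic, converged, eligible) over the grid.
#' @export
optimize_bandwidth <- function(sample, site_index, config = kernel_config(),
                               global = NULL, covariates = NULL) {
  pc <- sample_pieces(sample, covariates)
  p <- length(pc$covariate_names)
  D <- pairwise_distances(sample$coords, config$distance)
  grid <- site_bandwidth_grid(D[site_index, ], p, config,
                              dmax = max(D))
  if (is.null(global)) global <- wr_fit(sample, covariates = covariates)
  rows <- purrr::map(grid, function(a) {
    w <- kernel_weights(D[site_index, ], a, config$kind)
    if (sum(w * pc$delta) < p + 2) {
      return(tibble::tibble(bandwidth = a, bic = NA_real_,
                            converged = NA, eligible = FALSE))
    }
    lf <- tryCatch(local_fit(sample, site_index, a, config, global, covariates),
                   error = function(e) NULL)
    if (is.null(lf)) {
      tibble::tibble(bandwidth = a, bic = NA_real_, converged = FALSE,
                     eligible = TRUE)
    } else {
      tibble::tibble(bandwidth = a, bic = lf$bic, converged = lf$converged,
                     eligible = TRUE)
    }
  })
  trace <- dplyr::bind_rows(rows)
  ok <- trace[trace$eligible & !is.na(trace$bic) & trace$converged %in% TRUE, ]
  if (nrow(ok) == 0) {
    stop_convergence(sprintf("site %d: no eligible bandwidth candidate.",
                             site_index))
  }
  best <- max(ok$bandwidth[ok$bic <= min(ok$bic) + 1e-10])
  list(bandwidth = best, trace = trace)
}

#' Fit the geographically weighted censored Weibull regression model
#'
#' Runs, for every site, the per-site adaptive bandwidth search
#' ([optimize_bandwidth()]) followed by the locally weighted fit
#' ([local_fit()]), all warm-started from the global fit. Deterministic
#' given the sample and configuration. Individual site failures are recorded
#' and the fit only aborts when more than 20% of sites fail.
#'
#' @param sample A [spatial_sample()] object.
#' @param config A [kernel_config()].
#' @param covariates Covariate subset (default all).
#' @param global Optional precomputed global `wr_fit` on the same covariates.
#' @return A `gwwr_fit` object: list with `locals` (per-site `local_fit`s,
#'   `NULL` where failed), `estimates` (tibble: site_id, bandwidth, shape,
#'   coefficients, loglik, bic, converged), `global` (`wr_fit`), `config`,
#'   `sample`, `failed` (integer sites). Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' s <- simulate_sites(sim_config(n_sites = 25, p = 1, seed = 11))$sample
#' fit <- gwwr_fit(s, kernel_config(n_candidates = 8))
#' tidy(fit)
#' @export
gwwr_fit <- function(sample, config = kernel_config(), covariates = NULL,
                     global = NULL) {
  if (is.null(global)) global <- wr_fit(sample, covariates = covariates)
  n <- nrow(sample$data)
  locals <- vector("list", n)
  for (i in seq_len(n)) {
    locals[[i]] <- tryCatch({
      a <- if (config$bandwidth_mode == "fixed") config$fixed_bandwidth else
        optimize_bandwidth(sample, i, config, global, covariates)$bandwidth
      local_fit(sample, i, a, config, global, covariates)
    }, error = function(e) NULL)
  }
  failed <- which(vapply(locals, is.null, logical(1)))
  if (length(failed) > 0.2 * n) {
    stop_convergence(sprintf("%d of %d local fits failed.", length(failed), n))
  }
  est <- purrr::map_dfr(seq_len(n), function(i) {
    lf <- locals[[i]]
    if (is.null(lf)) {
      return(tibble::tibble(site_index = i, site_id = sample$data$site_id[i],
                            bandwidth = NA_real_, converged = FALSE))
    }
    row <- tibble::tibble(site_index = i, site_id = sample$data$site_id[i],
                          bandwidth = lf$bandwidth, converged = lf$converged,
                          shape = lf$shape, loglik = lf$loglik, bic = lf$bic)
    coefs <- tibble::as_tibble(as.list(lf$coef))
    dplyr::bind_cols(row, coefs)
  })
  structure(
    list(locals = locals, estimates = est, global = global, config = config,
         sample = sample, failed = failed,
         covariate_names = global$covariate_names),
    class = "gwwr_fit"
  )
}

#' @export
print.gwwr_fit <- function(x, ...) {
  cat(sprintf(
    "Geographically weighted Weibull regression: %d sites, %d covariate(s), %s kernel\n",
    nrow(x$estimates), length(x$covariate_names), x$config$kind))
  if (length(x$failed) > 0) {
    cat("  failed sites:", paste(x$failed, collapse = ", "), "\n")
  }
  print(x$estimates, ...)
  invisible(x)
}

#' Tidy method for geographically weighted fits
#'
#' @param x A `gwwr_fit` object.
#' @param ... Unused.
#' @return Long tibble with one row per (site, parameter): `site_index`,
#'   `site_id`, `bandwidth`, `term`, `estimate`, `std.error`.
#' @method tidy gwwr_fit
#' @export
tidy.gwwr_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$locals), function(i) {
    lf <- x$locals[[i]]
    if (is.null(lf)) return(NULL)
    se <- if (is.null(lf$varcov)) rep(NA_real_, length(lf$par)) else
      sqrt(pmax(diag(lf$varcov), 0))
    tibble::tibble(site_index = i, site_id = x$sample$data$site_id[i],
                   bandwidth = lf$bandwidth, term = names(lf$par),
                   estimate = unname(lf$par), std.error = unname(se))
  })
}

#' Glance method for geographically weighted fits
#'
#' @param x A `gwwr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n_sites`, `n_failed`, `median_bandwidth`,
#'   `n_infinite_bandwidth`, plus the model-level goodness-of-fit columns of
#'   [gof_report()].
#' @method glance gwwr_fit
#' @export
glance.gwwr_fit <- function(x, ...) {
  bw <- x$estimates$bandwidth
  dplyr::bind_cols(
    tibble::tibble(
      n_sites = nrow(x$estimates),
      n_failed = length(x$failed),
      median_bandwidth = stats::median(bw[is.finite(bw)], na.rm = TRUE),
      n_infinite_bandwidth = sum(is.infinite(bw), na.rm = TRUE)
    ),
    gof_report(x)
  )
}
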