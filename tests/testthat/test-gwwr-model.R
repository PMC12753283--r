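test_that("pairwise distances are Euclidean, symmetric and zero-diagonal", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(4)
  pts <- matrix(runif(20), 10, 2)
  D <- pairwise_distances(pts)
  expect_equal(diag(D), rep(0, 10), ignore_attr = TRUE)
  expect_equal(D, t(D))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)), tolerance = 1e-12)
  }
})

test_that("kernel weights follow their closed forms and decay monotonely", {
  expect_equal(kernel_weights(0, 1, "gaussian"), 1)
  expect_equal(kernel_weights(0, 1, "bisquare"), 1)
  expect_equal(kernel_weights(2, 2, "gaussian"), exp(-0.5))
  expect_equal(kernel_weights(1 / sqrt(2), 1, "bisquare"), 0.25)
  expect_equal(kernel_weights(1.01, 1, "bisquare"), 0)
  # infinite bandwidth pools everything
  expect_equal(kernel_weights(c(0, 5, 50), Inf, "gaussian"), rep(1, 3))
  d <- seq(0, 3, by = 0.1)
  for (kind in c("gaussian", "bisquare")) {
    w <- kernel_weights(d, 1.3, kind)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(kernel_weights(-1, 1), class = "gwwr_validation_error")
})

test_that("unit weights reduce the local likelihood to the global one", {
  s <- toy_sample(n = 20, seed = 61)
  phi <- c(2, -3, 0.5, 0.1)
  w1 <- rep(1, 20)
  expect_equal(wr_loglik(phi[1], phi[-1], s, weights = w1),
               wr_loglik(phi[1], phi[-1], s), tolerance = 1e-12)
  # integer weight 2 equals duplicating the row
  w2 <- w1; w2[7] <- 2
  dup <- s$data[c(1:20, 7), ]
  sdup <- spatial_sample(
    tibble::tibble(site_id = as.character(1:21), u = dup$u, v = dup$v,
                   y = dup$response, x1 = dup$x1, x2 = dup$x2),
    threshold = s$threshold)
  expect_equal(wr_loglik(phi[1], phi[-1], s, weights = w2),
               wr_loglik(phi[1], phi[-1], sdup), tolerance = 1e-10)
})

test_that("weighted gradient and Hessian match finite differences", {
  s <- toy_sample(n = 25, seed = 71)
  set.seed(8)
  w <- runif(25)
  for (r in 1:5) {
    phi <- c(runif(1, 0.8, 4), -2 + runif(3, -0.5, 0.5))
    f <- function(p) wr_loglik(p[1], p[-1], s, weights = w)
    expect_equal(unname(wr_gradient(phi[1], phi[-1], s, weights = w)),
                 fd_gradient(f, phi), tolerance = 1e-4)
    H_fd <- fd_jacobian(function(p)
      unname(wr_gradient(p[1], p[-1], s, weights = w)), phi)
    expect_equal(unname(wr_hessian(phi[1], phi[-1], s, weights = w)),
                 (H_fd + t(H_fd)) / 2, tolerance = 1e-3)
  }
})

test_that("bisquare compact support zeroes far rows exactly", {
  s <- toy_sample(n = 30, seed = 81)
  D <- pairwise_distances(s$coords)
  a <- stats::median(D[1, ])
  w <- kernel_weights(D[1, ], a, "bisquare")
  far <- D[1, ] > a
  expect_true(any(far))
  phi <- c(2, -3, 0.2, 0.1)
  # dropping the zero-weight rows changes nothing
  keep <- which(!far)
  skeep <- spatial_sample(
    tibble::tibble(site_id = s$data$site_id[keep], u = s$data$u[keep],
                   v = s$data$v[keep], y = s$data$response[keep],
                   x1 = s$data$x1[keep], x2 = s$data$x2[keep]),
    threshold = s$threshold)
  expect_equal(wr_loglik(phi[1], phi[-1], s, weights = w),
               wr_loglik(phi[1], phi[-1], skeep, weights = w[keep]),
               tolerance = 1e-12)
})

test_that("infinite bandwidth reproduces the global fit at any site", {
  s <- toy_sample(n = 40, seed = 91)
  global <- wr_fit(s)
  lf <- local_fit(s, site_index = 13, bandwidth = Inf, global = global)
  expect_equal(unname(lf$par), unname(global$par), tolerance = 1e-8)
  # very large finite bandwidth converges to the same place
  lf2 <- local_fit(s, site_index = 13,
                   bandwidth = 1e6 * max(pairwise_distances(s$coords)),
                   global = global)
  expect_equal(unname(lf2$par), unname(global$par), tolerance = 1e-6)
  # local optimum beats the global parameters under the same weights
  expect_gte(lf$loglik + 1e-8,
             wr_loglik(global$shape, global$coef, s, weights = lf$weights))
})

test_that("bandwidth search returns the BIC argmin over the grid", {
  s <- toy_sample(n = 30, seed = 101)
  global <- wr_fit(s)
  cfg <- kernel_config(n_candidates = 10)
  res <- optimize_bandwidth(s, 5, cfg, global)
  tr <- res$trace[res$trace$eligible & res$trace$converged %in% TRUE, ]
  expect_true(all(tr$bic[tr$bandwidth == res$bandwidth][1] <= tr$bic + 1e-10))
  # exhaustive re-evaluation through independent local fits
  for (i in seq_len(nrow(tr))) {
    lf <- local_fit(s, 5, tr$bandwidth[i], cfg, global)
    expect_equal(lf$bic, tr$bic[i], tolerance = 1e-8)
  }
  # single-candidate grid returns that candidate
  one <- kernel_config(candidate_grid = 0.9, include_infinite = FALSE)
  expect_equal(optimize_bandwidth(s, 5, one, global)$bandwidth, 0.9)
})

test_that("bandwidth selection respects the identifiability floor", {
  # the per-site BIC rewards compact kernels, so the weighted-event floor
  # (>= p + 2) is the binding constraint; the chosen bandwidth must always
  # satisfy it and must be the trace argmin among converged candidates
  cfg0 <- sim_config(n_sites = 60, p = 1,
                     shape_surface = surface_spec("constant", value = 4),
                     coefficient_surfaces = list(
                       surface_spec("constant", value = log(1.5) - 4 * log(6)),
                       surface_spec("constant", value = 0.5)))
  kc <- kernel_config(n_candidates = 8)
  for (r in 1:5) {
    cfg0$seed <- 1000L + r
    s <- simulate_sites(cfg0)$sample
    global <- wr_fit(s)
    res <- optimize_bandwidth(s, 1, kc, global)
    D <- pairwise_distances(s$coords)
    w <- kernel_weights(D[1, ], res$bandwidth, "gaussian")
    expect_gte(sum(w * s$data$delta), 1 + 2)
    ok <- res$trace[res$trace$eligible & res$trace$converged %in% TRUE, ]
    expect_equal(min(ok$bic), ok$bic[ok$bandwidth == res$bandwidth][1],
                 tolerance = 1e-10)
  }
})

test_that("full fit is deterministic and a forced unit-weight fit is global", {
  sim <- river_fixture(2)
  s <- sim$sample
  covs <- c("fe", "phosphate", "temperature", "bod")
  forced <- kernel_config(bandwidth_mode = "fixed", fixed_bandwidth = Inf)
  g1 <- gwwr_fit(s, forced, covariates = covs)
  for (lf in g1$locals) {
    expect_equal(unname(lf$par), unname(g1$global$par), tolerance = 1e-8)
  }
  kc <- kernel_config(n_candidates = 10)
  g2 <- gwwr_fit(s, kc, covariates = covs)
  g3 <- gwwr_fit(s, kc, covariates = covs)
  expect_identical(g2$estimates, g3$estimates)
})

test_that("a drifting coefficient surface is recovered across sites", {
  sim <- simulate_sites(spatial_config(n_sites = 80, seed = 1234))
  s <- sim$sample
  g <- gwwr_fit(s, kernel_config(n_candidates = 15))
  est <- g$estimates$x1
  truth <- sim$truth$b1_true
  keep <- g$estimates$converged
  expect_gt(cor(est[keep], truth[keep]), 0.7)
})

test_that("optional config flags change the advertised quantities", {
  # effective-sample-size BIC penalty uses the kernel mass
  s <- toy_sample(n = 30, seed = 111)
  global <- wr_fit(s)
  cfg_eff <- kernel_config(bic_n = "effective")
  lf <- local_fit(s, 3, bandwidth = 0.5, config = cfg_eff, global = global)
  expect_equal(lf$bic, -2 * lf$loglik + 4 * log(sum(lf$weights)),
               tolerance = 1e-10)
  lf_full <- local_fit(s, 3, bandwidth = 0.5, global = global)
  expect_equal(lf_full$bic, -2 * lf_full$loglik + 4 * log(30),
               tolerance = 1e-10)
  # great-circle distances: one degree of longitude at the equator
  D <- pairwise_distances(rbind(c(0, 0), c(1, 0)), method = "greatcircle")
  expect_equal(D[1, 2], 111.2, tolerance = 0.01)
})
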