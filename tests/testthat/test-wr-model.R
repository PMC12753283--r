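one_row_sample <- function(y, threshold = 6) {
  spatial_sample(tibble::tibble(site_id = "a", u = 0, v = 0, y = y),
                 threshold = threshold, covariates = character(0))
}

test_that("log-likelihood matches hand-computed single-observation values", {
  # event at y = 1 with gamma = 1, b0 = 0: 0 + 0 + 0 - 1
  expect_equal(wr_loglik(1, 0, one_row_sample(1)), -1)
  # censored at y* = 2 (raw y above): pure survival term -y^gamma e^b0
  expect_equal(wr_loglik(1, 0, one_row_sample(5, threshold = 2)), -2)
})

test_that("log-likelihood is additive over observations", {
  s <- toy_sample(n = 10, seed = 21)
  phi_b <- c(-3, 0.4, 0.2)
  total <- wr_loglik(2.5, phi_b, s)
  per_row <- vapply(seq_len(10), function(i) {
    df <- s$data[i, ]
    si <- spatial_sample(
      tibble::tibble(site_id = df$site_id, u = df$u, v = df$v,
                     y = df$response, x1 = df$x1, x2 = df$x2),
      threshold = s$threshold)
    wr_loglik(2.5, phi_b, si)
  }, numeric(1))
  expect_equal(total, sum(per_row), tolerance = 1e-10)
})

test_that("analytic gradient and Hessian match finite differences", {
  s <- toy_sample(n = 30, seed = 8)
  set.seed(33)
  for (r in 1:20) {
    phi <- c(runif(1, 0.5, 5), runif(3, -1, 1) + c(-2, 0, 0))
    f <- function(p) wr_loglik(p[1], p[-1], s)
    g_an <- unname(wr_gradient(phi[1], phi[-1], s))
    g_fd <- fd_gradient(f, phi)
    expect_equal(g_an, g_fd, tolerance = 1e-4)
    H_an <- unname(wr_hessian(phi[1], phi[-1], s))
    H_fd <- fd_jacobian(function(p) unname(wr_gradient(p[1], p[-1], s)), phi)
    H_fd <- (H_fd + t(H_fd)) / 2
    expect_equal(H_an, H_fd, tolerance = 1e-3)
  }
})

test_that("gradient vanishes at the exponential score solution", {
  s <- toy_sample(n = 40, seed = 9)
  b0 <- log(sum(s$data$delta) / sum(s$data$censored_response))
  g <- wr_gradient(1, c(b0, 0, 0), s)
  expect_equal(unname(g["(Intercept)"]), 0, tolerance = 1e-10)
})

test_that("slope block of the Hessian is negative semidefinite under full events", {
  s <- toy_sample(n = 25, seed = 14, threshold = 1e6) # nothing censored
  set.seed(77)
  for (r in 1:20) {
    phi <- c(runif(1, 0.5, 4), runif(3, -2, 1))
    H <- wr_hessian(phi[1], phi[-1], s)
    Hbb <- H[-1, -1]
    expect_lte(max(eigen(Hbb, symmetric = TRUE, only.values = TRUE)$values),
               1e-8)
  }
})

test_that("maximum likelihood recovers simulated global parameters", {
  cfg <- sim_config(
    n_sites = 400, p = 1,
    shape_surface = surface_spec("constant", value = 5),
    coefficient_surfaces = list(surface_spec("constant", value = -10),
                                surface_spec("constant", value = 0.8)),
    seed = 2024)
  s <- simulate_sites(cfg)$sample
  fit <- wr_fit(s)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  se <- sqrt(diag(fit$varcov))
  expect_lt(abs(fit$shape - 5), 3 * se[1])
  expect_lt(abs(fit$coef[1] - (-10)), 3 * se[2])
  expect_lt(abs(fit$coef[2] - 0.8), 3 * se[3])
  # the optimum beats random nearby parameter points
  set.seed(5)
  for (r in 1:100) {
    pert <- fit$par + runif(3, -0.1, 0.1)
    if (pert[1] <= 0) next
    expect_gte(fit$loglik, wr_loglik(pert[1], pert[-1], s) - 1e-8)
  }
})

test_that("the null fit is nested and matches a covariate-free fit", {
  s <- toy_sample(n = 60, seed = 31)
  full <- wr_fit(s)
  null <- wr_null_fit(s)
  expect_lte(null$loglik, full$loglik + 1e-8)
  alt <- wr_fit(s, covariates = character(0))
  expect_equal(null$par, alt$par, tolerance = 1e-10)
})

test_that("all-censored input is an estimation error", {
  df <- tibble::tibble(site_id = as.character(1:5), u = runif(5), v = runif(5),
                       y = c(7, 8, 9, 6.5, 7.2), x1 = rnorm(5))
  s <- spatial_sample(df, threshold = 6)
  expect_error(wr_fit(s), class = "gwwr_convergence_error")
})

test_that("predictions satisfy the functional identities", {
  s <- toy_sample(n = 50, seed = 12)
  fit <- wr_fit(s)
  pr <- predict(fit)
  expect_equal(pr$survival + pr$cdf, rep(1, nrow(pr)), tolerance = 1e-12)
  expect_equal(pr$density, pr$hazard * pr$survival, tolerance = 1e-10)
  expect_true(all(pr$mean > 0))
  expect_error(predict(fit, newdata = data.frame(zz = 1)),
               class = "gwwr_validation_error")
})

test_that("rescaling a covariate rescales its coefficient only", {
  s <- toy_sample(n = 80, seed = 55)
  fit1 <- wr_fit(s)
  s2 <- s
  s2$data$x1 <- s$data$x1 * 10
  s2$design[, "x1"] <- s$design[, "x1"] * 10
  fit2 <- wr_fit(s2)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
  expect_equal(fit2$shape, fit1$shape, tolerance = 1e-6)
  expect_equal(unname(fit2$coef["x1"]), unname(fit1$coef["x1"]) / 10,
               tolerance = 1e-6)
  expect_equal(unname(fit2$coef["x2"]), unname(fit1$coef["x2"]),
               tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom shape", {
  s <- toy_sample(n = 50, seed = 3)
  fit <- wr_fit(s)
  td <- tidy(fit)
  expect_equal(td$term, c("shape", "(Intercept)", "x1", "x2"))
  expect_equal(td$statistic, td$estimate / td$std.error)
  gl <- glance(fit)
  expect_equal(gl$BIC, -2 * fit$loglik + 4 * log(50))
})

test_that("estimates agree with an independent AFT parametrization fit", {
  # survreg fits log(T) = mu + sigma * W: shape = 1/sigma and the
  # rate-scale coefficients satisfy b = -coef(survreg) / sigma
  s <- toy_sample(n = 150, seed = 99)
  fit <- wr_fit(s)
  sv <- survival::survreg(
    survival::Surv(s$data$censored_response, s$data$delta) ~ x1 + x2,
    data = s$data, dist = "weibull")
  expect_equal(fit$shape, 1 / sv$scale, tolerance = 1e-4)
  expect_equal(unname(fit$coef), unname(-coef(sv) / sv$scale),
               tolerance = 1e-4)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-6)
})
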