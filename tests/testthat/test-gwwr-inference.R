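unit_weight_gwwr <- function(s, covariates = NULL) {
  gwwr_fit(s, kernel_config(bandwidth_mode = "fixed", fixed_bandwidth = Inf),
           covariates = covariates)
}

test_that("unit-weight fits give a null similarity statistic", {
  s <- toy_sample(n = 30, seed = 41)
  g <- unit_weight_gwwr(s)
  lik <- similarity_test(g, method = "likelihood")
  expect_equal(lik$statistic, 0, tolerance = 1e-6)
  expect_equal(lik$p_value, 1, tolerance = 1e-6)
  qf <- similarity_test(g, method = "quadratic_form")
  expect_equal(qf$statistic, 0, tolerance = 1e-4)
  expect_equal(qf$df, 30 * 2)
})

test_that("quadratic-form statistics equal a brute-force loop", {
  sim <- simulate_sites(spatial_config(n_sites = 12, seed = 55))
  s <- sim$sample
  g <- gwwr_fit(s, kernel_config(n_candidates = 6))
  B_global <- g$global$coef[-1]
  G_sim <- 0
  G_w <- 0
  for (lf in g$locals) {
    Bi <- lf$coef[-1]
    V22 <- lf$varcov[3:4, 3:4]
    G_sim <- G_sim + drop(t(Bi - B_global) %*% solve(V22) %*% (Bi - B_global))
    G_w <- G_w + drop(t(Bi) %*% solve(V22) %*% Bi)
  }
  expect_equal(similarity_test(g)$statistic, G_sim, tolerance = 1e-10)
  expect_equal(simultaneous_test(g)$statistic, G_w, tolerance = 1e-10)
})

test_that("likelihood simultaneous statistic sums per-site Wilks gaps", {
  sim <- simulate_sites(spatial_config(n_sites = 10, seed = 66))
  s <- sim$sample
  g <- gwwr_fit(s, kernel_config(candidate_grid = c(0.5, 1),
                                 include_infinite = TRUE))
  got <- simultaneous_test(g, method = "likelihood")$statistic
  manual <- 0
  pc_null <- wr_fit(s, covariates = character(0))
  for (lf in g$locals) {
    null_w <- wr_fit(s, covariates = character(0), weights = lf$weights)
    manual <- manual + max(2 * (lf$loglik - null_w$loglik), 0)
  }
  expect_equal(got, manual, tolerance = 1e-6)
})

test_that("per-site Wald p-values match the normal tail arithmetic", {
  sim <- river_fixture(4)
  g <- gwwr_fit(sim$sample, kernel_config(n_candidates = 8),
                covariates = c("fe", "temperature", "bod"))
  tab <- local_wald_tests(g)
  expect_equal(tab$p_value, 2 * (1 - pnorm(abs(tab$statistic))))
  expect_equal(tab$statistic, tab$estimate / tab$std.error)
  expect_identical(tab$significant, tab$p_value < 0.05)
})

test_that("significant sets reproduce the published decision pattern", {
  # |W| over (intercept, X1..X4) at one site; 1.96 cutoff keeps X2, X3, X4
  W <- c(3.0428, 1.7490, 1.9636, 2.3731, 2.9945)
  terms <- c("(Intercept)", "X1", "X2", "X3", "X4")
  p <- 2 * (1 - pnorm(abs(W)))
  tab <- tibble::tibble(site_index = 1, site_id = "s1", term = terms,
                        estimate = W, std.error = 1, statistic = W,
                        p_value = p, significant = p < 0.05)
  fg <- factor_groups(tab)
  expect_equal(fg$sites$significant_set, "X2,X3,X4")
})

test_that("factor grouping partitions sites exactly", {
  tab <- tidyr::expand_grid(site_index = 1:6, term = c("X1", "X3", "X4"))
  tab$site_id <- paste0("s", tab$site_index)
  tab$significant <- with(tab, (term %in% c("X3", "X4")) |
                            (term == "X1" & site_index > 4))
  tab$estimate <- 1; tab$std.error <- 1; tab$statistic <- 1; tab$p_value <- 0.5
  fg <- factor_groups(tab)
  expect_equal(nrow(fg$groups), 2)
  expect_equal(sort(fg$groups$significant_set), c("X1,X3,X4", "X3,X4"))
  all_sites <- sort(unlist(fg$groups$site_ids))
  expect_equal(all_sites, sort(unique(tab$site_id))) # disjoint cover
  expect_equal(sum(fg$groups$n_sites), 6)
})

test_that("per-site likelihood-ratio statistics are calibrated under the null", {
  # no covariate effects; near-unit weights so the chi-square reference holds
  cfg <- sim_config(n_sites = 30, p = 1,
                    shape_surface = surface_spec("constant", value = 4),
                    coefficient_surfaces = list(
                      surface_spec("constant", value = log(1.5) - 4 * log(6)),
                      surface_spec("constant", value = 0)))
  kc <- kernel_config(bandwidth_mode = "fixed", fixed_bandwidth = 5)
  stats <- c()
  for (r in 1:60) {
    cfg$seed <- 3000L + r
    s <- simulate_sites(cfg)$sample
    g <- gwwr_fit(s, kc)
    lr <- simultaneous_test(g, method = "likelihood")
    stats <- c(stats, lr$statistic / lr$df) # mean per-site per-df statistic
  }
  expect_gt(mean(stats), 0.8)
  expect_lt(mean(stats), 1.2)
})

test_that("both similarity methods agree under strong spatial effects", {
  for (r in 1:3) {
    cfg <- spatial_config(n_sites = 50, seed = 7000 + r)
    cfg$coefficient_surfaces[[2]]$slope_u <- 3
    s <- simulate_sites(cfg)$sample
    g <- gwwr_fit(s, kernel_config(n_candidates = 10))
    d_lik <- similarity_test(g, method = "likelihood")$reject
    d_qf <- similarity_test(g, method = "quadratic_form")$reject
    expect_identical(d_lik, d_qf)
  }
})
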