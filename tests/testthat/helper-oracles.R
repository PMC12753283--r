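# Shared oracles and fixture builders.

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# finite differences of a vector-valued function (returns Jacobian)
fd_jacobian <- function(f, x, h = 1e-5) {
  cols <- lapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

# small synthetic sample with two covariates
toy_sample <- function(n = 30, seed = 42, shape = 3, b = c(-4, 0.6, -0.4),
                       threshold = 6) {
  cfg <- sim_config(
    n_sites = n, p = length(b) - 1,
    shape_surface = surface_spec("constant", value = shape),
    coefficient_surfaces = lapply(b, function(v) surface_spec("constant", value = v)),
    censor_threshold = threshold, seed = seed)
  simulate_sites(cfg)$sample
}

# spatially varying truth: the slope of covariate 1 drifts west-to-east
spatial_config <- function(n_sites = 50, seed = 1) {
  sim_config(
    n_sites = n_sites, p = 2,
    shape_surface = surface_spec("constant", value = 5),
    coefficient_surfaces = list(
      surface_spec("constant", value = log(1.5) - 5 * log(6)),
      surface_spec("linear", value = 0.5, slope_u = 2.5),
      surface_spec("constant", value = 0.5)),
    seed = seed)
}
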