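# gwwr

Geographically weighted Weibull regression (GWWR) for right-censored,
spatially heterogeneous, nonnegative continuous responses.

The motivating setting is environmental monitoring: a network of river
sampling sites records a water-quality indicator such as dissolved oxygen
(DO, ppm) together with chemistry and physical covariates. Values at or
above a quality threshold `y*` (6 ppm for Class-I river water) are recorded
as "good" — formally right-censored at `y*` — while values below it are
events ("degradation"). The response is modelled as Weibull in a scale–shape
parametrization with the rate-style scale driven by covariates, and, in the
geographically weighted extension, with regression coefficients that vary
over space. Users are applied statisticians and environmental scientists who
want per-site models, maps of locally influential factors, and interpretable
risk measures from a modest number of monitoring sites.

## The model

Each observation `y_i ~ Weibull(γ, λ_i)` with density
`f(y) = λγ y^(γ−1) exp(−λ y^γ)` and `λ_i = exp(bᵀx_i)`, right-censored at
`y*` with event indicator `δ_i = 1{y_i < y*}`. The global (WR) model
maximizes the censored log-likelihood

    ℓ(φ) = Σ_i δ_i [log γ + (γ−1) log y_i + bᵀx_i] − y_i^γ exp(bᵀx_i),

over `φ = (γ, b)` by damped Newton–Raphson with analytic gradient and
Hessian; `var(φ̂) = −H(φ̂)⁻¹`. The geographically weighted model refits this
likelihood at every site `u_i` with kernel weights
`w_ij = exp[−½ (d_ij / a_i)²]` (or a compact-support bi-square kernel),
where the per-site adaptive bandwidth `a_i` minimizes the local
`BIC(u_i) = −2 ℓ(φ̂(u_i)) + K log n`, giving site-specific parameters
`φ(u_i) = (γ(u_i), b(u_i))`. Four regression functions carry the
interpretation at each site: survival `S(y,x)` (probability the indicator
stays above `y`, i.e. quality improvement), distribution `F = 1 − S`
(degradation probability), hazard `h(y,x) = γ y^(γ−1) exp(bᵀx)`
(degradation rate; covariates act proportionally, `R_h = exp(b_k)`), and the
mean `μ(x) = Γ(1+1/γ) exp(−bᵀx/γ)` (so a one-unit covariate increase scales
the expected response by `exp(−b_k/γ)`).

The inference suite has Wilks and Wald tests for the global model; a
similarity test of GWWR against WR, a simultaneous test of all local
coefficients (both chi-square with `n·p` degrees of freedom), and per-site
Wald tests whose significant-covariate sets partition the sites into factor
groups. Pre-fit screening covers VIF multicollinearity, the Glejser
spatial-heterogeneity F test, and a Kolmogorov–Smirnov check of the Weibull
assumption with *exact* finite-sample critical values. Model comparison uses
BIC, GCV, McFadden R², and MAPE. A seeded generator of spatially varying
censored Weibull datasets stands in for the (request-only) survey data.

## Worked example

```r
library(gwwr)

sim    <- river_fixture(seed = 1)   # 27-site synthetic river survey
rivers <- sim$sample
censoring_summary(rivers)
#>       n events event_fraction
#> 1    27     22          0.815

sel <- backward_eliminate(rivers)   # drop covariates with partial p > 0.10
tidy(sel$fit)
#>   term        estimate std.error statistic       p.value
#> 1 shape         14.2       2.42       5.88 0.00000000409
#> 2 (Intercept)  -53.3      11.2       -4.78 0.00000173
#> 3 fe             8.45      2.49       3.40 0.000675
#> 4 phosphate     52.4      16.6        3.16 0.00159
#> 5 temperature    0.632     0.308      2.05 0.0401
#> 6 bod            1.45      0.457      3.17 0.00150
#> 7 nitrate       -0.424     0.154     -2.75 0.00596

gw <- gwwr_fit(rivers, kernel_config(), covariates = sel$covariates,
               global = sel$fit)
dplyr::bind_rows(WR = gof_report(sel$fit), GWWR = gof_report(gw), .id = "model")
#>   model   bic   gcv mcfadden_r2 mape_percent     K     n
#> 1 WR     53.3 0.451       0.559         7.37     7    27
#> 2 GWWR   26.3 0.178       0.943         4.73     7    27

tail(site_measures(gw), 3)
#>   site_id            improvement_prob degradation_prob degradation_rate
#> 1 s26                           0.912           0.0882            0.236
#> 2 s27                           0.381           0.619             2.70
#> 3 (regional average)            0.525           0.475             2.94
```

Reading the output: the global fit (shape 14.2) says iron, phosphate,
temperature and BOD raise the degradation hazard (positive coefficients →
hazard ratios `exp(b_k) > 1`, mean-DO ratios `exp(−b_k/γ) < 1`), and the
Wilks test rejects the no-covariate null. The geographically weighted refit
improves every goodness-of-fit measure (BIC 26.3 vs 53.3, MAPE 4.7% vs
7.4%). The site-measure table gives each site's improvement/degradation
probability, degradation rate, and expected DO, plus the regional averages;
`local_wald_tests()` + `factor_groups()` then map which covariates matter
where, and `autoplot(gw)` draws the coefficient surfaces.

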