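---
title: "Censored Weibull regression with geographically weighted coefficients: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored Weibull regression with geographically weighted coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwwr)
```

This vignette documents the statistical model behind **gwwr**, the numerical
choices in its estimators, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the methodology left
genuine freedom.

## The model and its assumptions

A nonnegative continuous indicator $y$ (the motivating case is dissolved
oxygen in river water, in ppm) is observed at $n$ sites with planar
coordinates $u_i = (u_i, v_i)$, together with $p$ covariates $x_i$. Values
at or above a quality threshold $y^*$ are recorded as $y^*$ and flagged
right-censored ($\delta_i = 0$); values below it are events
($\delta_i = 1$). Ties with the threshold are censored — conventions differ
across survival software, so this is worth stating: $y \ge y^*$ is the
"good quality" (censored) side.

Responses follow a scale–shape Weibull,
$f(y) = \lambda\gamma y^{\gamma-1} e^{-\lambda y^\gamma}$, with the
rate-style scale linked to covariates through
$\lambda_i = \exp(b^\top x_i)$ (intercept included in $x_i$). The classic
scale of `stats::dweibull` is $\tau = \lambda^{-1/\gamma}$. Assumptions:
observations are independent given the covariates; the shape $\gamma$ is
common to all observations within one (local or global) fit; covariates act
proportionally on the hazard $h(y,x) = \gamma y^{\gamma-1} e^{b^\top x}$.
Four regression functions carry the interpretation: survival $S$
(improvement probability), distribution $F = 1 - S$ (degradation
probability), hazard $h$ (degradation rate), and the mean
$\mu(x) = \Gamma(1 + 1/\gamma)\, e^{-b^\top x/\gamma}$.

The geographically weighted extension replaces the single parameter vector
by site-specific $\phi(u_i) = (\gamma(u_i), b(u_i))$, estimated by
maximizing the kernel-weighted censored log-likelihood with weights
$w_{ij}$ that decay with the Euclidean distance $d_{ij}$.

**Coordinate caveat.** Coordinates are treated as planar and distances as
Euclidean, so bandwidths inherit the coordinate units. If coordinates are
geographic degrees (as in the bundled fixture), this is an approximation
the analyst accepts at provincial scale; no great-circle correction is
applied by default.

## Estimation

The log-likelihood, gradient and Hessian are analytic (`wr_loglik`,
`wr_gradient`, `wr_hessian`; weighted versions reduce exactly to the global
ones at unit weights). Maximization is damped Newton–Raphson:

* **Step halving.** The Newton step is halved (up to 30 times) until the
  log-likelihood does not decrease and the shape stays positive. The plain
  iteration diverges for poor starts, especially with sharp shapes.
* **Convergence.** $\|\Delta\phi\|_\infty < 10^{-8}$ or
  $\|v\|_\infty < 10^{-6}$, at most 100 iterations; the reported
  `converged` flag is honest and downstream code checks it.
* **Initialization.** Shape 1, intercept $\log(\sum\delta_i / \sum y_i)$
  (the exponential moment start), slopes 0. If that run fails to converge,
  one retry warm-starts from the univariate censored Weibull fit. Local
  fits warm-start from the global estimate, which stabilizes the small
  effective samples that compact kernels produce.
* **Conditioning.** Covariates are standardized internally and estimates
  back-transformed; likelihood, derivatives and the variance matrix
  $\widehat{\mathrm{var}}(\hat\phi) = -H(\hat\phi)^{-1}$ are reported on
  the original scale. With shapes near 20 and covariates on scales from
  0.03 to 180, this matters.
* **Degenerate Hessians.** Singular or indefinite Hessians get an
  escalating ridge ($10^{-8}$ to $10^{-2}$) before the fit is declared
  failed. All-censored input is an error: the censored likelihood is then
  unbounded in $b_0$.

## Spatial weighting and bandwidth selection

Two adaptive kernels are provided: Gaussian
$w_{ij} = \exp[-\tfrac12 (d_{ij}/a_i)^2]$ and bi-square
$w_{ij} = [1-(d_{ij}/a_i)^2]^2$ for $d_{ij} \le a_i$, else 0. An infinite
bandwidth gives unit weights and reproduces the global fit exactly — a
reduction the test suite checks to $10^{-8}$.

Each site searches its own bandwidth over 40 log-spaced candidates from the
$(p+2)$-th nearest-neighbour distance to twice the maximum pairwise
distance, plus the infinite candidate, choosing the minimizer of the local
$\mathrm{BIC}(u_i) = -2\,\ell(\hat\phi(u_i)) + K \log n$ with $K = p + 2$
and $n$ the full sample size; ties break toward the larger bandwidth.
"Adaptive" here means a per-site scalar distance, not a neighbour count.
A candidate is eligible only if its weighted event mass satisfies
$\sum_j w_{ij}\delta_j \ge p + 2$; an effective-sample-size penalty variant
($K\log\sum_j w_{ij}$) exists behind a flag but is off by default.

**A known degeneracy, documented deliberately.** Because the weighted
log-likelihood's magnitude shrinks with total kernel mass while the penalty
$K\log n$ is constant across candidates, this criterion is typically
monotone in the bandwidth: when per-observation log-likelihood
contributions are negative (diffuse shapes) the smallest eligible candidate
wins, and sharp shapes reward compact kernels through near-interpolation.
The weighted-event floor is therefore the *effective* regularizer of the
bandwidth search, and selected bandwidths concentrate near the smallest
value it admits; the infinite candidate is selected mainly when no finite
candidate is eligible or converged. Users wanting smoother coefficient
surfaces should pass a `fixed` bandwidth or a custom `candidate_grid`.
Leave-one-out cross-validation, the standard cure, is out of scope by
design (the method under study selects by per-site BIC only).

## Inference

* **Global model.** Wilks $W = 2(\ell_{\text{full}} - \ell_{\text{null}})$
  against $\chi^2_p$, where the null refit keeps shape and intercept; an
  asymptotically equivalent quadratic form
  $\hat B^\top [I_{F22}]^{-1} \hat B$ in the slope estimates (variance
  submatrix with the shape and intercept rows/columns removed) is available
  and reduces to the squared Wald statistic when $p = 1$. Partial tests use
  $Q_k = \hat b_k / \mathrm{se}(\hat b_k)$ with two-sided normal p-values —
  estimate over the *square root* of the variance; published tables of this
  method confirm the ratio-to-SE form.
* **Local model.** The similarity test compares GWWR with WR,
  $G = 2\sum_i (\ell_{w_i}(\hat\phi(u_i)) - \ell_{w_i}(\hat\phi))$; the
  global log-likelihood inside each per-site gap is evaluated *under the
  same kernel weights* as the local fit, otherwise the gap would not
  compare nested parameterizations of one likelihood. The simultaneous test
  sums per-site Wilks statistics against site-specific null fits (same
  weights, shape and intercept only). Both have quadratic-form companions
  (summing $C(u_i)$ resp. $C_w(u_i)$) and reference distribution
  $\chi^2_{np}$, the stated df of the method — no effective-df correction is
  attempted. The quadratic form is the default: its ingredients are the
  per-site estimates and variances the method tabulates. Per-site Wald
  tests give each site a significant-covariate set; `factor_groups()`
  partitions sites by identical sets.
* **Calibration caveat.** With kernel weights the per-site likelihood-ratio
  statistics are only approximately $\chi^2_p$; the approximation is good
  near unit weights and degrades for compact kernels. The suite checks
  calibration in a near-unit-weight regime only.

## Screening and goodness of fit

VIF uses the usual auxiliary least-squares regressions,
$\mathrm{VIF}_k = 1/(1-R_k^2)$, flagging above 10. The Glejser test
regresses absolute OLS residuals of the response on the covariates and
forms the overall F statistic with $(p,\, n-p-1)$ df; residuals come from
ordinary least squares because the screen precedes any Weibull fit and the
statistic's algebra is OLS throughout (a flag switches to Weibull-mean
residuals). The Weibull-distribution check is a one-sample KS test on the
*event* observations against the fitted univariate censored-Weibull CDF,
with fitted parameters treated as known (no Lilliefors-style correction)
and **exact finite-sample critical values** computed from the Kolmogorov
distribution by the matrix-power construction with bisection — at $n = 21$,
$\alpha = 0.05$ this gives 0.2872, the small-sample table value, not the
asymptotic $1.36/\sqrt{n} = 0.2963$.

Model-level goodness of fit reports BIC, GCV, McFadden $R^2$ and MAPE. Two
of these require declared extensions, since a per-site model family does
not define single-number measures by itself:

* the GWWR model-level log-likelihood is the sum over sites of each
  observation's *own-site* contribution
  $\delta_i \log h(y_i, x_i; \hat\phi(u_i)) + \log S(y_i, x_i; \hat\phi(u_i))$,
  with $K = p + 2$ — the minimal extension consistent with the global
  definition, declared rather than claimed canonical;
* GCV is $n\,\mathrm{RSS}/(n-K)^2$ on mean-scale residuals; a hat-matrix
  GCV is not definable for this nonlinear family without further invention.

MAPE compares mean-model predictions against the *raw* responses: the
indicator is fully observed and censoring is an analysis construct (a flag
restricts to event rows). Backward elimination drops the covariate with the
largest partial p-value above `alpha_stay` (default 0.10, so a covariate
significant at the 10% level is retained), refits, records BIC, and
returns the visited model minimizing BIC among those meeting the stay rule.

## Interpretation measures

For a one-unit increase in covariate $k$ at a site: $R_S$ and $R_F$ by
direct evaluation of the survival and distribution functions at
$(y_i, x_i)$ versus $(y_i, x_i + e_k)$; the hazard ratio
$R_h = e^{\hat b_k(u_i)}$, constant in $y$ (the proportional-hazards
property, which `covariate_curves()` exhibits as parallel before/after
hazard curves); and the mean ratio $R_\mu = e^{-\hat b_k(u_i)/\hat\gamma(u_i)}$,
which follows from the mean regression function — note the sign flip and
the $1/\gamma$ damping relative to the hazard ratio: a covariate that
accelerates degradation ($b_k > 0$) lowers the expected indicator. The
linearized mean model (`mean_model_coefficients()`) exposes the constant
$\Gamma(1+1/\gamma)$ and exponent vector $-b/\gamma$ on which these read
off directly.

## The synthetic-data generator

`simulate_sites()` draws coordinates uniformly in a box, covariates from
configurable marginals (normal, lognormal matched to raw-scale mean/sd,
uniform), evaluates coefficient and shape surfaces from a small rule family
(constant, linear-in-coordinates, radial bump), and generates
$y_j \sim \text{Weibull}(\gamma(u_j), e^{b(u_j)^\top x_j})$ by inverse CDF
before censoring at the threshold. Identical seeds give identical output
within this implementation; cross-implementation bitwise equality is not
promised, so all downstream checks use statistical tolerances.

`river_fixture()` is a 27-site, 10-covariate instance emulating a
provincial river survey: covariate marginals match routine monitoring
panels (iron, phosphate, temperature, BOD, nitrate, ammonia, oil and
grease, pH, suspended solids, colour), shape near 20, threshold 6 ppm, and
an intercept baseline calibrated once (by Monte Carlo over the covariate
marginals) so the marginal event fraction is 77.78%; the intercept and the
iron coefficient drift linearly across the box so the data carry genuine
spatial structure, and six covariates are pure noise for selection to
remove. Everything about it is synthetic: it reproduces marginal scales
and an event rate, not any real river network's spatial autocorrelation,
covariate dependence structure, or measurement error. Passing tests on it
therefore demonstrate internal correctness of the estimators and tests
under the model's own assumptions — not field validity on real survey data.

The spatially-varying-truth configuration used in the recovery and
model-comparison experiments lets the first covariate's coefficient drift
linearly with amplitude ±1.25 around 0.5 across the unit box. The
amplitude is chosen so the surface's variation is clearly detectable above
local estimation noise at a few dozen sites; smaller amplitudes are
legitimate data-generating processes but make site-wise recovery a
low-power exercise that says little about the estimator.

## Problem sizes and runtime choices

The test-suite experiments run at sizes chosen to exercise the asymptotics
meaningfully while staying desk-scale: parameter recovery and coverage on
100 replicates of $n = 400$; Wilks empirical size on 500 null replicates of
$n = 200$; GWWR-vs-WR dominance on 20 spatially varying replicates of 50
sites with 20-point bandwidth grids; derivative checks on 20 random points
of a 30-row sample against central finite differences ($10^{-4}$ relative
for the gradient, $10^{-3}$ for the Hessian).

## Known limitations

* The per-site BIC bandwidth rule is degenerate as discussed above; treat
  selected bandwidths as the most local fit the identifiability floor
  allows, not as an estimate of a "true" smoothing scale.
* $\chi^2_{np}$ reference distributions for the similarity and simultaneous
  tests ignore the dependence between overlapping local fits and the
  weighting of the per-site statistics; p-values are approximate.
* The KS check uses events only; censored points do not enter the empirical
  CDF. With estimated parameters and no Lilliefors correction the test is
  conservative.
* One shape parameter per (local) fit; no time-varying covariates, frailty,
  interval or left censoring, or mixed global/local coefficient models.
* Bandwidth units depend on the coordinate units; nothing in the package
  converts degrees to distances.
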