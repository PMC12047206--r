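---
title: "Modelling heterogeneity itself: location-scale meta-analysis with lsmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterogeneity itself: location-scale meta-analysis with lsmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmeta)
```

## Why model the scale part

A meta-analytic dataset is a set of effect sizes $y_i$ with known
sampling variances $v_i$, nested in studies $j$. The classical
random-effects model treats the spread of true effects as a single
number ($\tau^2$). But heterogeneity is itself structured: aquatic
versus terrestrial systems, persistent versus acute exposures, early
versus late publications can differ in *variance* as much as in mean.
`lsmeta` fits the location-scale family, in which the mean (location)
and the log residual standard deviation (scale) are both linear models:

$$y_i = \mathbf{x}_i^{(l)\top}\boldsymbol\beta^{(l)} + u^{(l)}_{j(i)}
  + a_{k(i)} + s_{k(i)} + e_i + m_i, \qquad
\ln \sigma_{e,i} = \mathbf{x}_i^{(s)\top}\boldsymbol\beta^{(s)}
  + u^{(s)}_{j(i)},$$

with $e_i \sim N(0, \sigma^2_{e,i})$, sampling errors
$\mathbf m \sim N(\mathbf 0, \mathbf V)$, study effects
$(u^{(l)}_j, u^{(s)}_j)$ bivariate normal with variances
$\sigma^2_{ul}, \sigma^2_{us}$ and correlation $\rho_u$, a phylogenetic
species effect $a_k \sim N(0, \sigma^2_a \mathbf A)$ and a
non-phylogenetic one $s_k \sim N(0, \sigma^2_s)$. The scale part
models the log *standard deviation* (not the log variance); variance
scale quantities are obtained as $\exp(2\cdot)$.

Assumptions worth keeping in mind: sampling variances are known (the
usual plug-in estimators), residuals and random effects are Gaussian,
and the scale part is log-linear in its moderators. The phylogenetic
and species effects enter the location part only; scale-part
phylogenetic effects demand far more data than typical meta-analyses
offer and are deliberately not provided.

## The sampling covariance V and $\rho_m$

$\mathbf V$ is block-diagonal by study. Within a study, two effects
computed on the *same subjects* (declared via `subject_group`) get
covariance $\rho_m \sigma_{m a}\sigma_{m b}$; other within-study pairs
are left at zero because their dependence is carried by the study
random effect. The true $\rho_m$ is unknowable without raw data, so a
working value is assumed: the default is 0.5, with 0.8 a recommended
sensitivity value (`build_sampling_vcov(..., rho_m = 0.8)`). For extra
protection against misspecifying $\mathbf V$, `cluster_robust_vcov()`
provides study-clustered sandwich standard errors for the location
coefficients, with a $J/(J-1)\times(K-1)/(K-p)$ small-sample factor;
they are meant to be reported alongside the model-based ones.

## Estimation

**Marginal REML/ML** (`fit_reml_ml`, `fit_phylogenetic`). When the
scale part has fixed effects only, the Gaussian location random effects
integrate out exactly:
$\boldsymbol\Sigma = \sigma^2_{ul}\mathbf Z_u\mathbf Z_u^\top +
\sigma^2_a \mathbf Z_a \mathbf A \mathbf Z_a^\top +
\sigma^2_s \mathbf Z_s\mathbf Z_s^\top +
\mathrm{diag}(e^{2\mathbf X^{(s)}\boldsymbol\beta^{(s)}}) + \mathbf V$,
and $\boldsymbol\beta^{(l)}$ is profiled out by GLS at every objective
evaluation. Variance components are optimized on the log scale
(positivity for free), with five deterministic multi-starts, a
quasi-Newton optimizer at relative tolerance $10^{-10}$ and a final
polish at $10^{-14}$ — the polish matters for the exactness checks
below (equivariance to $10^{-6}$). When only the study effect is random
and $\mathbf V$ is diagonal, each study block is diagonal-plus-rank-one
and the likelihood is evaluated in $O(K)$ via the Woodbury identity;
the general case takes a dense Cholesky. Wald covariances come from the
numerical Hessian over $(\boldsymbol\beta^{(s)}, \log \text{variances})$;
log-variance coordinates at the zero boundary make that surface flat,
so boundary components are reported as exact zeros with flagged (NA)
uncertainty instead of contaminating the rest. Confidence intervals are
Wald on transformed scales (log for variances) and back-transformed.

**Identifiability.** With one effect size per study and an
intercept-only scale part, $\sigma^2_{ul}$ and $e^{2\beta_0^{(s)}}$
enter the marginal variance only through their sum. The fit then drops
the study random effect (with a message) and $e^{2\beta_0^{(s)}}$
carries the whole classical $\tau^2$.

**MCMC for the double-hierarchical model** (`fit_bayes`). With a
random effect in the scale part, the marginal likelihood has no closed
form. The sampler keeps the scale effects in non-centered form
$u^{(s)}_j = \sigma_{us} w_j$ and integrates the location study effects
analytically given $w$ (conditional on $w$, each study block is again
diagonal-plus-rank-one). One iteration consists of: a Gibbs draw of
$\boldsymbol\beta^{(l)}$; three parallel element-wise random-walk
sweeps over $w$ (adaptive per-study step sizes, 44% target acceptance);
an adaptive joint random-walk over the remaining hyperparameters
(empirically adapted covariance, 23.4% target); near-exact conditional
draws of $\mathrm{atanh}\,\rho_u$, $\log\sigma_{ul}$,
$\log\sigma_{us}$ and $\beta_0^{(s)}$ on fine grids computed from
per-study sufficient statistics; and two interweaving moves that
re-express $(\beta_0^{(s)}, \sigma_{us})$ against the invariant latent
field $u^{(s)}$ — a Gibbs shift with the location intercept absorbing
the offset change, and a rescale paired with an opposite rescale of
$\rho_u$. The grid draws use fixed fine grids (width well beyond the
conditional support, 31–101 points), a standard griddy-Gibbs
approximation whose discretization error is negligible against Monte
Carlo error; parameter-recovery tests against the generator back this
up. Priors default to Normal(0, 2²) for coefficients, half-Normal(0, 1)
for SD components, uniform(−1, 1) for $\rho_u$; all overridable.
Convergence requires split-$\hat R < 1.01$ and summed per-chain ESS
$> 400$ for every reported parameter; when estimating $\rho_u$ fails
these criteria, the model is refitted once with $\rho_u = 0$, the
variant the double-hierarchical literature recommends when the
correlation mixes poorly. Defaults: 4 chains, 1500 warmup + 2500 kept
iterations; every run requires an explicit seed and is exactly
reproducible. The MCMC path treats sampling errors as independent
(diagonal $\mathbf V$): shared-subject correlation combined with scale
random effects would require per-block solves inside the sampler, and
the REML path plus robust errors covers that need.

## Heterogeneity statistics

From a fit, `heterogeneity()` assembles: the multilevel $I^2$ partition
$I^2_B = \sigma^2_u / (\sigma^2_u + \sigma^2_e + \bar\sigma^2_m)$ (and
$I^2_W$, $I^2_T = I^2_B + I^2_W$) with the typical sampling variance
$\bar\sigma^2_m = (K-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$,
$w_i = 1/v_i$; the location-scale $I^2_B$ whose residual term is the
log-normal mean $\bar\sigma^2_e = \exp(2\beta_0^{(s)} + 2\sigma^2_{us})$;
and the mean-standardized family
$CVH_B = \sigma_u/|\beta_0|$, $CVH_W = \sigma_e/|\beta_0|$,
$CVH_T^2 = CVH_B^2 + CVH_W^2$, plus the scale-part
$CVH_B^{(s)} = \sqrt{\exp(\sigma^2_{us}) - 1}$ (use
$4\sigma^2_{us}$ for the variance-scale variant), which makes
between-study variability in means and in variances directly
comparable. $CVH$ with $|\beta_0| < 10^{-8}$ is reported as undefined
(`NA`) rather than infinite — mean-standardized measures presume a
ratio-like mean. For Bayesian fits each statistic is computed per
posterior draw and summarized; for REML fits the statistics are
plug-in (no delta-method interval is attached). Phylogenetic fits add
$\lambda = H^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_s)$.

## Four publication-bias tests

`four_way_bias_test()` puts a small-study axis (the standard error, or
$1/\sqrt{\tilde n}$ with $\tilde n = n_1 n_2/(n_1+n_2)$ for two-group
designs, $\tilde n = n$ for correlation-type ones — the sample-size
axis avoids the intrinsic estimate–SE correlation of SMD-type effect
sizes) and the mean-centered publication year into *both* model parts
and reports four slopes: small-study effect and decline effect
(location), small-study divergence and Proteus effect (scale). Each
verdict is a 95% interval excluding zero; the four are distinct
a-priori hypotheses, so no multiplicity correction is applied. The
effective-sample-size formula is not uniquely standardized in the
bias-test literature; the harmonic form above is used and can be
bypassed by passing `n_eff` directly. Below roughly 40 effect sizes the
scale part is poorly estimated and the function warns.

A point the simulations make concrete: *ignoring* a small-study
divergence can manufacture a small-study effect. With many precise
studies, a minority of small noisy ones, and residual variance growing
with the standard error (but no location dependence at all), the
homoscedastic Egger-type regression rejects its null far above nominal
level (about 20% at $\alpha = 0.05$ in the acceptance simulation: its
single $\tau^2$, dominated by the precise majority, understates the
true variance exactly where the regressor has leverage), while the
location-scale version stays at the nominal rate and instead flags the
divergence on the scale part, where it belongs.

## The synthetic-data generator

`sim_config()`/`simulate_meta()` generate from the same family the
models fit: bivariate study effects with $\rho_u$, log-linear scale
part, optional phylogenetic/species effects on a supplied or simulated
coalescent tree, moderators (normal, uniform, categorical, publication
year, or the effect's own standard error — the latter for injecting
small-study bias into either part), and sampling variances from a
uniform, fixed, or precise/noisy mixture profile. Defaults are chosen
to mimic ecological meta-analyses: $v \sim U(0.01, 0.2)$, residual SD
0.3, $\sigma^2_{ul} = 0.25$, giving total $I^2$ in the 0.85–0.95 range
the field typically reports. Scale-effect variances have no
field-standard magnitude; scenarios in the tests use
$\sigma^2_{us} \in \{0, 0.25\}$ and are labelled illustrative. The
truth (latent effects and parameters) is returned with the table, and
`recovery_study()` / `operating_characteristics()` wrap the
simulate–refit loop into bias/RMSE/coverage and size/power tables with
deterministic per-replicate seeds.

What the generator does *not* emulate: non-Gaussian random effects,
selection-driven publication (effects are never censored — bias enters
only through moderator dependence), raw arm-level data, or measurement
error in $v_i$. Passing recovery tests therefore demonstrates internal
consistency of estimator and model family, not robustness to those
real-data features.

## Validation study sizes

The test suite validates: exact agreement of the intercept-only fit
with an independent classical RE-REML implementation ($|\Delta\tau^2| <
10^{-6}$ on a 10-study table); the algebraic $I^2$ and $CVH$ identities
on 1000 random inputs; recovery of a true scale slope of 0.3 over 200
replicates of 200 studies × 3 effects (|mean bias| < 0.05, 95% coverage
in [0.92, 0.98]); size within [0.03, 0.07] over 1000 homoscedastic
null replicates (100 studies × 2 effects, precise Zr-like $v \sim
U(0.01, 0.05)$ so the group residual SDs are identified) and power
above 0.8 against an $\ln 2$ residual-SD contrast at 150 studies; MCMC
recovery of $\rho_u = 0.8$ within ±0.15 with all split-$\hat R < 1.01$
at 300 studies × 3 effects; scale-equivariance ($y \to cy$ shifts
$\beta_0^{(s)}$ by exactly $\ln c$) to $10^{-6}$; and the
spurious-Egger phenomenon above over 200 replicates.

## Known limitations

Wald intervals for variance components are asymptotic and can
undercover near the zero boundary (boundary estimates are flagged
instead). The REML path's scale part is fixed-effects only by design.
$CVH$ statistics are unstable when the overall mean is near zero. The
griddy conditional draws are an approximation, though a practically
exact one at the grid resolutions used. Model comparison (information
criteria, cross-validation) is out of scope; so is estimating
transformations of the phylogenetic correlation (the tree's Brownian
correlation is used as supplied).
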