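---
title: "Measuring agricultural eco-efficiency and its digital-infrastructure drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agricultural eco-efficiency and its digital-infrastructure drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrecoeff)
```

`agrecoeff` implements a complete measurement-and-inference chain for
agricultural eco-efficiency (AEE) on province-year panels. The chain has four
stages — carbon accounting, efficiency scoring, composite index construction,
and panel regression — plus a synthetic data generator with a known
data-generating process (DGP) so that every stage can be validated end to end
without access to the statistical yearbooks that real applications draw on.
This vignette documents the models, the numerical choices, and what the
synthetic validation does and does not establish.

## 1. Carbon accounting

**Sequestration.** Crop carbon uptake is accounted per crop type from its
economic yield $y_i$ (tons), water content $r_i$, carbon uptake rate $cs_i$,
and economic coefficient (harvest index) $HI_i$:

$$CSA = \sum_i (1 - r_i)\, cs_i\, \frac{y_i}{HI_i}.$$

The position of the harvest index deserves a note. The carbon-sink literature
converts *economic* yield to *biological* yield by dividing by the harvest
index before applying the uptake rate; printed versions of the formula often
render the four factors as a plain product, leaving the intent ambiguous.
`carbon_sequestration()` therefore defaults to `hi_mode = "divide"` (the
biomass conversion reading) and offers `"multiply"` as a switch, so either
convention is one argument away. The fifteen crop coefficients ship as an
editable CSV (`crop_coefficients()`); user files with the same columns extend
or replace the table.

**Emission.** Carbon emission is the coefficient-weighted sum over six
sources — pesticide, fertilizer, diesel and film per kg applied, irrigation
and tillage per hectare:

$$CE = \sum_{i=1}^{6} \beta_i A_i,$$

with the shipped coefficients 4.9341, 0.8956, 0.5927 and 5.18 kg/kg for the
mass sources and 266.48 and 312.6 kg/hm² for the area sources
(`emission_coefficients()`). Units are enforced per source class; the
aggregate is reported in tons (kg totals divided by 1000). Scaling to 10⁴ or
10⁶ t is presentation only and never applied internally.

Two auxiliary constructions complete the input/output system:
`impute_labor()` allocates primary-industry employment to agriculture by the
agricultural share of sector output value, and `chemical_composite()` /
`nps_pollution()` form the chemical-input proxy (pesticide + pure-nutrient
fertilizer + film) and the non-point-source pollution proxy (COD + ammonia
nitrogen + total nitrogen + total phosphorus). Fertilizer is accepted as
pure-nutrient (discounted) tons; the package does not convert from gross
weight.

## 2. Super-efficiency SBM scoring

Each decision-making unit (DMU; one province-year) is scored with the
slacks-based measure (SBM) with undesirable outputs. With $m$ inputs $x$,
$r_1$ desired outputs $y^d$ and $r_2$ undesired outputs $y^u$, the standard
SBM score of unit $k$ is

$$\rho_k = \min \frac{1 - \frac{1}{m}\sum_i s^-_i / x_{ik}}
{1 + \frac{1}{r_1 + r_2}\left(\sum_s s^d_s / y^d_{sk} + \sum_q s^u_q / y^u_{qk}\right)}$$

subject to $x_k = X\lambda + s^-$, $y^d_k = Y^d\lambda - s^d$,
$y^u_k = Y^u\lambda + s^u$, all slacks and weights nonnegative (plus
$\sum\lambda = 1$ under variable returns to scale, VRS). Units on the
frontier ($\rho = 1$) are then re-scored with the *super-efficiency* program,
which excludes the evaluated unit from the reference set and measures the
distance to a projection point weakly worse than the unit itself; its value
is $\ge 1$ and discriminates among efficient units. Sub-frontier units keep
their standard score — for them the own unit never enters the optimal
reference basis, so exclusion changes nothing (this is asserted to $10^{-6}$
in the test suite). Writing the chain this way, rather than as a single
program with projection bounds, is what makes scores below 1 possible at all;
a single bounded program is identically $\ge 1$.

Both fractional programs are linearised by the Charnes–Cooper substitution
and solved with a small dense two-phase simplex written for the package
(`R/lp.R`), with a $10^{-9}$ pivot tolerance and a Bland's-rule fallback for
the degenerate bases that duplicated or tied units create. Scores are kept at
full precision internally and rounded to 4 decimals only in printed and CSV
output.

Numerical and design choices:

* **Zero data are rejected**, not epsilon-shifted: SBM slack ratios are
  undefined at zero, the synthetic generator guarantees positivity, and
  silently shifting real data changes results in ways the user should decide.
* **Frontier pooling** defaults to `pooled` (all province-years against one
  frontier) so that score levels are comparable across years; `by_year`
  scores each cross-section against itself.
* **VRS super-efficiency can be infeasible** (a known pathology when a unit's
  bad outputs lie below the convex hull of the others). This is reported as
  `status = "infeasible_super"`; `score_panel()` substitutes the standard
  (inclusive) score of 1 with a warning, keeping the panel balanced for the
  regression stage.
* **Validation** is dual-route: on single-input single-output CRS instances
  the scores must match the closed-form best-ratio expression
  $\rho_k = (y_k/x_k) / \max_{j \ne k}(y_j/x_j)$ to $10^{-6}$; on tiny
  instances with bad outputs they must match an exact vertex-enumeration
  oracle (the slack-eliminated objective is linear-fractional in $\lambda$,
  so its optimum sits on a vertex of the feasible polytope).

## 3. Composite index construction

The digital-infrastructure index aggregates three sub-dimensions.
Information (INFI) and innovation (INNI) sub-indices are entropy-weighted
composites of their indicator blocks: indicators are min-max normalised with
direction flags, every value is shifted by $(v + \varepsilon)/(1 +
\varepsilon)$ with $\varepsilon = 10^{-4}$ (configurable) so the entropy
logarithms never see zero, and weights are

$$w_j = \frac{1 - e_j}{\sum_j (1 - e_j)}, \qquad
e_j = -\frac{1}{\ln n}\sum_i p_{ij} \ln p_{ij},$$

so indicators with more cross-unit dispersion carry more weight. Constant
columns cannot be scaled; they are flagged degenerate and receive weight 0
rather than raising an error, which keeps panels balanced. Weights are
computed **pooled over the whole panel** by default so that index levels are
comparable over time (per-period weighting is available by applying the
functions per year).

The convergence sub-index (CI) summarises how jointly developed traditional
infrastructure and informatisation are, through the canonical two-system
coupled coordination model:

$$C = \frac{2\sqrt{u_1 u_2}}{u_1 + u_2}, \qquad T = \alpha u_1 + \beta u_2,
\qquad D = \sqrt{CT},$$

with $\alpha = \beta = 0.5$ by default and $C := 0$ when both subsystems are
zero. The literature names this model more often than it prints it; the form
above is the standard one, and both subsystem scores are themselves
entropy-weighted block composites. The final index is the fixed
expert-weighted aggregate

$$NDI = 0.4\,INFI + 0.3\,CI + 0.3\,INNI,$$

with the weights exposed as data (`composite_ndi(weights = ...)`); the
elicitation behind them is out of scope and they are treated as given.

## 4. Regression stage

All estimators consume the long panel and return a common fit record whose
t-values are coefficient/SE by construction.

* **Baseline** (`pooled_ols()`): pooled OLS of AEE on one index regressor
  plus five controls (agricultural economic development, planting structure,
  disaster rate, rural human capital, fiscal support), after two-sided
  winsorization of the continuous variables at the 1st/99th percentiles
  (the "1% tailing" convention; order-statistic quantiles, so the operation
  is exactly idempotent). Pooled ("mixed") regression is deliberately the
  default rather than unit fixed effects; conventional and HC1 robust
  standard errors are both available because the source methodology is
  silent on the variance estimator.
* **Threshold** (`threshold_fit()`): Hansen-style piecewise regression with
  the innovation sub-index as its own threshold variable. The grid is the
  observed unique values with 1% trimmed per tail; the cut point minimises
  the SSR of the two-regime fit; threshold existence is tested with
  $F = n(SSR_0 - SSR_1)/SSR_1$ against a fixed-regressor residual bootstrap
  (300 replications by default, seeded), and testing proceeds sequentially
  (single, then double threshold) stopping at the first stage insignificant
  at 5%. Internally the grid search runs on Frisch–Waugh residualised
  columns with precomputed Gram matrices, so a full bootstrap costs
  seconds, not minutes.
* **Moderation** (`moderation_fit()`): adds urbanisation and its interaction
  with the index, optionally with year fixed effects;
  `marginal_effect()` returns $\alpha_1 + \alpha_3 LU$ at chosen
  urbanisation levels.
* **Lag robustness** (`lagged_regressor_fit()`): the index is replaced by its
  within-unit one-year lag, dropping the first year of each unit (a
  30×10 panel yields exactly 270 observations).
* **Tobit** (`tobit_fit()`): censored-normal maximum likelihood, estimated
  through `survival::survreg` with interval coding — the exact likelihood of
  the latent-variable model with a lower bound (default 0). With no censored
  rows the coefficients coincide with OLS to well under $10^{-4}$, which the
  suite asserts.
* **2SLS** (`iv_2sls()`): single-instrument two-stage least squares with
  controls in both stages, the excluded-instrument first-stage F (weak
  below 10), and the second-stage covariance computed from structural
  residuals so that an instrument identical to the regressor reproduces OLS
  exactly. The historical-telephone-type instrument is a generic
  user-supplied column.
* **Subsamples** (`subsample_fit()`): the pooled baseline on the two sides of
  any row predicate (period splits, region splits), with both sizes
  reported.

## 5. The synthetic data generator

`synthetic_config()` fixes the study conditions; its defaults are chosen once
and are not tuning knobs:

* 30 units × 10 years, balanced; seed mandatory, all randomness flows through
  one seeded generator that saves and restores the caller's RNG state.
* Sub-indices are Beta draws with moments matched to the published
  descriptive statistics (INFI mean 0.256 / sd 0.177, CI 0.406 / 0.226, INNI
  0.214 / 0.150); the composite index is their 0.4/0.3/0.3 combination, so
  the index identity holds in the panel by construction. Urbanisation is
  uniform on [35, 90] (percent); the five controls are independent Gaussians
  with the published moments. Physical activity quantities are log-normal
  with a persistent per-unit scale factor so that large units are large on
  both sides of the production set and the DEA frontier stays
  non-degenerate.
* The outcome follows
  $AEE_{it} = \alpha_0 + \beta_{NDI} NDI_{it}
  + \beta_{low} INNI_{it}\,1[INNI_{it} \le \theta]
  + \beta_{high} INNI_{it}\,1[INNI_{it} > \theta]
  + \gamma\, NDI_{it} LU_{it} + \alpha_2' C_{it} + \varepsilon_{it}$,
  $\varepsilon \sim N(0, \sigma^2)$, with defaults at the published point
  estimates: $\beta_{NDI} = 1.0237$, $\theta = 0.2813$,
  $\beta_{low} = 14.9609$, $\beta_{high} = -4.1182$, $\gamma = 0.158$,
  control coefficients from the published baseline column, and
  $\sigma = 0.5$. A urbanisation main effect is available (`lu_coef`) but
  defaults to 0, matching the stated DGP so the noise-free limit identifies
  the baseline exactly. A constant-returns outcome with slope 0.1917 is
  generated alongside.
* `censor_frac` left-censors the outcome at its empirical quantile (the bound
  travels with the panel) for Tobit experiments; `endog_rho` pushes a shared
  confounder into both the information sub-index and the error while the
  shipped instrument is built from the *pre-confounding* index, so it stays
  relevant and exogenous — the configuration used to demonstrate that 2SLS
  removes the OLS bias.
* `sigma_eps = 0` is explicitly allowed: the noise-free limit is the
  identification check (OLS recovers the generating coefficients to
  $10^{-8}$ relative error), and several exactness tests rely on it.

**What passing tests show — and what they do not.** The generator emulates
marginal distributions, effect sizes and the panel geometry; it does not
emulate spatial autocorrelation between provinces, serial correlation within
provinces, measurement error in yearbook quantities, or any feedback from
eco-efficiency to infrastructure investment. Recovery results on this DGP
therefore validate the *estimators and plumbing*, not the substantive
conclusions one would draw from real data; with real panels the pooled-OLS
independence assumptions deserve scrutiny that synthetic validation cannot
provide.

## 6. Validation design and problem sizes

The test suite validates each stage against independent oracles: hand
arithmetic for the accounting worked examples; closed-form and
vertex-enumeration oracles for the DEA scores; hand-computed entropy and
coupling examples for the index; exact noise-free identities, degenerate-limit
collapses (Tobit→OLS, 2SLS→OLS), and seeded Monte-Carlo recovery for the
regressions. The Monte-Carlo blocks use 50 replicate panels for threshold
recovery (the cut point must land within one grid step of the truth in at
least 90% of seeds), 200 replicate panels for 95%-interval coverage of the
baseline slope, the interaction and the Tobit slope (coverage within
90–100%), and 100 replicate panels for the OLS-vs-2SLS bias comparison.
These sizes give binomial standard errors of 1.5–4 percentage points on the
checked rates, tight enough to detect a broken estimator while keeping the
default suite fast; pipeline-level tests run on 12×5 panels for the same
reason.

## 7. Known limitations

* The simplex solver is dense and written in R; it is comfortable at a few
  hundred DMUs per frontier (one LP solves in well under 0.1 s) but is not
  intended for thousands of units per group.
* Only the two-regime and sequential three-regime threshold models are
  implemented; confidence intervals for the threshold location itself
  (likelihood-ratio inversion) are not.
* The Tobit implementation covers lower (and optional upper) censoring with
  homoskedastic normal errors; no random-effects or semiparametric variant.
* Standard errors are not clustered by unit anywhere, matching the source
  methodology; with real panels, clustering would usually be advisable.
* Directional-distance, EBM and network DEA variants, Malmquist
  decompositions and spatial econometric models are out of scope.
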