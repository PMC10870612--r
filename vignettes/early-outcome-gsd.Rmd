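---
title: "Planning group sequential trials with early longitudinal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning group sequential trials with early longitudinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlygsd)
```

## The problem

In a two-arm randomized trial with a continuous outcome measured at occasions
$d_1 < d_2 < \dots < d_s$ after recruitment, the treatment effect of interest
is $\beta_s$, the between-arm difference at the primary endpoint time $d_s$.
When follow-up is long — say a 12-month primary endpoint recruited over 24
months — the window in which an interim analysis of primary data alone could
stop the trial is narrow: by the time enough 12-month data exist, recruitment
is nearly finished. If the earlier assessments (3 and 6 months) are correlated
with the final one, a generalized least squares (GLS) analysis of the whole
longitudinal record recovers part of the missing primary-outcome information
from participants who have, so far, only early data. This package provides
closed-form accounts of how much information that recovers, as a function of
calendar time, so that interim analyses can be planned without
individual-participant simulation; a group sequential engine to turn
information fractions into boundary-crossing probabilities and power; and a
simulator plus GLS monitoring estimator that validate the closed forms.

## Data model

Participant $i$ in arm $j$ contributes a multivariate normal outcome vector
with occasion means $\mu_{jr}$ and covariance
$\Sigma = S^{1/2} R S^{1/2}$, where $S$ holds the occasion variances
$\sigma_r^2$ and $R$ is the working correlation. At calendar time $t$ during
the trial a participant recruited at time $u$ has observed exactly the
occasions with $u + d_r \le t$: missingness is monotone (each record is a
prefix of the schedule) and purely administrative. With known $\Sigma$ the GLS
estimator $\hat\beta = (\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}\sum_i
X_i'\Sigma_i^{-1}y_i$ is unbiased with covariance
$(\sum_i X_i'\Sigma_i^{-1}X_i)^{-1}$.

The design matrix convention is a cell-means parameterization: columns
$1,\dots,s$ are occasion indicators (the control-arm occasion means) and
columns $s+1,\dots,2s$ are occasion-by-treatment indicators, so the final
coefficient is $\beta_s$ itself. This choice is fixed and documented because
only "separate fixed effects per occasion" is required conceptually; any
full-rank reparameterization gives the same $\hat\beta_s$ and variance.

## Recruitment models

`recruitment_model()` implements three deterministic accrual shapes over a
recruitment period $T_R$, all recruiting $N$ participants in total with mean
rate $N/T_R$:

| model | rate $\lambda(t)$ | accrual shape $g(u)$, $u = t - d_r$ | $k$ |
|---|---|---|---|
| fixed | $N/T_R$ | $u$ | $N/T_R$ |
| increasing | $2Nt/\{T_R(T_R+1)\}$ | $u(u+1)$ | $N/\{T_R(T_R+1)\}$ |
| decreasing | $2N(T_R-t+1)/\{T_R(T_R+1)\}$ | $u(2T_R-u+1)$ | $N/\{T_R(T_R+1)\}$ |

The expected number of participants with occasion-$r$ data at time $t$ is
$N_r(t) = k\,g_r(t, d_r)$, clamped to $0$ before $d_r$ and to $N$ after
$d_r + T_R$. Counts are kept real-valued internally; table renderers round
for display. A fourth model can be plugged in by any pair $(k, g)$ with $g$
non-negative, non-decreasing and $g(0) = 0$.

Two conventions coexist deliberately. The $(T_R+1)$ factors arise from a
discrete (integer-day) rate derivation and are kept in $k$ exactly, because
they reproduce the published planning numbers; accrual is nevertheless
evaluated as a continuous function of $t$. The participant simulator, by
contrast, draws recruitment times from the continuous-time densities
proportional to $\lambda(t)$ (inverse CDFs: uniform, $T_R\sqrt{u}$,
$T_R(1-\sqrt{1-u})$). For the fixed model the two conventions coincide
exactly; for the other two the expected counts differ by $O(N/T_R)$ — one to
two participants at $T_R = 8$ — which is why the simulator's accrual tests
compare against the continuous-time expectation while the planning formulas
keep the printed form. Monte Carlo validation of variances is done under the
fixed model, where there is no discrepancy.

`time_at_tau0()` inverts the primary-outcome accrual curve: for the fixed
model linearly, for the other two via the root of the corresponding quadratic
inside $(0, T_R]$. Interim times are always recomputed this way rather than
tabulated.

## Correlation models and the variance of $\hat\beta_s$

Two single-parameter working correlations are supported, chosen because both
admit closed-form inverses and therefore closed-form variances:

* **uniform** (compound symmetry): $\rho_{rr'} = \alpha$ for all pairs — the
  natural model when within-participant correlation is driven by stable
  subject characteristics, common for patient-reported outcome measures;
* **exponential** (AR(1)-type): $\rho_{rr'} = \gamma^{|d_r - d_{r'}|}$,
  decaying with time separation; $\gamma$ is the correlation at unit
  separation and `gamma_from_reference()` calibrates it from a known
  correlation between any two occasions.

The parameter is restricted to $[0, 1)$; the value 1 makes $R$ singular, and
the limiting variances are instead available analytically (all information
concentrates in the first occasion). Only relative spacings matter for the
exponential model, so `rescale_schedule()` normalises a schedule to
$d_1 = 1$.

Writing $h_r = (N0_r + N1_r)/(N0_r N1_r)$ for the per-occasion "harmonic"
count term, the monotone data structure gives

$$\mathrm{var}(\hat\beta_s^{\mathrm{unif}}) = \sigma_s^2\Big[h_1 +
\sum_{m=1}^{s-1} D_m\,(h_{m+1}-h_m)\Big],\qquad
D_m = \frac{(1-\alpha)(1+m\alpha)}{1+(m-1)\alpha},$$

where $D_m$ is the ratio of successive compound-symmetry determinants
$\det(R_{m+1})/\det(R_m)$, and, with $c_r = \gamma^{2(d_s-d_r)}$,

$$\mathrm{var}(\hat\beta_s^{\mathrm{exp}}) = \sigma_s^2\Big[h_1 c_1 +
\sum_{r=2}^{s} h_r\,(c_r - c_{r-1})\Big].$$

The second expression is an algebraically telescoped form of the usual
backward-indexed sum; the two are identical term by term. Both formulas
depend on $\sigma_s$ and the correlations only — the early-occasion SDs
cancel — which the test suite verifies against the structure-free
information-matrix computation `gls_variance_oracle()` on random
configurations. At $s = 2$ both reduce to the familiar two-occasion formula,
and at zero correlation to $\sigma_s^2/\{k\phi(1-\phi)g_s(t,d_s)\}$.

## The variance-reduction factor V and its extrema

$V_s(t)$ is the ratio of $\mathrm{var}(\hat\beta_s)$ with early outcomes to
the variance using primary data alone; $1/V$ is the proportionate information
gain. It depends on the data only through the count ratios
$n_{sr}(t) = g_s/g_r$, satisfies $n_{s1}(t) \le V \le 1$, and decreases
monotonically in the correlation parameter.

Over placements of the intermediate occasions between fixed $d_1$ and $d_s$,
the uniform-model V has closed-form extrema (`v_uniform_extrema()`): the
minimum moves all intermediate occasions to $d_1$ (maximal data, unchanged
correlation), the maximum moves them to $d_s$. The exponential model's
maximum is likewise closed-form (`v_exp_max()`), but its minimum trades data
quantity against correlation decay and is found numerically
(`v_exp_min()`): linearly constrained BFGS from an equal-spacing start,
strict ordering enforced with a $10^{-6}$ minimum gap, using analytic
gradients

$$\frac{\partial V}{\partial d_m} = (c_m - c_{m-1})\,
\frac{g_s\,g'(u_m)}{g_m^2} \;-\; 2\ln\gamma\,(n_{sm} - n_{s,m+1})\,c_m,$$

which the tests validate against central finite differences (step $10^{-6}$)
and against dense grid searches for $s = 3, 4$ (agreement to $10^{-4}$).
At $\gamma = 0$ the objective is constant at 1 and the optimizer is bypassed.

## Information fractions

With end-of-study information $I_{\max} = N\phi(1-\phi)/\sigma_s^2$, the
information fraction at time $t$ splits as $\tau(t) = \tau_0(t)/V_s(t)$:
$\tau_0(t) = N_s(t)/N$ is the part contributed directly by primary-outcome
data, and $1/V$ the multiplier contributed by the early outcomes
(`information_fraction()` returns all the pieces).

## Group sequential engine

Sequential z-statistics at increasing information levels follow the canonical
joint distribution: $Z_k \sim N(\delta\sqrt{I_k}, 1)$ with
$\mathrm{cov}(Z_j, Z_k) = \sqrt{I_j/I_k}$. First-exit probabilities through
lower (futility) and upper (efficacy) z-boundaries are computed by the
standard recursion over the continuation density, discretised with composite
Simpson quadrature on 1025 nodes per analysis, the continuation region
clipped to $\pm 8$ SDs around the marginal mean (truncation error below
$10^{-15}$; halving the step changes probabilities by less than $10^{-6}$,
and agreement with deterministic multivariate-normal quadrature is at the
$10^{-6}$ level). Infinite upper bounds encode "no efficacy stopping at this
look". Testing is one-sided throughout — the final shared bound near 1.91 in
the worked example is not a two-sided 1.96 rule — and rejection means
crossing an upper bound.

`solve_boundaries()` root-solves bounds sequentially (analysis $1 \to K$)
from target null first-exit probabilities, a spending specification by
increments; zero targets produce sentinel infinite bounds.
`sample_size_for_power()` exploits that drift scales with
$\sqrt{I_{\max}} \propto \sqrt{N}$, making power monotone in $N$, and binary
searches for the smallest integer $N$ meeting a target.

`futility_probability_fixed_bounds()` implements a specific monitoring
semantics: the planned z-scale lower bounds are held fixed while the realized
information varies (because an interim was moved, or the true correlation
differs from the planning value). This convention reproduces the published
futility-stopping spot values and is the documented meaning of the
`fig2_grid()` probability surface. One printed reference value resists all
conventions we tried: the two-interim probability at (first interim 4.5,
correlation 0) computes to 0.530 under the canonical joint distribution
(confirmed against an exact bivariate-normal evaluation), where 0.525 was
reported; the four single-interim values match to three decimals.

## Simulator and monitoring estimator

`simulate_trial()` is the Monte Carlo oracle: recruitment times from the
continuous-time inverse CDFs, deterministic arm totals in randomized order
(a Bernoulli option exists; the stratified default removes allocation noise
from variance checks), complete MVN outcome vectors via a Cholesky factor,
then truncation to the administratively observable prefix. Identical seeds
give identical datasets. Missingness arises only from shortened follow-up —
no dropout model.

`gls_fit()` estimates the model with known (plug-in) $\Sigma$, grouping the
computation by missingness pattern and arm (at most $2s$ distinct blocks;
identical results to the per-participant sum, which the tests verify against
a naive implementation). Occasions observed in only one arm are not
identifiable; their columns are dropped and flagged. `estimate_covariance_ml()`
maximises the profile likelihood over the correlation parameter and occasion
SDs with the means profiled out by GLS at each candidate, for monitoring
realism; REML refinements and post-stopping bias corrections are out of
scope, and the plug-in variance understates uncertainty slightly when
$\Sigma$ is estimated — no correction is applied.

## Reference table conventions

`v_factor_tables()` reproduces the planning grids: schedules on $[1, 2]$
with equal spacing $d_r = 1 + (r-1)/(s-1)$, recruitment period $T_R = 4 d_s$
(chosen so the three tabulated interims at $\tau_0 = 0.15/0.30/0.45$ fall in
the usable window; exposed as an argument), and the cross-family calibration
$\gamma = \alpha^{1/(d_s - d_1)}$ that equates the first-to-final correlation
and hence the two maxima. Printed-table comparisons in the tests allow
$\pm 0.01$ beyond the 2-dp precision because the original rounding rule is
unknown.

## Problem sizes used in validation

The package's stochastic checks use: 2,000 replicate trials of $N = 188$ for
the empirical-variance recovery at the first replanned interim (plus 800 at
zero correlation), $N = 500$ single datasets for ML correlation recovery
(3-SE bands from the likelihood Hessian), 300 replicates of $N = 80$ for the
independent-increments covariance of sequential z-statistics, $10^6$
multivariate-normal draws for the Monte Carlo check of the exit-probability
recursion, and 200/1,000-case random sweeps for the oracle-equivalence and
extrema-bracketing properties. These sizes make 3-standard-error bands tight
enough to detect formula errors of practical magnitude while keeping the
default test run to a few minutes.

## What the synthetic data do and do not show

The simulator emulates exactly the assumptions of the planning model:
multivariate normal outcomes, a correctly specified single-parameter
correlation, deterministic accrual shape, monotone administrative
missingness, no dropout, no site effects. Passing tests therefore demonstrate
internal consistency — the closed forms equal the GLS variance under the
stated model — not robustness to informative dropout, non-normal outcomes,
site-driven recruitment surges, or misspecified correlation families, all of
which are real-data phenomena outside this package's scope. The worked
example's own history is a caution: the realized correlation (about 0.75)
exceeded the planned 0.5, and the realized recruitment pattern differed from
any of the three models.
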