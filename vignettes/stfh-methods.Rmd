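---
title: "Spatio-temporal Fay-Herriot models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal Fay-Herriot models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stfh)
```

## The estimation problem

National household surveys are powered for national and regional estimates;
at finer administrative levels (zones, districts) the per-domain samples are
small and the *direct* survey estimator — unbiased, but using only that
domain's sample — has a variance too large to act on. Small area estimation
replaces the direct estimate with a model-based compromise that borrows
strength from auxiliary covariates (typically census proportions),
neighbouring areas, and earlier survey rounds. The canonical application
this package emulates is zone-level estimation of child undernutrition
z-score means from a handful of survey rounds plus census covariates.

## The model family

For area $i = 1,\dots,m$ and period $t = 1,\dots,T$ the two-stage
area-level model is

$$\hat\theta_{it}^{\mathrm{dir}} = \theta_{it} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma_{it}^2) \ \text{known},$$
$$\theta_{it} = x_{it}^\top \beta + \nu_{1i} + \nu_{2it},$$

with a simultaneous-autoregressive (SAR(1)) spatial area effect
$\nu_1 \sim N\!\big(0,\ \sigma_1^2\,\Omega_1(\rho_1)\big)$,
$\Omega_1 = [(I-\rho_1 W)^\top (I-\rho_1 W)]^{-1}$ on a row-standardized
proximity matrix $W$, and a stationary AR(1) area-by-period effect
$\nu_{2it} = \rho_2 \nu_{2i,t-1} + \epsilon_{2it}$,
$\epsilon_{2it} \sim N(0,\sigma_2^2)$, independent across areas, so that
$\mathrm{cov}(\nu_{2i}) = \sigma_2^2\,\Omega_2(\rho_2)$ with
$\Omega_2[t,s] = \rho_2^{|t-s|}/(1-\rho_2^2)$.

Stacking area-major / time-minor ($\text{row} = (i-1)T + t$), the full
covariance is

$$\mathrm{var}(y) \;=\; \sigma_1^2\,(\Omega_1 \otimes J_T)
\;+\; \sigma_2^2\,(I_m \otimes \Omega_2) \;+\; \mathrm{diag}(\sigma^2_{it}),$$

and $\tau = (\sigma_1^2, \rho_1, \sigma_2^2, \rho_2)$ collects the
covariance parameters. Three nested model tags share this representation:

| tag  | free parameters              | interpretation                        |
|------|------------------------------|---------------------------------------|
| `fh`   | $\sigma_2^2$               | independent cell effects (classical Fay-Herriot on the stacked cells) |
| `sfh`  | $\sigma_1^2, \rho_1$       | SAR(1) area effects, constant over periods |
| `stfh` | all four                   | spatial + temporal borrowing           |

Setting $\rho_1 = \rho_2 = 0$ and $\sigma_1^2 = 0$ reduces the
spatio-temporal model to cell-wise independent Fay-Herriot shrinkage; the
acceptance suite verifies this reduction against the scalar closed form
$\hat\gamma y + (1-\hat\gamma) x^\top\hat\beta$,
$\hat\gamma = \hat\sigma^2/(\hat\sigma^2 + \sigma_{it}^2)$.

Periods are treated as equally spaced integers $1..T$ even when the survey
labels are unequally spaced years (5/6/5-year gaps in the motivating
application); the unit-lag AR(1) is the only temporal structure exposed.

## REML, EBLUP, and uncertainty

Variance components maximize the Gaussian restricted likelihood

$$\ell_R(\tau) = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
\log|X^\top V^{-1}X| + y^\top P y\right],$$

the standard definition (the model family's literature names REML without
printing a criterion). $V$ is Cholesky-factorized once per evaluation (in
compiled code; no explicit inverses), and the optimizer works on
transformed parameters: $\log \sigma^2$ for variances, and tanh maps for
the autocorrelations onto their admissible intervals — $|\rho_2| < 1$, and
$\rho_1 \in (\max(-0.999,\ 1/\omega_{\min} + 10^{-6}),\ 0.999)$ with
$\omega_{\min}$ the smallest real eigenvalue of $W$, which keeps
$I - \rho_1 W$ nonsingular. Bounded quasi-Newton (L-BFGS-B, iteration cap
500, objective tolerance $\sim 10^{-8}$ relative, projected gradient
$10^{-5}$) with a Nelder-Mead fallback on line-search failure; two starts
($\sigma^2$ at half the median sampling variance with $\rho = 0$, plus
$\rho_1 = 0.5, \rho_2 = -0.3$) guard against multimodality in $\rho_2$.

Numerical conventions worth knowing:

* variance estimates below $10^{-10}$ are reported as 0 with a boundary
  flag, and the corresponding autocorrelation — unidentified when its
  variance vanishes — is reported as 0. (In a null-spatial world the
  likelihood is *flat* in $\rho_1$; any value would be equally likely, so
  reporting the boundary convention is the only honest summary.)
* evaluation at $\sigma^2 = 0$ exactly is permitted; optimization on the
  log scale approaches but never hits it.
* the `converged` flag is false whenever the iteration cap is reached.

The EBLUP is $\hat\theta = X\hat\beta + \hat V_\nu Z^\top \hat V^{-1}
(y - X\hat\beta)$, computed as $y - D \circ (\hat V^{-1} r)$. For the FH
tag, MSE uses the Prasad-Rao decomposition $g_1 + g_2 + 2g_3$ with the
REML information variance $\mathrm{var}(\hat\sigma^2) = 2 / \sum_j
(\hat\sigma^2 + \sigma_j^2)^{-2}$. For the spatial and spatio-temporal
models no analytic $g_3$ is published for this covariance family, so the
supported path is the parametric bootstrap: draw effects and sampling
errors from the fitted model, refit, predict, and average
$(\hat\theta^* - \theta^*)^2$. Both bootstrap modes are provided — refit
per replicate (default, matching the methodology the model family cites)
and fixed-$\tau$ (which targets $g_1 + g_2$ only and is used to
cross-validate against the analytic FH components). Replicates whose refit
fails to converge are redrawn up to a 10% cap, then the bootstrap errors
out rather than silently biasing the MSE. All periods are predicted; the
final period is flagged as the headline, since the spatio-temporal model's
purpose is to enhance the current survey round.

## Diagnostics

The assessment battery mirrors standard practice for this model family:
$-2\ell_R$, AIC $= -2\ell_R + 2k$ and BIC $= -2\ell_R + k\log n$ with
$k = p + \#\{\text{free covariance parameters}\}$ (FH $p+1$, SFH $p+2$,
STFH $p+4$) — comparable only across models fitted to identical stacked
data with identical $X$, which the `compare` pipeline enforces; a
Kolmogorov-Smirnov check of the standardized marginal residuals
$\mathrm{diag}(\hat V)^{-1/2}(y - X\hat\beta)$ against $N(0,1)$ using the
asymptotic null (parameters are estimated from the same data — the
Lilliefors caveat — which makes the p-value mildly conservative; it is
documented, not corrected); the bias-diagnostic OLS regression of direct on
model-based estimates, where (slope, intercept) near (1, 0) supports
validity; CV% $= 100\sqrt{\mathrm{MSE}}/|\hat\theta|$ with cells under
$|\hat\theta| < 10^{-8}$ flagged unstable instead of reported (the target
is a z-score mean and may legitimately be near 0); and the efficiency gain
$100\,(\mathrm{CV}_{\mathrm{ref}} - \mathrm{CV}_{\mathrm{model}}) /
\mathrm{CV}_{\mathrm{ref}}$, the relative CV reduction — the one common
definition bounded above by 100 and unbounded below, consistent with
published summaries that show negative minima — reported per area with a
Min/Q1/Mean/Median/Q3/Max block.

## The synthetic world

Because the motivating study's inputs are registration-restricted, every
claim this package tests is established on synthetic panels with known
truth. The generator draws exactly from the model: $\nu_1$ through the
*symmetric* square root of $\sigma_1^2 \Omega_1$ (symmetric rather than
Cholesky so that relabelling areas permutes the draw), $\nu_2$ initialized
at the stationary law $N(0, \sigma_2^2/(1-\rho_2^2))$ and recursed (so the
$\Omega_2$ scaling is exact at every $t$), and heteroscedastic sampling
errors with known variances. Random draws come from sub-streams keyed by
(seed, component, area id), so toggling one component leaves the others'
draws unchanged and generators are pure functions of the scenario; each
sub-stream discards ten uniforms after seeding, since first draws from
numerically related Mersenne-Twister seeds are weakly cross-correlated.

Defaults state a world resembling the motivating application and are not
revisited: $m = 83$ zones on a random contiguity graph, $T = 4$ rounds,
$p = 6$ covariates (intercept plus five time-constant uniform
proportions, emulating census auxiliaries held fixed across rounds),
cell-level sampling variances $\sim U(0.005, 0.05)$ (z-score scale), and
$\tau = (0.001, 0.95, 0.01, -0.6)$ — small spatial variance, strong
positive spatial correlation, moderate negative temporal correlation, the
regime reported for such indicators. $\beta$ defaults to
$(-1, 0.5, \dots)$, giving z-score-scale means. Two named test scenarios
are fixed: a strong-signal recovery scenario
$\tau = (0.5, 0.8, 0.25, -0.6)$, $m = 60$, $T = 4$, $p = 2$,
$\beta = (3, 1)$, where all four components are well identified; and a
weak-signal scenario with the default $\tau$ at the same shape, where
effect variances are comparable to sampling variances so shrinkage — and
hence the CV ordering STFH < SFH < direct — is material. $\beta = (3,1)$
keeps $|\theta|$ away from 0 so CV% is well defined everywhere.

What the generator does *not* emulate: unit-level (child-level)
anthropometry and survey weighting, unbalanced panels, GPS displacement,
non-Gaussian sampling errors, or informative sampling. A green simulation
test therefore establishes correctness of the estimator machinery under
the stated model, not robustness to those real-data features.

In simulation experiments the covariates and sampling variances are held
fixed across replicates (they are survey-design quantities) while effects
and errors are redrawn; empirical MSEs therefore condition on the design,
which is what the bootstrap MSE estimates.

## Open design choices made here

* **SFH has two roles.** For information-criteria comparison all three
  tags are fitted to the identical stacked panel with identical $X$ (REML
  criteria are otherwise incomparable). For CV and root-MSE comparison the
  spatial model is fitted to the final-period slice — the way a
  single-round spatial analysis is actually produced — via
  `panel_slice()`.
* **Bootstrap refit is the default** (the cited methodology re-estimates);
  the fixed-$\tau$ mode is flagged in `mse_method` output.
* **Published-table quirks are not reproduced.** One published comparison
  table prints an AIC smaller than its $-2$LL, which is arithmetically
  impossible; the package asserts its own identities. Prose that scales
  correlations to percentages is ignored: correlations are reported on
  $[-1, 1]$.
* **Time labels are opaque**: survey years are carried as labels, modeled
  as periods $1..T$.

## Limitations

Balanced panels only; no missing cells; no analytic Prasad-Rao $g_3$
outside the FH tag; no confidence intervals or benchmarking to higher-level
totals; proximity must be supplied as a matrix or neighbor list (no
shapefile ingestion). Every empirical statement above is computed by the
test suite or the pipeline itself; none is quoted from external results.
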