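# stfh — spatio-temporal Fay–Herriot small area estimation

Surveys are powered for national or regional estimates; below that level
the per-domain samples are too small and the **direct** survey estimator is
too noisy to act on. `stfh` implements the area-level small area
estimation stack that addresses this for balanced zone-by-round panels:
the Fay–Herriot (FH) model, its spatial extension with SAR(1) area effects
(SFH), and the spatio-temporal extension with SAR(1) × AR(1) effects
(STFH), which borrows strength from covariates, neighbouring areas *and*
earlier survey rounds at once. The intended audience is statisticians
producing sub-regional estimates of survey indicators — the motivating use
case is zone-level child-undernutrition z-score means from a few DHS-style
survey rounds plus census covariates.

## The model

For area *i* = 1..m and period *t* = 1..T, with known sampling variances:

    θ̂ᵢₜ = θᵢₜ + εᵢₜ,          εᵢₜ ~ N(0, σᵢₜ²)  (known)
    θᵢₜ = xᵢₜᵀβ + ν₁ᵢ + ν₂ᵢₜ

    ν₁ ~ N(0, σ₁² Ω₁(ρ₁)),    Ω₁ = [(I − ρ₁W)ᵀ(I − ρ₁W)]⁻¹   (SAR(1))
    ν₂ᵢₜ = ρ₂ ν₂ᵢ,ₜ₋₁ + ε₂ᵢₜ,  cov(ν₂ᵢ) = σ₂² Ω₂(ρ₂),
                               Ω₂[t,s] = ρ₂^|t−s| / (1 − ρ₂²)   (AR(1))

W is a row-standardized proximity (contiguity) matrix. Variance components
τ = (σ₁², ρ₁, σ₂², ρ₂) are estimated by REML; predictions are EBLUPs; MSE
comes from the Prasad–Rao decomposition g₁+g₂+2g₃ (FH) or a parametric
bootstrap (SFH/STFH). Diagnostics: −2LL/AIC/BIC, Kolmogorov–Smirnov
residual normality, bias-diagnostic regression, CV% and efficiency-gain
summaries. A synthetic-data module generates panels with known truth so
every claim is testable without restricted survey microdata.

## Worked example

```r
library(stfh)
sc  <- simulation_scenario(m = 30, T = 4, p = 2,
                           tau = variance_components(0.001, 0.95, 0.01, -0.6),
                           beta = c(3, 1), seed = 42)
sim <- simulate_panel(sc)                  # panel + proximity + known truth
fit <- fit_model(sim$panel, sim$W, "stfh")
fit
#> STFH model fit by REML (30 areas x 4 periods)
#>   log-restricted-likelihood: 24.6070  (converged: TRUE)
#>   sigma1^2  4.13804e-05
#>   rho1      0.998988
#>   sigma2^2  0.00675355
#>   rho2      -0.765293
#>   fixed effects:
#> intercept        x1
#>   2.92099   1.02094
```

The fitted variance components sit in the regime the generator stated:
tiny spatial variance with strong positive spatial correlation, and a
moderate negative temporal correlation. (With σ₁² this small, ρ₁ is barely
identified and drifts toward its admissible bound — expected, and why the
package reports a boundary flag when a variance collapses entirely.)

```r
pred <- mse_bootstrap(fit, sim$panel, sim$W, B = 100, seed = 42)
head(pred, 4)
#>  area_id time   direct var_direct    eblup         mse   root_mse cv_direct cv_model
#>      A01    1 4.132940 0.03934814 4.038488 0.007683309 0.08765449  4.799577 2.170478
#>      A01    2 3.882498 0.02685721 3.850051 0.007272609 0.08527959  4.221038 2.215025
#>      A01    3 4.162174 0.01361348 4.069546 0.005436209 0.07373065  2.803266 1.811766
#>      A01    4 3.844571 0.03140017 3.852577 0.007709542 0.08780400  4.609122 2.279098

fin <- pred[pred$time == "4", ]            # headline (current) period
efficiency_gain(fin$cv_direct, fin$cv_model)$summary
#>   Min     Q1   Mean Median     Q3    Max
#> 13.78  30.23  40.45  42.39  49.93  58.08
```

Reading: per-cell bootstrap MSEs (~0.004–0.008) are 3–5× smaller than the
direct sampling variances, so the spatio-temporal EBLUP cuts CV% by a
median 42% at the final period here — the kind of precision gain that
makes sub-regional estimates usable.

```r
information_criteria(fit)
#> -2LL = -49.21, AIC = -37.21, BIC = -20.49   (lower = preferred)
```

## Command-line pipeline

```sh
Rscript inst/cli/stfh.R simulate --seed 5 --out runs/demo
Rscript inst/cli/stfh.R fit      --panel runs/demo/panel.csv \
    --proximity runs/demo/proximity.csv --model stfh --out runs/demo
Rscript inst/cli/stfh.R predict  --panel runs/demo/panel.csv \
    --proximity runs/demo/proximity.csv --model stfh --bootstrap-B 200 \
    --seed 5 --out runs/demo
Rscript inst/cli/stfh.R compare  --panel runs/demo/panel.csv \
    --proximity runs/demo/proximity.csv --out runs/demo
```

Formats: comma-separated panels (`area_id,time,y,var_y,x1,...`), proximity
as dense matrix or `area_id,neighbor_id` list (auto-detected,
row-standardized on load), JSON configs. Identical seed ⇒ byte-identical
outputs except the `# created:` header line.

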