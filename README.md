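# lactowave

Microwave dielectric spectroscopy of raw bovine milk as a non-invasive
pregnancy monitor for dairy cows.

Milk is ~87% water, and the 0.5–40 GHz dielectric response of that water
tracks how much of it is bound in the hydration shells of milk solids —
above all the membranes of milk fat globules, whose size and number respond
to reproductive hormones. `lactowave` implements the complete analysis
chain for exploiting this: the permittivity model and its fitter, a
synthetic longitudinal cohort generator, a staged variability-reduction
analysis, correlation/PCA summaries of the fitted parameters, and a
self-normalizing neural-network classifier of pregnancy status.

## The model

The complex permittivity of milk in the microwave band is

ε\*(ω) = ε∞ + Δε / (1 + (iωτ)^α) + σ_dc / (iωε₀) + A·(iω)^(n−1)

— a Cole–Cole relaxation of bulk water (dielectric strength Δε, relaxation
time τ, symmetric broadening α), a dc-conductivity term from ionic
mobility, and a Jonscher power-law tail for sub-band processes. Losses are
reported as ε″ = −Im ε\*. Pregnancy manifests as a contraction (and slight
downward shift) of the day-to-day dispersion of the fitted parameters,
most visibly in Δε: successful insemination is followed by a large drop in
Δε variability after pregnancy day 16, while failed inseminations leave
the variability unchanged.

## Worked example

Simulate the pregnant reference cohort (5 cows, daily sampling; 66
pre-insemination points, 8 in pregnancy days 1–15, 14 from day 16 on;
three replicate spectra per sample at 5% instrument noise), fit every
spectrum, and measure the staged variability drop:

```r
library(lactowave)

coh  <- fit_cohort(simulate_cohort(design_preset("pregnant_fixture", seed = 1)))
drop <- variability_drop(coh$table, "delta_eps", c("stage1", "stage3"))
drop$summary[, c("stage", "n_points", "mean_delta_eps", "sd_delta_eps")]
#>    stage n_points mean_delta_eps sd_delta_eps
#> 1 stage1       66       67.63885    0.5947294
#> 2 stage2        8       67.43783    0.2176914
#> 3 stage3       14       67.11793    0.3822101
drop$drop_pct
#> [1] 35.7  # percent reduction in delta-eps SD, stage 1 -> stage 3 (this seed)
```

The fitted dielectric strength carries the negative fat coupling (more fat
globule surface binds more water and depresses the bulk-water dispersion):

```r
cm <- correlation_matrix(coh$table)
cm$r["delta_eps", "fat_pct"]      # -0.59 on this seed (population value -0.66)
cm$p["delta_eps", "fat_pct"]      # 1.4e-09
```

And the SNN classifier separates pregnancy states on the cross-sectional
cohort (117 samples, 50 pregnant):

```r
rnd <- fit_cohort(simulate_cohort(design_preset("random_fixture", seed = 1)))
cls <- classify_pregnancy(rnd$table[, c("delta_eps", "tau_ps", "alpha", "sigma_dc")],
                          rnd$table$pregnant_outcome, seed = 1, test_per_class = 10)
cls$test_accuracy
#> [1] 0.8   # on the 20-point held-out test set (80 train / 20 test)
```

Single-seed numbers fluctuate; the calibrated expectations (44% pregnant
drop, 3.26% nonpregnant drop, r = −0.66) are recovered as seed averages —
see below.

An end-to-end run (simulate → fit → variability → correlation/PCA →
classifier) with a hashed artifact manifest:

```r
run_pipeline(run_config(design_preset = "random_fixture", seed = 1), "my_run")
```

A thin CLI over the same functions is installed at
`inst/exec/lactowave` (`lactowave simulate|fit|pipeline`).

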