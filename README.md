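# pdmbma — model-based meta-analysis of pharmacodynamic time courses

`pdmbma` implements a model-based meta-analysis (MBMA) pipeline for
aggregate (arm-level) longitudinal efficacy data, built around the
pharmacodynamics of cinacalcet in secondary hyperparathyroidism (SHPT):
pooled published trials report, per study arm, the mean serum PTH, calcium
and phosphorus response over follow-up, and the package estimates and
simulates structural time-course models on those summaries.

It is aimed at pharmacometricians and meta-analysts who work with
literature-level data rather than patient-level records: every observation
is an arm mean with a sample size, studies are the exchangeable unit, and
residual precision scales with arm size.

## The model

For a cinacalcet arm with baseline `B`, the decrease of a biomarker from
baseline at time `t` (months; 1 month = 4 weeks) is

* PTH (pg/mL): `ΔPTH(t) = Emax_i · t / (ET50 + t)` with
  `Emax_i = Emax + θ_B (B − 636)` — a hyperbolic onset whose maximal
  decrease grows with the baseline;
* serum calcium (mg/dL): `ΔCa(t) = Emax_i (1 − e^{−K t})` with
  `Emax_i = Emax + θ_VD (VD − 66)` where `VD` is the percentage of
  patients on vitamin-D compounds;
* serum phosphorus (mg/dL): `ΔP(t) = Emax (1 − e^{−K t})`, no covariates.

Study `s` deviates from the typical parameters through random effects
(`Emax_s = Emax · e^{η}` etc.), and an observed arm-mean change at time `t`
is `Normal(Δ(t), σ²/n)` for an arm of `n` subjects. Estimation maximizes
the marginal likelihood, integrating the study effects out by a Laplace
approximation (adaptive Gauss–Hermite quadrature is available as an
accuracy cross-check). Reported final estimates of these models (Emax 308
pg/mL, ET50 0.46 months, θ_B 0.503 for PTH; Emax 0.811 mg/dL, K
4.64/month, θ_VD −0.00588 for calcium; Emax 0.524 mg/dL, K 2.4/month for
phosphorus) ship as ready-made model objects.

## Worked example

```r
library(pdmbma)

# typical PTH trajectory for a patient pool starting at 600 pg/mL
pth <- shpt_pth_model()
simulate_profile(pth, baseline = 600, times_weeks = c(3, 6, 12, 24))
#> Typical PTH trajectory (baseline 600)
#>  time_weeks t_months typical
#>           3     0.75   420.3
#>           6     1.50   378.1
#>          12     3.00   348.6
#>          24     6.00   330.8

# onset time (months to half of the maximal effect) and target attainment
time_to_fraction(pth, 0.5)
#> [1] 0.46
baseline_threshold_for_target(pth, target = 600, horizon_months = 3)
#> [1] 1045.759
```

The trajectory says a typical pool starting at 600 pg/mL falls to about
349 pg/mL by week 12 — a ~30% reduction that has essentially plateaued —
and the solver says pools starting at ~1046 pg/mL or higher cannot reach
the 600 pg/mL guideline upper target within 12 weeks under monotherapy.

A full round trip on synthetic literature:

```r
d <- simulate_trials(shpt_scenario("PTH", seed = 1))   # 26 studies
fit <- mbma(d, shpt_pth_model())                        # Laplace ML
summary(fit)
vpc(fit, n_sim = 500, seed = 2)                         # predictive check
mbma_bootstrap(fit, B = 200, seed = 3)                  # study bootstrap
subgroup_effect(d, fit, "dialysis_months")              # median split
```

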