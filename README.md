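# warfinr

Bayesian warfarin dose individualization from INR measurements.

Warfarin has a narrow therapeutic window, a delayed indirect effect on
coagulation, and more than ten-fold between-patient variability in dose
requirement — yet it is monitored with a single cheap measurement, the
INR. `warfinr` implements the decision-support machinery for that setting:

* **Model core** — a kinetic-pharmacodynamic (KPD) model of INR response:
  one-compartment PK driving a sigmoid inhibition of vitamin-K-cycle
  activity, delayed through two parallel three-compartment transit chains,

  > dA/dt = −k₁₀·A,  DR = k₁₀·A,
  > EFF = Emax·DRᵞ / (EDK₅₀ᵞ + DRᵞ),
  > INR = INR_base + INR_max·(1 − (C₁,₃ + C₂,₃)/2),

  with covariate effects (age, bodyweight, CYP2C9 on clearance; VKORC1 on
  EDK₅₀) and log-normal between-subject variability on k₁₀ and EDK₅₀.
* **Solver** — fixed-step Heun (second-order Runge-Kutta) integration with
  exact handling of bolus dose events and observation times, compiled
  (Rcpp) with a pure-R reference engine cross-checked in the tests.
* **A priori dosing** — bisection on log-dose to the maintenance dose whose
  steady-state mean INR (100 simulated administrations, trapezoidal mean
  over the final interval) hits the midpoint of the target range within 1%;
  reported per day, per week, and as 2.5 mg tablets per week.
* **A posteriori dosing** — MAP estimation of the individual deviations
  (η_k10, η_edk50) from a dosing history plus INR observations, using
  Powell's direction-set method; a Laplace-approximation 90% prediction
  band; and dose re-optimization from the patient's current model state.
* **I/O and CLI** — YAML population configuration, a CSV dosing/INR history
  format with a covariate header, JSON/CSV outputs, and a `warfinr`
  command-line tool.
* **Synthetic patients** — a seeded generator and recovery/coverage
  experiments used to validate the estimator against itself.

**The bundled parameter set (`demo_population.yaml`) is a demo — not for
clinical use.** All population parameters are configuration, and a real
deployment must supply its own estimates.

## Worked example

A priori: recommended maintenance dose for a typical adult before any INR
has been observed.

```r
library(warfinr)
pop <- demo_config()

cov <- patient_covariates(age = 60, weight = 70, cyp2c9 = "*1/*1",
                          vkorc1 = "A/G", baseline_inr = 1.0,
                          target_low = 2, target_high = 3)
estimate_dose(resolve_missing_covariates(cov), pop)
#> Maintenance dose recommendation
#>   dose: 4.49 mg/day  (31.4 mg/week, ~13 x 2.5 mg tablets/week)
#>   steady-state mean INR: 2.502 (target 2.5)
```

Predicted INR under an explicit regimen (three loading doses, then
maintenance):

```r
reg <- build_regimen(4, n_doses = 10, loading_doses = c(10, 7.5, 5))
predict_inr(resolve_missing_covariates(cov), reg, pop)
#> Predicted INR: 2.375  [mean INR over the final dosing interval (steady state)]
```

A posteriori: fit an individual from a dosing history with INR
observations (here a synthetic patient: 8 days at 4 mg with INR measured
on days 3, 5 and 8), then re-optimize the dose from their current state.

```r
pt  <- draw_patient(pop, design = sparse_design(), seed = 42)
est <- fit_individual(pt$history, pop)
est
#> Individual (MAP) parameter estimate
#>   typical:    k10 = 0.016266 /h, EDK50 = 1.6 mg/h
#>   individual: k10 = 0.019659 /h, EDK50 = 1.1008 mg/h
#>   eta = (0.1894, -0.3740), objective = 1.696

estimate_dose_individual(est, pt$history, pop)
#> Maintenance dose recommendation
#>   dose: 1.97 mg/day  (13.8 mg/week, ~6 x 2.5 mg tablets/week)
#>   steady-state mean INR: 2.479 (target 2.5)
```

This patient is more sensitive than typical (η_edk50 < 0), so the
individualized dose is well below the a priori one. A 90% forecast band
for the coming week:

```r
band <- predict_band(est, build_regimen(2, n_doses = 7), pop,
                     level = 0.90, seed = 1)
head(band$table)
```

Real histories come from CSV files (`read_history()`; covariates in a
`# key: value` header, then `type,time,value` rows), and the same
workflows are scriptable via the CLI:

```sh
inst/cli/warfinr estimate-dose --config inst/extdata/demo_population.yaml \
    --age 60 --weight 70 --cyp2c9 '*1/*1' --vkorc1 A/G --target 2:3 \
    --out results/adult
```

Subcommands: `estimate-dose`, `predict-inr`, `fit`, `synth`; run the tool
without arguments for usage.

## Methods

The model equations, parameter conventions, numerical choices, estimation
and band construction, and the scope and limits of the synthetic-patient
generator are documented in `vignettes/warfarin-kpd-methods.Rmd`.

## License

MIT (see `LICENSE`).
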