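---
title: "Methods: the warfarin KPD model and its dose-individualization machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the warfarin KPD model and its dose-individualization machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warfinr)
```

## The model

Warfarin dosing is difficult because the drug has a narrow therapeutic
window, a slow and indirect effect on coagulation, and more than ten-fold
between-patient variability in dose requirement. `warfinr` simulates the
INR response with a kinetic-pharmacodynamic (KPD) model: the effect is
driven by the *dose rate* derived from the drug amount, not by measured
concentrations, which suits routine care where INR is measured but drug
levels are not.

The pharmacokinetic part is a single compartment with first-order
elimination and no explicit absorption phase; oral doses are bolus
additions to the amount $A$:

$$\frac{dA}{dt} = -k_{10} A, \qquad DR = k_{10} A,$$

with $k_{10} = CL/V$. The dose rate drives a sigmoid inhibition of
vitamin-K-cycle activity,

$$EFF = \frac{E_{max}\,DR^{\gamma}}{EDK_{50}^{\gamma} + DR^{\gamma}},$$

with $E_{max} = 1$. The delay between exposure and INR response is carried
by two parallel chains of three transit compartments each (mean transit
times $MTT_1$, $MTT_2$, rate $3/MTT_c$ per chain), both fed by the same
$(1-EFF)$ input:

$$\frac{dC_{c,1}}{dt} = \bigl((1 - EFF) - C_{c,1}\bigr)\frac{3}{MTT_c},
\qquad
\frac{dC_{c,j}}{dt} = \bigl(C_{c,j-1} - C_{c,j}\bigr)\frac{3}{MTT_c}.$$

Two chains with different transit times reproduce the biphasic INR
trajectory that a single chain cannot, plausibly reflecting the different
half-lives of the affected coagulation factors. The INR is read from the
terminal compartments:

$$INR = INR_{base} + INR_{max}\Bigl(1 - \frac{C_{1,3} + C_{2,3}}{2}\Bigr),$$

with $INR_{max} = 20$. Before treatment $A = 0$ and all activities are 1,
so the model sits exactly at the baseline INR.

Individual variability enters through log-normal random effects on
$k_{10}$ and $EDK_{50}$ (the two parameters displayed and individualized by
the tool); residual variability is additive on the INR scale by default,
with a proportional option in the configuration.

## Parameters and configuration

All population parameters are data, not code: they are loaded from a YAML
file (see `read_config()`), which declares typical clearance and volume,
per-VKORC1-genotype $EDK_{50}$ values with an explicit unit (`mg/h` or
`mg/day`, converted on load), $\gamma$, the two mean transit times, the
covariate relations (allometric weight exponents with a reference weight,
an exponential age slope on clearance, CYP2C9 clearance multipliers), the
between-subject variances $\omega^2_{k10}$, $\omega^2_{EDK50}$, and the
residual SD $\sigma$. The loader refuses missing or non-positive entries
and logs the file's provenance string.

The package deliberately ships no published parameter estimates. The
bundled `demo_population.yaml` is a physiologically plausible but
clinically invalid set chosen once for testing: $CL$ 0.2 L/h and $V$ 10 L
(typical $k_{10}$ = 0.02/h, terminal half-life about 35 h, in the range
reported for warfarin), $\gamma = 1$, $EDK_{50}$ of 3.0/2.3/1.6 mg/h for
G/G / A/G / A/A (A-allele carriers more sensitive), $MTT$ 30 and 110 h
(a fast and a slow chain, matching the day-scale and week-scale phases of
INR onset), $\omega^2$ of 0.09 and 0.16 (30% and 40% CV), and $\sigma$ =
0.15 INR, a realistic assay-plus-model residual. With these values a
typical 60-year-old, 70 kg A/G patient needs about 4.5 mg/day for a target
INR of 2.5 — a clinically familiar magnitude, which is all the demo set is
meant to achieve. Deployers must transcribe a published parameter set into
their own configuration before any result carries real-world meaning.

Missing covariates are imputed with fixed conventions: CYP2C9 `*1/*1`
(the highest-dose-requirement genotype), VKORC1 `A/G` for Caucasian or
unspecified ethnicity, `A/A` for Asians, `G/G` for Africans, baseline INR
1, dosing interval 24 h.

## Numerical integration

The ODE system is non-stiff and smooth between doses, so the solver is
Heun's method (the explicit trapezoidal second-order Runge-Kutta), fixed
step, default 0.1 h. The time grid is the union of the uniform steps with
every dose-event and observation time, so doses and observations are never
interpolated; a dose coincident with an observation time is applied first
and the observation read after. The hot loop is compiled (Rcpp); a pure-R
reference integrator with the same contract is kept and cross-checked in
the tests, along with checks against the analytic single-dose solution,
the Erlang step response of the transit chain, and an independent stiff
solver (`deSolve::lsoda`). At the default step the INR at 16 h post dose
is stable to better than $10^{-4}$ INR units.

## A priori dose estimation

The target INR is the midpoint of the prescribed range. For a candidate
dose, 100 repeated administrations are simulated and the steady-state INR
summarized as the trapezoidal mean over the final dosing interval. Since
the steady-state mean INR is strictly increasing in dose (the effect
function is strictly increasing in dose rate), the search brackets the
target geometrically starting from the conventional 10 mg/day and then
bisects on log-dose until the achieved INR is within 1% of the target —
the same 1% tolerance used for the steady-state criterion itself (INR
change between consecutive doses, compared at the matched 16-h post-dose
phase, not to exceed 1%). Dose bounds are 0.01–100 mg per administration,
far beyond any clinical range; an unreachable target inside those bounds
is an error, not a silent extrapolation. The weekly dose is reported as
the nearest count of 2.5 mg tablets, with exact half-tablet ties rounded
up (a deliberate, documented tie-break).

INR prediction for an arbitrary regimen reports the mean INR over the
final dosing interval when the steady-state criterion holds, and the INR
16 h after the last dose otherwise — morning sampling after an evening
dose — with the convention flagged explicitly in the result rather than
guessed by the reader.

## A posteriori (MAP) individualization

Given a dosing history and INR observations, the individual deviations
$\eta = (\eta_{k10}, \eta_{EDK50})$ are estimated by maximum a posteriori:

$$O(\eta) = \sum_j \frac{(INR_{obs,j} - INR_{pred,j}(\eta))^2}{\sigma^2}
 + \frac{\eta_{k10}^2}{\omega^2_{k10}}
 + \frac{\eta_{EDK50}^2}{\omega^2_{EDK50}},$$

minimized with Powell's direction-set method (Brent line searches, started
at the prior mode, inside a $[-3, 3]$ box with a single restart from a
perturbed point if the first run ends on the boundary; convergence when a
full cycle improves the objective by less than $10^{-8}$). Powell's method
is used because the estimation problem is two-dimensional, smooth but
derivative-free (the gradient would have to be pushed through the
integrator), and the method is simple and robust here; the tests
cross-check it against Nelder-Mead. Observations recorded before the first
dose inform the baseline INR only, never the fit.

The curvature reported with the estimate is the observed information of
the negative log-posterior (half the finite-difference Hessian of $O$);
its inverse is the Laplace-approximation covariance. With no observations
this reduces exactly to the prior covariance and the estimate to the
typical parameters.

The individualized dose re-runs the same dose search with the MAP
parameters, projecting from the model state at the end of the fitted
history ("Day 0"), so the recommendation accounts for drug and effect
already on board.

## Prediction bands

The 90% band draws $\eta$ from the Gaussian approximation
$N(\hat\eta, \text{curvature}^{-1})$, simulates each draw, and takes
pointwise 5th/95th percentiles around the MAP curve. By default residual
noise (SD $\sigma$) is added to each simulated curve, making the band
predictive for *measured* INRs; `include_residual = FALSE` gives the
narrower parameter-uncertainty band appropriate for covering the
noise-free INR curve. When a band is projected beyond an observed history,
each draw is propagated through the entire history plus the continuation,
so uncertainty in the accumulated transit-chain state at the projection
start is part of the band — pinning the start state to the MAP fit alone
demonstrably under-covers. Bands are seeded and bit-reproducible. A full
posterior (MCMC) treatment is out of scope; the Laplace band is the
documented approximation and its empirical coverage is measured by
simulation rather than assumed.

## The synthetic-patient generator

`draw_patient()` emulates exactly the statistical structure the estimator
assumes: covariates from documented fixture distributions (age uniform on
1–80 years, an age-linked weight curve, Caucasian-typical genotype
frequencies), $\eta$ from zero-mean Gaussians with the configured
$\omega^2$, the design's regimen simulated at the true individual
parameters, and additive Gaussian residual noise on the observations. Two
standard designs are bundled: a *sparse* arm (4 mg/day for 8 days, INR on
days 3, 5 and 8 — the one-to-three-observation scale on which such tools
are typically validated) and a *rich* arm (30 days, 20 observations) for
asymptotic checks.

Because generator and estimator share the same model family, passing
recovery tests demonstrates internal consistency — correct equations,
integration, optimization and uncertainty propagation — not clinical
validity. Real INR data have features the generator deliberately omits:
model misspecification, adherence lapses, assay and timing errors beyond
additive noise, drug interactions and time-varying diet or illness.

Problem sizes used by the bundled experiments (chosen to characterize the
estimator precisely while staying convenient to re-run): 50 rich-design
patients at $\sigma = 0.01$ for the bias check (observed mean bias of both
$\eta$ well under 0.02), 30 patients at 3 vs 10 observations for the
information-monotonicity check, and 200 sparse-design patients with
300-draw bands for band coverage (observed close to the nominal 90%).

## Known limitations

* Fixed-step explicit integration: adequate for this non-stiff system, but
  there is no adaptive error control; the step is a documented parameter.
* Covariates are fixed at entry; long paediatric simulations do not mature
  clearance over the simulated period.
* The MAP/Laplace machinery individualizes $k_{10}$ and $EDK_{50}$ only;
  transit-time variability is not estimated.
* The tablet rounding and 16-h sampling conventions are Swedish practice;
  both are parameters or documented conventions rather than assumptions
  buried in code.
* Nothing produced with the demo parameter set is clinical advice.
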