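#' Individual model parameters
#'
#' The pair of parameters that the model individualizes: the first-order
#' elimination rate constant `k10` (= CL/V, 1/h) and `edk50` (mg/h), the dose
#' rate of half-maximal inhibition (displayed as EC50 in some tools).
#'
#' @param k10 Elimination rate constant (1/h, > 0).
#' @param edk50 Dose rate of half-maximal inhibition (mg/h, > 0).
#' @return An object of class `individual_parameters`.
#' @export
individual_parameters <- function(k10, edk50) {
  if (!is_scalar_num(k10) || k10 <= 0) stop_arg("`k10` must be positive")
  if (!is_scalar_num(edk50) || edk50 <= 0) stop_arg("`edk50` must be positive")
  structure(list(k10 = k10, edk50 = edk50), class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf("Individual parameters: k10 = %.5g /h, EDK50 = %.5g mg/h\n",
              x$k10, x$edk50))
  invisible(x)
}

#' Typical (population-mean) parameters for a patient
#'
#' Applies the population model's covariate relations to fully resolved
#' patient covariates: clearance is scaled allometrically by bodyweight,
#' adjusted exponentially for age and multiplied by the CYP2C9 genotype
#' factor; volume is scaled allometrically by weight; k10 = CL/V. EDK50 is
#' read from the VKORC1 genotype table.
#'
#' @param cov Resolved [patient_covariates()] (no missing genotype/baseline).
#' @param pop A [population_model()].
#' @return An [individual_parameters()] object.
#' @export
typical_parameters <- function(cov, pop) {
  stopifnot(inherits(cov, "patient_covariates"),
            inherits(pop, "population_model"))
  if (!covariates_resolved(cov))
    stop_arg("covariates contain missing fields; call resolve_missing_covariates() first")
  cr <- pop$covariate_relations
  if (!cov$cyp2c9 %in% names(cr$cl_cyp2c9))
    stop_arg("config has no CYP2C9 multiplier for genotype '", cov$cyp2c9, "'")
  if (!cov$vkorc1 %in% names(pop$edk50_by_vkorc1))
    stop_arg("config has no EDK50 entry for VKORC1 genotype '", cov$vkorc1, "'")
  cl <- pop$tv_cl *
    (cov$weight / cr$reference_weight)^cr$cl_weight_exponent *
    exp(cr$cl_age_slope * (cov$age - cr$reference_age)) *
    cr$cl_cyp2c9[[cov$cyp2c9]]
  v <- pop$tv_v * (cov$weight / cr$reference_weight)^cr$v_weight_exponent
  individual_parameters(k10 = cl / v,
                        edk50 = pop$edk50_by_vkorc1[[cov$vkorc1]])
}

#' Inhibitory effect of a given warfarin dose rate
#'
#' The sigmoid inhibition of vitamin-K-cycle activity driven by the dose rate
#' DR = k10 * A: `EFF = Emax * DR^gamma / (EDK50^gamma + DR^gamma)`. Returns
#' 0 at zero dose rate and saturates at `Emax`.
#'
#' @param dose_rate Dose rate DR in mg/h (>= 0); vectorized.
#' @param pop A [population_model()] (supplies `gamma`, `emax`).
#' @param indiv [individual_parameters()] (supplies `edk50`).
#' @return Effect fraction(s) in `[0, emax)`.
#' @export
effect <- function(dose_rate, pop, indiv) {
  if (any(dose_rate < 0)) stop_arg("`dose_rate` must be non-negative")
  drg <- dose_rate^pop$gamma
  out <- pop$emax * drg / (indiv$edk50^pop$gamma + drg)
  out[dose_rate == 0] <- 0
  out
}

#' Model state constructor
#'
#' The model state is the drug amount `a` (mg) plus the activities of the
#' three transit compartments in each of the two parallel chains. The
#' pre-treatment steady state is `a = 0` with every activity equal to 1
#' (100% coagulation-factor activity).
#'
#' @param a Drug amount (mg).
#' @param c1,c2 Numeric activity vectors, one value per transit compartment.
#' @param n_transit Number of compartments per chain (used only when `c1`,
#'   `c2` are left at their defaults).
#' @return An object of class `model_state`.
#' @export
model_state <- function(a = 0, c1 = rep(1, n_transit),
                        c2 = rep(1, n_transit), n_transit = 3L) {
  stopifnot(length(c1) == length(c2), a >= 0, all(c1 >= 0), all(c2 >= 0))
  structure(list(a = a, c1 = as.numeric(c1), c2 = as.numeric(c2)),
            class = "model_state")
}

state_to_vector <- function(state) c(state$a, state$c1, state$c2)

vector_to_state <- function(y, n_transit) {
  model_state(a = y[1], c1 = y[1 + seq_len(n_transit)],
              c2 = y[1 + n_transit + seq_len(n_transit)])
}

#' Time derivative of the model state
#'
#' Implements the KPD state equations: `dA/dt = -k10 * A`; the dose rate
#' `DR = k10 * A` drives [effect()]; each transit chain is a cascade with
#' rate `n/MTT` (chain 1 with `mtt1`, chain 2 with `mtt2`), both fed by the
#' same `(1 - EFF)` input:
#' `dC_1/dt = (1 - EFF) * n/MTT - C_1 * n/MTT`,
#' `dC_j/dt = (C_{j-1} - C_j) * n/MTT` for j > 1.
#'
#' @param state A [model_state()].
#' @param indiv [individual_parameters()].
#' @param pop A [population_model()].
#' @param force_eff Optional constant overriding EFF (testing hook used to
#'   compare the solver with closed-form solutions).
#' @return A `model_state` holding the derivatives.
#' @export
state_derivative <- function(state, indiv, pop, force_eff = NULL) {
  n <- length(state$c1)
  eff <- if (is.null(force_eff)) {
    effect(indiv$k10 * state$a, pop, indiv)
  } else force_eff
  kr1 <- n / pop$mtt1
  kr2 <- n / pop$mtt2
  d1 <- kr1 * (c(1 - eff, state$c1[-n]) - state$c1)
  d2 <- kr2 * (c(1 - eff, state$c2[-n]) - state$c2)
  structure(list(a = -indiv$k10 * state$a, c1 = d1, c2 = d2),
            class = "model_state")
}

#' Predicted INR from a model state
#'
#' `INR = baseline + INRmax * (1 - (C1_3 + C2_3)/2)`, where `C1_3` and `C2_3`
#' are the terminal-compartment activities of the two chains. Equals the
#' baseline INR when both terminal activities are 1 (no treatment), and
#' baseline + INRmax when both are fully suppressed.
#'
#' @param state A [model_state()] (or anything with `c1`/`c2` activity
#'   vectors).
#' @param baseline_inr Pre-treatment INR.
#' @param pop A [population_model()] (supplies `inr_max`).
#' @return Predicted INR.
#' @export
inr_from_state <- function(state, baseline_inr, pop) {
  n <- length(state$c1)
  baseline_inr + pop$inr_max * (1 - (state$c1[n] + state$c2[n]) / 2)
}
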