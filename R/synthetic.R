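#' Covariate sampler specification for synthetic patients
#'
#' Defines the ranges and frequencies from which synthetic patient
#' covariates are drawn. The defaults are test fixtures, not epidemiological
#' claims: age uniform on 1-80 years, bodyweight from an age-linked range
#' (a saturating growth curve times a uniform 0.8-1.2 factor), and genotype
#' frequencies typical of a Caucasian population.
#'
#' @param age_range Length-2 age range in years.
#' @param cyp2c9_freq,vkorc1_freq Named genotype probability vectors.
#' @param baseline_inr_range Length-2 baseline-INR range.
#' @param target_low,target_high Target INR range given to every patient.
#' @return A list of class `covariate_sampler_spec`.
#' @export
covariate_sampler_spec <- function(
    age_range = c(1, 80),
    cyp2c9_freq = c("*1/*1" = 0.65, "*1/*2" = 0.17, "*1/*3" = 0.12,
                    "*2/*2" = 0.02, "*2/*3" = 0.03, "*3/*3" = 0.01),
    vkorc1_freq = c("G/G" = 0.37, "A/G" = 0.45, "A/A" = 0.18),
    baseline_inr_range = c(0.9, 1.2),
    target_low = 2, target_high = 3) {
  stopifnot(length(age_range) == 2, all(age_range > 0),
            abs(sum(cyp2c9_freq) - 1) < 1e-6,
            abs(sum(vkorc1_freq) - 1) < 1e-6)
  structure(list(age_range = age_range, cyp2c9_freq = cyp2c9_freq,
                 vkorc1_freq = vkorc1_freq,
                 baseline_inr_range = baseline_inr_range,
                 target_low = target_low, target_high = target_high),
            class = "covariate_sampler_spec")
}

#' Study designs for synthetic histories
#'
#' `sparse_design()` mirrors the scale on which such tools are typically
#' validated — a few INR observations early in therapy: a fixed 4 mg/day
#' regimen for 8 days with INR sampled on days 3, 5 and 8 (16 h after the
#' previous dose). `rich_design()` is the asymptotic-checks arm: 30 days of
#' dosing with 20 observations. Both carry a one-week continuation regimen
#' and check times for band-coverage experiments.
#'
#' @param dose Daily dose in mg (default 4).
#' @param n_obs Number of observations (rich design, default 20).
#' @param n_days Days of dosing (rich design, default 30).
#' @return A list of class `study_design` with `regimen`, `obs_times` (h),
#'   `future_regimen` (times relative to end of history) and `check_times`.
#' @export
sparse_design <- function(dose = 4) {
  structure(list(
    regimen = build_regimen(dose, n_doses = 8),
    obs_times = c(2, 4, 7) * 24 + 16,         # days 3, 5, 8 (16 h post dose)
    future_regimen = build_regimen(dose, n_doses = 7),
    check_times = c(48, 96, 144)),
    class = "study_design")
}

#' @rdname sparse_design
#' @export
rich_design <- function(dose = 4, n_obs = 20, n_days = 30) {
  structure(list(
    regimen = build_regimen(dose, n_doses = n_days),
    obs_times = round(seq(24, n_days * 24, length.out = n_obs), 3),
    future_regimen = build_regimen(dose, n_doses = 7),
    check_times = c(48, 96, 144)),
    class = "study_design")
}

#' Draw one synthetic patient
#'
#' Samples covariates from the sampler spec, log-scale deviations `eta` from
#' independent zero-mean Gaussians with the population variances
#' `omega_k10` / `omega_edk50`, simulates the design's regimen at the true
#' individual parameters, and emits INR observations at the design's
#' observation times with additive Gaussian residual noise of SD sigma.
#' Fully deterministic given `seed`.
#'
#' @param pop A [population_model()].
#' @param sampler A [covariate_sampler_spec()].
#' @param design A [sparse_design()] / [rich_design()]-style list.
#' @param seed Integer RNG seed.
#' @param step Integration step (h).
#' @return A `synthetic_patient`: covariates, `true_eta`, `true_params`,
#'   `history` (doses + noisy observations), and `noise_free_inr` at the
#'   observation times.
#' @export
draw_patient <- function(pop, sampler = covariate_sampler_spec(),
                         design = sparse_design(), seed = 1, step = 0.1) {
  stopifnot(inherits(pop, "population_model"))
  if (length(design$obs_times) == 0)
    stop_arg("design has an empty observation schedule")
  with_seed(seed, {
    age <- runif(1, sampler$age_range[1], sampler$age_range[2])
    wt_typ <- min(70, 8 + 62 * (age / 18)^1.2)   # crude growth curve, kg
    weight <- wt_typ * runif(1, 0.8, 1.2)
    cyp <- sample(names(sampler$cyp2c9_freq), 1, prob = sampler$cyp2c9_freq)
    vko <- sample(names(sampler$vkorc1_freq), 1, prob = sampler$vkorc1_freq)
    bl <- runif(1, sampler$baseline_inr_range[1],
                sampler$baseline_inr_range[2])
    cov <- patient_covariates(age = age, weight = weight, cyp2c9 = cyp,
                              vkorc1 = vko, ethnicity = "Caucasian",
                              baseline_inr = bl,
                              target_low = sampler$target_low,
                              target_high = sampler$target_high)
    eta <- c(rnorm(1, 0, sqrt(pop$omega_k10)),
             rnorm(1, 0, sqrt(pop$omega_edk50)))
    typ <- typical_parameters(cov, pop)
    truth <- individual_parameters(typ$k10 * exp(eta[1]),
                                   typ$edk50 * exp(eta[2]))
    reg <- design$regimen
    traj <- simulate_regimen(reg, truth, pop, bl,
                             t_end = max(max(reg$events$time) +
                                           reg$dosing_interval,
                                         max(design$obs_times)),
                             step = step, obs_times = design$obs_times)
    noise_free <- vapply(design$obs_times, function(t) inr_at(traj, t),
                         numeric(1))
    noisy <- noise_free + rnorm(length(noise_free), 0, pop$sigma_add)
    noisy <- pmax(noisy, 0.5)   # INR observations must stay positive
    hist <- patient_history(cov, doses = reg$events,
                            observations = data.frame(
                              time = design$obs_times, value = noisy))
    structure(list(covariates = cov,
                   true_eta = setNames(eta, c("eta_k10", "eta_edk50")),
                   true_params = truth, typical_params = typ,
                   history = hist, noise_free_inr = noise_free,
                   design = design, seed = seed),
              class = "synthetic_patient")
  })
}

#' Parameter-recovery and band-coverage experiment
#'
#' For `n_patients` synthetic patients, fits individual parameters by MAP
#' and (optionally) checks whether the Laplace-approximation band covers the
#' true individual's noise-free INR at the design's future check times. The
#' coverage check uses the parameter-uncertainty band (no residual noise)
#' since the quantity being covered is the noise-free curve. Deterministic
#' given `seed`; fit failures are counted and reported, not fatal.
#'
#' @param pop A [population_model()].
#' @param design A study design (see [sparse_design()]).
#' @param n_patients Number of synthetic patients (>= 1).
#' @param seed Integer seed; patient `i` uses `seed + i`.
#' @param sampler A [covariate_sampler_spec()].
#' @param band Compute band coverage (default `TRUE`; fitting-only runs are
#'   faster with `FALSE`).
#' @param level Band level (default 0.90).
#' @param n_draws Posterior draws per band.
#' @param step Integration step (h).
#' @return A `recovery_summary`: per-parameter mean bias and RMSE of the
#'   estimated `eta`, empirical band coverage, failure count and the
#'   per-patient table.
#' @export
recovery_experiment <- function(pop, design, n_patients, seed = 1,
                                sampler = covariate_sampler_spec(),
                                band = TRUE, level = 0.90, n_draws = 300,
                                step = 0.1) {
  stopifnot(n_patients >= 1)
  rows <- vector("list", n_patients)
  n_fail <- 0L
  covered <- integer(0); checked <- integer(0)
  for (i in seq_len(n_patients)) {
    pt <- draw_patient(pop, sampler = sampler, design = design,
                       seed = seed + i, step = step)
    est <- tryCatch(fit_individual(pt$history, pop, step = step),
                    error = function(e) NULL)
    if (is.null(est)) {
      n_fail <- n_fail + 1L
      next
    }
    cov_hits <- NA_real_
    if (band) {
      hit <- tryCatch({
        # each posterior draw is propagated through the whole history plus
        # the continuation, so uncertainty in the accumulated transit-chain
        # state at the projection start is part of the band
        t_h <- est$history_end
        full_times <- c(pt$history$doses$time,
                        t_h + design$future_regimen$events$time)
        full_amt <- c(pt$history$doses$amount,
                      design$future_regimen$events$amount)
        keep <- !duplicated(round(full_times, 9))
        full_reg <- regimen(full_times[keep], full_amt[keep],
                            interval = design$future_regimen$dosing_interval)
        t_check <- t_h + design$check_times
        bd <- predict_band(est, full_reg, pop, level = level,
                           n_draws = n_draws, seed = seed + 10000L + i,
                           include_residual = FALSE, step = step,
                           t_end = max(t_check), init_state = NULL)
        # noise-free truth over the same horizon
        tr_true <- simulate_regimen(
          full_reg, pt$true_params, pop, pt$covariates$baseline_inr,
          t_end = max(t_check), step = step, obs_times = t_check)
        truth <- vapply(t_check, function(t) inr_at(tr_true, t), numeric(1))
        lo <- stats::approx(bd$time, bd$lower, xout = t_check)$y
        up <- stats::approx(bd$time, bd$upper, xout = t_check)$y
        as.integer(truth >= lo & truth <= up)
      }, error = function(e) NULL)
      if (!is.null(hit)) {
        covered <- c(covered, sum(hit))
        checked <- c(checked, length(hit))
        cov_hits <- mean(hit)
      }
    }
    rows[[i]] <- data.frame(
      patient = i,
      true_eta_k10 = pt$true_eta[1], true_eta_edk50 = pt$true_eta[2],
      est_eta_k10 = est$eta[1], est_eta_edk50 = est$eta[2],
      objective = est$objective_value, band_coverage = cov_hits)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  err_k <- tab$est_eta_k10 - tab$true_eta_k10
  err_e <- tab$est_eta_edk50 - tab$true_eta_edk50
  structure(list(
    n_patients = n_patients, n_fit_failures = n_fail,
    bias = c(eta_k10 = mean(err_k), eta_edk50 = mean(err_e)),
    rmse = c(eta_k10 = sqrt(mean(err_k^2)), eta_edk50 = sqrt(mean(err_e^2))),
    band_coverage = if (length(checked) > 0)
      sum(covered) / sum(checked) else NA_real_,
    level = level, table = tab),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d patients (%d fit failure(s))\n",
              x$n_patients, x$n_fit_failures))
  cat(sprintf("  eta_k10:   bias %+.4f, RMSE %.4f\n",
              x$bias["eta_k10"], x$rmse["eta_k10"]))
  cat(sprintf("  eta_edk50: bias %+.4f, RMSE %.4f\n",
              x$bias["eta_edk50"], x$rmse["eta_edk50"]))
  if (!is.na(x$band_coverage))
    cat(sprintf("  %d%% band coverage of noise-free INR: %.1f%%\n",
                round(100 * x$level), 100 * x$band_coverage))
  invisible(x)
}
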