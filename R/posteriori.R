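#' MAP objective for individual parameter estimation
#'
#' The penalized least-squares objective of MAP (empirical-Bayes) estimation
#' in a nonlinear mixed-effects model with log-normal between-subject
#' variability and (by default) additive residual error:
#' \deqn{O(\eta) = \sum_j (INR_{obs,j} - INR_{pred,j}(\eta))^2/\sigma^2 +
#'   \eta_{k10}^2/\omega^2_{k10} + \eta_{EDK50}^2/\omega^2_{EDK50}}
#' where predictions come from integrating the history's doses with
#' individual parameters `typical * exp(eta)`, and the `omega^2` are the
#' between-subject variances from the population model. `O` equals twice the
#' negative log-posterior up to an additive constant.
#'
#' With no observations the objective reduces to the prior term, minimized
#' at `eta = 0`. Non-finite predictions return a large penalty with a
#' warning rather than aborting the optimizer.
#'
#' @param eta Length-2 numeric: log-scale deviations (eta_k10, eta_edk50).
#' @param history A [patient_history()].
#' @param pop A [population_model()].
#' @param step Integration step (h).
#' @return Scalar objective value.
#' @export
map_objective <- function(eta, history, pop, step = 0.1) {
  stopifnot(inherits(history, "patient_history"), length(eta) == 2)
  prior <- eta[1]^2 / pop$omega_k10 + eta[2]^2 / pop$omega_edk50
  obs <- history$observations
  if (nrow(obs) == 0) return(prior)
  pred <- predict_at_observations(eta, history, pop, step = step)
  if (any(!is.finite(pred))) {
    warning("non-finite INR prediction at eta = (",
            paste(signif(eta, 4), collapse = ", "), ")", call. = FALSE)
    return(1e10 + prior)
  }
  sd_res <- if (pop$residual_model == "proportional")
    pop$sigma_add * pred else pop$sigma_add
  sum(((obs$value - pred) / sd_res)^2) + prior
}

# predicted INR at the history's observation times for a given eta
predict_at_observations <- function(eta, history, pop, step = 0.1) {
  cov <- resolve_missing_covariates(history$covariates)
  typ <- typical_parameters(cov, pop)
  indiv <- individual_parameters(typ$k10 * exp(eta[1]),
                                 typ$edk50 * exp(eta[2]))
  obs <- history$observations
  reg <- regimen(history$doses$time, history$doses$amount,
                 interval = cov$dosing_interval)
  traj <- simulate_regimen(reg, indiv, pop, cov$baseline_inr,
                           t_end = max(history_end(history),
                                       max(history$doses$time)),
                           step = step, obs_times = obs$time)
  vapply(obs$time, function(t) inr_at(traj, t), numeric(1))
}

# Powell's direction-set minimization with Brent line searches.
# Box-constrained by clipping the line-search range to [lower, upper].
powell_minimize <- function(fn, x0, lower, upper, tol = 1e-8, maxit = 200) {
  p <- length(x0)
  dirs <- diag(p)
  x <- pmin(pmax(x0, lower), upper)
  f0 <- fn(x)
  n_eval <- 1L
  line_min <- function(x, d) {
    if (sqrt(sum(d^2)) < 1e-14) return(list(x = x, f = fn(x)))
    a_lo <- -Inf; a_hi <- Inf
    for (j in seq_len(p)) {
      if (d[j] > 0) {
        a_lo <- max(a_lo, (lower[j] - x[j]) / d[j])
        a_hi <- min(a_hi, (upper[j] - x[j]) / d[j])
      } else if (d[j] < 0) {
        a_lo <- max(a_lo, (upper[j] - x[j]) / d[j])
        a_hi <- min(a_hi, (lower[j] - x[j]) / d[j])
      }
    }
    if (!is.finite(a_lo)) a_lo <- -10
    if (!is.finite(a_hi)) a_hi <- 10
    if (a_hi - a_lo < 1e-12) return(list(x = x, f = fn(x)))
    g <- function(a) fn(x + a * d)
    opt <- stats::optimize(g, c(a_lo, a_hi), tol = 1e-7)
    list(x = x + opt$minimum * d, f = opt$objective)
  }
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    f_start <- f0
    x_start <- x
    biggest <- 0; i_big <- 1L
    for (i in seq_len(p)) {
      f_prev <- f0
      ls <- line_min(x, dirs[, i])
      if (ls$f < f0) { x <- ls$x; f0 <- ls$f }
      if (f_prev - f0 > biggest) { biggest <- f_prev - f0; i_big <- i }
    }
    if (f_start - f0 < tol) { converged <- TRUE; break }
    # Powell's direction-replacement test on the extrapolated point
    xe <- pmin(pmax(2 * x - x_start, lower), upper)
    fe <- fn(xe)
    if (fe < f_start) {
      tcrit <- 2 * (f_start - 2 * f0 + fe) *
        (f_start - f0 - biggest)^2 - biggest * (f_start - fe)^2
      if (tcrit < 0) {
        dnew <- x - x_start
        ls <- line_min(x, dnew)
        if (ls$f < f0) { x <- ls$x; f0 <- ls$f }
        dirs[, i_big] <- dnew / sqrt(sum(dnew^2))
      }
    }
  }
  list(par = x, value = f0, converged = converged, iterations = iter)
}

# central finite-difference Hessian
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' Fit individual parameters by MAP (empirical-Bayes) estimation
#'
#' Minimizes [map_objective()] over the log-scale deviations `eta` with a
#' Powell direction-set search started at `eta = (0, 0)` (the prior mode),
#' inside a `[-3, 3]` box; if the first run terminates on the box boundary
#' the search is restarted once from a perturbed point. The curvature
#' (observed information of the negative log-posterior, i.e. half the
#' objective's Hessian) is computed at the optimum by central finite
#' differences; its inverse is the Laplace-approximation covariance used by
#' [predict_band()].
#'
#' @param history A [patient_history()].
#' @param pop A [population_model()].
#' @param step Integration step (h).
#' @param tol Convergence tolerance on objective improvement per Powell
#'   cycle (default 1e-8).
#' @param maxit Maximum Powell cycles (default 200).
#' @return An `individual_estimate`: `map_params`, `typical_params`, `eta`,
#'   `curvature` (2x2), `objective_value`, the resolved covariates, a fitted
#'   trajectory at the MAP parameters and the model state at the end of the
#'   history.
#' @export
fit_individual <- function(history, pop, step = 0.1, tol = 1e-8,
                           maxit = 200) {
  stopifnot(inherits(history, "patient_history"),
            inherits(pop, "population_model"))
  cov <- resolve_missing_covariates(history$covariates)
  typ <- typical_parameters(cov, pop)
  fn <- function(eta) map_objective(eta, history, pop, step = step)
  lower <- c(-3, -3); upper <- c(3, 3)
  res <- powell_minimize(fn, c(0, 0), lower, upper, tol = tol, maxit = maxit)
  if (any(abs(abs(res$par) - 3) < 1e-6)) {
    res2 <- powell_minimize(fn, pmin(pmax(res$par * 0.5 + c(0.1, -0.1),
                                          lower), upper),
                            lower, upper, tol = tol, maxit = maxit)
    if (res2$value < res$value) res <- res2
  }
  if (!res$converged)
    stop_arg("Powell search did not converge in ", maxit,
             " cycles (best objective ", signif(res$value, 6),
             " at eta = ", paste(signif(res$par, 4), collapse = ", "), ")")
  eta <- res$par
  curvature <- fd_hessian(fn, eta) / 2
  map <- individual_parameters(typ$k10 * exp(eta[1]),
                               typ$edk50 * exp(eta[2]))
  # fitted trajectory at the MAP parameters over the recorded history
  t_h <- history_end(history)
  reg <- regimen(history$doses$time, history$doses$amount,
                 interval = cov$dosing_interval)
  traj <- simulate_regimen(reg, map, pop, cov$baseline_inr,
                           t_end = max(t_h, max(history$doses$time)),
                           step = step, obs_times = history$observations$time)
  structure(list(map_params = map, typical_params = typ,
                 eta = setNames(eta, c("eta_k10", "eta_edk50")),
                 curvature = curvature, objective_value = res$value,
                 covariates = cov, fitted_trajectory = traj,
                 final_state = final_state(traj), history_end = t_h,
                 iterations = res$iterations),
            class = "individual_estimate")
}

#' @export
print.individual_estimate <- function(x, ...) {
  cat("Individual (MAP) parameter estimate\n")
  cat(sprintf("  typical:    k10 = %.5g /h, EDK50 = %.5g mg/h\n",
              x$typical_params$k10, x$typical_params$edk50))
  cat(sprintf("  individual: k10 = %.5g /h, EDK50 = %.5g mg/h\n",
              x$map_params$k10, x$map_params$edk50))
  cat(sprintf("  eta = (%.4f, %.4f), objective = %.5g\n",
              x$eta[1], x$eta[2], x$objective_value))
  invisible(x)
}

#' Individualized maintenance-dose estimation (a posteriori)
#'
#' Re-runs the dose search of [estimate_dose()] with the MAP individual
#' parameters, projecting forward from the model state at the end of the
#' fitted history ("Day 0") rather than from the untreated state.
#'
#' @param estimate An `individual_estimate` from [fit_individual()].
#' @param history The [patient_history()] that was fitted.
#' @param pop A [population_model()].
#' @param ... Passed on to [estimate_dose()].
#' @return A `dose_recommendation`; its trajectory's time 0 is the end of
#'   the recorded history.
#' @export
estimate_dose_individual <- function(estimate, history, pop, ...) {
  stopifnot(inherits(estimate, "individual_estimate"))
  estimate_dose(estimate$covariates, pop, indiv = estimate$map_params,
                init_state = estimate$final_state, ...)
}

#' Prediction band from the Laplace approximation
#'
#' Draws `eta` from the Gaussian (Laplace) approximation of the posterior —
#' mean at the MAP estimate, covariance the inverse curvature — simulates
#' the regimen for each draw and returns pointwise percentile bands around
#' the MAP curve. With `include_residual = TRUE` (default) additive residual
#' noise of SD sigma is added to each simulated curve on the observation
#' scale, so the band is predictive for measured INRs; with `FALSE` the band
#' reflects parameter uncertainty only.
#'
#' @param estimate An `individual_estimate`.
#' @param reg The future [regimen()] to simulate (times relative to the end
#'   of the fitted history).
#' @param pop A [population_model()].
#' @param level Band level (default 0.90).
#' @param n_draws Posterior draws (default 500).
#' @param seed RNG seed (the band is bit-reproducible for a fixed seed).
#' @param include_residual Add residual noise to the simulated curves.
#' @param step Integration step (h).
#' @param t_end Simulation horizon (h); defaults to one interval past the
#'   last dose.
#' @param init_state Starting state; defaults to the end of the fitted
#'   history.
#' @return An `inr_band`: data.frame `time`, `lower`, `point` (MAP curve),
#'   `upper`, with the level and draw count as attributes.
#' @export
predict_band <- function(estimate, reg, pop, level = 0.90, n_draws = 500,
                         seed = 1, include_residual = TRUE, step = 0.1,
                         t_end = NULL, init_state = estimate$final_state) {
  stopifnot(inherits(estimate, "individual_estimate"),
            inherits(reg, "regimen"))
  Sigma <- tryCatch(solve(estimate$curvature), error = function(e) NULL)
  if (is.null(Sigma) || any(eigen(Sigma, symmetric = TRUE,
                                  only.values = TRUE)$values <= 0))
    stop_arg("curvature is singular or not positive-definite; ",
             "more observations may be needed")
  cov <- estimate$covariates
  typ <- estimate$typical_params
  t_end <- t_end %||% (max(reg$events$time) + reg$dosing_interval)
  map_traj <- simulate_regimen(reg, estimate$map_params, pop,
                               cov$baseline_inr, t_end = t_end, step = step,
                               init_state = init_state)
  m <- nrow(map_traj)
  curves <- with_seed(seed, {
    draws <- MASS::mvrnorm(n_draws, mu = as.numeric(estimate$eta),
                           Sigma = Sigma)
    out <- matrix(NA_real_, n_draws, m)
    for (i in seq_len(n_draws)) {
      ind <- individual_parameters(typ$k10 * exp(draws[i, 1]),
                                   typ$edk50 * exp(draws[i, 2]))
      tr <- simulate_regimen(reg, ind, pop, cov$baseline_inr, t_end = t_end,
                             step = step, init_state = init_state)
      out[i, ] <- tr$inr
      if (include_residual) {
        sd_res <- if (pop$residual_model == "proportional")
          pop$sigma_add * out[i, ] else pop$sigma_add
        out[i, ] <- out[i, ] + rnorm(m, 0, sd_res)
      }
    }
    out
  })
  alpha <- (1 - level) / 2
  band <- data.frame(
    time = map_traj$time,
    lower = apply(curves, 2, quantile, probs = alpha, names = FALSE),
    point = map_traj$inr,
    upper = apply(curves, 2, quantile, probs = 1 - alpha, names = FALSE))
  class(band) <- c("inr_band", "data.frame")
  attr(band, "level") <- level
  attr(band, "n_draws") <- n_draws
  attr(band, "include_residual") <- include_residual
  band
}
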