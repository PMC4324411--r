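#' One step of Heun's method
#'
#' The explicit trapezoidal second-order Runge-Kutta step:
#' predictor `y* = y + h f(t, y)`, corrector
#' `y_next = y + (h/2) (f(t, y) + f(t + h, y*))`; local truncation error
#' O(h^3).
#'
#' @param state Numeric state vector `y`.
#' @param t Current time.
#' @param h Step size (> 0).
#' @param derivative_fn Function `f(t, y)` returning the derivative vector.
#' @return The state vector advanced to `t + h`.
#' @export
heun_step <- function(state, t, h, derivative_fn) {
  if (!is_scalar_num(h) || h <= 0) stop_arg("`h` must be positive")
  f0 <- derivative_fn(t, state)
  pred <- state + h * f0
  state + (h / 2) * (f0 + derivative_fn(t + h, pred))
}

# shared grid construction: uniform steps unioned with event/observation
# times so every dose and observation falls exactly on a grid point
make_grid <- function(t_end, step, event_times, obs_times = NULL) {
  g <- c(seq(0, t_end, by = step), t_end, event_times, obs_times)
  g <- sort(unique(round(g, 9)))
  g[g <= t_end + 1e-9]
}

#' Simulate the INR response to a dosing regimen
#'
#' Integrates the KPD state equations over a regimen with Heun's
#' second-order Runge-Kutta method. The state starts at the pre-treatment
#' steady state (no drug, all activities 1) unless `init_state` is given;
#' each dose is an instantaneous addition to the drug amount, applied before
#' the step that leaves its time point. The time grid is the union of
#' uniform steps with every event and observation time, so doses and
#' observations are never interpolated.
#'
#' @param reg A [regimen()].
#' @param indiv [individual_parameters()].
#' @param pop A [population_model()].
#' @param baseline_inr Pre-treatment INR.
#' @param t_end End of simulation (h); must be >= the last event time.
#'   Defaults to one dosing interval past the last dose.
#' @param step Integration step (h, default 0.1).
#' @param obs_times Optional times to force onto the grid.
#' @param init_state Optional [model_state()] to continue from.
#' @param force_eff Optional constant overriding the inhibitory effect
#'   (testing hook for closed-form comparisons).
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @return A `trajectory`: a data.frame with columns `time`, `amount`,
#'   `c1_1..c1_n`, `c2_1..c2_n` and `inr`.
#' @export
simulate_regimen <- function(reg, indiv, pop, baseline_inr,
                             t_end = NULL, step = 0.1, obs_times = NULL,
                             init_state = NULL, force_eff = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(reg, "regimen"), inherits(pop, "population_model"))
  if (!is_scalar_num(step) || step <= 0) stop_arg("`step` must be positive")
  ev <- reg$events
  t_end <- t_end %||% (max(ev$time) + reg$dosing_interval)
  if (t_end < max(ev$time))
    stop_arg("`t_end` must reach the last dose event")
  n <- pop$n_transit
  init <- if (is.null(init_state)) model_state(n_transit = n) else init_state
  if (length(init$c1) != n) stop_arg("init_state has the wrong chain length")
  grid <- make_grid(t_end, step, ev$time, obs_times)
  idx <- match(round(ev$time, 9), grid)

  if (engine == "cpp") {
    y <- .integrate_kpd_cpp(grid, idx, ev$amount,
                            indiv$k10, indiv$edk50, pop$gamma, pop$emax,
                            pop$mtt1, pop$mtt2, n,
                            state_to_vector(init),
                            if (is.null(force_eff)) NA_real_ else force_eff)
  } else {
    y <- integrate_r(grid, idx, ev$amount, indiv, pop, init, force_eff)
  }
  colnames(y) <- c("amount", paste0("c1_", seq_len(n)),
                   paste0("c2_", seq_len(n)))
  inr <- baseline_inr + pop$inr_max *
    (1 - (y[, paste0("c1_", n)] + y[, paste0("c2_", n)]) / 2)
  traj <- data.frame(time = grid, y, inr = inr)
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "dose_times") <- ev$time
  attr(traj, "interval") <- reg$dosing_interval
  attr(traj, "baseline_inr") <- baseline_inr
  traj
}

# pure-R reference integrator (same contract as the C++ engine); used to
# cross-validate the compiled path on small problems
integrate_r <- function(grid, dose_idx, dose_amt, indiv, pop, init,
                        force_eff = NULL) {
  n <- pop$n_transit
  d <- 1 + 2 * n
  fn <- function(t, y) {
    st <- list(a = y[1], c1 = y[1 + seq_len(n)],
               c2 = y[1 + n + seq_len(n)])
    state_to_vector(state_derivative(st, indiv, pop, force_eff = force_eff))
  }
  bolus <- numeric(length(grid))
  for (i in seq_along(dose_idx)) {
    bolus[dose_idx[i]] <- bolus[dose_idx[i]] + dose_amt[i]
  }
  out <- matrix(NA_real_, length(grid), d)
  y <- state_to_vector(init)
  for (i in seq_along(grid)) {
    y[1] <- y[1] + bolus[i]
    out[i, ] <- y
    if (i == length(grid)) break
    y <- heun_step(y, grid[i], grid[i + 1] - grid[i], fn)
  }
  out
}

#' Model state at the end of a trajectory
#'
#' @param traj A trajectory from [simulate_regimen()].
#' @return A [model_state()] at the final grid point.
#' @export
final_state <- function(traj) {
  n <- sum(grepl("^c1_", names(traj)))
  last <- nrow(traj)
  model_state(a = traj$amount[last],
              c1 = as.numeric(traj[last, paste0("c1_", seq_len(n))]),
              c2 = as.numeric(traj[last, paste0("c2_", seq_len(n))]))
}

# INR at an exact grid time; errors if the time is not on the grid
inr_at <- function(traj, t) {
  i <- which(abs(traj$time - t) < 1e-8)
  if (length(i) != 1)
    stop_arg("time ", t, " h is not a grid point of the trajectory")
  traj$inr[i]
}

#' Export a trajectory to CSV
#'
#' Writes `time`, `amount`, the terminal activities of both chains and the
#' predicted INR.
#'
#' @param traj A trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  n <- sum(grepl("^c1_", names(traj)))
  out <- data.frame(time = traj$time, amount = traj$amount,
                    c1_terminal = traj[[paste0("c1_", n)]],
                    c2_terminal = traj[[paste0("c2_", n)]],
                    inr = traj$inr)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
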