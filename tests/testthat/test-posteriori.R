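make_history <- function(pop = demo_pop, eta = c(0, 0), seed = 1,
                         design = sparse_design(), noise = TRUE) {
  # history simulated at typical*exp(eta) with optional residual noise
  cov <- resolve_missing_covariates(adult_cov())
  typ <- typical_parameters(cov, pop)
  ind <- individual_parameters(typ$k10 * exp(eta[1]),
                               typ$edk50 * exp(eta[2]))
  reg <- design$regimen
  tr <- simulate_regimen(reg, ind, pop, cov$baseline_inr,
                         t_end = max(design$obs_times,
                                     max(reg$events$time) + 24),
                         obs_times = design$obs_times)
  val <- vapply(design$obs_times, function(t) warfinr:::inr_at(tr, t),
                numeric(1))
  if (noise) val <- val + with_seed_local(seed, rnorm(length(val), 0, pop$sigma_add))
  patient_history(cov, doses = reg$events,
                  observations = data.frame(time = design$obs_times,
                                            value = val))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

test_that("the MAP objective has the stated structure", {
  hist0 <- make_history(eta = c(0, 0), noise = FALSE)
  # noise-free data at the typical parameters: objective is exactly zero
  expect_lt(map_objective(c(0, 0), hist0, demo_pop), 1e-16)
  # no observations: pure prior, quadratic in eta over the omega^2
  hist_no <- patient_history(hist0$covariates, doses = hist0$doses)
  eta <- c(0.4, -0.7)
  expect_equal(map_objective(eta, hist_no, demo_pop),
               eta[1]^2 / demo_pop$omega_k10 +
                 eta[2]^2 / demo_pop$omega_edk50)
  expect_equal(map_objective(c(0, 0), hist_no, demo_pop), 0)
  # doubling sigma quarters the data term (sum of squares / sigma^2)
  hist1 <- make_history(eta = c(0.3, -0.3), noise = FALSE)
  pop2 <- demo_pop; pop2$sigma_add <- 2 * demo_pop$sigma_add
  d1 <- map_objective(c(0, 0), hist1, demo_pop)
  d2 <- map_objective(c(0, 0), hist1, pop2)
  expect_equal(d1, 4 * d2)
})

test_that("fitting with no observations returns the typical parameters", {
  hist0 <- make_history(noise = FALSE)
  hist_no <- patient_history(hist0$covariates, doses = hist0$doses)
  est <- fit_individual(hist_no, demo_pop)
  expect_equal(est$eta, c(eta_k10 = 0, eta_edk50 = 0), tolerance = 1e-6)
  expect_equal(est$map_params$k10, est$typical_params$k10, tolerance = 1e-6)
  # prior-only curvature is the inverse prior covariance
  expect_equal(est$curvature,
               diag(1 / c(demo_pop$omega_k10, demo_pop$omega_edk50)),
               tolerance = 1e-3)
})

test_that("noise-free rich data recovers a known individual", {
  eta_true <- c(0.3, -0.4)
  hist <- make_history(eta = eta_true, design = rich_design(),
                       noise = FALSE)
  # fit with a small residual SD so the data term dominates the prior;
  # at the demo sigma of 0.15 the MAP is legitimately shrunk ~0.07
  pop_fit <- demo_pop
  pop_fit$sigma_add <- 0.01
  est <- fit_individual(hist, pop_fit)
  expect_lt(abs(est$eta[1] - eta_true[1]), 0.02)
  expect_lt(abs(est$eta[2] - eta_true[2]), 0.02)
  # fit -> predict self-consistency at the MAP parameters
  pred <- warfinr:::predict_at_observations(est$eta, hist, demo_pop)
  expect_equal(pred, hist$observations$value, tolerance = 1e-3)
})

test_that("a vanishing between-subject variance pins the estimate to the typical value", {
  hist <- make_history(eta = c(0.5, 0.5), design = sparse_design())
  pop0 <- demo_pop
  pop0$omega_k10 <- 1e-6
  pop0$omega_edk50 <- 1e-6
  est <- fit_individual(hist, pop0)
  expect_lt(abs(est$eta[1]), 0.01)
  expect_lt(abs(est$eta[2]), 0.01)
})

test_that("the optimizer never loses to the prior mode", {
  for (seed in 1:5) {
    pt <- draw_patient(demo_pop, design = sparse_design(), seed = seed)
    est <- fit_individual(pt$history, demo_pop)
    expect_lte(est$objective_value,
               map_objective(c(0, 0), pt$history, demo_pop) + 1e-8)
  }
})

test_that("Powell minimization agrees with an independent optimizer", {
  pt <- draw_patient(demo_pop, design = sparse_design(), seed = 11)
  fn <- function(eta) map_objective(eta, pt$history, demo_pop)
  est <- fit_individual(pt$history, demo_pop)
  nm <- optim(c(0, 0), fn, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(as.numeric(est$eta), nm$par, tolerance = 1e-3)
  expect_equal(est$objective_value, nm$value, tolerance = 1e-6)
})

test_that("Powell handles standard test functions within the box", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  res <- warfinr:::powell_minimize(rosen, c(-1.2, 1), c(-3, -3), c(3, 3))
  expect_equal(res$par, c(1, 1), tolerance = 1e-4)
  quad <- function(x) sum((x - c(0.5, -0.25))^2)
  res2 <- warfinr:::powell_minimize(quad, c(0, 0), c(-3, -3), c(3, 3))
  expect_equal(res2$par, c(0.5, -0.25), tolerance = 1e-6)
})

test_that("individualized dose estimation projects from the end of the history", {
  hist0 <- make_history(noise = FALSE)
  hist_no <- patient_history(hist0$covariates, doses = hist0$doses)
  est0 <- fit_individual(hist_no, demo_pop)
  # zero observations: recommendation matches the a priori one
  rec_post <- estimate_dose_individual(est0, hist_no, demo_pop)
  rec_pri <- estimate_dose(est0$covariates, demo_pop)
  expect_equal(rec_post$dose, rec_pri$dose, tolerance = 1e-6)
  # Day-0 continuity: the projection starts at the fitted curve's end
  pt <- draw_patient(demo_pop, design = sparse_design(), seed = 3)
  est <- fit_individual(pt$history, demo_pop)
  rec <- estimate_dose_individual(est, pt$history, demo_pop)
  expect_equal(rec$trajectory$inr[1],
               tail(est$fitted_trajectory$inr, 1), tolerance = 1e-9)
  # a more sensitive patient (eta_edk50 < 0) needs no more drug than typical
  hist_sens <- make_history(eta = c(0, -0.6), design = rich_design(),
                            noise = FALSE)
  est_sens <- fit_individual(hist_sens, demo_pop)
  rec_sens <- estimate_dose_individual(est_sens, hist_sens, demo_pop)
  expect_lt(rec_sens$dose, rec_pri$dose)
})

test_that("the prediction band is seeded, brackets the MAP curve, and collapses without uncertainty", {
  pt <- draw_patient(demo_pop, design = sparse_design(), seed = 5)
  est <- fit_individual(pt$history, demo_pop)
  reg <- build_regimen(4, 5)
  b1 <- predict_band(est, reg, demo_pop, n_draws = 150, seed = 99)
  b2 <- predict_band(est, reg, demo_pop, n_draws = 150, seed = 99)
  expect_identical(b1, b2)                      # bit-reproducible
  b3 <- predict_band(est, reg, demo_pop, n_draws = 150, seed = 100)
  expect_false(identical(b1$lower, b3$lower))
  expect_true(all(b1$lower <= b1$point & b1$point <= b1$upper))

  # no residual noise + near-infinite curvature: band collapses on MAP curve
  est0 <- est
  est0$curvature <- diag(c(1e12, 1e12))
  pop0 <- demo_pop; pop0$sigma_add <- 1e-12
  b0 <- predict_band(est0, reg, pop0, n_draws = 100, seed = 1)
  expect_lt(max(b0$upper - b0$lower), 1e-4)

  # singular curvature is refused with advice
  est_bad <- est
  est_bad$curvature <- matrix(0, 2, 2)
  expect_error(predict_band(est_bad, reg, demo_pop), "singular|positive")
})

test_that("shrinkage decreases as the data become more informative", {
  # same true individual and design, noise-free data, decreasing residual SD:
  # the MAP moves monotonically from the prior mode toward the true eta
  eta_true <- c(0.25, -0.35)
  hist <- make_history(eta = eta_true, design = rich_design(n_obs = 10),
                       noise = FALSE)
  norms <- vapply(c(0.5, 0.15, 0.01), function(s) {
    pop_s <- demo_pop
    pop_s$sigma_add <- s
    est <- fit_individual(hist, pop_s)
    sqrt(sum(est$eta^2))
  }, numeric(1))
  expect_true(all(diff(norms) > 1e-4))
  expect_lt(norms[1], sqrt(sum(eta_true^2)))   # shrunk toward the prior mode
  expect_equal(norms[3], sqrt(sum(eta_true^2)), tolerance = 0.05)
})
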