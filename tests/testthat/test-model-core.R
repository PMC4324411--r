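test_that("missing covariates resolve to the documented defaults", {
  cases <- list(
    list(ethnicity = "Caucasian", vkorc1 = "A/G"),
    list(ethnicity = "unspecified", vkorc1 = "A/G"),
    list(ethnicity = "Asian", vkorc1 = "A/A"),
    list(ethnicity = "African", vkorc1 = "G/G"))
  for (cs in cases) {
    cov <- patient_covariates(age = 30, weight = 60, ethnicity = cs$ethnicity)
    res <- resolve_missing_covariates(cov)
    expect_identical(res$cyp2c9, "*1/*1")
    expect_identical(res$vkorc1, cs$vkorc1)
    expect_identical(res$baseline_inr, 1)
  }
  # present values are never touched
  cov <- patient_covariates(age = 30, weight = 60, cyp2c9 = "*2/*3",
                            vkorc1 = "A/A", ethnicity = "African",
                            baseline_inr = 1.3)
  res <- resolve_missing_covariates(cov)
  expect_identical(res$cyp2c9, "*2/*3")
  expect_identical(res$vkorc1, "A/A")
  expect_identical(res$baseline_inr, 1.3)
})

test_that("covariate validation rejects invalid input", {
  expect_error(patient_covariates(age = -1, weight = 60), "age")
  expect_error(patient_covariates(age = 30, weight = 0), "weight")
  expect_error(patient_covariates(age = 30, weight = 60, cyp2c9 = "*4/*4"),
               "CYP2C9")
  expect_error(patient_covariates(age = 30, weight = 60, baseline_inr = 0.5),
               "baseline")
  expect_error(patient_covariates(age = 30, weight = 60,
                                  target_low = 3, target_high = 2),
               "target")
})

test_that("typical parameters follow the covariate relations", {
  # flat config: k10 is simply CL/V
  pop0 <- population_model(tv_cl = 0.2, tv_v = 10,
                           edk50_by_vkorc1 = c("G/G" = 3, "A/G" = 2.3,
                                               "A/A" = 1.6),
                           gamma = 1, mtt1 = 30, mtt2 = 110,
                           omega_k10 = 0.09, omega_edk50 = 0.16,
                           sigma_add = 0.15)
  ind <- typical_parameters(resolve_missing_covariates(
    patient_covariates(age = 77, weight = 33)), pop0)
  expect_equal(ind$k10, 0.02)

  # at the reference weight/age the allometric and age multipliers are 1
  ind_ref <- typical_parameters(adult_cov(age = 40, weight = 70) |>
                                  resolve_missing_covariates(), demo_pop)
  expect_equal(ind_ref$k10, demo_pop$tv_cl / demo_pop$tv_v)

  # a resolved Caucasian with missing VKORC1 gets the A/G entry
  cov <- resolve_missing_covariates(
    patient_covariates(age = 40, weight = 70, ethnicity = "Caucasian"))
  ind <- typical_parameters(cov, demo_pop)
  expect_equal(ind$edk50, demo_pop$edk50_by_vkorc1[["A/G"]])

  # allometric scaling: CL ~ wt^0.75, V ~ wt^1 so k10 ~ wt^-0.25
  ind_light <- typical_parameters(adult_cov(age = 40, weight = 35) |>
                                    resolve_missing_covariates(), demo_pop)
  expect_equal(ind_light$k10 / ind_ref$k10, (35 / 70)^(0.75 - 1))

  # unresolved covariates and unknown genotypes are refused
  expect_error(typical_parameters(patient_covariates(age = 40, weight = 70),
                                  demo_pop), "missing")
})

test_that("effect is the standard sigmoid: zero at zero, half-maximal at EDK50, saturating, monotone", {
  ind <- individual_parameters(k10 = 0.02, edk50 = 2)
  for (g in c(0.5, 1, 2.7)) {
    pop <- demo_pop; pop$gamma <- g
    expect_identical(effect(0, pop, ind), 0)
    expect_equal(effect(ind$edk50, pop, ind), 0.5)
    expect_lt(effect(1e6, pop, ind), 1)
    # analytic saturation bound: EFF >= 1 - (EDK50/DR)^gamma
    expect_gt(effect(1e6, pop, ind), 1 - (ind$edk50 / 1e6)^g)
    dr <- seq(0, 10, by = 0.05)
    eff <- effect(dr, pop, ind)
    expect_true(all(diff(eff) > 0))
    expect_true(all(eff >= 0 & eff < pop$emax))
  }
  expect_error(effect(-0.1, demo_pop, ind), "non-negative")
})

test_that("state derivative vanishes at the pre-treatment steady state and is consistent with the cascade", {
  ind <- adult_indiv()
  st0 <- model_state()
  d0 <- state_derivative(st0, ind, demo_pop)
  expect_equal(state_to_vector(d0), rep(0, 7))

  # k10 = 0 never produces a dose rate: amount constant, chains at rest
  ind0 <- individual_parameters(k10 = 1e-12, edk50 = 2)
  st <- model_state(a = 10)
  d <- state_derivative(st, ind0, demo_pop)
  expect_equal(d$a, -1e-11)
  expect_equal(d$c1, rep(0, 3), tolerance = 1e-9)

  # with a fixed effect e, the chain's fixed point is all compartments at 1-e
  e <- 0.3
  st_fp <- model_state(a = 5, c1 = rep(1 - e, 3), c2 = rep(1 - e, 3))
  d_fp <- state_derivative(st_fp, ind, demo_pop, force_eff = e)
  expect_equal(c(d_fp$c1, d_fp$c2), rep(0, 6))
})

test_that("INR output is linear in the terminal activities with the expected identities", {
  pop <- demo_pop
  expect_equal(inr_from_state(model_state(), 1.2, pop), 1.2)
  expect_equal(inr_from_state(model_state(c1 = rep(0, 3), c2 = rep(0, 3)),
                              1, pop), 21)
  expect_equal(inr_from_state(model_state(c1 = c(1, 1, 1), c2 = rep(0, 3)),
                              1, pop), 11)
  # slope in (C1_3 + C2_3) is -inr_max/2
  x <- seq(0, 1, by = 0.1)
  inr <- vapply(x, function(v)
    inr_from_state(model_state(c1 = c(1, 1, v), c2 = c(1, 1, v)), 1, pop),
    numeric(1))
  fit <- coef(lm(inr ~ I(2 * x)))
  expect_equal(unname(fit[2]), -pop$inr_max / 2)
})

test_that("population model constructor validates positivity and completeness", {
  expect_error(population_model(tv_cl = -0.2, tv_v = 10,
                                edk50_by_vkorc1 = c("G/G" = 3, "A/G" = 2.3, "A/A" = 1.6),
                                gamma = 1, mtt1 = 30, mtt2 = 110,
                                omega_k10 = 0.09, omega_edk50 = 0.16,
                                sigma_add = 0.15),
               "tv_cl")
  expect_error(population_model(tv_cl = 0.2, tv_v = 10,
                                edk50_by_vkorc1 = c("G/G" = 3, "A/G" = 2.3),
                                gamma = 1, mtt1 = 30, mtt2 = 110,
                                omega_k10 = 0.09, omega_edk50 = 0.16,
                                sigma_add = 0.15),
               "edk50")
})
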