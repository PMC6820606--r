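test_that("reference population has the specified composition and is
           reproducible by seed", {
  m <- default_model()
  pop <- build_reference_population(m, n = 4, seed = 7)
  expect_equal(pop$sex, c("male", "male", "female", "female"))
  expect_equal(pop$weight, c(85, 85, 64, 64))
  expect_true(all(pop$albumin == 40 & pop$tumor_size == 63 &
                    pop$ada == "negative"))

  pop2 <- build_reference_population(m, n = 4, seed = 7)
  expect_identical(pop, pop2)
  pop3 <- build_reference_population(m, n = 4, seed = 8)
  expect_false(identical(pop$eta_CL, pop3$eta_CL))

  # omega = 0: all males identical, all females identical
  m0 <- poppk_model(m$typical, m$covariate_effects, omega = diag(0, 4))
  p0 <- build_reference_population(m0, n = 6, seed = 1)
  expect_equal(length(unique(p0$CL[p0$sex == "male"])), 1)
  expect_equal(length(unique(p0$CL[p0$sex == "female"])), 1)

  expect_error(build_reference_population(m, n = 0), "positive")
})

test_that("weight-quartile populations honor bounds, sex mix and the
           truncated-normal sampling distribution", {
  m <- default_model()
  q1 <- build_weight_quartile_population(m, 1, n = 10, seed = 3)
  expect_equal(sum(q1$sex == "female"), 8)
  expect_true(all(q1$weight > 36.5 & q1$weight < 63.7))

  q4 <- build_weight_quartile_population(m, 4, n = 50, seed = 3)
  expect_equal(sum(q4$sex == "female"), 5)
  expect_true(all(q4$weight > 90.9 & q4$weight < 168.0))

  expect_error(build_weight_quartile_population(m, 5), "quartile")

  # sample mean vs analytic truncated-normal mean (3 SE band)
  big <- build_weight_quartile_population(m, 2, n = 10000, seed = 11)
  mu <- atezodose:::truncnorm_mean(77, 20.2, 63.7, 77.0)
  se <- stats::sd(big$weight) / sqrt(nrow(big))
  expect_lt(abs(mean(big$weight) - mu), 3 * se)
})

test_that("exposure metrics obey their closed-form identities", {
  m <- default_model()
  pop <- build_reference_population(m, n = 20, seed = 5)
  reg <- dosing_regimen(1200, 21, n_doses = 16)
  met <- derive_exposure(pop, reg)

  # steady-state AUC is exactly dose / CL; weekly AUC is dose / CL per week
  expect_equal(met$auc_ss, 1200 / pop$CL, tolerance = 1e-12)
  expect_equal(met$auc_week_ss, (1200 / pop$CL) / 3, tolerance = 1e-12)

  # trapezoid AUC to 10 half-lives within 0.5% of the closed-form AUCinf
  one <- pop[1, ]
  t_end <- 10 * terminal_half_life(unlist(one[, c("CL", "V1", "Q", "V2")]))
  grid <- seq(0, t_end, by = 0.1)
  conc <- concentration_profile(unlist(one[, c("CL", "V1", "Q", "V2")]),
                                dosing_regimen(1200, t_end + 1, n_doses = 1),
                                grid)
  expect_equal(atezodose:::trapz(grid, conc), 1200 / one$CL,
               tolerance = 5e-3)

  # metric ordering within cycles
  expect_true(all(met$cmax_c1 >= met$cmin_c1))
  expect_true(all(met$cmax_ss >= met$cmin_ss))
  # accumulation: steady-state trough exceeds cycle-1 trough for all four
  # regimens (terminal half-life exceeds every interval)
  for (reg_k in list(dosing_regimen(1200, 21, n_doses = 16),
                     dosing_regimen(840, 14, n_doses = 24),
                     dosing_regimen(1680, 28, n_doses = 12),
                     dosing_regimen(NULL, 21, n_doses = 16,
                                    sex_dose = c(male = 1700,
                                                 female = 1280)))) {
    mk <- derive_exposure(pop, reg_k)
    expect_true(all(mk$cmin_ss > mk$cmin_c1))
    expect_true(all(mk$cmax_ss > mk$cmax_c1))
  }

  expect_error(derive_exposure(pop, reg, grid_step = 0.3), "0.25")
})

test_that("geometric-mean exposure converges to the covariate-mixture
           typical value", {
  m <- default_model()
  pop <- build_reference_population(m, n = 50000, seed = 21)
  ref <- reference_covariates()
  male <- individual_params(m, modifyList(ref, list(weight = 85)))
  female <- individual_params(m, modifyList(ref, list(weight = 64,
                                                      sex = "female")))
  expected <- exp(mean(log(1200 / c(male["CL"], female["CL"]))))
  expect_equal(geo_mean(1200 / pop$CL), expected, tolerance = 0.01)
})

test_that("regimen comparison reports percent differences with the stated
           rounding conventions", {
  a <- data.frame(metric = "auc_week_ss", geo_mean = 2188)
  b <- data.frame(metric = "auc_week_ss", geo_mean = 2115)
  cmp <- compare_regimens(a, b)
  expect_equal(cmp$pct_1dp, 3.5)

  ident <- compare_regimens(a, a)
  expect_equal(ident$pct, 0)
  expect_error(compare_regimens(a, data.frame(metric = "auc_week_ss",
                                              geo_mean = 0)), "zero")
  expect_error(compare_regimens(a, data.frame(metric = "other",
                                              geo_mean = 1)), "shared")
})

test_that("with common random draws the steady-state weekly AUC ratio is
           the analytic weekly-dose ratio", {
  m <- default_model()
  pop <- build_reference_population(m, n = 50, seed = 9)
  q3w <- derive_exposure(pop, dosing_regimen(1200, 21, n_doses = 16))
  q2w <- derive_exposure(pop, dosing_regimen(840, 14, n_doses = 24))
  q4w <- derive_exposure(pop, dosing_regimen(1680, 28, n_doses = 12))
  expect_equal(q2w$auc_week_ss / q3w$auc_week_ss, rep(1.05, 50),
               tolerance = 1e-12)
  expect_equal(q4w$auc_week_ss / q3w$auc_week_ss, rep(1.05, 50),
               tolerance = 1e-12)
})

test_that("degenerate variability collapses the prediction interval onto the
           typical metric", {
  m <- default_model()
  m0 <- poppk_model(m$typical, m$covariate_effects, omega = diag(0, 4))
  pop <- build_reference_population(m0, n = 10, seed = 2)
  pop_m <- pop[pop$sex == "male", ]
  sim <- simulate_regimen(m0, pop_m, dosing_regimen(1200, 21, n_doses = 16))
  expect_true(all(sim$summary$pi_hi - sim$summary$pi_lo < 1e-9))
  expect_equal(sim$summary$geo_mean[sim$summary$metric == "auc_ss"],
               1200 / pop_m$CL[1], tolerance = 1e-12)
})
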