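test_that("Cox screening recovers a known log-hazard coefficient and
           rejects all-censored data", {
  set.seed(5)
  n <- 600
  x <- stats::rbinom(n, 1, 0.5)
  b <- 0.7
  t_event <- stats::rexp(n, rate = 0.002 * exp(b * x))
  cens <- stats::runif(n, 200, 1500)
  surv <- data.frame(time_days = pmin(t_event, cens),
                     event = as.integer(t_event <= cens))
  rep_tab <- screen_covariates(surv, data.frame(x = x))
  expect_lt(abs(rep_tab$coef - b), 2 * rep_tab$se)
  expect_lt(rep_tab$p, 0.001)
  # KM medians ordered: higher hazard, shorter survival
  expect_gt(rep_tab$median_low, rep_tab$median_high)

  surv0 <- transform(surv, event = 0)
  expect_error(screen_covariates(surv0, data.frame(x = x)), "events")
})

test_that("null covariates produce uniform screening P values", {
  set.seed(9)
  pvals <- vapply(1:150, function(r) {
    n <- 120
    t_event <- stats::rexp(n, 0.003)
    surv <- data.frame(time_days = pmin(t_event, 900),
                       event = as.integer(t_event <= 900))
    screen_covariates(surv, data.frame(z = stats::rnorm(n)))$p
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("intercept-only log-normal AFT reduces to the sample moments of
           log time", {
  set.seed(2)
  surv <- data.frame(time_days = stats::rlnorm(400, 6, 0.8),
                     event = 1)
  m <- fit_os_model(surv, family = "lognormal")
  lt <- log(surv$time_days)
  expect_equal(unname(stats::coef(m$fit)[1]), mean(lt), tolerance = 1e-6)
  expect_equal(unname(m$scale), stats::sd(lt) * sqrt(399 / 400),
               tolerance = 1e-6)
})

test_that("AIC-based family selection identifies the generating family and
           rank-deficient covariates are rejected", {
  set.seed(13)
  surv <- data.frame(time_days = stats::rlnorm(800, 6, 0.9), event = 1)
  m <- fit_os_model(surv, family = "auto")
  expect_equal(m$family, "lognormal")
  expect_equal(nrow(m$aic), 3)

  covs <- data.frame(a = stats::rnorm(800))
  covs$b <- 2 * covs$a
  expect_error(fit_os_model(surv, covs), "rank deficient")
})

test_that("tumor-type indicator separates the synthetic arms calibrated to
           different median survivals", {
  oak <- generate_trial(trial_config("oak", n = 350, seed = 4),
                        tables = "survival")
  imv <- generate_trial(trial_config("imvigor", n = 350, seed = 5),
                        tables = "survival")
  surv <- rbind(oak$survival, imv$survival)
  covs <- data.frame(
    log_kg = c(oak$patients$log_kg_true, imv$patients$log_kg_true),
    tumor_type_uc = rep(c(0, 1), each = 350))
  m <- fit_os_model(surv, covs)
  tt_row <- grep("tumor_type_uc", rownames(m$coefficients))
  expect_lt(m$coefficients[tt_row, "Value"], 0)  # UC arm shorter survival
  expect_lt(m$coefficients[tt_row, "p"], 0.05)

  km <- survival::survfit(survival::Surv(surv$time_days, surv$event) ~
                            covs$tumor_type_uc)
  med <- summary(km)$table[, "median"]
  expect_gt(med[1], med[2])
})

test_that("exposure flag applies the alpha = 0.01 convention", {
  set.seed(6)
  trial <- generate_trial(trial_config("oak", n = 300, seed = 6),
                          tables = c("survival", "endpoints"))
  covs <- data.frame(log_kg = trial$patients$log_kg_true,
                     ecog_pos = trial$patients$ecog_pos)
  m <- fit_os_model(trial$survival, covs)
  res <- test_exposure(m, trial$truth$exposure$auc_c1)
  expect_identical(res$significant, unname(res$wald_p < 0.01))
  expect_true(res$lrt_p > 0 && res$lrt_p <= 1)
  expect_error(test_exposure(m, rep(1, 300)), "constant")
})

test_that("AFT coefficient estimation is calibrated: 95% CI coverage over
           replicates", {
  set.seed(123)
  b_true <- c(x1 = -0.4, x2 = 0.25)
  cover <- matrix(NA, 200, 2)
  for (r in 1:200) {
    n <- 800
    X <- data.frame(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
    lt <- 6 + as.matrix(X) %*% b_true + 0.9 * stats::rnorm(n)
    cens <- log(stats::runif(n, 200, 3000))
    surv <- data.frame(time_days = exp(pmin(lt, cens)),
                       event = as.integer(lt <= cens))
    m <- fit_os_model(surv, X)
    est <- m$coefficients[c("x1", "x2"), "Value"]
    se <- m$coefficients[c("x1", "x2"), "Std. Error"]
    cover[r, ] <- abs(est - b_true) <= 1.96 * se
  }
  cv <- colMeans(cover)
  expect_true(all(cv > 0.91 & cv < 0.985))
})

test_that("identical treated and control specifications give a null hazard
           ratio", {
  set.seed(3)
  trial <- generate_trial(trial_config("oak", n = 400, seed = 3),
                          tables = "survival")
  covs <- data.frame(log_kg = trial$patients$log_kg_true)
  m <- fit_os_model(trial$survival, covs)
  ## exposure independent of the covariate: quartiles are random subsets,
  ## so treated and control specifications coincide distributionally
  hr <- simulate_os_hr(m, treated = covs, control = covs,
                       exposure = stats::runif(nrow(covs)),
                       n_reps = 100, seed = 10)
  expect_true(all(hr$hr_lo < 1 & hr$hr_hi > 1))
  expect_true(all(abs(log(hr$hr_median)) < 0.35))
})

test_that("exponential special case recovers the analytic AFT-PH hazard
           ratio", {
  # Weibull AFT with scale 1 is exponential: HR for covariate shift dx is
  # exp(-beta dx / scale) = exp(-beta dx)
  set.seed(8)
  n <- 500
  lt <- log(stats::rexp(n, 0.002))
  surv <- data.frame(time_days = exp(lt), event = 1)
  covs <- data.frame(log_kg = stats::rnorm(n))   # null covariate
  m <- fit_os_model(surv, covs, family = "weibull")
  beta <- m$coefficients["log_kg", "Value"]
  treated <- data.frame(log_kg = rep(1, 200))
  control <- data.frame(log_kg = rep(0, 200))
  hr <- simulate_os_hr(m, treated, control,
                       exposure = stats::runif(200), n_reps = 400, seed = 2)
  analytic <- exp(-beta * 1 / m$scale)
  for (k in 1:4) {
    expect_gt(hr$hr_hi[k], analytic * 0.99)
    expect_lt(hr$hr_lo[k], analytic * 1.01)
  }
})

test_that("simulated OS from the fitted model reproduces its own training
           Kaplan-Meier curve", {
  set.seed(11)
  trial <- generate_trial(trial_config("oak", n = 400, seed = 11),
                          tables = "survival")
  covs <- data.frame(log_kg = trial$patients$log_kg_true,
                     ecog_pos = trial$patients$ecog_pos,
                     albumin = trial$patients$albumin)
  m <- fit_os_model(trial$survival, covs)
  lp <- predict(m$fit, type = "lp")
  grid <- seq(60, 720, by = 60)
  km <- survival::survfit(survival::Surv(trial$survival$time_days,
                                         trial$survival$event) ~ 1)
  obs <- summary(km, times = grid, extend = TRUE)$surv
  sims <- replicate(200, {
    tt <- atezodose:::simulate_aft_times(lp, m$scale, m$family)
    cens <- trial$truth$os$censor_time
    s <- survival::survfit(survival::Surv(pmin(tt, cens),
                                          as.integer(tt <= cens)) ~ 1)
    summary(s, times = grid, extend = TRUE)$surv
  })
  lo <- apply(sims, 1, stats::quantile, 0.05)
  hi <- apply(sims, 1, stats::quantile, 0.95)
  inside <- obs >= lo & obs <= hi
  expect_gte(mean(inside), 0.9)
})
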