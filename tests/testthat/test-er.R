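test_that("logistic slope for a binary exposure equals the 2x2 log odds
           ratio", {
  # 40 exposed with 12 events, 60 unexposed with 6 events
  d <- data.frame(exposure = rep(c(1, 0), c(40, 60)),
                  outcome = c(rep(c(1, 0), c(12, 28)),
                              rep(c(1, 0), c(6, 54))))
  fit <- fit_logistic(d)
  expect_equal(fit$slope, log((12 * 54) / (28 * 6)), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$p, 2 * stats::pnorm(-abs(fit$z)), tolerance = 1e-12)
})

test_that("degenerate and separated inputs are rejected or flagged", {
  expect_error(fit_logistic(data.frame(exposure = 1:10,
                                       outcome = rep(1, 10))),
               "single class")
  expect_error(fit_logistic(data.frame(exposure = rep(1, 10),
                                       outcome = rep(0:1, 5))),
               "distinct")
  sep <- data.frame(exposure = c(1:10, 11:20),
                    outcome = rep(c(0, 1), each = 10))
  fit <- fit_logistic(sep)
  expect_true(fit$separation)
  expect_true(is.na(fit$p))
})

test_that("Wald P is invariant to exposure unit rescaling while the slope
           scales inversely", {
  set.seed(42)
  d <- data.frame(exposure = stats::rlnorm(300, 7, 0.3))
  d$outcome <- stats::rbinom(300, 1, stats::plogis(-2 + 0.001 * d$exposure))
  f1 <- fit_logistic(d)
  d2 <- transform(d, exposure = exposure / 1000)
  f2 <- fit_logistic(d2)
  expect_equal(f2$slope, 1000 * f1$slope, tolerance = 1e-6)
  expect_equal(f2$p, f1$p, tolerance = 1e-9)
})

test_that("quartile summaries count events exactly and use exact binomial
           intervals", {
  # 8 equally spaced exposures, one event in the top quartile
  d <- data.frame(exposure = 1:8, outcome = c(0, 0, 0, 0, 0, 0, 0, 1))
  qs <- quartile_summary(d)
  expect_equal(qs$proportion[1:4], c(0, 0, 0, 0.5))
  expect_equal(qs$n[1:4], rep(2, 4))

  # quartile counts partition the pooled row
  set.seed(1)
  d2 <- data.frame(exposure = stats::rlnorm(203),
                   outcome = stats::rbinom(203, 1, 0.2))
  q2 <- quartile_summary(d2)
  pooled <- q2[q2$quartile == "pooled", ]
  expect_equal(sum(q2$n[1:4]), pooled$n)
  expect_equal(sum(q2$events[1:4]), pooled$events)
  expect_true(all(diff(range(q2$n[1:4])) <= 1))
  ci <- stats::binom.test(pooled$events, pooled$n)$conf.int
  expect_equal(c(pooled$ci_lo, pooled$ci_hi), as.numeric(ci))
})

test_that("pooling check compares stratum frequencies against the
           threshold", {
  d <- data.frame(
    tumor_type = rep(c("NSCLC", "UC"), c(501, 541)),
    outcome = c(rep(c(1, 0), c(78, 423)), rep(c(1, 0), c(86, 455))))
  pc <- pool_check(d)
  expect_equal(pc$table$frequency_pct,
               c(100 * 78 / 501, 100 * 86 / 541), tolerance = 1e-9)
  expect_true(pc$pooled)

  # 14.9% vs 19.6%: difference 4.7 pp, still pooled at the 5 pp threshold
  d2 <- data.frame(tumor_type = rep(c("A", "B"), c(1000, 1000)),
                   outcome = c(rep(c(1, 0), c(149, 851)),
                               rep(c(1, 0), c(196, 804))))
  pc2 <- pool_check(d2)
  expect_equal(pc2$max_abs_diff_pp, 4.7, tolerance = 1e-9)
  expect_true(pc2$pooled)
  expect_false(pool_check(d2, threshold = 4)$pooled)

  # identical strata pool trivially; empty stratum is rejected
  d3 <- data.frame(tumor_type = rep(c("A", "B"), each = 10),
                   outcome = rep(c(1, 0), 10))
  expect_equal(pool_check(d3)$max_abs_diff_pp, 0)
  d4 <- d3[d3$tumor_type == "A" | d3$outcome == 2, ]
  expect_error(pool_check(d4), "strata")
})

test_that("subgroup safety summaries count by hand and support metric and
           weight-quartile groupings", {
  d <- data.frame(
    id = 1:10,
    grp = rep(c("A", "B"), c(4, 6)),
    cmax = c(800, 900, 700, 950, 300, 350, 280, 320, 310, 305),
    weight = c(50, 55, 60, 62, 70, 75, 80, 85, 90, 95),
    ae = c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0))
  by_col <- subgroup_safety_summary(d, "ae", "grp")
  expect_equal(by_col$frequency, c(2 / 4, 2 / 6))

  by_thr <- subgroup_safety_summary(d, "ae",
                                    list(metric = "cmax", threshold = 500))
  expect_equal(by_thr$n, c(6, 4))
  expect_equal(by_thr$frequency[by_thr$subgroup == "above"], 0.5)

  by_wt <- subgroup_safety_summary(d, "ae",
                                   list(weight = "weight",
                                        bounds = c(63.7, 77.0, 90.9)))
  expect_equal(by_wt$n, c(4, 6))
})

test_that("weight-quartile grouping reproduces a 25/75 split on
           quartile-mixed populations", {
  m <- default_model()
  mix <- do.call(rbind, lapply(1:4, function(q)
    build_weight_quartile_population(m, q, n = 100, seed = q)))
  mix$ae <- 0
  s <- subgroup_safety_summary(mix, "ae",
                               list(weight = "weight",
                                    bounds = c(63.7, 77.0, 90.9)))
  expect_equal(s$n, c(100, 300))
})

test_that("power of the Wald test increases with the exposure slope", {
  set.seed(77)
  power_at <- function(slope, reps = 200, n = 400) {
    hits <- vapply(seq_len(reps), function(r) {
      x <- stats::rlnorm(n, 7, 0.3)
      y <- stats::rbinom(n, 1, stats::plogis(-1.7 + slope * (x - 1200)))
      f <- fit_logistic(data.frame(exposure = x, outcome = y))
      !is.na(f$p) && f$p < 0.05
    }, logical(1))
    mean(hits)
  }
  pw <- c(power_at(0.0002), power_at(0.0006), power_at(0.0012))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.8)
})
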