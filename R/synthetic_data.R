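## Synthetic virtual-trial generator.  Emulates the statistical structure
## the downstream analyses assume — log-normal between-patient PK
## variability with covariate effects, biexponential SLD kinetics with
## proportional noise, log-normal AFT survival driven by log(KG) and
## prognostic factors, and binary endpoints with a configurable (default
## zero) exposure slope — so every pipeline stage is testable without
## patient-level trial data.

#' Build a synthetic trial configuration
#'
#' Defaults correspond to a single atezolizumab monotherapy arm. Presets:
#' \describe{
#'   \item{"oak"}{NSCLC-like arm: n = 425, target median OS 467 days,
#'     evaluable fraction 91%.}
#'   \item{"imvigor"}{UC-like arm: n = 467, target median OS 344 days,
#'     evaluable fraction 82%.}
#'   \item{"impassion"}{PK-focused q2w arm: n = 445, 840 mg q2w, richer
#'     trough sampling.}
#' }
#' The OS intercept is derived from the target median and the expected
#' covariate mix. All values can be overridden via `...` (names matching
#' the returned list).
#'
#' @param preset "custom", "oak", "imvigor" or "impassion".
#' @param n number of patients.
#' @param seed integer seed.
#' @param model a [poppk_model()]; default [default_model()].
#' @param ... overrides for config elements (covariates, regimen,
#'   pk_schedule, tgi, os, er, clearance_decline).
#' @return list of class `trial_config`.
#' @export
trial_config <- function(preset = c("custom", "oak", "imvigor", "impassion"),
                         n = NULL, seed = 1, model = default_model(), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n = 400,
    seed = seed,
    model = model,
    tumor_type = "NSCLC",
    regimen = dosing_regimen(1200, interval_days = 21, n_doses = 16),
    covariates = list(
      weight_median = c(male = 85, female = 64), weight_sdlog = 0.18,
      weight_bounds = c(36.5, 168), female_prop = 0.4,
      albumin_mean = 40, albumin_sd = 4,
      tumor_size_median = 63, tumor_size_sdlog = 0.55,
      ada_prob = 0.08, ecog_pos_prob = 0.62,
      ldh_sdlog = 0.4, alp_sdlog = 0.35, pdl1_pos_prob = 0.45),
    pk_schedule = list(peak_doses = 1, trough_doses = c(2, 4, 8)),
    tgi = list(ks_meanlog = log(0.02), ks_sdlog = 0.8,
               kg_meanlog = log(0.002), kg_sdlog = 0.9,
               kg_cl_gamma = 0.5, sld_sigma = 0.10,
               visit_interval_days = 42, max_follow_days = 336,
               dropout_first_scan = 0.09),
    os = list(family = "lognormal",
              target_median_days = 467,
              coefs = c(log_kg = -0.45, ecog_pos = -0.35,
                        log_tumor_size = -0.25, albumin = 0.025,
                        log_ldh = -0.30, log_alp = -0.20,
                        pdl1_pos = 0.20, tumor_type_uc = -0.306),
              scale = 0.9, accrual_days = 365, study_days = 1100,
              dropout_rate = 1e-4),
    er = list(metric = "auc_c1",
              intercepts = c(orr = stats::qlogis(0.157),
                             ae_g3 = stats::qlogis(0.170),
                             aesi = stats::qlogis(0.243)),
              slopes = c(orr = 0, ae_g3 = 0, aesi = 0)),
    clearance_decline = list(imax = 0, t50 = 60)
  )
  if (preset == "oak") {
    cfg$n <- 425
    cfg$tumor_type <- "NSCLC"
    cfg$tgi$dropout_first_scan <- 0.09
    cfg$os$target_median_days <- 467
  } else if (preset == "imvigor") {
    cfg$n <- 467
    cfg$tumor_type <- "UC"
    cfg$tgi$dropout_first_scan <- 0.18
    cfg$os$target_median_days <- 344
  } else if (preset == "impassion") {
    cfg$n <- 445
    cfg$tumor_type <- "TNBC"
    cfg$regimen <- dosing_regimen(840, interval_days = 14, n_doses = 32)
    cfg$pk_schedule <- list(peak_doses = 1,
                            trough_doses = c(2, 4, 6, 14, 30))
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !inherits(cfg[[nm]], "dosing_regimen")) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if (!is.null(n)) cfg$n <- n
  ## OS intercept from the target median and expected covariate mix
  ## (continuous covariates are centered, so only the categorical mix and
  ## the tumor-type indicator shift the expected linear predictor)
  co <- cfg$os$coefs
  cfg$os$intercept <- log(cfg$os$target_median_days) -
    co[["ecog_pos"]] * cfg$covariates$ecog_pos_prob -
    co[["pdl1_pos"]] * cfg$covariates$pdl1_pos_prob -
    co[["tumor_type_uc"]] * as.numeric(identical(cfg$tumor_type, "UC"))
  cfg$os$centers <- c(log_kg = cfg$tgi$kg_meanlog,
                      log_tumor_size = log(cfg$covariates$tumor_size_median),
                      albumin = cfg$covariates$albumin_mean,
                      log_ldh = 0, log_alp = 0)
  structure(cfg, class = "trial_config")
}

## centered OS design matrix columns from a patients table
os_design <- function(patients, os) {
  data.frame(
    log_kg = patients$log_kg_true - os$centers[["log_kg"]],
    ecog_pos = patients$ecog_pos,
    log_tumor_size = log(patients$tumor_size) -
      os$centers[["log_tumor_size"]],
    albumin = patients$albumin - os$centers[["albumin"]],
    log_ldh = log(patients$ldh_rel),
    log_alp = log(patients$alp_rel),
    pdl1_pos = patients$pdl1_pos,
    tumor_type_uc = as.numeric(patients$tumor_type == "UC")
  )
}

#' Generate a complete synthetic trial
#'
#' Draws patient covariates, PK random effects and exposure metrics, a
#' sparse PK event-record dataset with residual error, longitudinal SLD
#' data from the biexponential model with proportional noise, overall
#' survival from the AFT truth (uniform accrual plus administrative
#' censoring and exponential dropout), and binary endpoints from
#' Bernoulli(logit^-1(b0 + b1 x exposure)). The tumor growth rate is
#' coupled to clearance (`tgi$kg_cl_gamma`), so exposure and survival are
#' confounded through KG while the direct (causal) exposure effect on the
#' endpoints defaults to zero.
#'
#' @param config a [trial_config()].
#' @param tables which component tables to generate (any of "pk", "sld",
#'   "survival", "endpoints"); patients, exposure and TGI/OS ground truth
#'   are always produced. Restricting tables speeds up replicate loops.
#' @return list of class `synthetic_trial`: patients, pk (event records),
#'   sld, survival, endpoints, truth (per-patient generating parameters).
#' @export
generate_trial <- function(config, tables = c("pk", "sld", "survival",
                                              "endpoints")) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(config$seed, {
    patients <- draw_patients(config)
    exposure <- derive_exposure(patients, config$regimen)
    truth_tgi <- draw_tgi_truth(config, patients)
    patients$log_kg_true <- log(truth_tgi$kg)
    surv <- if (any(c("survival", "sld") %in% tables)) {
      draw_survival(config, patients)
    }
    sld <- if ("sld" %in% tables) draw_sld(config, patients, truth_tgi, surv)
    endpoints <- if ("endpoints" %in% tables) {
      draw_endpoints(config, patients, exposure)
    }
    pk <- if ("pk" %in% tables) build_event_records(config, patients)
    structure(list(
      patients = patients, pk = pk, sld = sld,
      survival = if ("survival" %in% tables) surv$table,
      endpoints = endpoints,
      truth = list(tgi = truth_tgi,
                   os = if (!is.null(surv)) surv$truth,
                   exposure = exposure)),
      class = "synthetic_trial")
  })
}

#' Generate a PK-only event-record dataset
#'
#' The input generator for popPK and pcVPC checks. Optionally applies a
#' time-varying clearance decline CL(t) = CL0 x (1 - Imax t / (T50 + t)),
#' evaluated at each dose's administration time (piecewise-constant per
#' dose), to emulate the slow on-treatment clearance reduction seen with
#' checkpoint inhibitors.
#'
#' @param config a [trial_config()].
#' @return Event-record data.frame (passes [validate_event_records()]).
#' @export
generate_pk_only <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(config$seed, {
    patients <- draw_patients(config)
    build_event_records(config, patients)
  })
}

## ---- internal draws ------------------------------------------------------

draw_patients <- function(config) {
  n <- config$n
  cv <- config$covariates
  sex <- ifelse(stats::runif(n) < cv$female_prop, "female", "male")
  w_med <- cv$weight_median[sex]
  weight <- pmin(pmax(stats::rlnorm(n, log(w_med), cv$weight_sdlog),
                      cv$weight_bounds[1]), cv$weight_bounds[2])
  pop <- data.frame(
    id = seq_len(n),
    sex = sex,
    weight = weight,
    albumin = pmax(stats::rnorm(n, cv$albumin_mean, cv$albumin_sd), 20),
    tumor_size = stats::rlnorm(n, log(cv$tumor_size_median),
                               cv$tumor_size_sdlog),
    ada = ifelse(stats::runif(n) < cv$ada_prob, "positive", "negative"),
    ecog_pos = as.integer(stats::runif(n) < cv$ecog_pos_prob),
    ldh_rel = stats::rlnorm(n, 0, cv$ldh_sdlog),
    alp_rel = stats::rlnorm(n, 0, cv$alp_sdlog),
    pdl1_pos = as.integer(stats::runif(n) < cv$pdl1_pos_prob),
    tumor_type = config$tumor_type,
    stringsAsFactors = FALSE
  )
  finalize_population(config$model, pop, seed = NULL)
}

draw_tgi_truth <- function(config, patients) {
  tg <- config$tgi
  n <- nrow(patients)
  ## growth rate coupled to clearance: faster-clearing (lower-exposure)
  ## patients tend to have faster-growing tumors, confounding exposure and
  ## outcome without any causal exposure effect
  log_cl_c <- log(patients$CL) - mean(log(patients$CL))
  log_kg <- tg$kg_meanlog + tg$kg_cl_gamma * log_cl_c +
    stats::rnorm(n, 0, tg$kg_sdlog)
  data.frame(
    id = patients$id,
    bsld = patients$tumor_size,
    ks = stats::rlnorm(n, tg$ks_meanlog, tg$ks_sdlog),
    kg = exp(log_kg)
  )
}

draw_survival <- function(config, patients) {
  os <- config$os
  X <- os_design(patients, os)
  lp <- os$intercept + as.matrix(X) %*% os$coefs[names(X)]
  t_event <- simulate_aft_times(as.numeric(lp), os$scale, os$family)
  accrual <- stats::runif(nrow(patients), 0, os$accrual_days)
  c_admin <- os$study_days - accrual
  c_drop <- stats::rexp(nrow(patients), os$dropout_rate)
  cens <- pmin(c_admin, c_drop)
  time <- pmax(pmin(t_event, cens), 0.5)
  list(table = data.frame(id = patients$id, time_days = time,
                          event = as.integer(t_event <= cens)),
       truth = data.frame(id = patients$id, lp = as.numeric(lp),
                          true_time = t_event, censor_time = cens))
}

draw_sld <- function(config, patients, truth_tgi, surv) {
  tg <- config$tgi
  evaluable <- stats::runif(nrow(patients)) >= tg$dropout_first_scan
  visits <- seq(tg$visit_interval_days, tg$max_follow_days,
                by = tg$visit_interval_days)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    ## baseline for everyone; the first post-baseline scan is guaranteed
    ## for non-dropouts, later scans stop at death/censoring
    tt <- 0
    if (evaluable[i]) {
      keep <- visits <= surv$table$time_days[i]
      keep[1] <- TRUE
      tt <- c(0, visits[keep])
    }
    f <- sld_model(tt, truth_tgi$bsld[i], truth_tgi$ks[i], truth_tgi$kg[i])
    data.frame(id = patients$id[i], time_days = tt,
               sld_mm = pmax(f * (1 + stats::rnorm(length(tt),
                                                   0, tg$sld_sigma)), 0.1))
  })
  out <- do.call(rbind, rows)
  attr(out, "evaluable_true") <- patients$id[evaluable]
  out
}

draw_endpoints <- function(config, patients, exposure) {
  er <- config$er
  x <- exposure[[er$metric]]
  out <- data.frame(id = patients$id, tumor_type = patients$tumor_type,
                    exposure_metric = er$metric, exposure = x,
                    auc_c1 = exposure$auc_c1, cmin_c1 = exposure$cmin_c1,
                    cmax_c1 = exposure$cmax_c1)
  for (ep in names(er$intercepts)) {
    p <- stats::plogis(er$intercepts[[ep]] + er$slopes[[ep]] * x)
    out[[ep]] <- stats::rbinom(nrow(out), 1, p)
  }
  out
}

build_event_records <- function(config, patients) {
  reg <- config$regimen
  sch <- config$pk_schedule
  decline <- config$clearance_decline
  tinf <- reg$infusion_duration_days
  dose <- resolve_dose(reg, patients$sex, patients$weight)
  model <- config$model
  n_doses <- reg$n_doses
  dose_times <- (seq_len(n_doses) - 1) * reg$interval_days
  peak_t <- (sch$peak_doses - 1) * reg$interval_days + tinf
  trough_t <- (sch$trough_doses - 1) * reg$interval_days
  trough_t <- trough_t[sch$trough_doses <= n_doses]
  cov_cols <- c("weight", "sex", "albumin", "tumor_size", "ada")
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pars <- unlist(patients[i, PK_PARS])
    obs_t <- sort(c(peak_t, trough_t))
    conc <- conc_tvcl(pars, dose[i], dose_times, tinf, obs_t,
                      decline$imax, decline$t50)
    dv <- conc * (1 + model$sigma_prop * stats::rnorm(length(conc))) +
      model$sigma_add * stats::rnorm(length(conc))
    ev <- rbind(
      data.frame(TIME = dose_times, AMT = dose[i], RATE = dose[i] / tinf,
                 DV = 0, EVID = 1, MDV = 1),
      data.frame(TIME = obs_t, AMT = 0, RATE = 0,
                 DV = pmax(dv, 0), EVID = 0, MDV = 0)
    )
    ## troughs sort before the concurrent dose row (pre-dose samples)
    ev <- ev[order(ev$TIME, ev$EVID), ]
    cbind(ID = patients$id[i], ev, patients[i, cov_cols, drop = FALSE],
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## concentration under an optional clearance decline, applied as the CL in
## effect at each dose's administration time (piecewise-constant per dose)
conc_tvcl <- function(params, dose, dose_times, tinf, times, imax, t50) {
  out <- numeric(length(times))
  for (k in seq_along(dose_times)) {
    pk <- params
    if (imax > 0) {
      td <- dose_times[k]
      pk[["CL"]] <- params[["CL"]] * (1 - imax * td / (t50 + td))
    }
    out <- out + infusion_conc(macro_constants(pk), dose, tinf,
                               times - dose_times[k])
  }
  out
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d patients (%s)\n", nrow(x$patients),
              x$patients$tumor_type[1]))
  cat(sprintf("  PK records: %d; SLD records: %d; deaths: %d/%d\n",
              nrow(x$pk), nrow(x$sld), sum(x$survival$event),
              nrow(x$survival)))
  invisible(x)
}
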