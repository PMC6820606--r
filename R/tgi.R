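## Biexponential tumor-size model and per-patient estimation of shrinkage
## (KS) and growth (KG) rates from longitudinal sum-of-longest-diameters
## (SLD) data.

#' Biexponential tumor-size model
#'
#' SLD(t) = BSLD x (exp(-KS t) + exp(KG t) - 1): the sum of a shrinking
#' (treatment-sensitive) and a regrowing (resistant) component of the tumor
#' burden. At t = 0 the model returns the baseline BSLD; with KS = KG = 0 it
#' is constant.
#'
#' @param t time in days (>= 0), vectorized.
#' @param bsld baseline SLD in mm (> 0).
#' @param ks shrinkage rate per day (>= 0).
#' @param kg growth rate per day (>= 0).
#' @return SLD in mm at `t`.
#' @export
sld_model <- function(t, bsld, ks, kg) {
  if (any(t < 0)) stop("t must be >= 0")
  bsld * (exp(-ks * t) + exp(kg * t) - 1)
}

#' Time of the SLD nadir
#'
#' For KS > KG > 0 the model's minimum is at ln(KS/KG)/(KS+KG).
#'
#' @inheritParams sld_model
#' @return Nadir time in days (0 when no interior minimum exists).
#' @export
sld_nadir_time <- function(ks, kg) {
  if (ks <= kg || kg <= 0) return(0)
  log(ks / kg) / (ks + kg)
}

#' TGI-evaluable filter
#'
#' Retains patients with a baseline SLD record (time <= 0) plus at least
#' one post-baseline assessment; all exclusions are logged with a reason.
#'
#' @param sld_data long-format data.frame with columns id, time_days,
#'   sld_mm.
#' @return list with `evaluable` (ids), `exclusions` (data.frame id,
#'   reason) and `fraction_evaluable`.
#' @export
tgi_evaluable_filter <- function(sld_data) {
  ids <- unique(sld_data$id)
  reasons <- vapply(ids, function(i) {
    d <- sld_data[sld_data$id == i, ]
    if (!any(d$time_days <= 0)) "no baseline assessment"
    else if (!any(d$time_days > 0)) "no post-baseline assessment"
    else ""
  }, character(1))
  list(
    evaluable = ids[reasons == ""],
    exclusions = data.frame(id = ids[reasons != ""],
                            reason = reasons[reasons != ""]),
    fraction_evaluable = mean(reasons == "")
  )
}

#' Default log-normal priors for per-patient TGI estimation
#'
#' @param mean named numeric of log-scale prior means for bsld (mm),
#'   ks and kg (per day).
#' @param sd log-scale prior SDs; the default of 10 is effectively vague,
#'   so estimation reduces to nonlinear least squares when the data are
#'   informative.
#' @return list used by [fit_tgi()].
#' @export
tgi_priors <- function(mean = c(bsld = log(60), ks = log(0.02),
                                kg = log(0.002)),
                       sd = c(bsld = 10, ks = 10, kg = 10)) {
  list(mean = mean, sd = sd)
}

#' Fit the biexponential TGI model to one patient
#'
#' Penalized least squares on log(SLD) with log-normal priors on
#' (BSLD, KS, KG) — a maximum a posteriori approximation to the
#' empirical-Bayes individual estimates of a population model. With several
#' informative observations and vague priors this reduces to ordinary
#' nonlinear least squares. Non-convergence returns the prior means with a
#' flag; SLD values below `floor` are floored before the log transform.
#'
#' @param time_days,sld_mm observation vectors for one patient (baseline at
#'   time <= 0 treated as time 0).
#' @param priors from [tgi_priors()].
#' @param sigma proportional (log-scale) residual SD used to weight the data
#'   relative to the priors (default 0.1).
#' @param floor positive floor in mm applied to observed SLD (default 2).
#' @return one-row data.frame: bsld, ks, kg, converged, shrunk_to_prior,
#'   n_obs.
#' @export
fit_tgi <- function(time_days, sld_mm, priors = tgi_priors(), sigma = 0.1,
                    floor = 2) {
  t <- pmax(time_days, 0)
  y <- log(pmax(sld_mm, floor))
  mu <- priors$mean[c("bsld", "ks", "kg")]
  tau <- priors$sd[c("bsld", "ks", "kg")]
  resid_fn <- function(theta) {
    pred <- log(sld_model(t, exp(theta[1]), exp(theta[2]), exp(theta[3])))
    c((y - pred) / sigma, (theta - mu) / tau)
  }
  ## heuristic start: baseline from the first record, shrinkage from the
  ## drop to the observed nadir, regrowth from the nadir-to-last rebound
  start <- mu
  base_idx <- which.min(t)
  start[1] <- y[base_idx]
  i_min <- which.min(y)
  if (t[i_min] > 0) {
    start[2] <- log(max((y[base_idx] - y[i_min]) / t[i_min], 1e-4))
  }
  i_last <- which.max(t)
  if (t[i_last] > t[i_min] && y[i_last] > y[i_min]) {
    start[3] <- log(max((y[i_last] - y[i_min]) / (t[i_last] - t[i_min]),
                        1e-5))
  }
  lower <- c(log(0.5), -12, -12)
  upper <- c(log(1000), 1, 1)
  run <- function(par) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(par, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
  }
  ## multistart: heuristic and prior-mean starts, keep the better optimum
  fits <- Filter(function(f) !is.null(f) && f$info %in% 1:4,
                 list(run(start), run(mu)))
  fit <- if (length(fits)) fits[[which.min(vapply(fits, "[[", numeric(1),
                                                  "deviance"))]] else NULL
  ok <- !is.null(fit)
  theta <- if (ok) fit$par else mu
  n_post <- sum(time_days > 0)
  data.frame(bsld = exp(theta[[1]]), ks = exp(theta[[2]]),
             kg = exp(theta[[3]]), converged = ok,
             shrunk_to_prior = !ok || n_post < 2,
             n_obs = length(t))
}

#' Fit the TGI model to every evaluable patient
#'
#' @param sld_data long-format data.frame (id, time_days, sld_mm).
#' @inheritParams fit_tgi
#' @return data.frame of per-patient parameters with convergence flags;
#'   non-evaluable patients are omitted (see [tgi_evaluable_filter()]).
#' @export
fit_tgi_population <- function(sld_data, priors = tgi_priors(), sigma = 0.1,
                               floor = 2) {
  keep <- tgi_evaluable_filter(sld_data)$evaluable
  out <- lapply(keep, function(i) {
    d <- sld_data[sld_data$id == i, ]
    cbind(id = i, fit_tgi(d$time_days, d$sld_mm, priors, sigma, floor))
  })
  do.call(rbind, out)
}
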