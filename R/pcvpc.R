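## Prediction-corrected visual predictive check (pcVPC) of a popPK model
## against an observed (or synthetic) event-record concentration dataset.

#' Run a prediction-corrected visual predictive check
#'
#' For every observation the population prediction (PRED; zero random
#' effects, actual dosing and covariates) is computed; the
#' prediction-corrected value is obs x (bin median PRED / individual PRED)
#' — the standard multiplicative, lower-bound-zero correction. The same
#' correction is applied to each of `n_reps` simulated replicates (random
#' effects drawn from omega, residual error applied), and the observed
#' 5/50/95th percentiles per time bin are compared with the simulated 90%
#' prediction interval of each percentile.
#'
#' @param model a [poppk_model()] with residual-error parameters.
#' @param data event-record data.frame (NONMEM dialect: ID, TIME, AMT,
#'   RATE, DV, EVID, MDV plus covariate columns weight, sex, albumin,
#'   tumor_size, ada). Doses are EVID 1 rows; observations EVID 0, MDV 0.
#' @param n_reps number of simulation replicates (default 1000).
#' @param bins either `NULL` (bin on unique nominal observation times when
#'   there are at most `max_unique_bins` of them, otherwise 8 quantile
#'   bins), an integer number of quantile bins, or a numeric vector of bin
#'   break points.
#' @param seed integer seed.
#' @param lloq optional lower limit of quantification; observations below
#'   it are excluded and logged.
#' @param max_unique_bins see `bins`.
#' @return object of class `pcvpc`: per-bin data.frame (n, observed
#'   percentiles, simulated 90% PIs), exclusion log, n_reps.
#' @export
run_pcvpc <- function(model, data, n_reps = 1000, bins = NULL, seed = 1,
                      lloq = NULL, max_unique_bins = 20) {
  data <- validate_event_records(data)$data
  obs <- data[data$EVID == 0 & data$MDV == 0, ]
  doses <- data[data$EVID == 1, ]
  excluded <- data.frame(id = numeric(0), time = numeric(0),
                         reason = character(0))
  if (!is.null(lloq)) {
    drop <- obs$DV < lloq
    if (any(drop)) {
      excluded <- rbind(excluded, data.frame(
        id = obs$ID[drop], time = obs$TIME[drop],
        reason = "below limit of quantification"))
      obs <- obs[!drop, ]
    }
  }
  ids <- unique(obs$ID)
  ## population prediction per observation (eta = 0, actual dosing)
  covs <- obs[!duplicated(obs$ID),
              c("ID", "weight", "sex", "albumin", "tumor_size", "ada")]
  pars0 <- individual_params_df(model, covs)
  pred <- numeric(nrow(obs))
  for (k in seq_along(ids)) {
    i <- ids[k]
    oi <- obs$ID == i
    pred[oi] <- conc_event_times(unlist(pars0[k, ]),
                                 doses[doses$ID == i, ], obs$TIME[oi])
  }
  zero <- pred <= 0
  if (any(zero)) {
    excluded <- rbind(excluded, data.frame(
      id = obs$ID[zero], time = obs$TIME[zero],
      reason = "population prediction is zero"))
    obs <- obs[!zero, ]
    pred <- pred[!zero]
  }
  ## binning
  bin <- make_bins(obs$TIME, bins, max_unique_bins)
  med_pred <- stats::ave(pred, bin, FUN = stats::median)
  pc_obs <- obs$DV * med_pred / pred
  ## simulate replicates
  sims <- with_seed(seed, {
    out <- matrix(NA_real_, nrow(obs), n_reps)
    for (r in seq_len(n_reps)) {
      eta <- MASS::mvrnorm(length(ids), rep(0, 4), model$omega)
      if (!is.matrix(eta)) eta <- matrix(eta, nrow = 1)
      colnames(eta) <- PK_PARS
      pars <- individual_params_df(model, covs, eta)
      conc <- numeric(nrow(obs))
      for (k in seq_along(ids)) {
        i <- ids[k]
        oi <- obs$ID == i
        conc[oi] <- conc_event_times(unlist(pars[k, PK_PARS]),
                                     doses[doses$ID == i, ], obs$TIME[oi])
      }
      dv <- conc * (1 + model$sigma_prop * stats::rnorm(length(conc))) +
        model$sigma_add * stats::rnorm(length(conc))
      out[, r] <- pmax(dv, 0) * med_pred / pred
    }
    out
  })
  ## per-bin percentiles
  probs <- c(0.05, 0.5, 0.95)
  lev <- levels(bin)
  rows <- lapply(lev, function(b) {
    sel <- bin == b
    oq <- stats::quantile(pc_obs[sel], probs, names = FALSE)
    simq <- apply(sims[sel, , drop = FALSE], 2, stats::quantile,
                  probs = probs, names = FALSE)   # 3 x n_reps
    pi_lo <- apply(simq, 1, stats::quantile, probs = 0.05, names = FALSE)
    pi_md <- apply(simq, 1, stats::median)
    pi_hi <- apply(simq, 1, stats::quantile, probs = 0.95, names = FALSE)
    data.frame(bin = b, time_median = stats::median(obs$TIME[sel]),
               n = sum(sel), flagged_small = sum(sel) < 5,
               obs_p5 = oq[1], obs_p50 = oq[2], obs_p95 = oq[3],
               sim_p5_lo = pi_lo[1], sim_p5_med = pi_md[1],
               sim_p5_hi = pi_hi[1],
               sim_p50_lo = pi_lo[2], sim_p50_med = pi_md[2],
               sim_p50_hi = pi_hi[2],
               sim_p95_lo = pi_lo[3], sim_p95_med = pi_md[3],
               sim_p95_hi = pi_hi[3])
  })
  structure(list(bins = do.call(rbind, rows), excluded = excluded,
                 n_reps = n_reps, n_obs = nrow(obs)),
            class = "pcvpc")
}

#' @export
print.pcvpc <- function(x, ...) {
  inside <- with(x$bins, obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi)
  cat(sprintf("pcVPC: %d observations in %d bins, %d replicates\n",
              x$n_obs, nrow(x$bins), x$n_reps))
  cat(sprintf("  observed medians inside simulated 90%% PI: %d/%d bins\n",
              sum(inside), length(inside)))
  if (nrow(x$excluded)) {
    cat(sprintf("  %d observations excluded (see $excluded)\n",
                nrow(x$excluded)))
  }
  invisible(x)
}

make_bins <- function(times, bins, max_unique_bins) {
  if (is.null(bins)) {
    ut <- sort(unique(times))
    if (length(ut) <= max_unique_bins) {
      return(factor(times, levels = ut))
    }
    bins <- 8
  }
  if (length(bins) == 1) {
    breaks <- unique(stats::quantile(times, seq(0, 1, length.out = bins + 1),
                                     names = FALSE))
  } else {
    breaks <- bins
  }
  cut(times, breaks = breaks, include.lowest = TRUE)
}

## concentration at arbitrary times given explicit dose rows
## (TIME, AMT, RATE; RATE 0 or missing = 1-hour default infusion)
conc_event_times <- function(params, doses, times) {
  mc <- macro_constants(params)
  out <- numeric(length(times))
  for (j in seq_len(nrow(doses))) {
    amt <- doses$AMT[j]
    rate <- doses$RATE[j]
    tinf <- if (is.null(rate) || is.na(rate) || rate <= 0) 1 / 24
    else amt / rate
    out <- out + infusion_conc(mc, amt, tinf, times - doses$TIME[j])
  }
  out
}

#' Plot a pcVPC
#'
#' Observed prediction-corrected percentiles (lines/points) against the
#' simulated 90% prediction intervals (ribbons) per bin. Requires ggplot2.
#'
#' @param x a `pcvpc` object.
#' @param log_y plot the y axis on the log scale (default TRUE).
#' @return A ggplot object.
#' @export
plot_pcvpc <- function(x, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  b <- x$bins
  p <- ggplot2::ggplot(b, ggplot2::aes(x = time_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p5_lo, ymax = sim_p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo, ymax = sim_p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p95_lo, ymax = sim_p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50)) +
    ggplot2::geom_point(ggplot2::aes(y = obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p95), linetype = 2) +
    ggplot2::labs(x = "Time (days)",
                  y = "Prediction-corrected concentration (ug/mL)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
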