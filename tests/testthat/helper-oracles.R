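# Independent oracles and fixture builders used across tests.

# Adaptive-step numerical solution of the two-compartment infusion model,
# independent of the package's closed-form solution.
ode_conc_oracle <- function(params, dose, interval, tinf, n_doses, times) {
  p <- as.list(params)
  deriv <- function(t, y, parms) {
    c1 <- y[1] / p$V1
    c2 <- y[2] / p$V2
    list(c(parms$rate - p$CL * c1 - p$Q * (c1 - c2),
           p$Q * (c1 - c2)))
  }
  ## integrate piecewise between infusion on/off breakpoints so the solver
  ## never steps across a rate discontinuity
  starts <- (seq_len(n_doses) - 1) * interval
  bounds <- sort(unique(c(0, starts, starts + tinf, max(times))))
  bounds <- c(bounds[bounds < max(times)], max(times))
  state <- c(A1 = 0, A2 = 0)
  conc <- numeric(length(times))
  for (seg in seq_len(length(bounds) - 1)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    rate <- if (any(t0 >= starts - 1e-12 & t0 < starts + tinf - 1e-12)) {
      dose / tinf
    } else 0
    inner <- times[times > t0 & times <= t1]
    grid <- sort(unique(c(t0, inner, t1)))
    out <- deSolve::lsoda(state, times = grid, func = deriv,
                          parms = list(rate = rate),
                          rtol = 1e-10, atol = 1e-8)
    state <- out[nrow(out), c("A1", "A2")]
    if (length(inner)) {
      conc[match(inner, times)] <- out[match(inner, out[, "time"]), "A1"] /
        p$V1
    }
  }
  conc
}

# random positive two-compartment parameter sets around the default scale
random_pk_params <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(
    CL = stats::runif(n, 0.05, 0.6),
    V1 = stats::runif(n, 1.5, 6),
    Q = stats::runif(n, 0.1, 2),
    V2 = stats::runif(n, 1.5, 6)
  )
}

# reference covariate vector for the default model
reference_covariates <- function() {
  list(weight = 77, sex = "male", albumin = 40, tumor_size = 63,
       ada = "negative")
}

# tiny valid event-record dataset: one dose plus one observation
minimal_event_records <- function() {
  data.frame(
    ID = c(1, 1), TIME = c(0, 7), AMT = c(1200, 0), RATE = c(28800, 0),
    DV = c(0, 50), EVID = c(1, 0), MDV = c(1, 0),
    weight = 77, sex = "male", albumin = 40, tumor_size = 63,
    ada = "negative", stringsAsFactors = FALSE
  )
}

flat_priors <- function() {
  tgi_priors(sd = c(bsld = Inf, ks = Inf, kg = Inf))
}
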