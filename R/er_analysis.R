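## Exposure-response analysis of binary endpoints (ORR, grade >= 3 AE,
## AESI) versus a continuous cycle-1 exposure metric, with quartile
## summaries, a pooling check across tumor types and subgroup safety
## tabulation.

#' Logistic exposure-response fit
#'
#' Maximum-likelihood fit of logit(p) = b0 + b1 x exposure with the Wald
#' test for the exposure slope, the convention used to screen for
#' exposure-response relationships of binary endpoints.
#'
#' @param data data.frame with an exposure column and a 0/1 outcome column.
#' @param exposure,outcome column names.
#' @return list of class `er_logistic_fit` with elements `intercept`,
#'   `slope`, `se`, `z`, `p` (two-sided Wald), `converged`, `separation`,
#'   `n`, `events` and the underlying `glm` fit.
#' @export
fit_logistic <- function(data, exposure = "exposure", outcome = "outcome") {
  x <- data[[exposure]]
  y <- data[[outcome]]
  if (is.null(x) || is.null(y)) stop("exposure/outcome columns not found")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(x)) < 2) stop("need >= 2 distinct exposure values")
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fit is undefined")
  }
  ## separation is detected explicitly below, so the fitted-probability
  ## warnings glm emits in that case are redundant
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(fit)
  separation <- !fit$converged ||
    any(abs(fit$coefficients) > 1e3) ||
    max(fit$fitted.values) > 1 - 1e-8 || min(fit$fitted.values) < 1e-8
  z <- sm$coefficients["x", "Estimate"] / sm$coefficients["x", "Std. Error"]
  out <- list(
    intercept = unname(fit$coefficients[1]),
    slope = unname(fit$coefficients[2]),
    se = unname(sm$coefficients["x", "Std. Error"]),
    z = unname(z),
    p = if (separation) NA_real_ else unname(2 * stats::pnorm(-abs(z))),
    converged = fit$converged && !separation,
    separation = separation,
    n = length(y), events = sum(y), fit = fit
  )
  class(out) <- "er_logistic_fit"
  out
}

#' @export
print.er_logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic ER fit: n = %d, events = %d\n", x$n, x$events))
  if (x$separation) {
    cat("  complete/quasi-complete separation detected; no Wald P reported\n")
  } else {
    cat(sprintf("  slope = %.4g per exposure unit (SE %.3g), Wald P = %.3g\n",
                x$slope, x$se, x$p))
  }
  invisible(x)
}

#' Exposure-quartile event summary
#'
#' Splits patients into exposure quartiles (edges at the empirical
#' 25/50/75th percentiles, ties assigned to the lower quartile) and reports
#' the event proportion with an exact Clopper-Pearson 95% CI per quartile,
#' plus the pooled row.
#'
#' @inheritParams fit_logistic
#' @return data.frame with quartile ("Q1".."Q4", "pooled"), n, events,
#'   proportion, ci_lo, ci_hi, and the quartile exposure ranges.
#' @export
quartile_summary <- function(data, exposure = "exposure",
                             outcome = "outcome") {
  x <- data[[exposure]]
  y <- data[[outcome]]
  if (length(x) < 4) stop("need at least 4 patients for quartiles")
  edges <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  q <- cut(x, breaks = c(-Inf, edges, Inf), labels = paste0("Q", 1:4),
           right = TRUE)
  rows <- lapply(levels(q), function(lev) {
    yi <- y[q == lev]
    ci <- if (length(yi)) stats::binom.test(sum(yi), length(yi))$conf.int
    else c(NA, NA)
    data.frame(quartile = lev, n = length(yi), events = sum(yi),
               proportion = if (length(yi)) mean(yi) else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2],
               exp_lo = if (length(yi)) min(x[q == lev]) else NA_real_,
               exp_hi = if (length(yi)) max(x[q == lev]) else NA_real_)
  })
  pooled_ci <- stats::binom.test(sum(y), length(y))$conf.int
  rows <- c(rows, list(data.frame(
    quartile = "pooled", n = length(y), events = sum(y),
    proportion = mean(y), ci_lo = pooled_ci[1], ci_hi = pooled_ci[2],
    exp_lo = min(x), exp_hi = max(x))))
  do.call(rbind, rows)
}

#' Check whether strata can be pooled
#'
#' Compares per-stratum event frequencies (e.g. by tumor type) and
#' recommends pooling when the largest absolute difference is below a
#' threshold in percentage points.
#'
#' @param data data.frame with an outcome column and a stratum column.
#' @param stratum stratum column name (default "tumor_type").
#' @param outcome outcome column name.
#' @param threshold pooling threshold in percentage points (default 5).
#' @return list with per-stratum table, `max_abs_diff_pp` and logical
#'   `pooled`.
#' @export
pool_check <- function(data, stratum = "tumor_type", outcome = "outcome",
                       threshold = 5) {
  s <- data[[stratum]]
  y <- data[[outcome]]
  tab <- do.call(rbind, lapply(split(y, s), function(yi) {
    if (length(yi) == 0) stop("empty stratum")
    data.frame(n = length(yi), events = sum(yi),
               frequency_pct = 100 * mean(yi))
  }))
  if (nrow(tab) < 2) stop("need >= 2 strata")
  tab <- cbind(stratum = rownames(tab), tab)
  rownames(tab) <- NULL
  d <- max(tab$frequency_pct) - min(tab$frequency_pct)
  list(table = tab, max_abs_diff_pp = d, threshold_pp = threshold,
       pooled = d < threshold)
}

#' Subgroup safety summary
#'
#' Summarizes event frequencies per subgroup for one or more binary AE
#' columns. Supported groupings: any factor/character column, a threshold
#' split of a numeric metric (e.g. observed Cmax above/below a predicted
#' reference Cmax), or the lowest-vs-upper-3 body-weight-quartile split.
#'
#' @param data data.frame of patients.
#' @param events character vector of binary (0/1) event column names.
#' @param group either a column name, or `list(metric=, threshold=)`, or
#'   `list(weight = "weight", bounds = <length-3 numeric of inner quartile
#'   edges>)`.
#' @return data.frame with one row per subgroup x event: n, events,
#'   frequency (NA when the subgroup is empty).
#' @export
subgroup_safety_summary <- function(data, events, group) {
  g <- if (is.character(group) && length(group) == 1) {
    factor(data[[group]])
  } else if (is.list(group) && !is.null(group$metric)) {
    factor(ifelse(data[[group$metric]] > group$threshold,
                  "above", "below"), levels = c("below", "above"))
  } else if (is.list(group) && !is.null(group$weight)) {
    factor(ifelse(data[[group$weight]] <= group$bounds[1],
                  "lowest_quartile", "upper_quartiles"),
           levels = c("lowest_quartile", "upper_quartiles"))
  } else stop("unsupported grouping specification")
  out <- list()
  for (lev in levels(g)) {
    idx <- which(g == lev)
    for (ev in events) {
      yi <- data[[ev]][idx]
      out[[length(out) + 1]] <- data.frame(
        subgroup = lev, event = ev, n = length(idx),
        events = if (length(idx)) sum(yi) else 0L,
        frequency = if (length(idx)) mean(yi) else NA_real_)
    }
  }
  do.call(rbind, out)
}
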