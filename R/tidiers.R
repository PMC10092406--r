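# broom-style tidiers for fitted objects.

#' @method tidy wr_regain_fit
#' @export
tidy.wr_regain_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope_per_month"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    conf.low = c(x$ci95_intercept[1], x$ci95_slope[1]),
    conf.high = c(x$ci95_intercept[2], x$ci95_slope[2])
  )
}

#' @method glance wr_regain_fit
#' @export
glance.wr_regain_fit <- function(x, ...) {
  tibble(model = x$model, outcome = x$outcome, tau2 = x$tau2,
         n_studies = x$n_studies, n_points = x$n_points,
         weights_policy = x$weights_policy)
}

#' @method tidy wr_km
#' @export
tidy.wr_km <- function(x, ...) {
  tibble(time = x$times, n.risk = x$n_risk, n.event = x$n_event,
         estimate = x$surv)
}

#' @method glance wr_km
#' @export
glance.wr_km <- function(x, ...) {
  tibble(n_studies = x$n, n_events = sum(x$n_event),
         median_months = x$median_months,
         median_years = x$median_months / 12)
}

#' @method tidy wr_econ
#' @export
tidy.wr_econ <- function(x, ...) {
  x$thresholds
}

#' @method glance wr_econ
#' @export
glance.wr_econ <- function(x, ...) {
  tibble(qaly_gain = x$qaly_gain, cost_offset = x$cost_offset,
         perspective = x$perspective)
}

#' @method tidy wr_mc
#' @export
tidy.wr_mc <- function(x, ...) {
  x$summary
}

#' @method glance wr_mc
#' @export
glance.wr_mc <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, seed = x$seed,
         redraws = x$redraws)
}
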