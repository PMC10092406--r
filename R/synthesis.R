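# Synthesis of post-programme weight-regain trajectories: a random-intercept
# mixed model on all visits (model "mixed"), a random-effects meta-regression
# on final follow-ups (model "metareg"), and a Kaplan-Meier time-to-crossing
# analysis, plus the publication-bias check on follow-up length.

new_regain_fit <- function(model, outcome, intercept, slope, se_intercept,
                           se_slope, tau2, n_studies, n_points,
                           weights_policy, engine_fit = NULL) {
  z <- qnorm(0.975)
  structure(
    list(
      model = model, outcome = outcome,
      intercept = intercept, slope = slope,
      se_intercept = se_intercept, se_slope = se_slope,
      ci95_intercept = c(intercept - z * se_intercept,
                         intercept + z * se_intercept),
      ci95_slope = c(slope - z * se_slope, slope + z * se_slope),
      tau2 = tau2, n_studies = n_studies, n_points = n_points,
      weights_policy = weights_policy, engine_fit = engine_fit
    ),
    class = "wr_regain_fit"
  )
}

#' @export
print.wr_regain_fit <- function(x, ...) {
  cat(sprintf("<regain fit: %s model, outcome %s>\n", x$model, x$outcome))
  cat(sprintf("  studies: %d, observations: %d (weights: %s)\n",
              x$n_studies, x$n_points, x$weights_policy))
  cat(sprintf("  intercept (t = 0): %.4g (95%% CI %.4g to %.4g)\n",
              x$intercept, x$ci95_intercept[1], x$ci95_intercept[2]))
  cat(sprintf("  slope per month:   %.4g (95%% CI %.4g to %.4g)\n",
              x$slope, x$ci95_slope[1], x$ci95_slope[2]))
  cat(sprintf("  between-study variance tau2: %.4g\n", x$tau2))
  invisible(x)
}

# Choose observation weights: inverse-variance when at least `frac` of the
# points carry sampling variances (missing ones get the median weight),
# otherwise total analyzed n.
resolve_weights <- function(data, policy, frac = 0.8) {
  if (policy == "auto") {
    policy <- if (mean(!is.na(data$var)) >= frac) "invvar" else "n"
  }
  w <- switch(policy,
    invvar = {
      w <- 1 / data$var
      w[!is.finite(w)] <- NA
      w[is.na(w)] <- median(w, na.rm = TRUE)
      w
    },
    n = data$n_total,
    none = rep(1, nrow(data)),
    abort(paste0("unknown weights policy: ", policy))
  )
  if (any(!is.finite(w))) {
    abort("weights could not be resolved (missing variances and n)")
  }
  attr(w, "policy") <- policy
  w
}

# Random-intercept regression of y on x, one intercept deviation per study;
# REML through lme4. A single study carries no between-study information, so
# the model collapses to (weighted) OLS there.
fit_random_intercept <- function(data, x_col, y_col, model, outcome,
                                 weights_policy = "auto") {
  w <- resolve_weights(data, weights_policy)
  policy <- attr(w, "policy")
  df <- tibble(study_id = data$study_id, x = data[[x_col]],
               y = data[[y_col]], w = w)
  if (diff(range(df$x)) == 0) {
    abort("slope inestimable: no variation in the predictor")
  }
  if (n_distinct(df$study_id) < 2) {
    fit <- lm(y ~ x, data = df, weights = w)
    est <- coef(fit)
    se <- suppressWarnings(sqrt(diag(vcov(fit))))
    se[!is.finite(se)] <- 0
    return(new_regain_fit(model, outcome, est[["(Intercept)"]], est[["x"]],
                          se[["(Intercept)"]], se[["x"]], tau2 = 0,
                          n_studies = 1L, n_points = nrow(df),
                          weights_policy = policy, engine_fit = fit))
  }
  # Degenerate (noiseless) data exactly interpolate a_j + b x; REML residual
  # variance collapses to 0 and the profiled optimisation is ill-posed, so
  # solve that case directly: common slope from any study with x variation,
  # intercepts by difference, tau2 = Var(a_j).
  det_fit <- deterministic_ri_fit(df)
  if (!is.null(det_fit)) {
    return(new_regain_fit(model, outcome, det_fit$intercept, det_fit$slope,
                          0, 0, tau2 = det_fit$tau2,
                          n_studies = n_distinct(df$study_id),
                          n_points = nrow(df), weights_policy = policy))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ x + (1 | study_id), data = df, weights = w, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "study_id"][1]
  new_regain_fit(model, outcome, est[["(Intercept)"]], est[["x"]],
                 se[[1]], se[[2]], tau2 = tau2,
                 n_studies = n_distinct(df$study_id), n_points = nrow(df),
                 weights_policy = policy, engine_fit = fit)
}

# Exact solution when the data interpolate a_j + b x with zero residual:
# returns NULL unless the interpolation is exact to a relative tolerance.
deterministic_ri_fit <- function(df, tol = 1e-9) {
  slope <- NA_real_
  for (sid in unique(df$study_id)) {
    xs <- df$x[df$study_id == sid]
    ys <- df$y[df$study_id == sid]
    if (diff(range(xs)) > 0) {
      k <- which.max(xs)
      j <- which.min(xs)
      slope <- (ys[k] - ys[j]) / (xs[k] - xs[j])
      break
    }
  }
  if (is.na(slope)) return(NULL)
  a <- tapply(df$y - slope * df$x, df$study_id, mean)
  resid <- df$y - slope * df$x - a[as.character(df$study_id)]
  scale <- max(abs(df$y), 1)
  if (max(abs(resid)) > tol * scale) return(NULL)
  list(slope = slope, intercept = mean(a),
       tau2 = if (length(a) > 1) var(as.numeric(a)) else 0)
}

#' Mixed-model synthesis of post-programme regain (model "mixed")
#'
#' Regresses the intervention-minus-control difference on months since
#' programme end with a common slope, a common intercept, and a random
#' intercept per study (REML). The slope is the average regain relative to
#' control, in kg/month for weight (positive = the advantage erodes).
#' Observations are inverse-variance weighted when at least 80% of points
#' carry sampling variances, otherwise weighted by total analyzed n.
#'
#' @param series A `wr_diff_series` tibble (post-eligibility).
#' @param weights_policy `"auto"` (default), `"invvar"`, `"n"` or `"none"`.
#' @return A `wr_regain_fit`.
#' @examples
#' corpus <- generate_corpus(corpus_params(n_studies = 20, seed = 7))
#' series <- filter_regain_eligible(build_difference_series(corpus), corpus)
#' fit_mixed(series)
#' @export
fit_mixed <- function(series, weights_policy = "auto") {
  series <- as_tibble(series)
  if (nrow(series) == 0) abort("fit_mixed: empty series")
  if (all(series$t == 0)) {
    abort("fit_mixed: all observations at programme end; slope inestimable")
  }
  fit_random_intercept(series, x_col = "t", y_col = "diff",
                       model = "mixed", outcome = series$outcome[1],
                       weights_policy = weights_policy)
}

#' Random-effects meta-regression on final follow-ups (model "metareg")
#'
#' Reduces every study to its final post-programme difference, and fits a
#' random-effects meta-regression (REML between-study variance, weights
#' `1/(v_i + tau2)`) of that difference on the final follow-up time. The
#' intercept estimates the programme-end difference and the slope the monthly
#' regain. Studies missing sampling variances receive a variance proportional
#' to `1/n_total`, scaled to the observed variances when any are present.
#'
#' @param series A `wr_diff_series` tibble.
#' @return A `wr_regain_fit`.
#' @export
fit_metareg <- function(series) {
  series <- as_tibble(series)
  finals <- series |>
    group_by(.data$study_id) |>
    slice_max(.data$t, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(finals) < 3) {
    abort("fit_metareg: fewer than 3 studies; between-study variance unidentifiable")
  }
  if (diff(range(finals$t)) == 0) {
    abort("fit_metareg: all studies share the final follow-up time; slope inestimable")
  }
  vi <- finals$var
  if (any(is.na(vi))) {
    obs <- !is.na(vi)
    scale <- if (any(obs)) median(vi[obs] * finals$n_total[obs]) else 1
    vi[!obs] <- scale / finals$n_total[!obs]
  }
  fit <- suppressWarnings(
    metafor::rma(yi = finals$diff, vi = vi, mods = ~ finals$t,
                 method = "REML")
  )
  b <- as.numeric(fit$b)
  se <- as.numeric(fit$se)
  new_regain_fit("metareg", series$outcome[1], b[1], b[2], se[1], se[2],
                 tau2 = fit$tau2, n_studies = nrow(finals),
                 n_points = nrow(finals), weights_policy = "invvar+tau2",
                 engine_fit = fit)
}

#' Time for each study's difference to reach zero
#'
#' Walks each study's difference series from programme end and records the
#' first time the difference reaches zero, linearly interpolated between the
#' consecutive visits that bracket the crossing. Studies whose difference
#' stays below zero through the last visit are censored there.
#'
#' @param series A `wr_diff_series` tibble (regain-eligible).
#' @return A tibble with `study_id`, `time_months` and `event` (TRUE when the
#'   crossing was observed).
#' @examples
#' s <- tibble::tibble(study_id = "a", outcome = "weight_kg",
#'                     t = c(0, 10), diff = c(-2, 2),
#'                     var = NA_real_, n_total = 100)
#' crossing_times(s) # event at t = 5
#' @export
crossing_times <- function(series) {
  as_tibble(series) |>
    group_by(.data$study_id) |>
    arrange(.data$t, .by_group = TRUE) |>
    summarise(rec = list(crossing_one(.data$t, .data$diff)),
              .groups = "drop") |>
    tidyr::unnest("rec")
}

crossing_one <- function(t, d) {
  for (k in seq_along(t)[-1]) {
    if (d[k] >= 0 && d[k - 1] < 0) {
      tc <- t[k - 1] + (0 - d[k - 1]) * (t[k] - t[k - 1]) / (d[k] - d[k - 1])
      return(tibble(time_months = tc, event = TRUE))
    }
  }
  tibble(time_months = t[length(t)], event = FALSE)
}

#' Kaplan-Meier synthesis of crossing times
#'
#' Product-limit estimator over studies (each study is one unit at risk) of
#' the probability that the weight advantage persists beyond a given time.
#' The median is the first time the survival curve drops to 0.5 or below; it
#' is undefined (NA) when the curve never reaches 0.5.
#'
#' @param records A tibble from [crossing_times()].
#' @return An object of class `wr_km` with `times`, `surv`, `n_risk`,
#'   `n_event` and `median_months`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) abort("km_estimate: no records")
  sf <- survival::survfit(
    survival::Surv(records$time_months, records$event) ~ 1
  )
  med <- unname(summary(sf)$table["median"])
  structure(
    list(times = sf$time, surv = sf$surv, n_risk = sf$n.risk,
         n_event = sf$n.event, median_months = med,
         n = nrow(records), engine_fit = sf),
    class = "wr_km"
  )
}

#' @export
print.wr_km <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier crossing-time synthesis: %d studies, %d events>\n",
              x$n, sum(x$n_event)))
  if (is.na(x$median_months)) {
    cat("  median time to no difference: not reached\n")
  } else {
    cat(sprintf("  median time to no difference: %.1f months (%.1f years)\n",
                x$median_months, x$median_months / 12))
  }
  invisible(x)
}

#' Follow-up length versus programme-end effect (publication-bias check)
#'
#' Meta-regresses each study's programme-end difference on its maximum
#' follow-up (months since randomization), with REML between-study variance
#' and the Knapp-Hartung small-sample adjustment. An association would
#' suggest that studies with smaller programme-end effects were followed up
#' for less long.
#'
#' @param series A `wr_diff_series` tibble.
#' @param corpus The corpus the series came from (supplies follow-up length).
#' @return A one-row tibble with `slope` (kg per month of follow-up), `se`,
#'   `ci_lo`, `ci_hi`, `p_value` and `n_studies`.
#' @export
followup_bias_check <- function(series, corpus) {
  t0 <- as_tibble(series) |>
    filter(.data$t == 0) |>
    inner_join(study_meta(corpus), by = "study_id")
  if (nrow(t0) < 3) abort("followup_bias_check: fewer than 3 studies")
  if (diff(range(t0$max_followup_months)) == 0) {
    abort("followup_bias_check: follow-up constant across studies; slope inestimable")
  }
  vi <- t0$var
  if (any(is.na(vi))) {
    obs <- !is.na(vi)
    scale <- if (any(obs)) median(vi[obs] * t0$n_total[obs]) else 1
    vi[!obs] <- scale / t0$n_total[!obs]
  }
  fit <- suppressWarnings(
    metafor::rma(yi = t0$diff, vi = vi, mods = ~ t0$max_followup_months,
                 method = "REML", test = "knha")
  )
  tibble(slope = as.numeric(fit$b)[2], se = fit$se[2],
         ci_lo = fit$ci.lb[2], ci_hi = fit$ci.ub[2],
         p_value = fit$pval[2], n_studies = nrow(t0))
}
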