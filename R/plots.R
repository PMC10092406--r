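# ggplot2 visualisations for each result type.

#' Plot a difference series with a fitted regain trend
#'
#' Scatter of study-level differences against months since programme end,
#' dot size proportional to total analyzed participants, with the fitted
#' average trend overlaid when a fit is supplied.
#'
#' @param series A `wr_diff_series` tibble.
#' @param fit Optional `wr_regain_fit` whose trend line to draw.
#' @return A ggplot object.
#' @export
plot_difference_series <- function(series, fit = NULL) {
  p <- ggplot(as_tibble(series), aes(.data$t, .data$diff)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(aes(size = .data$n_total), alpha = 0.5) +
    scale_size_area(max_size = 6, name = "participants") +
    labs(x = "months since programme end",
         y = "intervention - control difference") +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "firebrick", linewidth = 0.8)
  }
  p
}

#' @rdname plot_difference_series
#' @param object,... Autoplot arguments (`object` is the fit; pass the
#'   series via `series`).
#' @method autoplot wr_regain_fit
#' @export
autoplot.wr_regain_fit <- function(object, series = NULL, ...) {
  if (is.null(series)) {
    abort("autoplot.wr_regain_fit: supply the difference series via `series`")
  }
  plot_difference_series(series, object)
}

#' @method autoplot wr_km
#' @export
autoplot.wr_km <- function(object, ...) {
  df <- tibble(time = c(0, object$times), surv = c(1, object$surv))
  ggplot(df, aes(.data$time / 12, .data$surv)) +
    geom_step() +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "years since programme end",
         y = "proportion of studies with a persisting difference") +
    theme_minimal()
}

#' @method autoplot wr_trajectory
#' @export
autoplot.wr_trajectory <- function(object, t_max_months = NULL, ...) {
  t_max <- t_max_months %||%
    (if (is.na(object$t_zero_months)) 240 else 1.2 * object$t_zero_months)
  tt <- seq(-object$programme_end_months, t_max, length.out = 400)
  ggplot(tibble(t = tt, d = trajectory_difference(object, tt)),
         aes(.data$t / 12, .data$d)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_line(colour = "steelblue", linewidth = 0.9) +
    labs(x = "years since programme end", y = "weight difference (kg)") +
    theme_minimal()
}

#' @method autoplot wr_mc
#' @export
autoplot.wr_mc <- function(object, output = NULL, bins = 60, ...) {
  output <- output %||% tail(names(object$draws), 1)
  ggplot(object$draws, aes(.data[[output]])) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    geom_vline(
      xintercept = object$summary$central[object$summary$output == output],
      colour = "firebrick") +
    labs(x = output, y = "draws") +
    theme_minimal()
}

#' @method autoplot wr_tornado
#' @export
autoplot.wr_tornado <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(group = factor(.data$group, levels = rev(.data$group)))
  base <- attr(object, "base")
  ggplot(df) +
    geom_segment(aes(x = .data$low, xend = .data$high, y = .data$group,
                     yend = .data$group), linewidth = 6,
                 colour = "steelblue") +
    geom_vline(xintercept = base, linetype = "dashed") +
    labs(x = attr(object, "output"), y = NULL) +
    theme_minimal()
}

#' Threshold price curve
#'
#' Plots the maximum cost-effective intervention price `C(lambda)` over a
#' range of willingness-to-pay thresholds.
#'
#' @param econ A `wr_econ`.
#' @param lambda_max Upper end of the threshold axis (default 50000).
#' @return A ggplot object.
#' @export
plot_threshold_curve <- function(econ, lambda_max = 50000) {
  ll <- seq(0, lambda_max, length.out = 200)
  ggplot(tibble(lambda = ll,
                price = max_cost(econ$qaly_gain, econ$cost_offset, ll)),
         aes(.data$lambda, .data$price)) +
    geom_line(colour = "steelblue", linewidth = 0.9) +
    labs(x = "willingness to pay (GBP/QALY)",
         y = "maximum cost-effective price (GBP/person)") +
    theme_minimal()
}
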