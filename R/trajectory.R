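# Scenario trajectories: the piecewise-linear weight-difference function that
# the lifetable consumes, and its conversion to BMI shifts.

#' Construct a weight-difference trajectory
#'
#' Defines the intervention-minus-control weight difference `D(t)` as a
#' function of months since programme end. Under `linear_regain`, lost weight
#' is regained linearly at `rate` kg/month until the difference reaches zero
#' at `t_zero = -d0/rate`, after which it stays at zero. Under `no_regain`
#' the programme-end difference persists indefinitely. During the programme
#' itself (negative clock values down to `-programme_end_months`) the
#' difference ramps linearly from 0 at baseline to `d0` at programme end.
#'
#' @param d0 Programme-end weight difference in kg; must be negative
#'   (intervention lighter than control).
#' @param rate Regain rate in kg/month, `>= 0`. Ignored under `no_regain`.
#' @param mode `"linear_regain"` (default) or `"no_regain"`.
#' @param programme_end_months Length of the programme in months, used only
#'   for the pre-programme ramp (default 6.5, a typical programme length).
#' @return An object of class `wr_trajectory` with fields `d0`, `rate`,
#'   `mode`, `t_zero_months` (NA when the difference never closes) and
#'   `programme_end_months`.
#' @examples
#' traj <- make_trajectory(-2.8, 0.027)
#' traj$t_zero_months / 12 # years until no difference
#' @export
make_trajectory <- function(d0, rate = 0, mode = c("linear_regain", "no_regain"),
                            programme_end_months = 6.5) {
  mode <- match.arg(mode)
  if (!is.finite(d0) || d0 >= 0) {
    abort("make_trajectory: d0 must be < 0 (not a weight-loss scenario)")
  }
  if (!is.finite(rate) || rate < 0) {
    abort("make_trajectory: rate must be >= 0")
  }
  t_zero <- if (mode == "linear_regain" && rate > 0) -d0 / rate else NA_real_
  structure(
    list(d0 = d0, rate = rate, mode = mode, t_zero_months = t_zero,
         programme_end_months = programme_end_months),
    class = "wr_trajectory"
  )
}

#' Evaluate a trajectory
#'
#' Returns `D(t)` in kg at `t` months since programme end (vectorised).
#' Negative `t` down to the programme start returns the during-programme
#' linear ramp; earlier times return 0.
#'
#' @param trajectory A `wr_trajectory`.
#' @param t_months Months since programme end.
#' @return Numeric vector of weight differences (kg, `<= 0`).
#' @export
trajectory_difference <- function(trajectory, t_months) {
  d0 <- trajectory$d0
  pe <- trajectory$programme_end_months
  post <- if (trajectory$mode == "no_regain") {
    rep(d0, length(t_months))
  } else {
    pmin(d0 + trajectory$rate * t_months, 0)
  }
  ramp <- d0 * pmax(0, 1 + t_months / pe)
  ifelse(t_months >= 0, post, ramp)
}

#' @export
print.wr_trajectory <- function(x, ...) {
  cat(sprintf("<weight-difference trajectory: %s>\n", x$mode))
  cat(sprintf("  programme-end difference d0: %.3g kg\n", x$d0))
  if (x$mode == "linear_regain") {
    cat(sprintf("  regain rate: %.3g kg/month (%.3g kg/year)\n",
                x$rate, 12 * x$rate))
    if (is.na(x$t_zero_months)) {
      cat("  difference never closes (rate 0)\n")
    } else {
      cat(sprintf("  difference reaches zero after %.1f months (%.2f years)\n",
                  x$t_zero_months, x$t_zero_months / 12))
    }
  }
  invisible(x)
}

#' Convert a weight difference into BMI shifts by age and sex
#'
#' Applies the static conversion `dBMI = D(t) / height^2` to every age-sex
#' stratum, using that stratum's mean height. The shift applies to the
#' intervention-eligible subpopulation (adults with BMI >= 30); downstream,
#' the population impact fraction moves only that part of the BMI
#' distribution.
#'
#' @param trajectory A `wr_trajectory`.
#' @param heights A tibble with columns `sex`, `age` and `height_m` (> 0).
#' @param t_months Months since programme end at which to evaluate `D`.
#' @return The `heights` tibble with added columns `t_months`, `d_kg` and
#'   `delta_bmi` (kg/m^2, `<= 0`).
#' @export
weight_to_bmi_shift <- function(trajectory, heights, t_months) {
  if (any(!is.finite(heights$height_m) | heights$height_m <= 0)) {
    abort("weight_to_bmi_shift: heights must be positive and finite")
  }
  tidyr::crossing(as_tibble(heights), t_months = t_months) |>
    mutate(d_kg = trajectory_difference(trajectory, .data$t_months),
           delta_bmi = .data$d_kg / .data$height_m^2)
}
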