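# Headline economics: maximum cost-effective intervention price across
# willingness-to-pay thresholds, cost-saving price, return on investment,
# and linear scaling by initial weight loss.

#' Maximum cost-effective intervention price
#'
#' The per-person price at which an intervention producing `q` QALYs and
#' `k` GBP of cost offsets per person offered remains cost-effective at a
#' willingness-to-pay threshold `lambda`: `C(lambda) = lambda * q + k`.
#' At `lambda = 0` this is the cost-saving price.
#'
#' @param q Discounted QALY gain per person offered the intervention.
#' @param k Discounted cost offset per person (GBP, positive = savings).
#' @param lambda Willingness-to-pay threshold(s), GBP/QALY (>= 0).
#' @return Price(s) in GBP per person; vectorised over `lambda`.
#' @examples
#' max_cost(0.025, 61, c(0, 20000, 30000))
#' @export
max_cost <- function(q, k, lambda) {
  if (any(lambda < 0)) abort("max_cost: lambda must be >= 0")
  lambda * q + k
}

#' Return on investment
#'
#' Net return per pound spent when QALYs are monetised at `v` GBP each:
#' `ROI = (v * q + k - cost) / cost`. The gross variant
#' (`(v * q + k) / cost`) is available behind `gross = TRUE`.
#'
#' @param cost Per-person intervention cost, GBP (> 0).
#' @param q QALY gain per person offered.
#' @param k Cost offset per person, GBP.
#' @param v Monetary value of one QALY (default 60000 GBP, the UK
#'   health-impact-assessment rate).
#' @param gross Report gross rather than net return (default FALSE).
#' @return The return-on-investment ratio.
#' @export
roi <- function(cost, q, k, v = 60000, gross = FALSE) {
  if (any(cost <= 0)) abort("roi: cost must be > 0")
  ret <- v * q + k
  if (gross) ret / cost else (ret - cost) / cost
}

#' Summarise lifetable scenarios into per-person economics
#'
#' Converts a [run_lifetable()] result into the per-person QALY gain `Q` and
#' cost offset `K` (denominator: the eligible population offered the
#' intervention), and tabulates the maximum cost-effective price over a set
#' of willingness-to-pay thresholds. Social-care cost offsets are included
#' only under the health-and-social-care perspective.
#'
#' @param lt A `wr_lifetable_result`.
#' @param lambdas Thresholds in GBP/QALY (default 0, 20000, 30000).
#' @return An object of class `wr_econ` with fields `qaly_gain`,
#'   `cost_offset`, `perspective`, and a `thresholds` tibble
#'   (`lambda`, `max_cost`).
#' @export
econ_summary <- function(lt, lambdas = c(0, 20000, 30000)) {
  q <- (lt$intervention$qalys - lt$reference$qalys) / lt$eligible_population
  k_health <- (lt$reference$health_costs - lt$intervention$health_costs) /
    lt$eligible_population
  k <- k_health
  if (lt$perspective == "health_social") {
    k <- k + (lt$reference$social_costs - lt$intervention$social_costs) /
      lt$eligible_population
  }
  new_econ(q, k, lt$perspective, lambdas)
}

new_econ <- function(q, k, perspective, lambdas) {
  structure(
    list(qaly_gain = q, cost_offset = k, perspective = perspective,
         thresholds = tibble(lambda = lambdas,
                             max_cost = max_cost(q, k, lambdas))),
    class = "wr_econ"
  )
}

#' @export
print.wr_econ <- function(x, ...) {
  cat(sprintf("<economic summary (%s perspective)>\n", x$perspective))
  cat(sprintf("  QALY gain per person offered:  %.5f\n", x$qaly_gain))
  cat(sprintf("  cost offset per person (GBP):  %.2f\n", x$cost_offset))
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  max price at %6.0f GBP/QALY:   %.2f\n",
                x$thresholds$lambda[i], x$thresholds$max_cost[i]))
  }
  invisible(x)
}

#' Rescale economics to a different initial weight loss
#'
#' Health benefits and cost offsets are assumed to scale linearly with the
#' programme-end weight difference, so an intervention achieving `w_new` kg
#' instead of `w_base` kg multiplies both `Q` and `K` (and hence every
#' threshold price) by `w_new / w_base`.
#'
#' @param econ A `wr_econ`.
#' @param w_new New programme-end weight loss, kg (magnitude).
#' @param w_base Baseline weight loss the result was computed for, kg
#'   (magnitude, > 0).
#' @return A rescaled `wr_econ`.
#' @examples
#' e <- weightregain:::new_econ(0.025, 36, "health", 20000)
#' scale_by_initial_loss(e, 7, 2.8)
#' @export
scale_by_initial_loss <- function(econ, w_new, w_base) {
  if (w_base <= 0) abort("scale_by_initial_loss: w_base must be > 0")
  f <- w_new / w_base
  new_econ(econ$qaly_gain * f, econ$cost_offset * f, econ$perspective,
           econ$thresholds$lambda)
}
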