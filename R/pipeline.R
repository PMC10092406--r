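# End-to-end economic pipeline: weight-loss scenario -> lifetable -> Q, K,
# C(lambda), packaged for the Monte Carlo and tornado layers.

#' Build the economic evaluation pipeline
#'
#' Returns a deterministic function mapping one draw of the uncertain inputs
#' to the per-person economics. The draw is a named list with elements
#' `weight_loss` (magnitude of the programme-end weight difference, kg),
#' `relative_risks` (multiplier on the log relative risks per BMI unit),
#' `unit_costs` (multiplier on all unit costs) and `utilities` (multiplier
#' on disease utility decrements). The regain rate is fixed across draws by
#' default — uncertainty enters through the start point of the trajectory —
#' but a draw element `regain_rate` (kg/month), supplied by adding an
#' [mc_group()] of that name, overrides it for analysts who prefer to
#' propagate rate uncertainty as well.
#'
#' @param epi A `wr_epi`.
#' @param rate Regain rate, kg/month.
#' @param mode `"linear_regain"` or `"no_regain"`.
#' @param perspective `"health"` or `"health_social"`.
#' @param lambda Willingness-to-pay threshold for the reported price
#'   (default 20000 GBP/QALY).
#' @param programme_end_months Programme length for the pre-programme ramp.
#' @return A function `draw -> c(qaly_gain, cost_offset, max_cost)`.
#' @export
build_econ_pipeline <- function(epi, rate, mode = "linear_regain",
                                perspective = "health", lambda = 20000,
                                programme_end_months = 6.5) {
  ctx <- prep_lifetable(epi)
  elig <- eligible_population(ctx)
  force(rate); force(mode); force(perspective); force(lambda)
  function(draw) {
    traj <- make_trajectory(-abs(draw$weight_loss),
                            draw$regain_rate %||% rate, mode,
                            programme_end_months = programme_end_months)
    res <- run_scenarios(
      ctx, traj, perspective = perspective,
      modifiers = list(theta_scale = draw$relative_risks %||% 1,
                       cost_scale = draw$unit_costs %||% 1,
                       decr_scale = draw$utilities %||% 1),
      trace = FALSE
    )
    q <- (res$intervention$qalys - res$reference$qalys) / elig
    k <- (res$reference$health_costs - res$intervention$health_costs) / elig
    if (perspective == "health_social") {
      k <- k + (res$reference$social_costs - res$intervention$social_costs) /
        elig
    }
    c(qaly_gain = q, cost_offset = k,
      max_cost = unname(max_cost(q, k, lambda)))
  }
}

#' Default uncertain input groups for the economic pipeline
#'
#' The conventional distribution choices: lognormal for the magnitude of the
#' programme-end weight loss (reflecting its between-study spread), the
#' relative risks and the unit costs; normal for utility decrements; the
#' regain rate carries no uncertainty and is not a group.
#'
#' @param weight_loss_mean Mean programme-end weight loss magnitude, kg.
#' @param weight_loss_ci 95% interval of the between-study weight-loss
#'   distribution, kg.
#' @return A list of [mc_group()]s suitable for [run_mc()] and [tornado()].
#' @export
econ_uncertainty_groups <- function(weight_loss_mean = 2.8,
                                    weight_loss_ci = c(1.2, 4.4)) {
  list(
    mc_group("weight_loss", "lognormal", mean = weight_loss_mean,
             lo = weight_loss_ci[1], hi = weight_loss_ci[2],
             lower = 1e-6),
    mc_group("relative_risks", "lognormal", mean = 1, lo = 0.7, hi = 1.43,
             lower = 1e-6),
    mc_group("unit_costs", "lognormal", mean = 1, lo = 0.7, hi = 1.43,
             lower = 1e-6),
    mc_group("utilities", "normal", mean = 1, lo = 0.9, hi = 1.1,
             lower = 0, upper = 2)
  )
}
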