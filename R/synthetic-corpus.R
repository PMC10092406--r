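# Synthetic trial-corpus generator. Emulates the statistical structure the
# synthesis models assume: programme-end differences centred near -2.8 kg
# with between-study heterogeneity, linear post-programme regain, irregular
# follow-up schedules with dropout of later visits, and a QoL co-outcome on
# a random subset of studies.

#' Parameters for the synthetic corpus generator
#'
#' @param n_studies Number of studies.
#' @param mean_d0 Mean programme-end intervention-minus-control difference,
#'   kg (default -2.8).
#' @param tau_intercept Between-study SD of the programme-end difference, kg
#'   (default 0.8).
#' @param true_slope Common post-programme regain rate, kg/month (default
#'   0.027).
#' @param noise_sd_kg Within-study observation noise SD on each difference,
#'   kg (default 0.5).
#' @param n_range Per-arm analyzed-n range (default 30-150).
#' @param programme_range Programme length range, months (default 3-12).
#' @param visit_offsets Post-programme visit grid, months after programme
#'   end (default 6, 12, 24, 36, 60); later visits drop out per study.
#' @param dropout Per-step probability that follow-up stops after each
#'   visit (default 0.3).
#' @param censor_months Administrative censoring horizon, months after
#'   programme end (default 72).
#' @param qol_prob Probability a study reports QoL (default 0.25).
#' @param qol_slope_smd_per_kg Built-in QoL association: SMD change per kg
#'   of weight difference (default -0.02, i.e. QoL falls as the weight
#'   advantage erodes).
#' @param qol_intercept_smd Programme-end QoL SMD (default 0.21).
#' @param qol_noise_sd_smd Observation noise on QoL SMDs (default 0.05).
#' @param rob_mix Overall risk-of-bias mix (probabilities for low, unclear,
#'   high; default 0.23/0.53/0.24).
#' @param followup_d0_slope Built-in association between follow-up length
#'   and programme-end difference, kg per month of follow-up (default 0: no
#'   publication bias).
#' @param seed RNG seed.
#' @return A list of class `wr_corpus_params`.
#' @export
corpus_params <- function(n_studies = 50, mean_d0 = -2.8,
                          tau_intercept = 0.8, true_slope = 0.027,
                          noise_sd_kg = 0.5, n_range = c(30, 150),
                          programme_range = c(3, 12),
                          visit_offsets = c(6, 12, 24, 36, 60),
                          dropout = 0.3, censor_months = 72,
                          qol_prob = 0.25, qol_slope_smd_per_kg = -0.02,
                          qol_intercept_smd = 0.21, qol_noise_sd_smd = 0.05,
                          rob_mix = c(low = 0.23, unclear = 0.53,
                                      high = 0.24),
                          followup_d0_slope = 0, seed = 1) {
  stopifnot(n_studies >= 1, tau_intercept >= 0, noise_sd_kg >= 0,
            qol_noise_sd_smd >= 0)
  structure(as.list(environment()), class = "wr_corpus_params")
}

#' Generate a synthetic study corpus
#'
#' Draws per-study programme-end differences `a_j ~ N(mean_d0, tau^2)` and
#' realises the difference trajectory `D_j(t) = a_j + slope * t + noise` at
#' an irregular post-programme visit schedule, then emits two internally
#' consistent arm series (control and intervention) in the documented
#' extraction-schema so that differencing recovers `D_j` exactly. SDs and
#' analyzed n are emitted so sampling variances are recoverable. A warning
#' is raised when `mean_d0 >= 0` (the eligibility filter would drop most
#' studies).
#'
#' @param params A [corpus_params()] list.
#' @return A `wr_corpus` tibble in the [load_corpus()] schema.
#' @examples
#' corpus <- generate_corpus(corpus_params(n_studies = 5, seed = 42))
#' @export
generate_corpus <- function(params = corpus_params()) {
  p <- params
  if (p$mean_d0 >= 0) {
    warn("generate_corpus: mean_d0 >= 0; the regain eligibility filter will drop most studies")
  }
  set.seed(p$seed)
  rows <- vector("list", p$n_studies)
  for (j in seq_len(p$n_studies)) {
    sid <- sprintf("S%03d", j)
    pe <- round(runif(1, p$programme_range[1], p$programme_range[2]))
    # follow-up schedule: programme end plus later visits with dropout
    offs <- 0
    for (v in p$visit_offsets) {
      if (v > p$censor_months) break
      offs <- c(offs, v)
      if (runif(1) < p$dropout) break
    }
    a_j <- rnorm(1, p$mean_d0, p$tau_intercept) +
      p$followup_d0_slope * (pe + max(offs))
    d <- a_j + p$true_slope * offs + rnorm(length(offs), 0, p$noise_sd_kg)
    n_c <- round(runif(1, p$n_range[1], p$n_range[2]))
    n_i <- round(runif(1, p$n_range[1], p$n_range[2]))
    sd_c <- runif(1, 3, 4.5)
    sd_i <- runif(1, 3, 4.5)
    # control arm loses a little and drifts back; intervention = control + D
    ctl_change <- -2.1 + 0.015 * offs + rnorm(1, 0, 0.6)
    t_abs <- pe + offs
    rob <- sample(names(p$rob_mix), 1, prob = p$rob_mix)
    has_qol <- runif(1) < p$qol_prob
    if (has_qol) {
      scale <- sample(c("SF-36", "EQ-5D VAS", "IWQOL-Lite"), 1)
      dir <- if (scale == "IWQOL-Lite") "lower_better" else "higher_better"
      qol_sd <- runif(1, 15, 30)
      # QoL tracks the realized weight difference around its typical
      # programme-end value, so random study intercepts stay independent of
      # the per-study weight level and the built-in slope is recoverable
      smd <- p$qol_intercept_smd +
        p$qol_slope_smd_per_kg * (d - p$mean_d0) +
        rnorm(length(offs), 0, p$qol_noise_sd_smd)
      qol_ctl <- rnorm(1, 1, 2) + 0.05 * offs
      qol_int <- qol_ctl + smd * qol_sd
      if (dir == "lower_better") {
        qol_ctl <- -qol_ctl
        qol_int <- -qol_int
      }
    }
    mk_arm <- function(arm_id, role, mean_chg, sdv, n, qmean, qsd) {
      tibble(
        study_id = sid, arm_id = arm_id, arm_role = role,
        rob_overall = rob, programme_end_month = pe, t_months = t_abs,
        mean_change_kg = mean_chg, sd_kg = sdv, n_analyzed = n,
        qol_scale = if (has_qol) scale else NA_character_,
        qol_direction = if (has_qol) dir else NA_character_,
        qol_mean_change = qmean, qol_sd = qsd
      )
    }
    rows[[j]] <- bind_rows(
      mk_arm("ctl", "control", ctl_change, sd_c, n_c,
             if (has_qol) qol_ctl else NA_real_,
             if (has_qol) qol_sd else NA_real_),
      mk_arm("int", "intervention", ctl_change + d, sd_i, n_i,
             if (has_qol) qol_int else NA_real_,
             if (has_qol) qol_sd else NA_real_)
    )
  }
  validate_corpus(bind_rows(rows))
}
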