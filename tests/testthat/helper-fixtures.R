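# Small programmatic fixtures shared across tests.

# one-study corpus with explicit arm means at given visit times
one_study_corpus <- function(ctl_means, int_means, t_months,
                             pe = t_months[1], sd = 4, n = 100,
                             study_id = "S1", rob = "low") {
  arm_rows <- function(arm_id, role, means) {
    tibble::tibble(
      study_id = study_id, arm_id = arm_id, arm_role = role,
      rob_overall = rob, programme_end_month = pe, t_months = t_months,
      mean_change_kg = means, sd_kg = sd, n_analyzed = n,
      qol_scale = NA_character_, qol_direction = NA_character_,
      qol_mean_change = NA_real_, qol_sd = NA_real_
    )
  }
  dplyr::bind_rows(arm_rows("ctl", "control", ctl_means),
                   arm_rows("int", "intervention", int_means))
}

# a difference series tibble built directly
make_series <- function(study_id, t, diff, var = NA_real_, n_total = 100,
                        outcome = "weight_kg") {
  s <- tibble::tibble(study_id = study_id, outcome = outcome, t = t,
                      diff = diff, var = var, n_total = n_total)
  class(s) <- c("wr_diff_series", class(s))
  s
}

# noiseless multi-study series with known intercepts and common slope
noiseless_series <- function(intercepts, slope, t = c(0, 6, 12, 24)) {
  dplyr::bind_rows(lapply(seq_along(intercepts), function(j) {
    make_series(sprintf("S%02d", j), t, intercepts[j] + slope * t,
                var = 0.04, n_total = 100)
  }))
}

# tiny epi grid (few ages) for fast engine tests
tiny_epi <- function(ages = 60:70, case_fatality = 0.05, incidence = 0.01,
                     rr = 1.1, mortality = 0.01, social_care_cost = 0,
                     utility = 0.9, decrement = 0.1, annual_cost = 1000,
                     other_cause_cost = 500) {
  strata <- tidyr::crossing(sex = c("female", "male"), age = ages) |>
    dplyr::mutate(population = 1000, mortality = mortality,
                  bmi_median = 27, bmi_sigma = 0.17, height_m = 1.7,
                  utility = utility)
  diseases <- tibble::tibble(disease = "d1", rr_per_bmi_unit = rr,
                             utility_decrement = decrement,
                             annual_cost = annual_cost)
  rates <- tidyr::crossing(disease = "d1", sex = c("female", "male"),
                           age = ages) |>
    dplyr::mutate(incidence = incidence, case_fatality = case_fatality)
  epi_inputs(strata, diseases, rates, other_cause_cost = other_cause_cost,
             social_care_cost = social_care_cost, social_care_age = 65)
}
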