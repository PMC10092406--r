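# Synthetic (toy) epidemiological inputs for the lifetable: a plausible but
# entirely simulated adult population with Gompertz all-cause mortality,
# lognormal BMI distributions, and four BMI-related diseases. These inputs
# are NOT calibrated to any real national statistics; they exist so the
# engine can be exercised and tested without external data.

#' Generate toy epidemiological inputs
#'
#' Builds a `wr_epi` for adults aged 18-100 of both sexes with:
#' Gompertz all-cause mortality; lognormal BMI distributions whose medians
#' rise through mid-life, putting roughly 25-30% of adults above BMI 30;
#' age-declining baseline utilities; and four diseases (ischaemic heart
#' disease, stroke, type 2 diabetes, colorectal cancer) with age-increasing
#' incidence, moderate case fatality, relative risks per BMI unit in
#' [1.02, 1.15], utility decrements and annual treatment costs. An optional
#' lognormal jitter perturbs disease incidence curves per seed.
#'
#' @param seed RNG seed for the incidence jitter.
#' @param jitter_sd Log-scale SD of the incidence jitter (default 0.05; 0
#'   gives fully deterministic inputs).
#' @param population_18 Population count at age 18 per sex (default 4e5).
#' @param discount_rate,baseline_year,b_ref Passed to [epi_inputs()].
#' @return A validated `wr_epi`.
#' @examples
#' epi <- generate_epi(seed = 3)
#' @export
generate_epi <- function(seed = 1, jitter_sd = 0.05, population_18 = 4e5,
                         discount_rate = 0.035, baseline_year = 2017,
                         b_ref = 21) {
  set.seed(seed)
  ages <- 18:100
  sexes <- c("female", "male")
  strata <- tidyr::crossing(sex = sexes, age = ages) |>
    mutate(
      population = population_18 * exp(-0.004 * (.data$age - 18)) *
        pmin(1, exp(-0.06 * pmax(0, .data$age - 75))),
      mortality = pmin(
        0.7, ifelse(.data$sex == "male", 1.4, 1) * 4e-5 *
          exp(0.092 * (.data$age - 18))),
      bmi_median = 24.5 + 3.5 * exp(-((.data$age - 58) / 28)^2),
      bmi_sigma = 0.17,
      height_m = ifelse(.data$sex == "male", 1.76, 1.63) -
        0.0008 * pmax(0, .data$age - 40),
      utility = pmax(0.55, 0.95 - 0.0030 * (.data$age - 18))
    )
  diseases <- tibble(
    disease = c("ihd", "stroke", "t2dm", "colorectal_cancer"),
    rr_per_bmi_unit = c(1.08, 1.06, 1.12, 1.03),
    utility_decrement = c(0.10, 0.15, 0.07, 0.12),
    annual_cost = c(1500, 3200, 1100, 5200)
  )
  base_inc <- c(ihd = 3.5e-5, stroke = 1.6e-5, t2dm = 1.6e-4,
                colorectal_cancer = 6e-6)
  inc_slope <- c(ihd = 0.075, stroke = 0.085, t2dm = 0.045,
                 colorectal_cancer = 0.080)
  base_cf <- c(ihd = 0.030, stroke = 0.050, t2dm = 0.008,
               colorectal_cancer = 0.090)
  jit <- exp(rnorm(length(base_inc), 0, jitter_sd))
  names(jit) <- names(base_inc)
  disease_rates <- tidyr::crossing(disease = diseases$disease,
                                   sex = sexes, age = ages) |>
    mutate(
      incidence = pmin(
        0.08, jit[.data$disease] * base_inc[.data$disease] *
          ifelse(.data$sex == "male", 1.3, 1) *
          exp(inc_slope[.data$disease] * (.data$age - 18))),
      case_fatality = pmin(
        0.5, base_cf[.data$disease] * exp(0.02 * (.data$age - 18)))
    )
  epi_inputs(
    strata = strata, diseases = diseases, disease_rates = disease_rates,
    other_cause_cost = 1100, social_care_cost = 9000, social_care_age = 85,
    discount_rate = discount_rate, baseline_year = baseline_year,
    b_ref = b_ref
  )
}
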