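# Proportional multi-state lifetable engine. Two populations are aged from a
# baseline year to age 100: a reference population with observed disease
# rates, and an intervention population whose disease incidence is reduced
# via population impact fractions derived from the BMI shift that the weight
# trajectory implies. Disease processes are annual-cycle three-state models
# (susceptible / case / dead-of-disease) run per disease and per cohort;
# their mortality differences perturb all-cause mortality in the
# intervention scenario.

#' Assemble epidemiological inputs for the lifetable
#'
#' Bundles and validates the stratum-level epidemiology, the disease
#' catalogue, and cost/discount settings that [run_lifetable()] consumes.
#'
#' @param strata Tibble with one row per sex and single year of age
#'   (18-100): `sex`, `age`, `population`, `mortality` (all-cause rate/yr),
#'   `bmi_median` and `bmi_sigma` (lognormal BMI distribution parameters:
#'   median in kg/m^2, dispersion on the log scale), `height_m`, `utility`
#'   (baseline utility in `[0, 1]`).
#' @param diseases Tibble with `disease`, `rr_per_bmi_unit` (relative risk
#'   per kg/m^2 above the reference BMI), `utility_decrement`, `annual_cost`
#'   (GBP per prevalent case-year).
#' @param disease_rates Tibble with `disease`, `sex`, `age`, `incidence`
#'   (/yr) and `case_fatality` (/yr).
#' @param other_cause_cost Health-sector cost per person-year not
#'   attributable to the modelled diseases (GBP); accrues in added life
#'   years.
#' @param social_care_cost Social-care cost per person-year above
#'   `social_care_age` (GBP), counted in the health-and-social-care
#'   perspective only.
#' @param social_care_age Age threshold for social-care costs (default 85).
#' @param discount_rate Annual discount rate (default 0.035, the NICE rate).
#' @param baseline_year First simulated year (default 2017).
#' @param b_ref BMI at which relative risks equal 1 (default 21 kg/m^2).
#' @param eligible_bmi Minimum BMI for intervention eligibility (default 30).
#' @param bmi_grid Evaluation grid for BMI integrals (default
#'   `seq(10, 60, by = 0.1)`).
#' @return A validated object of class `wr_epi`.
#' @export
epi_inputs <- function(strata, diseases, disease_rates,
                       other_cause_cost = 0, social_care_cost = 0,
                       social_care_age = 85, discount_rate = 0.035,
                       baseline_year = 2017, b_ref = 21, eligible_bmi = 30,
                       bmi_grid = seq(10, 60, by = 0.1)) {
  epi <- structure(
    list(strata = as_tibble(strata), diseases = as_tibble(diseases),
         disease_rates = as_tibble(disease_rates),
         other_cause_cost = other_cause_cost,
         social_care_cost = social_care_cost,
         social_care_age = social_care_age,
         discount_rate = discount_rate, baseline_year = baseline_year,
         b_ref = b_ref, eligible_bmi = eligible_bmi, bmi_grid = bmi_grid),
    class = "wr_epi"
  )
  validate_epi(epi)
}

#' Validate epidemiological inputs
#'
#' @param epi A `wr_epi` object.
#' @return `epi`, or an error describing the violated invariant.
#' @export
validate_epi <- function(epi) {
  s <- epi$strata
  need <- c("sex", "age", "population", "mortality", "bmi_median",
            "bmi_sigma", "height_m", "utility")
  if (!all(need %in% names(s))) {
    abort(paste0("epi_inputs: strata missing column(s): ",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  }
  if (any(s$population < 0) || any(s$mortality < 0)) {
    abort("epi_inputs: population and mortality must be >= 0")
  }
  if (any(s$utility < 0 | s$utility > 1)) {
    abort("epi_inputs: utilities must lie in [0, 1]")
  }
  if (any(s$height_m <= 0)) abort("epi_inputs: heights must be positive")
  d <- epi$diseases
  if (any(d$rr_per_bmi_unit < 1)) {
    abort("epi_inputs: rr_per_bmi_unit < 1; diseases are modelled as risk-increasing")
  }
  if (any(d$utility_decrement < 0 | d$utility_decrement > 1)) {
    abort("epi_inputs: utility decrements must lie in [0, 1]")
  }
  r <- epi$disease_rates
  if (any(r$incidence < 0) || any(r$case_fatality < 0)) {
    abort("epi_inputs: incidence and case fatality must be >= 0")
  }
  full <- tidyr::crossing(sex = unique(s$sex), age = unique(s$age),
                          disease = d$disease)
  if (nrow(anti_join(full, r, by = c("sex", "age", "disease"))) > 0) {
    abort("epi_inputs: disease_rates must cover every sex x age x disease")
  }
  epi
}

#' Population impact fraction over a BMI grid
#'
#' Computes the proportional change in disease incidence when the eligible
#' part of a BMI distribution (mass at or above `eligible_min`) is shifted
#' by `delta_bmi`:
#' `PIF = (sum p(b) RR(b) - sum p'(b) RR(b)) / (sum p(b) RR(b))`,
#' where the shifted distribution `p'` evaluates the relative risk at
#' `b + delta_bmi` for eligible mass and at `b` otherwise.
#'
#' @param bmi Grid of BMI values.
#' @param mass Probability mass at each grid point; must sum to 1 within
#'   1e-6.
#' @param delta_bmi BMI shift applied to the eligible mass (kg/m^2,
#'   typically negative).
#' @param rr Either a relative-risk function of BMI, or a scalar relative
#'   risk per BMI unit, in which case `RR(b) = rr^max(0, b - b_ref)`.
#' @param b_ref Reference BMI where RR = 1 (used for scalar `rr`).
#' @param eligible_min Minimum BMI of the shifted (eligible) mass.
#' @return The population impact fraction (dimensionless).
#' @examples
#' # two-mass toy: half the population at RR 2, half at RR 1; moving all
#' # high-risk mass to the low-risk point gives PIF = 1/3
#' pif(c(25, 35), c(0.5, 0.5), delta_bmi = -10,
#'     rr = function(b) ifelse(b >= 30, 2, 1))
#' @export
pif <- function(bmi, mass, delta_bmi, rr, b_ref = 21, eligible_min = 30) {
  if (abs(sum(mass) - 1) > 1e-6) {
    abort("pif: BMI distribution mass must integrate to 1 (tolerance 1e-6)")
  }
  rr_fn <- if (is.function(rr)) rr else function(b) rr^pmax(0, b - b_ref)
  eligible <- bmi >= eligible_min
  base <- sum(mass * rr_fn(bmi))
  shifted <- sum(mass[!eligible] * rr_fn(bmi[!eligible])) +
    sum(mass[eligible] * rr_fn(bmi[eligible] + delta_bmi))
  (base - shifted) / base
}

#' Annual three-state disease process
#'
#' Runs the susceptible/case difference equations for one disease in one
#' stratum: `C(y+1) = C(y) + i'(y) S(y) - f C(y)` with
#' `i'(y) = i (1 - PIF(y))`, and disease deaths `f C(y)`. States are
#' fractions of the entry cohort; the reference scenario corresponds to
#' `pif = 0`.
#'
#' @param incidence Incidence rate(s) /yr (scalar or length-`years` vector).
#' @param case_fatality Case-fatality rate(s) /yr.
#' @param years Number of annual cycles.
#' @param pif Population impact fraction schedule (scalar or vector).
#' @param s0,c0 Initial susceptible and case fractions (default 1 and 0).
#' @return A tibble with `year` (0-based), `susceptible`, `cases` (start-of-
#'   year states) and `deaths` (disease deaths during the year).
#' @export
run_disease <- function(incidence, case_fatality, years, pif = 0,
                        s0 = 1, c0 = 0) {
  i <- rep_len(incidence, years)
  f <- rep_len(case_fatality, years)
  p <- rep_len(pif, years)
  S <- C <- D <- numeric(years)
  s <- s0; cc <- c0
  for (y in seq_len(years)) {
    S[y] <- s; C[y] <- cc
    i_eff <- i[y] * (1 - p[y])
    d <- f[y] * cc
    new_s <- s - i_eff * s
    new_c <- cc + i_eff * s - d
    if (new_s < 0 || new_c < 0) {
      abort(paste0("run_disease: negative state at year ", y - 1,
                   "; annual rates too large for an annual Euler step ",
                   "(incidence ", signif(i[y], 3), ", case fatality ",
                   signif(f[y], 3), ")"))
    }
    D[y] <- d
    s <- new_s; cc <- new_c
  }
  tibble(year = seq_len(years) - 1, susceptible = S, cases = C, deaths = D)
}

#' Present value of an annual stream
#'
#' `PV = sum_y x_y / (1 + rate)^(y - t0)`.
#'
#' @param stream Annual amounts.
#' @param rate Discount rate per annum (>= 0).
#' @param years Year offsets of the stream entries (default `0, 1, ...`).
#' @param t0 Year to discount back to (default 0).
#' @return The present value.
#' @examples
#' discount(rep(1, 20), 0.035, years = 1:20) # 20-year annuity, 14.2124
#' @export
discount <- function(stream, rate, years = seq_along(stream) - 1, t0 = 0) {
  if (rate < 0) abort("discount: rate must be >= 0")
  sum(stream / (1 + rate)^(years - t0))
}

# ---- engine ---------------------------------------------------------------

# Precompute everything about the epi inputs that does not depend on the
# scenario or on Monte Carlo modifiers: rate lookup matrices indexed by
# (age, sex), per-stratum BMI grid masses split at the eligibility
# threshold, and cohort bookkeeping.
prep_lifetable <- function(epi) {
  s <- arrange(epi$strata, .data$sex, .data$age)
  sexes <- unique(s$sex)
  ages <- sort(unique(s$age))
  A <- length(ages)
  ns <- length(sexes)
  if (nrow(s) != A * ns) {
    abort("run_lifetable: strata must form a complete sex x age grid")
  }
  ai <- match(s$age, ages)
  si <- match(s$sex, sexes)
  mk <- function(v) {
    m <- matrix(NA_real_, A, ns)
    m[cbind(ai, si)] <- v
    m
  }
  dis <- epi$diseases
  D <- nrow(dis)
  r <- epi$disease_rates
  Ix <- Fx <- array(NA_real_, c(A, ns, D))
  for (k in seq_len(D)) {
    rk <- r[r$disease == dis$disease[k], ]
    Ix[cbind(match(rk$age, ages), match(rk$sex, sexes), k)] <- rk$incidence
    Fx[cbind(match(rk$age, ages), match(rk$sex, sexes), k)] <- rk$case_fatality
  }
  grid <- epi$bmi_grid
  # per-stratum BMI probability masses on the grid, renormalized, split at
  # the eligibility threshold
  P_low <- P_high <- matrix(0, A * ns, length(grid))
  for (j in seq_len(nrow(s))) {
    dens <- dlnorm(grid, meanlog = log(s$bmi_median[j]),
                   sdlog = s$bmi_sigma[j])
    mass <- dens / sum(dens)
    row <- (si[j] - 1) * A + ai[j]
    hi <- grid >= epi$eligible_bmi
    P_low[row, !hi] <- mass[!hi]
    P_high[row, hi] <- mass[hi]
  }
  elig_frac <- rowSums(P_high)
  cohort_row <- (si - 1) * A + ai
  list(
    ages = ages, sexes = sexes, A = A, ns = ns, D = D,
    pop = mk(s$population), Mx = mk(s$mortality), Ux = mk(s$utility),
    Hx = mk(s$height_m), Ix = Ix, Fx = Fx,
    theta = log(dis$rr_per_bmi_unit),
    decr = dis$utility_decrement, dcost = dis$annual_cost,
    grid = grid, P_low = P_low, P_high = P_high,
    elig_frac_row = elig_frac, cohort_row = cohort_row,
    strata = s, epi = epi
  )
}

# Eligible population: stratum population times the mass of its BMI
# distribution at or above the eligibility threshold.
eligible_population <- function(ctx) {
  sum(ctx$strata$population * ctx$elig_frac_row[ctx$cohort_row])
}

# Grid integrals of mass x RR below/above the eligibility threshold for each
# stratum and disease, for (possibly modifier-scaled) log relative risks.
pif_weights <- function(ctx, theta) {
  b <- pmax(0, ctx$grid - ctx$epi$b_ref)
  RR <- exp(outer(b, theta))                       # grid x disease
  list(wlow = ctx$P_low %*% RR, whigh = ctx$P_high %*% RR)
}

# Run reference and intervention populations through the lifetable in
# lockstep. `modifiers` rescale log relative risks, unit costs and utility
# decrements (used by the Monte Carlo layer); identity by default.
run_scenarios <- function(ctx, trajectory, perspective = "health",
                          modifiers = list(), trace = FALSE) {
  mod <- utils::modifyList(
    list(theta_scale = 1, cost_scale = 1, decr_scale = 1), modifiers)
  theta <- ctx$theta * mod$theta_scale
  decr <- ctx$decr * mod$decr_scale
  dcost <- ctx$dcost * mod$cost_scale
  occ <- ctx$epi$other_cause_cost * mod$cost_scale
  scc <- ctx$epi$social_care_cost * mod$cost_scale
  w <- pif_weights(ctx, theta)
  ages <- ctx$ages; A <- ctx$A; D <- ctx$D
  n_cohort <- A * ctx$ns
  a0 <- rep(ages, ctx$ns)
  sex_i <- rep(seq_len(ctx$ns), each = A)
  pop <- as.vector(ctx$pop)
  max_age <- max(ages)
  n_years <- max_age - min(ages) + 1
  rate <- ctx$epi$discount_rate
  pe <- trajectory$programme_end_months

  # guard for the exponential-shift shortcut used below: shifting eligible
  # mass must keep it above b_ref, otherwise fall back to the full grid PIF
  min_h2 <- min(ctx$Hx)^2
  max_shift <- abs(trajectory$d0) / min_h2
  use_shortcut <- (ctx$epi$eligible_bmi - max_shift) >= ctx$epi$b_ref

  run_one <- function(arm, dm_ref = NULL) {
    l <- rep(1, n_cohort); cumdead <- rep(0, n_cohort)
    S <- matrix(1, n_cohort, D); C <- matrix(0, n_cohort, D)
    qaly <- py <- hcost <- scost <- 0
    dm_store <- matrix(0, n_cohort, n_years)
    floor_hit <- FALSE
    traces <- if (trace) vector("list", n_years) else NULL
    for (y in seq_len(n_years) - 1) {
      age <- a0 + y
      act <- which(age <= max_age & pop > 0)
      if (length(act) == 0) break
      idx <- cbind(age[act] - min(ages) + 1, sex_i[act])
      disc <- 1 / (1 + rate)^y
      # mid-cycle months since programme end (baseline = programme start)
      t_m <- 12 * y + 6 - pe
      if (arm == "intervention") {
        d_kg <- trajectory_difference(trajectory, t_m)
        delta <- d_kg / ctx$Hx[idx]^2
        rowcur <- (idx[, 2] - 1) * A + idx[, 1]   # stratum at current age
        if (use_shortcut) {
          wl <- w$wlow[rowcur, , drop = FALSE]
          wh <- w$whigh[rowcur, , drop = FALSE]
          pifm <- wh * (1 - exp(outer(delta, theta))) / (wl + wh)
        } else {
          pifm <- matrix(0, length(act), D)
          rowm <- rowcur
          for (k in seq_len(D)) {
            rr_fn <- function(b) exp(theta[k] * pmax(0, b - ctx$epi$b_ref))
            for (jj in seq_along(act)) {
              mass <- ctx$P_low[rowm[jj], ] + ctx$P_high[rowm[jj], ]
              pifm[jj, k] <- pif(ctx$grid, mass, delta[jj], rr_fn,
                                 b_ref = ctx$epi$b_ref,
                                 eligible_min = ctx$epi$eligible_bmi)
            }
          }
        }
      } else {
        pifm <- matrix(0, length(act), D)
      }
      Sa <- S[act, , drop = FALSE]
      Ca <- C[act, , drop = FALSE]
      look <- cbind(idx[, 1][as.vector(row(Sa))],
                    idx[, 2][as.vector(row(Sa))], as.vector(col(Sa)))
      iy <- matrix(ctx$Ix[look], nrow(Sa), D)
      fy <- matrix(ctx$Fx[look], nrow(Sa), D)
      deaths_d <- fy * Ca
      dm <- rowSums(deaths_d)
      dm_store[act, y + 1] <- dm
      m_ref <- ctx$Mx[idx]
      q <- if (arm == "intervention") {
        m_ref - (dm_ref[act, y + 1] - dm)
      } else {
        m_ref
      }
      if (any(q < 0) || any(q > 1)) {
        abort("run_lifetable: all-cause mortality left [0, 1]; annual rates too large")
      }
      new_l <- l[act] * (1 - q)
      Lp <- (l[act] + new_l) / 2
      tot <- Sa + Ca
      prev <- Ca / ifelse(tot > 0, tot, 1)
      u <- ctx$Ux[idx] - as.vector(prev %*% decr)
      if (any(u < 0)) {
        floor_hit <- TRUE
        u <- pmax(u, 0)
      }
      popL <- pop[act] * Lp
      py <- py + disc * sum(popL)
      qaly <- qaly + disc * sum(popL * u)
      hcost <- hcost + disc * sum(popL * (as.vector(prev %*% dcost) + occ))
      old_age <- age[act] >= ctx$epi$social_care_age
      scost <- scost + disc * scc * sum(popL[old_age])
      if (trace) {
        traces[[y + 1]] <- tibble(
          year = y, sex = ctx$sexes[sex_i[act]], entry_age = a0[act],
          age = age[act], alive = l[act], cum_dead = cumdead[act],
          disease_mortality = dm,
          prevalence = as.vector(prev %*% rep(1, D)))
      }
      # state updates
      i_eff <- iy * (1 - pifm)
      newS <- Sa - i_eff * Sa
      newC <- Ca + i_eff * Sa - deaths_d
      if (any(newS < 0) || any(newC < 0)) {
        abort("run_lifetable: negative disease state; annual rates too large for Euler step")
      }
      S[act, ] <- newS
      C[act, ] <- newC
      cumdead[act] <- cumdead[act] + l[act] * q
      l[act] <- new_l
    }
    structure(
      list(person_years = py, qalys = qaly, health_costs = hcost,
           social_costs = scost,
           traces = if (trace) bind_rows(traces) else NULL,
           dm = dm_store, floor_hit = floor_hit),
      class = "wr_scenario"
    )
  }
  ref <- run_one("reference")
  int <- run_one("intervention", dm_ref = ref$dm)
  if (ref$floor_hit || int$floor_hit) {
    warn("run_lifetable: utility floored at 0 in some stratum-years (comorbidity overload)")
  }
  ref$dm <- NULL; int$dm <- NULL
  ref$floor_hit <- NULL; int$floor_hit <- NULL
  list(reference = ref, intervention = int,
       eligible_population = eligible_population(ctx),
       perspective = perspective)
}

#' Run the proportional multi-state lifetable
#'
#' Simulates every 2017 age-sex cohort (single year of age, both sexes) from
#' the baseline year until age 100 under two scenarios: a reference
#' population with observed disease rates, and an intervention population in
#' which the BMI shift implied by `trajectory` reduces disease incidence via
#' population impact fractions. All-cause mortality in the intervention
#' scenario equals reference mortality minus the sum over diseases of the
#' scenarios' disease-mortality difference. Person-years are accumulated by
#' trapezoid over survivors; utilities are the stratum baseline minus
#' prevalence-weighted disease decrements (floored at 0 with a warning);
#' QALYs and costs are discounted to the baseline year.
#'
#' @param epi A `wr_epi` from [epi_inputs()] or [generate_epi()].
#' @param trajectory A `wr_trajectory` from [make_trajectory()].
#' @param perspective `"health"` or `"health_social"`; social-care costs
#'   above the age threshold are counted only under the latter.
#' @param trace Keep per-year, per-cohort traces (default TRUE; the Monte
#'   Carlo layer turns them off).
#' @return A list of class `wr_lifetable_result` with elements `reference`
#'   and `intervention` (each with discounted `person_years`, `qalys`,
#'   `health_costs`, `social_costs` and optional `traces`),
#'   `eligible_population` and `perspective`.
#' @export
run_lifetable <- function(epi, trajectory,
                          perspective = c("health", "health_social"),
                          trace = TRUE) {
  perspective <- match.arg(perspective)
  ctx <- prep_lifetable(epi)
  out <- run_scenarios(ctx, trajectory, perspective = perspective,
                       trace = trace)
  class(out) <- "wr_lifetable_result"
  out
}

#' @export
print.wr_lifetable_result <- function(x, ...) {
  cat("<proportional multi-state lifetable result>\n")
  cat(sprintf("  eligible population: %.0f\n", x$eligible_population))
  dq <- x$intervention$qalys - x$reference$qalys
  dk <- (x$reference$health_costs - x$intervention$health_costs)
  cat(sprintf("  discounted QALY gain: %.1f\n", dq))
  cat(sprintf("  discounted health-cost offset: %.0f\n", dk))
  if (x$perspective == "health_social") {
    cat(sprintf("  discounted social-care offset: %.0f\n",
                x$reference$social_costs - x$intervention$social_costs))
  }
  invisible(x)
}
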