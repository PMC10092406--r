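test_that("population impact fractions reproduce hand calculations", {
  grid <- seq(10, 60, by = 0.1)
  mass <- dlnorm(grid, log(27), 0.17)
  mass <- mass / sum(mass)

  expect_equal(pif(grid, mass, -1, rr = 1), 0)        # null relative risk
  expect_equal(pif(grid, mass, 0, rr = 1.1), 0)       # null shift
  expect_gt(pif(grid, mass, -1, rr = 1.1), 0)

  # two-mass toy: masses 0.5 at RR 2 and 0.5 at RR 1; moving the high-risk
  # mass onto the low-risk point gives (1.5 - 1) / 1.5 = 1/3
  rr_fn <- function(b) ifelse(b >= 30, 2, 1)
  expect_equal(pif(c(25, 35), c(0.5, 0.5), -10, rr_fn), 1 / 3,
               tolerance = 1e-15)

  expect_error(pif(grid, mass * 1.01, -1, 1.1), "integrate to 1")
})

test_that("grid PIF converges to the two-mass analytic value as the grid refines", {
  rr_fn <- function(b) ifelse(b >= 30, 2, 1)
  # point masses sit exactly on every grid used, so the toy is exact
  expect_equal(pif(c(25, 35), c(0.5, 0.5), -10, rr_fn), 1 / 3,
               tolerance = 1e-15)

  # for a continuous BMI distribution the grid estimate approaches a
  # fine-grid reference as the step shrinks
  pif_at <- function(h) {
    grid <- seq(10, 60, by = h)
    m <- dlnorm(grid, log(27), 0.17)
    pif(grid, m / sum(m), -1, rr = 1.1)
  }
  ref <- pif_at(0.005)
  err <- abs(vapply(c(1, 0.5, 0.1), pif_at, numeric(1)) - ref)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
  # halving the step roughly halves the error (first-order accuracy)
  expect_lt(err[2], 0.7 * err[1])
})

test_that("the disease process has the right fixed points and guards", {
  none <- run_disease(0, 0.1, years = 50)
  expect_equal(none$cases, rep(0, 50))

  blocked <- run_disease(0.01, 0.1, years = 50, pif = 1)
  expect_equal(blocked$cases, rep(0, 50))

  # prevalent fraction among those alive in the disease model tends to i/f
  eq <- run_disease(0.01, 0.1, years = 500)
  prev <- eq$cases / (eq$cases + eq$susceptible)
  expect_equal(prev[500], 0.01 / 0.1, tolerance = 0.01)

  expect_error(run_disease(0.1, 1.2, years = 10, s0 = 0, c0 = 1),
               "negative state")
})

test_that("a constant PIF scales the effective incidence hazard every year", {
  ref <- run_disease(0.02, 0.05, years = 40)
  int <- run_disease(0.02, 0.05, years = 40, pif = 1 / 3)
  # new cases per susceptible = i (1 - PIF): ratio exactly 2/3 each year
  haz_ref <- 1 - ref$susceptible[-1] / head(ref$susceptible, -1)
  haz_int <- 1 - int$susceptible[-1] / head(int$susceptible, -1)
  expect_equal(haz_int / haz_ref, rep(2 / 3, 39), tolerance = 1e-12)
})

test_that("discounting matches closed forms", {
  expect_equal(discount(rep(1, 10), 0), 10)
  expect_equal(discount(1, 0.035, years = 1), 1 / 1.035, tolerance = 1e-12)
  annuity <- (1 - 1.035^-20) / 0.035
  expect_equal(discount(rep(1, 20), 0.035, years = 1:20), annuity,
               tolerance = 1e-13)
  expect_error(discount(1, -0.1), ">= 0")
})

test_that("a null intervention leaves the two scenarios bitwise identical", {
  epi <- tiny_epi()
  lt <- run_lifetable(epi, make_trajectory(-1e-300, 0.027), trace = FALSE)
  expect_identical(lt$reference$qalys, lt$intervention$qalys)
  expect_identical(lt$reference$health_costs, lt$intervention$health_costs)
  expect_identical(lt$reference$person_years, lt$intervention$person_years)
})

test_that("every stratum-year conserves cohort mass to 1e-9", {
  epi <- tiny_epi()
  lt <- run_lifetable(epi, make_trajectory(-2.8, 0.027), trace = TRUE)
  for (scn in c("reference", "intervention")) {
    tr <- lt[[scn]]$traces
    expect_true(all(abs(tr$alive + tr$cum_dead - 1) < 1e-9))
  }
})

test_that("QALY gains grow with the programme-end difference and without regain", {
  epi <- tiny_epi()
  gain <- function(traj) {
    lt <- run_lifetable(epi, traj, trace = FALSE)
    lt$intervention$qalys - lt$reference$qalys
  }
  g_small <- gain(make_trajectory(-1.4, 0.027))
  g_base <- gain(make_trajectory(-2.8, 0.027))
  g_big <- gain(make_trajectory(-5.6, 0.027))
  g_none <- gain(make_trajectory(-2.8, 0.027, mode = "no_regain"))
  expect_true(g_small <= g_base && g_base <= g_big)
  expect_gte(g_none, g_base)
  expect_gt(g_base, 0)
})

test_that("cost offsets are homogeneous of degree one in unit costs", {
  epi <- tiny_epi()
  pipe <- build_econ_pipeline(epi, rate = 0.027)
  base <- pipe(list(weight_loss = 2.8, unit_costs = 1))
  doubled <- pipe(list(weight_loss = 2.8, unit_costs = 2))
  expect_equal(doubled[["cost_offset"]], 2 * base[["cost_offset"]],
               tolerance = 1e-12)
  expect_equal(doubled[["qaly_gain"]], base[["qaly_gain"]], tolerance = 1e-12)

  # opt-in rate uncertainty: a slower drawn rate keeps the advantage longer
  slower <- pipe(list(weight_loss = 2.8, regain_rate = 0.001))
  expect_gt(slower[["qaly_gain"]], base[["qaly_gain"]])
})

test_that("social care costs accrue only in the broader perspective", {
  # with no disease fatality the scenarios share survival exactly, so the
  # social-care offset is zero and both perspectives agree
  epi0 <- tiny_epi(case_fatality = 0, social_care_cost = 5000)
  lt_h <- run_lifetable(epi0, make_trajectory(-2.8, 0.027), "health",
                        trace = FALSE)
  lt_hs <- run_lifetable(epi0, make_trajectory(-2.8, 0.027), "health_social",
                         trace = FALSE)
  e_h <- econ_summary(lt_h)
  e_hs <- econ_summary(lt_hs)
  expect_equal(lt_hs$reference$social_costs, lt_hs$intervention$social_costs,
               tolerance = 1e-12)
  expect_gte(e_hs$cost_offset, e_h$cost_offset - 1e-9)

  # with fatality reductions the intervention adds old-age person-years,
  # which the broader perspective prices
  epi1 <- tiny_epi(case_fatality = 0.2, social_care_cost = 5000)
  lt1 <- run_lifetable(epi1, make_trajectory(-2.8, 0.027), "health_social",
                       trace = FALSE)
  expect_gt(lt1$intervention$social_costs, lt1$reference$social_costs)
})

test_that("utility overload is floored with a warning", {
  epi <- tiny_epi(incidence = 0.2, case_fatality = 0.01, utility = 0.2,
                  decrement = 0.9)
  expect_warning(run_lifetable(epi, make_trajectory(-2.8, 0.027),
                               trace = FALSE), "floored")
})
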