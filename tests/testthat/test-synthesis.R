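test_that("mixed model recovers a noiseless common slope and the intercept spread", {
  set.seed(42)
  a <- rnorm(12, -2.8, 0.8)
  s <- noiseless_series(a, slope = 0.03)
  fit <- fit_mixed(s)
  expect_equal(fit$slope, 0.03, tolerance = 1e-6)
  expect_equal(fit$intercept, mean(a), tolerance = 0.02)
  expect_equal(fit$tau2, var(a), tolerance = 0.05 * var(a))
})

test_that("mixed model on a single study equals ordinary least squares", {
  s <- make_series("only", c(0, 6, 12, 24), c(-3, -2.9, -2.5, -2.2))
  fit <- fit_mixed(s, weights_policy = "none")
  ols <- lm(diff ~ t, data = s)
  expect_identical(fit$n_studies, 1L)
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-12)
})

test_that("degenerate designs raise explicit errors", {
  flat <- dplyr::bind_rows(make_series("a", 0, -2), make_series("b", 0, -3))
  expect_error(fit_mixed(flat), "slope inestimable")
  expect_error(fit_metareg(dplyr::bind_rows(
    make_series("a", c(0, 12), c(-2, -1)),
    make_series("b", c(0, 12), c(-3, -2)))), "fewer than 3")
  same_t <- noiseless_series(c(-2, -3, -2.5), 0.02, t = c(0, 12))
  expect_error(fit_metareg(same_t), "final follow-up")
})

test_that("meta-regression recovers a noiseless common slope with zero tau2", {
  s <- dplyr::bind_rows(lapply(1:5, function(j) {
    make_series(paste0("S", j), c(0, 6 * j), -2.8 + 0.01 * c(0, 6 * j),
                var = 0.04)
  }))
  fit <- fit_metareg(s)
  expect_equal(fit$slope, 0.01, tolerance = 1e-8)
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
})

test_that("mixed and meta-regression agree on two-point noiseless common-intercept data", {
  finals <- c(6, 12, 24, 36, 48, 60)
  s <- dplyr::bind_rows(lapply(seq_along(finals), function(j) {
    make_series(sprintf("S%d", j), c(0, finals[j]),
                -2.8 + 0.02 * c(0, finals[j]), var = 0.04)
  }))
  m1 <- fit_mixed(s)
  m2 <- fit_metareg(s)
  expect_equal(m1$slope, 0.02, tolerance = 1e-6)
  expect_equal(m2$slope, 0.02, tolerance = 1e-8)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-5)
})

test_that("crossing times are interpolated exactly and censored correctly", {
  s <- make_series("a", c(0, 10), c(-2, 2))
  rec <- crossing_times(s)
  expect_true(rec$event)
  expect_equal(rec$time_months, 5)

  cens <- make_series("b", c(0, 12, 36), c(-2, -1.5, -0.5))
  rec2 <- crossing_times(cens)
  expect_false(rec2$event)
  expect_equal(rec2$time_months, 36)

  # linear series cross exactly at -D0 / r
  for (r in c(0.01, 0.027, 0.1)) {
    d0 <- -2.8
    tt <- seq(0, 400, by = 7)
    s3 <- make_series("c", tt, d0 + r * tt)
    expect_equal(crossing_times(s3)$time_months, -d0 / r, tolerance = 1e-9)
  }
})

test_that("product-limit estimator matches hand and empirical results", {
  rec <- tibble::tibble(study_id = c("a", "b", "c"),
                        time_months = c(10, 20, 30), event = TRUE)
  km <- km_estimate(rec)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median_months, 20)

  all_cens <- dplyr::mutate(rec, event = FALSE)
  expect_true(is.na(km_estimate(all_cens)$median_months))

  one <- tibble::tibble(study_id = "a", time_months = 5, event = TRUE)
  km1 <- km_estimate(one)
  expect_equal(km1$surv, 0)
  expect_equal(km1$median_months, 5)

  # no censoring: KM equals the empirical survival function, n = 1..6
  set.seed(99)
  for (n in 1:6) {
    times <- sort(round(runif(n, 1, 120), 1))
    km_n <- km_estimate(tibble::tibble(study_id = letters[1:n],
                                       time_months = times, event = TRUE))
    emp <- vapply(km_n$times, function(tt) mean(times > tt), numeric(1))
    expect_equal(km_n$surv, emp, tolerance = 1e-12)
  }
})

test_that("follow-up length bias check flags built-in associations only", {
  corpus0 <- generate_corpus(corpus_params(n_studies = 60, seed = 2))
  s0 <- filter_regain_eligible(build_difference_series(corpus0), corpus0)
  chk0 <- followup_bias_check(s0, corpus0)
  expect_true(chk0$ci_lo < 0 && chk0$ci_hi > 0)

  corpus1 <- generate_corpus(corpus_params(n_studies = 120, seed = 3,
                                           followup_d0_slope = 0.05))
  s1 <- build_difference_series(corpus1)
  chk1 <- followup_bias_check(s1, corpus1)
  expect_lt(abs(chk1$slope - 0.05), 0.02)
  expect_lt(chk1$p_value, 0.05)

  const <- dplyr::bind_rows(
    make_series("a", c(0, 6), c(-2, -1.5)),
    make_series("b", c(0, 6), c(-3, -2.5)),
    make_series("c", c(0, 6), c(-1, -0.8)))
  const_corpus <- dplyr::bind_rows(
    one_study_corpus(c(-2, -1), c(-4, -3), c(6, 12), study_id = "a"),
    one_study_corpus(c(-2, -1), c(-4, -3), c(6, 12), study_id = "b"),
    one_study_corpus(c(-2, -1), c(-4, -3), c(6, 12), study_id = "c"))
  expect_error(followup_bias_check(const, const_corpus), "constant")
})
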