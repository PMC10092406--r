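test_that("lognormal parameterisation matches its mean and interval geometry", {
  deg <- lognormal_from_mean_ci(2.8, 2.8, 2.8)
  expect_equal(deg$sdlog, 0)
  expect_equal(exp(deg$meanlog), 2.8)

  par <- lognormal_from_mean_ci(2.8, 1.0, 6.0)
  expect_equal(par$sdlog, (log(6) - log(1)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  set.seed(1)
  draws <- rlnorm(1e6, par$meanlog, par$sdlog)
  expect_equal(mean(draws), 2.8, tolerance = 0.005)

  expect_error(lognormal_from_mean_ci(2.8, 3.0, 6.0), "lo <= mean")
  expect_error(lognormal_from_mean_ci(2.8, -1, 6.0), "lo <= mean")
})

test_that("fixed pipelines give zero-width intervals and seeds reproduce bitwise", {
  groups <- list(mc_group("a", "fixed", mean = 2),
                 mc_group("b", "fixed", mean = 3))
  pipe <- function(d) c(out = d$a * d$b)
  mc <- run_mc(pipe, groups, n_iterations = 200, seed = 42)
  expect_equal(mc$summary$lo, mc$summary$hi)
  expect_equal(mc$summary$central, 6)

  groups2 <- list(mc_group("a", "lognormal", mean = 2, lo = 1, hi = 4),
                  mc_group("b", "normal", mean = 3, lo = 2, hi = 4))
  m1 <- run_mc(pipe, groups2, n_iterations = 500, seed = 42)
  m2 <- run_mc(pipe, groups2, n_iterations = 500, seed = 42)
  expect_identical(m1$draws, m2$draws)
  expect_identical(m1$summary, m2$summary)
  m3 <- run_mc(pipe, groups2, n_iterations = 500, seed = 43)
  expect_false(identical(m1$draws, m3$draws))
})

test_that("each input group has its own stream: adding a group leaves others unchanged", {
  pipe2 <- function(d) c(out = d$a)
  g_a <- mc_group("a", "lognormal", mean = 2, lo = 1, hi = 4)
  g_b <- mc_group("b", "normal", mean = 0, lo = -1, hi = 1)
  alone <- run_mc(pipe2, list(g_a), n_iterations = 300, seed = 7)
  with_b <- run_mc(function(d) c(out = d$a + 0 * d$b), list(g_a, g_b),
                   n_iterations = 300, seed = 7)
  expect_identical(alone$draws$a, with_b$draws$a)
})

test_that("percentile intervals match an independent sort-based computation", {
  groups <- list(mc_group("a", "lognormal", mean = 2, lo = 1, hi = 4),
                 mc_group("b", "normal", mean = 3, lo = 2, hi = 4))
  mc <- run_mc(function(d) c(out = d$a * d$b), groups,
               n_iterations = 999, seed = 5)
  x <- sort(mc$draws$out)
  # linear interpolation of order statistics at p (n-1) + 1
  manual_q <- function(p) {
    h <- p * (length(x) - 1) + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(mc$summary$lo, manual_q(0.025), tolerance = 1e-12)
  expect_equal(mc$summary$hi, manual_q(0.975), tolerance = 1e-12)
  # central estimate of a monotone pipeline lies inside the interval
  expect_true(mc$summary$lo < mc$summary$central &&
                mc$summary$central < mc$summary$hi)
})

test_that("out-of-bounds draws are redrawn and counted", {
  g <- mc_group("u", "normal", mean = 1, lo = 0.5, hi = 1.5, lower = 1)
  expect_message(
    mc <- run_mc(function(d) c(out = d$u), list(g),
                 n_iterations = 400, seed = 3),
    "redrawn")
  expect_gt(mc$redraws, 0)
  expect_true(all(mc$draws$u >= 1))
})

test_that("Monte Carlo means converge to the closed-form expectation", {
  # out = exp(Z), Z ~ N(0, sigma): E[out] = exp(sigma^2 / 2)
  sigma <- 0.4
  g <- mc_group("z", "normal", mean = 0, lo = -qnorm(0.975) * sigma,
                hi = qnorm(0.975) * sigma)
  mc <- run_mc(function(d) c(out = exp(d$z)), list(g, mc_group("dummy", "fixed", mean = 1)),
               n_iterations = 4000, seed = 11)
  expect_equal(mean(mc$draws$out), exp(sigma^2 / 2), tolerance = 0.02)
})

test_that("tornado ranks a constructed dominant input first and degenerate inputs last", {
  groups <- list(
    mc_group("weight_loss", "lognormal", mean = 2.8, lo = 0.5, hi = 15),
    mc_group("costs", "lognormal", mean = 1, lo = 0.95, hi = 1.05),
    mc_group("fixed_rate", "fixed", mean = 0.027)
  )
  pipe <- function(d) c(price = 200 * d$weight_loss * d$costs)
  tor <- tornado(pipe, groups)
  expect_equal(tor$group[1], "weight_loss")
  expect_equal(tor$spread[tor$group == "fixed_rate"], 0)
  expect_equal(tor$group[nrow(tor)], "fixed_rate")
  # single-spread sanity: dominant group's spread equals its own range sweep
  expect_equal(tor$spread[1],
               pipe(list(weight_loss = groups[[1]]$qfun(0.975), costs = 1))[["price"]] -
                 pipe(list(weight_loss = groups[[1]]$qfun(0.025), costs = 1))[["price"]],
               tolerance = 1e-12)
})
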