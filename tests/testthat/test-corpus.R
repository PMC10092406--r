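test_that("loading an empty table and a generated fixture gives the right shapes", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(generate_corpus(corpus_params(n_studies = 2, seed = 1))[0, ], f)
  empty <- load_corpus(f)
  expect_equal(nrow(empty), 0)

  corpus <- generate_corpus(corpus_params(n_studies = 2, seed = 1))
  write_corpus(corpus, f)
  reread <- load_corpus(f)
  expect_equal(dplyr::n_distinct(reread$study_id), 2)
  expect_equal(dplyr::n_distinct(paste(reread$study_id, reread$arm_id)), 4)
})

test_that("write/load round-trips the documented schema field-for-field", {
  corpus <- generate_corpus(corpus_params(n_studies = 6, seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, f)
  reread <- load_corpus(f)
  expect_equal(as.data.frame(reread), as.data.frame(corpus))
})

test_that("schema and integrity violations are rejected with typed errors", {
  corpus <- generate_corpus(corpus_params(n_studies = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")

  readr::write_csv(dplyr::select(corpus, -"mean_change_kg"), f)
  expect_error(load_corpus(f), class = "wr_schema_error")

  bad <- corpus
  bad$n_analyzed[1] <- 0
  expect_error(validate_corpus(bad), class = "wr_integrity_error")

  dup <- dplyr::bind_rows(corpus, corpus[1, ])
  expect_error(validate_corpus(dup), class = "wr_integrity_error")

  two_ctl <- corpus
  two_ctl$arm_role[two_ctl$study_id == corpus$study_id[1]] <- "control"
  expect_error(validate_corpus(two_ctl), class = "wr_integrity_error")

  readr::write_csv(corpus, f)
  unparseable <- readr::read_lines(f)
  unparseable[2] <- sub("^(S[0-9]+,[a-z]+,[a-z]+,[a-z]+,)[0-9.]+",
                        "\\1oops", unparseable[2])
  readr::write_lines(unparseable, f)
  expect_error(load_corpus(f), class = "wr_parse_error")
})

test_that("differencing matches hand arithmetic at programme end", {
  # printed arm means: intervention -4.9, control -2.1 -> difference -2.8
  corpus <- one_study_corpus(ctl_means = c(-2.1, -1.6),
                             int_means = c(-4.9, -4.0),
                             t_months = c(6, 18))
  s <- build_difference_series(corpus)
  expect_equal(s$t, c(0, 12))
  expect_equal(s$diff[s$t == 0], -2.8)

  # identical arms: difference 0 with variance 2 sd^2 / n
  same <- one_study_corpus(c(-2, -1), c(-2, -1), c(6, 18), sd = 3, n = 50)
  s0 <- build_difference_series(same)
  expect_equal(s0$diff, c(0, 0))
  expect_equal(s0$var, rep(2 * 9 / 50, 2))
})

test_that("multi-arm studies pool by n-weighted mean or by most intensive arm", {
  extra <- one_study_corpus(c(-2), c(-5), t_months = 6, n = 100)
  arm2 <- dplyr::mutate(extra[extra$arm_role == "intervention", ],
                        arm_id = "int2", mean_change_kg = -3,
                        n_analyzed = 50)
  corpus <- dplyr::bind_rows(extra, arm2)
  s <- build_difference_series(corpus)
  expect_equal(s$diff, (-5 * 100 - 3 * 50) / 150 - (-2), tolerance = 1e-12)
  s_int <- build_difference_series(corpus, combine = "most_intensive")
  expect_equal(s_int$diff, -5 - (-2))
})

test_that("swapping arm roles negates every difference", {
  for (seed in 1:3) {
    corpus <- generate_corpus(corpus_params(n_studies = 8, seed = seed))
    swapped <- dplyr::mutate(corpus, arm_role = ifelse(
      arm_role == "control", "intervention", "control"))
    a <- build_difference_series(corpus)
    b <- build_difference_series(swapped)
    expect_equal(b$diff, -a$diff, tolerance = 1e-12)
  }
})

test_that("regain eligibility keeps losers with follow-up and is idempotent", {
  keep <- make_series("A", c(0, 12), c(-0.5, -0.2))
  wrong_sign <- make_series("B", c(0, 12), c(0.3, 0.1))
  no_post <- make_series("C", 0, -1)
  s <- dplyr::bind_rows(keep, wrong_sign, no_post)
  out <- filter_regain_eligible(s)
  expect_equal(unique(out$study_id), "A")
  expect_equal(filter_regain_eligible(out), out)

  # short follow-up (< 12 months from baseline) is excluded via the corpus
  short <- one_study_corpus(c(-2, -1.9), c(-4, -3.8), t_months = c(5, 11.5),
                            pe = 5)
  s_short <- build_difference_series(short)
  expect_equal(nrow(filter_regain_eligible(s_short, short)), 0)
  long <- one_study_corpus(c(-2, -1.9), c(-4, -3.8), t_months = c(5, 14),
                           pe = 5)
  expect_gt(nrow(filter_regain_eligible(build_difference_series(long), long)), 0)
})

test_that("risk-of-bias filtering subsets studies deterministically", {
  corpus <- generate_corpus(corpus_params(n_studies = 40, seed = 5))
  meta <- study_meta(corpus)
  kept <- filter_by_rob(corpus, exclude = "high")
  expect_equal(dplyr::n_distinct(kept$study_id),
               sum(meta$rob_overall != "high"))
  expect_equal(filter_by_rob(corpus, exclude = character(0)), corpus)
  expect_equal(nrow(filter_by_rob(corpus, exclude = c("low", "unclear", "high"))), 0)
})
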