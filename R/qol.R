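# Quality-of-life co-analysis: standardization across scales, back-conversion
# to SF-36 points, and the weight--QoL association.

#' Standardize quality-of-life differences across scales
#'
#' Converts per-study QoL change scores, reported on heterogeneous
#' instruments, into standardized mean differences (intervention minus
#' control change over the pooled change-score SD). Scales where lower scores
#' mean better QoL are sign-flipped first, so a positive SMD always favours
#' the intervention. Studies with missing QoL SDs are dropped with a warning.
#'
#' @inheritParams build_difference_series
#' @return A `wr_diff_series` tibble with `outcome = "qol_smd"`.
#' @export
standardize_qol <- function(corpus, tolerance = 0.5,
                            combine = c("nweight", "most_intensive"),
                            hedges = FALSE) {
  combine <- match.arg(combine)
  build_series_impl(corpus, value_col = "qol_mean_change", sd_col = "qol_sd",
                    outcome = "qol_smd", tolerance = tolerance,
                    combine = combine, standardize = TRUE, hedges = hedges)
}

#' Back-convert SMDs to SF-36 points
#'
#' Expresses a standardized mean difference on the Short-Form 36 scale by
#' multiplying it by each study's SF-36 SD, then summarises the resulting
#' per-study point differences by their median and interquartile range.
#'
#' @param smd A single standardized mean difference (e.g. the fitted
#'   programme-end SMD).
#' @param sf36_sds Per-study SF-36 standard deviations (points).
#' @return A tibble with `points` (per-study differences, list column
#'   unpacked as rows), plus attributes via [glance()]-style summary columns
#'   `median`, `q25`, `q75` repeated on each row.
#' @examples
#' smd_to_sf36(0.2, c(10, 30, 50))
#' @export
smd_to_sf36 <- function(smd, sf36_sds) {
  if (length(sf36_sds) == 0) {
    abort("smd_to_sf36: need at least one SF-36 SD")
  }
  pts <- smd * sf36_sds
  qs <- quantile(pts, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(sf36_sd = sf36_sds, points = pts,
         median = qs[2], q25 = qs[1], q75 = qs[3])
}

#' Association between weight regained and quality of life
#'
#' Pairs, within study and visit, the weight difference series with the QoL
#' SMD series, and regresses SMD on the weight difference with a random
#' study intercept (the same machinery as the mixed regain model). The slope
#' is the estimated change in standardized QoL per kg of weight difference;
#' a negative slope means QoL declines as the weight advantage erodes.
#'
#' @param qol_series A `wr_diff_series` with `outcome = "qol_smd"`.
#' @param weight_series A `wr_diff_series` with `outcome = "weight_kg"`.
#' @param tolerance Visit-matching window in months (default 0.5).
#' @return A `wr_regain_fit` whose `slope` is in SMD per kg.
#' @export
qol_weight_slope <- function(qol_series, weight_series, tolerance = 0.5) {
  q <- as_tibble(qol_series)
  w <- as_tibble(weight_series)
  paired <- inner_join(q, w, by = "study_id", suffix = c("_qol", "_wt"),
                       relationship = "many-to-many") |>
    filter(abs(.data$t_qol - .data$t_wt) <= tolerance) |>
    transmute(study_id = .data$study_id, t = .data$t_qol,
              qol = .data$diff_qol, wt = .data$diff_wt,
              var = .data$var_qol, n_total = .data$n_total_qol)
  if (nrow(paired) < 2) {
    abort("qol_weight_slope: fewer than 2 paired observations")
  }
  if (diff(range(paired$wt)) == 0) {
    abort("qol_weight_slope: weight differences are constant; slope inestimable")
  }
  fit_random_intercept(paired, x_col = "wt", y_col = "qol",
                       model = "mixed", outcome = "qol_smd_per_kg")
}
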