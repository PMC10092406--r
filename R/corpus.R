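# Study corpus: readers, validation, eligibility filters, and construction of
# intervention-minus-control difference series aligned to programme end.

CORPUS_COLUMNS <- c(
  "study_id", "arm_id", "arm_role", "rob_overall", "programme_end_month",
  "t_months", "mean_change_kg", "sd_kg", "n_analyzed",
  "qol_scale", "qol_direction", "qol_mean_change", "qol_sd"
)

corpus_col_types <- function() {
  readr::cols(
    study_id = readr::col_character(),
    arm_id = readr::col_character(),
    arm_role = readr::col_character(),
    rob_overall = readr::col_character(),
    programme_end_month = readr::col_double(),
    t_months = readr::col_double(),
    mean_change_kg = readr::col_double(),
    sd_kg = readr::col_double(),
    n_analyzed = readr::col_double(),
    qol_scale = readr::col_character(),
    qol_direction = readr::col_character(),
    qol_mean_change = readr::col_double(),
    qol_sd = readr::col_double()
  )
}

#' Load a study extraction table
#'
#' Reads a CSV of per-study, per-arm, per-visit weight (and optionally
#' quality-of-life) change observations into a validated corpus tibble. One
#' row is one arm at one visit; weight changes are from baseline, in kg, with
#' negative values meaning weight loss. `t_months` counts months since
#' randomization; `programme_end_month` is the study-level point at which
#' intervention contact intensity steps down, the origin of the regain clock.
#'
#' Required columns: `study_id`, `arm_id`, `arm_role`
#' (`"intervention"`/`"control"`), `rob_overall` (`"low"`/`"unclear"`/`"high"`),
#' `programme_end_month`, `t_months`, `mean_change_kg`, `sd_kg`, `n_analyzed`.
#' Optional quality-of-life columns: `qol_scale`, `qol_direction`
#' (`"higher_better"`/`"lower_better"`), `qol_mean_change`, `qol_sd`.
#'
#' @param path Path to a CSV file conforming to the schema above.
#' @return A tibble of class `wr_corpus`, one row per arm-visit.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_corpus(generate_corpus(corpus_params(n_studies = 3, seed = 1)), f)
#' corpus <- load_corpus(f)
#' dplyr::n_distinct(corpus$study_id)
#' @export
load_corpus <- function(path) {
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = corpus_col_types(), na = c("", "NA"))
  )
  missing_cols <- setdiff(setdiff(CORPUS_COLUMNS, QOL_COLUMNS), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus schema error: missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "wr_schema_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    bad_rows <- sort(unique(probs$row))
    abort(paste0("corpus parse error: unparseable values in data row(s) ",
                 paste(bad_rows, collapse = ", "), " (",
                 paste(unique(probs$col), collapse = ", "), ")"),
          class = "wr_parse_error")
  }
  for (col in setdiff(QOL_COLUMNS, names(raw))) raw[[col]] <- NA
  corpus <- as_tibble(raw)[, CORPUS_COLUMNS]
  validate_corpus(corpus)
}

QOL_COLUMNS <- c("qol_scale", "qol_direction", "qol_mean_change", "qol_sd")

#' Validate a corpus tibble
#'
#' Checks the structural invariants of the extraction schema: valid arm roles
#' and risk-of-bias levels, one control arm per study, strictly increasing
#' visit times within an arm, positive analyzed sample sizes, positive SDs
#' where present, and programme end not after the last visit.
#'
#' @param corpus A tibble in the `load_corpus()` schema.
#' @return The corpus, invisibly classed as `wr_corpus`, or an error.
#' @export
validate_corpus <- function(corpus) {
  corpus <- as_tibble(corpus)
  if (nrow(corpus) == 0) {
    class(corpus) <- c("wr_corpus", class(corpus))
    return(corpus)
  }
  bad_role <- !corpus$arm_role %in% c("intervention", "control")
  if (any(bad_role)) {
    abort(paste0("corpus integrity error: arm_role must be ",
                 "'intervention' or 'control' (rows ",
                 paste(head(which(bad_role), 5), collapse = ", "), ")"),
          class = "wr_integrity_error")
  }
  bad_rob <- !corpus$rob_overall %in% c("low", "unclear", "high")
  if (any(bad_rob)) {
    abort("corpus integrity error: rob_overall must be low/unclear/high",
          class = "wr_integrity_error")
  }
  if (any(is.na(corpus$n_analyzed) | corpus$n_analyzed < 1)) {
    abort("corpus integrity error: n_analyzed must be >= 1 on every row",
          class = "wr_integrity_error")
  }
  if (any(!is.na(corpus$sd_kg) & corpus$sd_kg <= 0)) {
    abort("corpus integrity error: sd_kg must be > 0 where present",
          class = "wr_integrity_error")
  }
  if (any(corpus$t_months < 0)) {
    abort("corpus integrity error: t_months must be >= 0",
          class = "wr_integrity_error")
  }
  dup <- duplicated(corpus[, c("study_id", "arm_id", "t_months")])
  if (any(dup)) {
    abort(paste0("corpus integrity error: duplicate (study, arm, t) rows: ",
                 paste(head(unique(corpus$study_id[dup]), 5), collapse = ", ")),
          class = "wr_integrity_error")
  }
  n_control <- corpus |>
    filter(.data$arm_role == "control") |>
    group_by(.data$study_id) |>
    summarise(k = n_distinct(.data$arm_id), .groups = "drop")
  studies <- unique(corpus$study_id)
  missing_ctl <- setdiff(studies, n_control$study_id)
  multi_ctl <- n_control$study_id[n_control$k > 1]
  if (length(missing_ctl) > 0 || length(multi_ctl) > 0) {
    abort(paste0("corpus integrity error: each study needs exactly one ",
                 "control arm (offending: ",
                 paste(head(c(missing_ctl, multi_ctl), 5), collapse = ", "),
                 ")"),
          class = "wr_integrity_error")
  }
  pe_chk <- corpus |>
    group_by(.data$study_id) |>
    summarise(pe = .data$programme_end_month[1],
              pe_varies = n_distinct(.data$programme_end_month) > 1,
              t_max = max(.data$t_months), .groups = "drop")
  if (any(pe_chk$pe_varies)) {
    abort("corpus integrity error: programme_end_month must be constant within a study",
          class = "wr_integrity_error")
  }
  if (any(pe_chk$pe > pe_chk$t_max)) {
    abort("corpus integrity error: programme_end_month exceeds last visit",
          class = "wr_integrity_error")
  }
  if (!inherits(corpus, "wr_corpus")) {
    class(corpus) <- c("wr_corpus", class(corpus))
  }
  corpus
}

#' Write a corpus back to CSV
#'
#' Inverse of [load_corpus()]: writes the documented schema columns so that
#' `load_corpus(write_corpus(x, f))` reproduces `x` field-for-field.
#'
#' @param corpus A corpus tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  readr::write_csv(as_tibble(corpus)[, CORPUS_COLUMNS], path)
  invisible(path)
}

#' Study-level metadata of a corpus
#'
#' Summarises the corpus to one row per study: programme end, maximum
#' follow-up (last visit of any arm, months since randomization), overall
#' risk of bias, and quality-of-life scale/direction where reported.
#'
#' @param corpus A corpus tibble.
#' @return A tibble with one row per study.
#' @export
study_meta <- function(corpus) {
  as_tibble(corpus) |>
    group_by(.data$study_id) |>
    summarise(
      programme_end_month = .data$programme_end_month[1],
      max_followup_months = max(.data$t_months),
      rob_overall = .data$rob_overall[1],
      qol_scale = first_non_na(.data$qol_scale),
      qol_direction = first_non_na(.data$qol_direction),
      .groups = "drop"
    )
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_character_ else x[1]
}

#' Filter a corpus by overall risk of bias
#'
#' Drops all rows of studies whose overall risk-of-bias rating falls in
#' `exclude`. Used for the sensitivity analysis that removes studies at high
#' risk of bias in any domain.
#'
#' @param corpus A corpus tibble.
#' @param exclude Character vector of ratings to drop (default `"high"`).
#' @return The filtered corpus.
#' @export
filter_by_rob <- function(corpus, exclude = "high") {
  out <- as_tibble(corpus) |> filter(!.data$rob_overall %in% exclude)
  class(out) <- c("wr_corpus", setdiff(class(out), "wr_corpus"))
  out
}

#' Build intervention-minus-control difference series
#'
#' For each study, subtracts the control arm's mean change from the
#' intervention arm's at every visit where the arms can be matched in time
#' (within `tolerance` months), and re-expresses time as months since
#' programme end. Studies with several intervention arms are pooled either by
#' an n-weighted average (`combine = "nweight"`, default) or by keeping the
#' arm with the largest weight loss at programme end
#' (`combine = "most_intensive"`). The sampling variance of a difference is
#' `sd_i^2/n_i + sd_c^2/n_c` when both SDs are present, `NA` otherwise.
#'
#' For `outcome = "qol_smd"` the difference is a standardized mean difference
#' (change-score difference over pooled change-score SD), with
#' lower-is-better scales sign-flipped so that positive SMD always means
#' better quality of life in the intervention arm; see [standardize_qol()].
#'
#' Studies with no visit matching programme end are dropped with a warning.
#' Visits before programme end (beyond tolerance) are discarded.
#'
#' @param corpus A corpus tibble.
#' @param outcome `"weight_kg"` (default) or `"qol_smd"`.
#' @param tolerance Arm-visit matching window, months (default 0.5).
#' @param combine Multi-intervention-arm pooling rule.
#' @param hedges For `qol_smd`, apply the small-sample (Hedges) correction.
#' @return A tibble of class `wr_diff_series` with columns `study_id`,
#'   `outcome`, `t` (months since programme end, `t = 0` at programme end),
#'   `diff`, `var` (possibly `NA`) and `n_total`.
#' @examples
#' corpus <- generate_corpus(corpus_params(n_studies = 5, seed = 1))
#' build_difference_series(corpus)
#' @export
build_difference_series <- function(corpus, outcome = c("weight_kg", "qol_smd"),
                                    tolerance = 0.5,
                                    combine = c("nweight", "most_intensive"),
                                    hedges = FALSE) {
  outcome <- match.arg(outcome)
  combine <- match.arg(combine)
  if (outcome == "qol_smd") {
    return(standardize_qol(corpus, tolerance = tolerance, combine = combine,
                           hedges = hedges))
  }
  build_series_impl(corpus, value_col = "mean_change_kg", sd_col = "sd_kg",
                    outcome = "weight_kg", tolerance = tolerance,
                    combine = combine, standardize = FALSE, hedges = FALSE)
}

# Shared worker for weight differences and QoL SMDs. For each study:
# match intervention visits to control visits within the tolerance window,
# pool multiple intervention arms, difference the means, and shift the clock
# so t = 0 at programme end.
build_series_impl <- function(corpus, value_col, sd_col, outcome, tolerance,
                              combine, standardize, hedges) {
  corpus <- as_tibble(corpus)
  out <- vector("list", 0L)
  dropped <- character(0)
  for (sid in unique(corpus$study_id)) {
    stud <- corpus[corpus$study_id == sid, ]
    pe <- stud$programme_end_month[1]
    if (standardize) {
      dir <- first_non_na(stud$qol_direction)
      stud <- stud[!is.na(stud[[value_col]]), ]
      if (nrow(stud) == 0) next
      if (is.na(dir)) dir <- "higher_better"
      if (!is.na(dir) && dir == "lower_better") {
        stud[[value_col]] <- -stud[[value_col]]
      }
      if (any(is.na(stud[[sd_col]]))) {
        warn(paste0("study ", sid,
                    ": missing QoL SD; dropped from QoL synthesis"))
        next
      }
    }
    ctl <- stud[stud$arm_role == "control", ]
    ints <- stud[stud$arm_role == "intervention", ]
    if (nrow(ctl) == 0 || nrow(ints) == 0) next
    if (combine == "most_intensive" && n_distinct(ints$arm_id) > 1) {
      at_pe <- ints[abs(ints$t_months - pe) <= tolerance, ]
      pick <- at_pe$arm_id[which.min(at_pe[[value_col]])]
      if (length(pick) == 1) ints <- ints[ints$arm_id == pick, ]
    }
    pts <- vector("list", nrow(ctl))
    for (k in seq_len(nrow(ctl))) {
      tc <- ctl$t_months[k]
      m <- ints[abs(ints$t_months - tc) <= tolerance, ]
      if (nrow(m) == 0) next
      w <- m$n_analyzed
      mi <- sum(w * m[[value_col]]) / sum(w)
      ni <- sum(w)
      sds_i <- m[[sd_col]]
      if (standardize) {
        sd_pool <- pooled_sd(m[[sd_col]], m$n_analyzed,
                             ctl[[sd_col]][k], ctl$n_analyzed[k])
        d <- (mi - ctl[[value_col]][k]) / sd_pool
        if (hedges) d <- d * hedges_j(ni + ctl$n_analyzed[k] - 2)
        v <- 1 / ni + 1 / ctl$n_analyzed[k] +
          d^2 / (2 * (ni + ctl$n_analyzed[k]))
      } else {
        d <- mi - ctl[[value_col]][k]
        if (all(!is.na(sds_i)) && !is.na(ctl[[sd_col]][k])) {
          # variance of the n-weighted pooled intervention mean + control mean
          v <- sum((w / ni)^2 * sds_i^2 / w) +
            ctl[[sd_col]][k]^2 / ctl$n_analyzed[k]
        } else {
          v <- NA_real_
        }
      }
      pts[[k]] <- tibble(t = tc - pe, diff = d, var = v,
                         n_total = ni + ctl$n_analyzed[k])
    }
    pts <- bind_rows(pts)
    if (nrow(pts) == 0) next
    # snap the visit nearest programme end (within tolerance) to t = 0
    at_pe <- which(abs(pts$t) <= tolerance)
    if (length(at_pe) == 0) {
      dropped <- c(dropped, sid)
      next
    }
    pts$t[at_pe[which.min(abs(pts$t[at_pe]))]] <- 0
    pts <- pts[pts$t >= 0, ]
    out[[sid]] <- mutate(pts, study_id = sid, outcome = outcome,
                         .before = 1)
  }
  if (length(dropped) > 0) {
    warn(paste0("no visit matches programme end; excluded: ",
                paste(dropped, collapse = ", ")))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(study_id = character(), outcome = character(),
                  t = double(), diff = double(), var = double(),
                  n_total = double())
  }
  res <- arrange(res, .data$study_id, .data$t)
  class(res) <- c("wr_diff_series", class(res))
  res
}

pooled_sd <- function(sd_i, n_i, sd_c, n_c) {
  num <- sum((n_i - 1) * sd_i^2) + (n_c - 1) * sd_c^2
  sqrt(num / (sum(n_i) + n_c - 2))
}

hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Keep series eligible for regain synthesis
#'
#' Retains a study's difference series only if (i) the intervention had lost
#' weight relative to control at programme end (difference strictly below
#' zero at `t = 0`), (ii) there is at least one post-programme observation,
#' and (iii) the study followed participants for at least `min_followup`
#' months from randomization. Idempotent.
#'
#' @param series A `wr_diff_series` tibble from [build_difference_series()].
#' @param corpus Optional corpus used to recover total follow-up from
#'   baseline; when omitted, follow-up is taken as programme end plus the
#'   last post-programme visit only if `series` carries a
#'   `max_followup_months` attribute, else the follow-up rule is skipped.
#' @param min_followup Minimum follow-up since baseline, months (default 12).
#' @return The filtered series tibble.
#' @export
filter_regain_eligible <- function(series, corpus = NULL, min_followup = 12) {
  series <- as_tibble(series)
  fup <- NULL
  if (!is.null(corpus)) {
    fup <- study_meta(corpus) |>
      select("study_id", "max_followup_months")
  }
  keep <- series |>
    group_by(.data$study_id) |>
    summarise(
      has_t0 = any(.data$t == 0),
      d0 = if (any(.data$t == 0)) .data$diff[.data$t == 0][1] else NA_real_,
      has_post = any(.data$t > 0),
      .groups = "drop"
    ) |>
    filter(.data$has_t0, !is.na(.data$d0), .data$d0 < 0, .data$has_post)
  if (!is.null(fup)) {
    keep <- keep |>
      inner_join(fup, by = "study_id") |>
      filter(.data$max_followup_months >= min_followup)
  }
  out <- semi_join(series, keep, by = "study_id")
  class(out) <- c("wr_diff_series", setdiff(class(out), "wr_diff_series"))
  out
}
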