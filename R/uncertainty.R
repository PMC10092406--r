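# Monte Carlo uncertainty propagation and tornado decomposition. Input
# uncertainty is organised into named groups, each with its own distribution
# and its own RNG stream split from the master seed, so adding a group never
# perturbs the draws of the others.

#' Lognormal parameters from a mean and 95% interval
#'
#' Parameterises a lognormal distribution so that its mean equals `mean` and
#' its log-scale spread matches the supplied 95% interval:
#' `sdlog = (log(hi) - log(lo)) / (2 * 1.95996...)`, with `meanlog` chosen so
#' the distribution's arithmetic mean is `mean`.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param lo,hi 95% interval bounds, `0 < lo <= mean <= hi`.
#' @return A list with `meanlog` and `sdlog`.
#' @export
lognormal_from_mean_ci <- function(mean, lo, hi) {
  if (!(lo > 0 && lo <= mean && mean <= hi)) {
    abort("lognormal_from_mean_ci: need 0 < lo <= mean <= hi")
  }
  sdlog <- (log(hi) - log(lo)) / (2 * qnorm(0.975))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Define one uncertain input group
#'
#' @param name Group name (used in pipelines and reports).
#' @param dist `"lognormal"`, `"normal"` or `"fixed"`. Lognormal is the
#'   conventional choice for relative risks, unit costs and the magnitude of
#'   programme-end weight loss; normal for utilities.
#' @param mean Central value (the value used in deterministic runs).
#' @param lo,hi 95% interval. Ignored for `"fixed"`.
#' @param lower,upper Hard bounds; draws outside are redrawn.
#' @return A list describing the group.
#' @export
mc_group <- function(name, dist = c("lognormal", "normal", "fixed"),
                     mean, lo = mean, hi = mean,
                     lower = -Inf, upper = Inf) {
  dist <- match.arg(dist)
  qfun <- switch(dist,
    fixed = function(p) rep(mean, length(p)),
    lognormal = {
      if (lo == hi) {
        function(p) rep(mean, length(p))
      } else {
        par <- lognormal_from_mean_ci(mean, lo, hi)
        function(p) qlnorm(p, par$meanlog, par$sdlog)
      }
    },
    normal = {
      sdv <- (hi - lo) / (2 * qnorm(0.975))
      function(p) qnorm(p, mean, sdv)
    }
  )
  list(name = name, dist = dist, mean = mean, lo = lo, hi = hi,
       lower = lower, upper = upper, qfun = qfun)
}

# deterministic per-group seed split from the master seed; stays well below
# 2^31
group_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

draw_group <- function(group, n, seed) {
  set.seed(group_seed(seed, group$name))
  x <- group$qfun(runif(n))
  redraws <- 0L
  while (any(bad <- x < group$lower | x > group$upper)) {
    redraws <- redraws + sum(bad)
    x[bad] <- group$qfun(runif(sum(bad)))
  }
  attr(x, "redraws") <- redraws
  x
}

#' Monte Carlo propagation through a pipeline
#'
#' Draws `n_iterations` joint samples of the uncertain input groups (each
#' from its own RNG stream split from `seed`), evaluates the pipeline on
#' every draw, and summarises every output by its central (all-inputs-at-
#' central-values) estimate and percentile 95% uncertainty interval. Draws
#' violating a group's hard bounds are redrawn and counted.
#'
#' @param pipeline A function taking a named list (one value per group) and
#'   returning a named numeric vector of outputs.
#' @param groups A list of [mc_group()] definitions.
#' @param n_iterations Number of Monte Carlo iterations (default 5000).
#' @param seed Master seed; identical seeds give bitwise-identical results.
#' @return An object of class `wr_mc` with `draws` (tibble of inputs and
#'   outputs per iteration), `summary` (tibble with `output`, `central`,
#'   `lo`, `hi`), `redraws`, `n_iterations` and `seed`.
#' @export
run_mc <- function(pipeline, groups, n_iterations = 5000, seed = 1) {
  names(groups) <- map_chr_(groups, "name")
  xs <- lapply(groups, draw_group, n = n_iterations, seed = seed)
  redraws <- sum(vapply(xs, function(x) attr(x, "redraws"), integer(1)))
  if (redraws > 0) {
    inform(paste0("run_mc: ", redraws, " out-of-bounds draws redrawn"))
  }
  inputs <- as_tibble(lapply(xs, as.numeric))
  outs <- lapply(seq_len(n_iterations), function(i) {
    pipeline(as.list(inputs[i, ]))
  })
  out_tbl <- as_tibble(do.call(rbind, outs))
  central_in <- lapply(groups, function(g) g$mean)
  central <- pipeline(central_in)
  summary <- tibble(
    output = names(out_tbl),
    central = as.numeric(central[names(out_tbl)]),
    lo = unname(vapply(out_tbl, quantile, numeric(1), probs = 0.025,
                       names = FALSE)),
    hi = unname(vapply(out_tbl, quantile, numeric(1), probs = 0.975,
                       names = FALSE))
  )
  structure(
    list(draws = bind_cols(inputs, out_tbl), summary = summary,
         redraws = redraws, n_iterations = n_iterations, seed = seed),
    class = "wr_mc"
  )
}

map_chr_ <- function(x, field) vapply(x, function(e) e[[field]], character(1))

#' @export
print.wr_mc <- function(x, ...) {
  cat(sprintf("<Monte Carlo result: %d iterations, seed %s>\n",
              x$n_iterations, format(x$seed)))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-12s %12.4g  (95%% UI %.4g to %.4g)\n",
                s$output, s$central, s$lo, s$hi))
  }
  invisible(x)
}

#' One-way tornado decomposition
#'
#' Evaluates the pipeline with each uncertain group in turn set to its 2.5th
#' and 97.5th percentile while all other groups stay at their central
#' values; the induced spread `|high - low|` ranks the groups by their
#' contribution to output uncertainty.
#'
#' @inheritParams run_mc
#' @param output Name of the pipeline output to decompose (default: the
#'   first output).
#' @return A tibble of class `wr_tornado` with `group`, `low`, `high`,
#'   `spread`, sorted by decreasing spread.
#' @export
tornado <- function(pipeline, groups, output = NULL) {
  names(groups) <- map_chr_(groups, "name")
  if (length(groups) < 2) abort("tornado: need at least 2 input groups")
  central_in <- lapply(groups, function(g) g$mean)
  base <- pipeline(central_in)
  output <- output %||% names(base)[1]
  rows <- lapply(groups, function(g) {
    at <- function(p) {
      v <- central_in
      v[[g$name]] <- max(min(g$qfun(p), g$upper), g$lower)
      pipeline(v)[[output]]
    }
    lo <- at(0.025); hi <- at(0.975)
    tibble(group = g$name, low = lo, high = hi, spread = abs(hi - lo))
  })
  out <- bind_rows(rows) |> arrange(desc(.data$spread))
  attr(out, "output") <- output
  attr(out, "base") <- base[[output]]
  class(out) <- c("wr_tornado", class(out))
  out
}
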