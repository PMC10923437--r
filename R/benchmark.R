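#' Median absolute bias
#'
#' Median over replicates of the absolute deviation of the estimates from the
#' true value.
#'
#' @param estimates Numeric vector of replicate estimates (length >= 1).
#' @param truth True parameter value.
#' @return The MAB (>= 0).
#' @export
mab <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("at least one estimate is required")
  stats::median(abs(estimates - truth))
}

#' Relative median absolute bias
#'
#' MAB divided by the absolute true value. Undefined (returned as `NA`,
#' rendered "-" in tables) exactly when the truth is zero, as in the
#' unidirectional model's reverse direction.
#'
#' @param mab_value A median absolute bias.
#' @param truth True parameter value.
#' @return The RMAB as a fraction, or `NA_real_` when `truth == 0`.
#' @export
rmab <- function(mab_value, truth) {
  if (truth == 0) return(NA_real_)
  mab_value / abs(truth)
}

#' Replicate benchmark of the four estimators
#'
#' Simulates `n_reps` cohorts from the configured generative model (replicate
#' r uses seed `base_seed + r`, so runs are reproducible and individually
#' re-creatable), applies each requested estimator in both directions, and
#' aggregates the accuracy metrics per method and direction: median estimate,
#' median absolute bias, relative median absolute bias, and the mean marginal
#' first-stage F-statistic of the direction's instrument set across
#' replicates. A replicate on which one estimator fails still contributes to
#' the other estimators' summaries; failures are counted, never silently
#' dropped.
#'
#' @param params A [bmr_params()] object (the scenario's structural truth;
#'   `gamma21` is the true reverse effect, 0 under the unidirectional model).
#' @param model `"bmr"` or `"umr"` generative model.
#' @param methods Subset of `c("ratio", "biratio", "liml", "biliml")`.
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Base seed of the replicate stream.
#' @param confounder_visible Pass the latent confounder to the estimators as
#'   a covariate (non-default diagnostic mode).
#' @return A data frame of class `bimr_benchmark`, one row per
#'   method x direction, with columns `model`, `method`, `direction`,
#'   `true_value`, `mean_f`, `median_estimate`, `mab`, `rmab`, `n_reps`,
#'   `n_fail`.
#' @export
run_benchmark <- function(params, model = c("bmr", "umr"),
                          methods = c("ratio", "biratio", "liml", "biliml"),
                          n_reps = 1000L, base_seed = 1L,
                          confounder_visible = FALSE) {
  model <- match.arg(model)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_reps >= 1L)
  truth12 <- params$gamma12
  truth21 <- if (model == "umr") 0 else params$gamma21
  est <- array(NA_real_, dim = c(n_reps, length(methods), 2L),
               dimnames = list(NULL, methods, c("1->2", "2->1")))
  fmat <- matrix(NA_real_, n_reps, 2L)
  for (r in seq_len(n_reps)) {
    dat <- simulate_cohort(params, model, seed = base_seed + r)
    fmat[r, 1] <- .mean_instrument_f(dat, 1)
    fmat[r, 2] <- .mean_instrument_f(dat, 2)
    cov <- if (confounder_visible) cbind(confounder = dat$confounder) else NULL
    for (m in methods) {
      fit <- tryCatch(switch(m,
                             ratio   = naive_bidirectional_ratio(dat, cov),
                             biratio = biratio(dat, cov),
                             liml    = naive_liml(dat, cov),
                             biliml  = biliml(dat, cov)),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        est[r, m, 1] <- fit$est12$estimate
        est[r, m, 2] <- fit$est21$estimate
      }
    }
  }
  rows <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(1:2, function(dir) {
      e <- est[, m, dir]
      ok <- !is.na(e)
      truth <- if (dir == 1) truth12 else truth21
      mab_v <- if (any(ok)) mab(e[ok], truth) else NA_real_
      data.frame(model = model, method = m,
                 direction = c("1->2", "2->1")[dir],
                 true_value = truth,
                 mean_f = mean(fmat[, dir]),
                 median_estimate = if (any(ok)) stats::median(e[ok]) else NA_real_,
                 mab = mab_v,
                 rmab = if (is.na(mab_v)) NA_real_ else rmab(mab_v, truth),
                 n_reps = n_reps, n_fail = sum(!ok))
    }))
  }))
  rownames(rows) <- NULL
  class(rows) <- c("bimr_benchmark", "data.frame")
  rows
}

#' Render benchmark summaries as a plain-text results table
#'
#' Formats one or more benchmark summaries in the layout of the simulation
#' study tables: rows keyed by the true (gamma12, gamma21) pair with one
#' sub-row per direction, a mean-F column, and Median/MAB/RMAB columns per
#' method. Medians and MAB are printed to two decimals, RMAB as an integer
#' percentage, and an undefined RMAB (true effect 0) as "-".
#'
#' @param summaries A `bimr_benchmark` data frame from one benchmark cell
#'   (one true effect pair).
#' @return A character vector of table lines, invisibly; printed as a side
#'   effect by [print.bimr_benchmark()].
#' @export
render_results_table <- function(summaries) {
  if (!nrow(summaries)) stop("no summaries to render")
  methods <- unique(summaries$method)
  lines <- c(paste(c(sprintf("%-24s", "True effects"), "F-stat",
                     unlist(lapply(methods, function(m)
                       sprintf("%8s %6s %6s", paste0(m, ":med"), "MAB", "RMAB")))),
                   collapse = "  "))
  fmt_rmab <- function(x) ifelse(is.na(x), "-", sprintf("%d%%", round(100 * x)))
  for (dir in c("1->2", "2->1")) {
    sub <- summaries[summaries$direction == dir, , drop = FALSE]
    lab <- if (dir == "1->2")
      sprintf("gamma12 = %g", sub$true_value[1])
    else sprintf("gamma21 = %g", sub$true_value[1])
    cells <- unlist(lapply(methods, function(m) {
      row <- sub[sub$method == m, , drop = FALSE]
      sprintf("%8.2f %6.2f %6s", row$median_estimate, row$mab, fmt_rmab(row$rmab))
    }))
    lines <- c(lines, paste(c(sprintf("%-24s", lab),
                              sprintf("%6.2f", sub$mean_f[1]), cells),
                            collapse = "  "))
  }
  invisible(lines)
}

#' @export
print.bimr_benchmark <- function(x, ...) {
  writeLines(render_results_table(x))
  invisible(x)
}

#' Scenario grids of the simulation study
#'
#' The packaged configurations of the three simulation scenarios: blocks of
#' instrument counts with their per-instrument effect sizes, crossed with the
#' true effect pairs. Scenario 1 is the unidirectional model (reverse effect
#' 0) with strong and weak instrument blocks; scenarios 2 and 3 are the
#' bidirectional model with strong and weak instruments respectively. All
#' blocks share MAF 0.3, confounder N(1,1) with effects 0.3, unit intercepts
#' and error SDs, and n = 1000.
#'
#' @param scenario 1, 2 or 3.
#' @return A data frame with columns `scenario`, `model`, `n_instruments`,
#'   `beta`, `gamma12`, `gamma21`.
#' @export
scenario_grid <- function(scenario) {
  stopifnot(scenario %in% 1:3)
  path <- system.file("extdata", "scenarios",
                      sprintf("scenario%d.yaml", scenario),
                      package = "feedbackMR")
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$blocks, function(b) {
    do.call(rbind, lapply(cfg$gamma_pairs, function(g)
      data.frame(scenario = scenario, model = cfg$model,
                 n_instruments = b$n_instruments, beta = b$beta,
                 gamma12 = g[[1]], gamma21 = g[[2]])))
  }))
}

#' Run one scenario cell of the simulation study
#'
#' Convenience wrapper turning one row of [scenario_grid()] (or equivalent
#' arguments) into a [run_benchmark()] call with the study's shared
#' parameters.
#'
#' @param model `"umr"` or `"bmr"`.
#' @param n_instruments Instruments per trait.
#' @param beta Per-instrument effect size (both traits).
#' @param gamma12,gamma21 True causal effects.
#' @param n Cohort size (default 1000).
#' @param ... Passed on to [run_benchmark()] (`methods`, `n_reps`,
#'   `base_seed`, `confounder_visible`).
#' @return A `bimr_benchmark` data frame.
#' @export
benchmark_cell <- function(model, n_instruments, beta, gamma12, gamma21 = 0,
                           n = 1000, ...) {
  params <- bmr_params(gamma12 = gamma12, gamma21 = gamma21,
                       beta11 = beta, beta22 = beta,
                       k1 = n_instruments, k2 = n_instruments, n = n)
  run_benchmark(params, model = model, ...)
}
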