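#' Fit bidirectional causal effects between two traits
#'
#' Main fitting function. Estimates the two directed causal effects
#' (trait 1 on trait 2 and trait 2 on trait 1) from a one-sample cohort with
#' per-trait instrument sets, using one of four estimators:
#'
#' * `"biliml"` (default) — feedback-aware limited information maximum
#'   likelihood; robust to many weak instruments. See [biliml()].
#' * `"biratio"` — feedback-aware cross-instrument adjusted IVW ratio.
#'   See [biratio()].
#' * `"liml"`, `"ratio"` — the naive unidirectional counterparts, provided
#'   as comparators; biased when the traits truly cause each other.
#'
#' The latent confounder stored in simulated cohorts is never used unless
#' `include_confounder = TRUE`, mirroring the MR premise that confounding is
#' unmeasured.
#'
#' @param data A [bimr_dataset()] cohort.
#' @param method Estimator name (see above).
#' @param covariates Optional n x p matrix of observed covariates to adjust
#'   for; defaults to the cohort's own `covariates` component.
#' @param include_confounder Also adjust for the stored latent confounder
#'   (diagnostic mode for simulated data).
#' @return An object of class `bimr` with components `est12`, `est21`
#'   (`causal_estimate`s), `method`, `n`, `mean_f1`, `mean_f2` (mean marginal
#'   first-stage F of each instrument set), `var_explained1`,
#'   `var_explained2` (variance of each exposure explained by its instrument
#'   set beyond the covariates), and `call`.
#' @seealso [summary.bimr()], [coef.bimr()], [confint.bimr()]
#' @export
#' @examples
#' p <- bmr_params(gamma12 = -1.9, gamma21 = 0.5, beta11 = 2, beta22 = 2,
#'                 k1 = 20, k2 = 20)
#' dat <- simulate_bmr(p, seed = 1)
#' fit <- bimr(dat, method = "biliml")
#' coef(fit)
bimr <- function(data, method = c("biliml", "biratio", "liml", "ratio"),
                 covariates = NULL, include_confounder = FALSE) {
  method <- match.arg(method)
  data <- validate_dataset(data)
  if (is.null(covariates)) covariates <- data$covariates
  if (include_confounder) {
    if (is.null(data$confounder))
      stop("include_confounder = TRUE but the cohort carries no confounder")
    covariates <- cbind(covariates, confounder = data$confounder)
  }
  ests <- switch(method,
                 ratio   = naive_bidirectional_ratio(data, covariates),
                 biratio = biratio(data, covariates),
                 liml    = naive_liml(data, covariates),
                 biliml  = biliml(data, covariates))
  structure(list(
    est12 = ests$est12, est21 = ests$est21,
    method = method, n = length(data$y1),
    k1 = ncol(data$X1), k2 = ncol(data$X2),
    mean_f1 = .mean_instrument_f(data, 1),
    mean_f2 = .mean_instrument_f(data, 2),
    var_explained1 = .instrument_r2(data$y1, data$X1, covariates),
    var_explained2 = .instrument_r2(data$y2, data$X2, covariates),
    call = match.call()
  ), class = "bimr")
}

# Variance of the exposure explained by its instrument set beyond the
# covariates: R^2(exposure ~ covariates + instruments) - R^2(exposure ~
# covariates).
.instrument_r2 <- function(y, X, covariates = NULL) {
  n <- length(y)
  r2 <- function(design) {
    res <- qr.resid(qr(design), y)
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  base <- cbind(rep(1, n), covariates)
  r2(cbind(base, X)) - r2(base)
}

#' @export
print.bimr <- function(x, digits = 4, ...) {
  cat(sprintf("Bidirectional MR fit (method: %s, n = %d)\n", x$method, x$n))
  for (e in list(x$est12, x$est21))
    cat(sprintf("  %s: %.*f (95%% CI %.*f to %.*f), p = %.3g\n",
                e$direction, digits, e$estimate, digits, e$ci_low,
                digits, e$ci_high, e$p_value))
  invisible(x)
}

#' @export
coef.bimr <- function(object, ...) {
  c(gamma12 = object$est12$estimate, gamma21 = object$est21$estimate)
}

#' @export
confint.bimr <- function(object, parm, level = 0.95, ...) {
  m <- rbind(gamma12 = c(object$est12$ci_low, object$est12$ci_high),
             gamma21 = c(object$est21$ci_low, object$est21$ci_high))
  colnames(m) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Summarise a bidirectional MR fit
#'
#' One row per causal direction: estimate, standard error, 95% confidence
#' interval, two-sided p-value, the mean marginal first-stage F-statistic of
#' the direction's instrument set and the variance of the exposure explained
#' by its instruments (beyond covariates).
#'
#' @param object A `bimr` fit.
#' @param ... Unused.
#' @return A data frame of class `summary.bimr`.
#' @export
summary.bimr <- function(object, ...) {
  rows <- data.frame(
    direction = c("1->2", "2->1"),
    method = object$method,
    estimate = c(object$est12$estimate, object$est21$estimate),
    se = c(object$est12$se, object$est21$se),
    ci_low = c(object$est12$ci_low, object$est21$ci_low),
    ci_high = c(object$est12$ci_high, object$est21$ci_high),
    p_value = c(object$est12$p_value, object$est21$p_value),
    mean_f = c(object$mean_f1, object$mean_f2),
    var_explained = c(object$var_explained1, object$var_explained2)
  )
  if (!is.null(object$est12$k_hat))
    rows$k_hat <- c(object$est12$k_hat, object$est21$k_hat)
  class(rows) <- c("summary.bimr", "data.frame")
  attr(rows, "n") <- object$n
  rows
}

#' @export
print.summary.bimr <- function(x, ...) {
  cat(sprintf("Bidirectional causal effect estimates (n = %d)\n\n", attr(x, "n")))
  out <- data.frame(
    Direction = x$direction,
    Method = x$method,
    `Estimation (95% CI)` = sprintf("%.4f (%.4f to %.4f)",
                                    x$estimate, x$ci_low, x$ci_high),
    `P-value` = sprintf("%.3g", x$p_value),
    `Mean F` = sprintf("%.2f", x$mean_f),
    `Variance explained` = sprintf("%.2f%%", 100 * x$var_explained),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  invisible(x)
}
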