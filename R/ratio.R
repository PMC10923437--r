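# One directed causal-effect estimate. Internal constructor shared by the
# ratio and k-class families.
.causal_estimate <- function(direction, method, estimate, se,
                             ci_low, ci_high, p_value,
                             k_hat = NULL, per_instrument = NULL) {
  stopifnot(se > 0, is.finite(estimate))
  # guard against underflow: p-values live in (0, 1]
  p_value <- max(p_value, .Machine$double.xmin)
  structure(list(direction = direction, method = method,
                 estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 k_hat = k_hat, per_instrument = per_instrument),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%s): %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
              x$direction, x$method, x$estimate, x$ci_low, x$ci_high,
              x$p_value))
  if (!is.null(x$k_hat)) cat(sprintf("  k-class eigenvalue k = %.6f\n", x$k_hat))
  invisible(x)
}

#' Single-instrument ratio estimate of one directed effect
#'
#' The causal effect of the exposure trait on the outcome trait is estimated
#' as the ratio of two regression coefficients on the same instrument:
#' (outcome on instrument) / (exposure on instrument). With `adjust_cross =
#' TRUE` both regressions additionally adjust for the complete
#' opposite-direction instrument set, which is what makes the ratio
#' feedback-aware: under mutual causation the reduced-form coefficients both
#' carry the factor 1/(1 - gamma12*gamma21), which cancels in the ratio. The
#' standard error is first-order delta method: sqrt(var(numerator)) /
#' |denominator|.
#'
#' @param data A `bimr_data` cohort.
#' @param direction `"1->2"` (trait 1 exposure) or `"2->1"`.
#' @param instrument Index into the exposure trait's instrument set.
#' @param adjust_cross Adjust both regressions for the opposite instrument
#'   set (the feedback-aware variant)?
#' @param covariates Optional adjustment matrix applied to both regressions.
#' @param min_denominator Absolute threshold below which the
#'   exposure-instrument coefficient is treated as zero and an error raised
#'   (irrelevant instrument; avoids silent sign flips).
#' @return A `causal_estimate`.
#' @export
ratio_single <- function(data, direction = c("1->2", "2->1"), instrument = 1L,
                         adjust_cross = FALSE, covariates = NULL,
                         min_denominator = 1e-8) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "bimr_data"))
  if (direction == "1->2") {
    exposure <- data$y1; outcome <- data$y2; Xe <- data$X1; Xo <- data$X2
  } else {
    exposure <- data$y2; outcome <- data$y1; Xe <- data$X2; Xo <- data$X1
  }
  if (instrument < 1 || instrument > ncol(Xe)) stop("invalid instrument index")
  adj <- if (adjust_cross) cbind(covariates, Xo) else covariates
  num <- focal_ols(outcome, Xe[, instrument], adj)
  den <- focal_ols(exposure, Xe[, instrument], adj)
  if (abs(den$coefficient) < min_denominator)
    stop("instrument ", instrument, " is irrelevant for the exposure ",
         "(|denominator coefficient| < ", format(min_denominator), ")")
  ivw_combine(list(c(num$coefficient, den$coefficient, num$variance)),
              direction = direction,
              method = if (adjust_cross) "biratio" else "ratio")
}

#' Inverse-variance weighted combination of per-instrument ratio estimates
#'
#' Combines per-instrument (numerator coefficient, denominator coefficient,
#' numerator variance) triples into one effect estimate:
#' \deqn{\hat\gamma = \frac{\sum_i b_{y,i} b_{x,i} / v_i}{\sum_i b_{x,i}^2 / v_i},
#'       \quad SE = \sqrt{1 / \sum_i b_{x,i}^2 / v_i}}
#' with a Wald 95% interval and a two-sided standard-normal p-value. With a
#' single triple this reduces exactly to the single-instrument ratio and its
#' delta-method standard error.
#'
#' @param triples List of numeric length-3 vectors `(numerator coefficient,
#'   denominator coefficient, numerator variance)`, one per instrument.
#' @param direction,method Labels stored on the returned estimate.
#' @return A `causal_estimate` carrying the triples in `$per_instrument`.
#' @export
ivw_combine <- function(triples, direction = "1->2", method = "ratio") {
  if (length(triples) < 1L) stop("at least one per-instrument triple is required")
  m <- do.call(rbind, lapply(triples, function(t) {
    if (length(t) != 3L) stop("each triple must have 3 elements")
    as.numeric(t)
  }))
  num <- m[, 1]; den <- m[, 2]; v <- m[, 3]
  if (any(v <= 0)) stop("numerator variances must be positive")
  w <- den^2 / v
  est <- sum(num * den / v) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  .causal_estimate(direction, method, est, se,
                   ci_low = est - stats::qnorm(0.975) * se,
                   ci_high = est + stats::qnorm(0.975) * se,
                   p_value = 2 * stats::pnorm(-abs(z)),
                   per_instrument = m)
}

# Shared worker for one direction of the ratio family. Marginal per-instrument
# regressions (one instrument at a time) with a common adjustment set; the
# feedback-aware variant adds the opposite instrument set to the adjustments.
.ratio_direction <- function(data, direction, adjust_cross, covariates) {
  if (direction == "1->2") {
    exposure <- data$y1; outcome <- data$y2; Xe <- data$X1; Xo <- data$X2
  } else {
    exposure <- data$y2; outcome <- data$y1; Xe <- data$X2; Xo <- data$X1
  }
  adj <- if (adjust_cross) cbind(covariates, Xo) else covariates
  num <- .marginal_focal(outcome, Xe, adj)
  den <- .marginal_focal(exposure, Xe, adj)
  triples <- lapply(seq_len(ncol(Xe)), function(i)
    c(num$coefficient[i], den$coefficient[i], num$variance[i]))
  ivw_combine(triples, direction = direction,
              method = if (adjust_cross) "biratio" else "ratio")
}

#' Naive bidirectional application of the IVW ratio method
#'
#' Applies the unidirectional per-instrument IVW ratio independently in each
#' direction, ignoring the feedback loop — the comparator that mutual
#' causation biases. Regressions are marginal (one instrument at a time) with
#' no cross-instrument adjustment.
#'
#' @param data A `bimr_data` cohort.
#' @param covariates Optional adjustment matrix.
#' @return List with `est12` and `est21`, both `causal_estimate`s.
#' @export
naive_bidirectional_ratio <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "bimr_data"))
  list(est12 = .ratio_direction(data, "1->2", FALSE, covariates),
       est21 = .ratio_direction(data, "2->1", FALSE, covariates))
}

#' Feedback-aware bidirectional IVW ratio (BiRatio)
#'
#' As [naive_bidirectional_ratio()], but every per-instrument regression
#' additionally adjusts for the complete opposite-direction instrument set,
#' so the estimated numerator and denominator are reduced-form coefficients
#' of the converged feedback system and their common feedback factor cancels
#' in the ratio.
#'
#' @inheritParams naive_bidirectional_ratio
#' @return List with `est12` and `est21`.
#' @export
biratio <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "bimr_data"))
  list(est12 = .ratio_direction(data, "1->2", TRUE, covariates),
       est21 = .ratio_direction(data, "2->1", TRUE, covariates))
}
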