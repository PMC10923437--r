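#' Ordinary least squares focused on one predictor
#'
#' Fits `response ~ 1 + focal + adjustments` by QR-decomposed least squares
#' and reports the focal coefficient with its sampling variance, the residual
#' variance, the residual degrees of freedom and the focal F-statistic
#' `(coefficient / SE)^2`. This is the shared primitive behind every ratio
#' regression and instrument-strength diagnostic.
#'
#' @param response Numeric response vector.
#' @param focal Numeric predictor of interest.
#' @param adjustments Optional matrix of adjustment covariates (no intercept
#'   column; one is always added).
#' @return A list of class `focal_fit` with components `coefficient`,
#'   `variance`, `residual_variance`, `df`, `f_statistic`.
#' @export
focal_ols <- function(response, focal, adjustments = NULL) {
  n <- length(response)
  if (length(focal) != n) stop("length mismatch between response and focal")
  if (!is.null(adjustments)) {
    adjustments <- as.matrix(adjustments)
    if (nrow(adjustments) != n) stop("length mismatch in adjustments")
  }
  X <- cbind(`(Intercept)` = 1, focal = focal, adjustments)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design: adjustments are collinear with the focal predictor or each other")
  coefs <- qr.coef(qx, response)
  resid <- response - drop(X %*% coefs)
  df <- n - ncol(X)
  if (df < 1) stop("not enough observations for the requested design")
  s2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  v <- s2 * xtx_inv[2, 2]
  f <- if (v > 0) coefs[2]^2 / v else Inf
  structure(list(coefficient = unname(coefs[2]), variance = unname(v),
                 residual_variance = s2, df = df, f_statistic = unname(f)),
            class = "focal_fit")
}

# Marginal focal regressions of one response on each column of Fmat, all
# sharing the same adjustment set. Frisch-Waugh-Lovell: residualise response
# and instruments on [1, A] once, then each marginal fit is a one-predictor
# regression of the residuals. Returns per-column coefficient, variance and F,
# identical to focal_ols(response, Fmat[, i], A) (tested against it).
.marginal_focal <- function(response, Fmat, adjustments = NULL) {
  n <- length(response)
  A <- cbind(rep(1, n), adjustments)
  qa <- qr(A)
  if (qa$rank < ncol(A)) stop("rank-deficient adjustment set")
  yr <- qr.resid(qa, response)
  Fr <- qr.resid(qa, Fmat)
  ss <- colSums(Fr^2)
  if (any(ss <= 0)) stop("instrument collinear with the adjustment set")
  coef <- colSums(Fr * yr) / ss
  df <- n - ncol(A) - 1L
  rss <- sum(yr^2) - coef^2 * ss
  v <- (rss / df) / ss
  list(coefficient = coef, variance = v, df = df,
       f_statistic = ifelse(v > 0, coef^2 / v, Inf))
}

#' First-stage F-statistic of one instrument
#'
#' Strength of a single SNP as an instrument for its own trait: the
#' F-statistic of the trait regressed on the instrument dosage (optionally
#' covariate-adjusted). A simple-regression F is symmetric in which variable
#' is response, so regressing trait on instrument is equivalent to the
#' instrument-on-trait orientation. Instruments with F below 10 are
#' conventionally called weak.
#'
#' @param data A `bimr_data` cohort.
#' @param trait 1 or 2: which trait's instrument set to assess.
#' @param instrument Column index within that instrument set.
#' @param adjustments Optional adjustment matrix.
#' @return The F-statistic (may be `Inf` for a noiseless relationship).
#' @export
instrument_f <- function(data, trait, instrument, adjustments = NULL) {
  stopifnot(inherits(data, "bimr_data"), trait %in% c(1, 2))
  X <- if (trait == 1) data$X1 else data$X2
  y <- if (trait == 1) data$y1 else data$y2
  if (instrument < 1 || instrument > ncol(X)) stop("invalid instrument index")
  focal_ols(y, X[, instrument], adjustments)$f_statistic
}

# Mean marginal first-stage F across an instrument set (the per-table
# diagnostic reported next to every benchmark cell).
.mean_instrument_f <- function(data, trait) {
  X <- if (trait == 1) data$X1 else data$X2
  y <- if (trait == 1) data$y1 else data$y2
  mean(.marginal_focal(y, X)$f_statistic)
}
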