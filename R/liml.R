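#' Assemble a k-class (LIML) estimation problem
#'
#' Sets up one directed structural equation for k-class estimation. The
#' structural design is `[1, included, endogenous]`; the full instrument
#' design is `W = [1, included, excluded]`; the restricted design
#' `C* = [1, included]` drops the excluded instruments. Annihilator products
#' (`M_W v = v - P_W v`, and likewise for `C*`) are computed through QR
#' decompositions of the designs, never as explicit n x n matrices.
#'
#' @param outcome Response vector of the structural equation.
#' @param endogenous The endogenous regressor (the other trait).
#' @param excluded n x k matrix of excluded instruments (the exposure's own
#'   set; they enter `W` but not the structural design). At least one column.
#' @param included Optional matrix of included exogenous columns (covariates
#'   and, in the feedback-aware variant, the opposite instrument set).
#' @return A list of class `kclass_problem` with the QR factorisations and
#'   design matrices needed by [kappa_hat()] and [kclass_solve()].
#' @export
kclass_problem <- function(outcome, endogenous, excluded, included = NULL) {
  n <- length(outcome)
  excluded <- as.matrix(excluded)
  if (ncol(excluded) < 1L)
    stop("degenerate direction: no excluded instruments for the endogenous regressor")
  if (!is.null(included)) included <- as.matrix(included)
  stopifnot(length(endogenous) == n, nrow(excluded) == n,
            is.null(included) || nrow(included) == n)
  Cstar <- cbind(rep(1, n), included)
  W <- cbind(Cstar, excluded)
  qr_w <- qr(W); qr_c <- qr(Cstar)
  if (qr_w$rank < ncol(W))
    stop("rank-deficient instrument design W (collinear instruments/covariates)")
  X <- cbind(Cstar, endogenous)
  structure(list(outcome = outcome, endogenous = endogenous,
                 X = X, qr_w = qr_w, qr_c = qr_c, n = n,
                 n_excluded = ncol(excluded)),
            class = "kclass_problem")
}

#' LIML eigenvalue of a k-class problem
#'
#' Returns the smallest eigenvalue of
#' \deqn{(Y^T M_W Y)^{-1/2}\, Y^T M_{C^*} Y\, (Y^T M_W Y)^{-1/2}}
#' where `Y = [outcome, endogenous]`, `M_W` and `M_{C*}` are the annihilators
#' of the full and restricted instrument designs. Because the column span of
#' `C*` is nested in that of `W`, every eigenvalue is at least 1; the smallest
#' one maximises the limited-information likelihood and equals the minimum
#' over gamma of the variance ratio
#' `(y - gamma x)' M_C* (y - gamma x) / (y - gamma x)' M_W (y - gamma x)`.
#'
#' @param problem A [kclass_problem()].
#' @return The scalar eigenvalue `k_hat >= 1`.
#' @export
kappa_hat <- function(problem) {
  stopifnot(inherits(problem, "kclass_problem"))
  Y <- cbind(problem$outcome, problem$endogenous)
  Mw_Y <- qr.resid(problem$qr_w, Y)
  Mc_Y <- qr.resid(problem$qr_c, Y)
  A <- crossprod(Mw_Y)          # Y' M_W Y (M idempotent)
  B <- crossprod(Mc_Y)          # Y' M_C* Y
  ea <- eigen(A, symmetric = TRUE)
  if (min(ea$values) <= sqrt(.Machine$double.eps) * max(ea$values))
    stop("Y' M_W Y is not positive definite (outcome and regressor collinear given W)")
  Ah <- ea$vectors %*% diag(1 / sqrt(ea$values), 2) %*% t(ea$vectors)
  k <- min(eigen(Ah %*% B %*% Ah, symmetric = TRUE, only.values = TRUE)$values)
  max(k, 1)  # nested projections guarantee k >= 1 up to rounding
}

#' Solve a k-class problem
#'
#' Closed-form k-class estimate of the structural equation
#' \deqn{\hat b = (X^T (I - k M_W) X)^{-1} X^T (I - k M_W) y}
#' with `k = k_hat` (LIML) by default; `k = 1` gives two-stage least squares
#' and `k = 0` ordinary least squares. The covariance is
#' `sigma^2 (X'(I - k M_W) X)^{-1}` with `sigma^2` estimated from the
#' structural residuals on `n - ncol(X)` degrees of freedom; the confidence
#' interval and p-value use t quantiles on those degrees of freedom.
#'
#' @param problem A [kclass_problem()].
#' @param k The k-class parameter; defaults to [kappa_hat()].
#' @param direction,method Labels stored on the returned estimate.
#' @param level Confidence level (default 0.95).
#' @return A `causal_estimate` for the endogenous regressor's coefficient,
#'   carrying `k` in `$k_hat`.
#' @export
kclass_solve <- function(problem, k = NULL, direction = "1->2",
                         method = "biliml", level = 0.95) {
  stopifnot(inherits(problem, "kclass_problem"))
  if (is.null(k)) k <- kappa_hat(problem)
  X <- problem$X; y <- problem$outcome
  Mw_X <- qr.resid(problem$qr_w, X)
  Mw_y <- qr.resid(problem$qr_w, y)
  XtX_k <- crossprod(X) - k * crossprod(Mw_X)
  Xty_k <- crossprod(X, y) - k * crossprod(Mw_X, Mw_y)
  b <- tryCatch(solve(XtX_k, Xty_k),
                error = function(e) stop("singular k-class system: ",
                                         conditionMessage(e)))
  resid <- y - drop(X %*% b)
  p <- ncol(X)
  df <- problem$n - p
  s2 <- sum(resid^2) / df
  cov <- s2 * solve(XtX_k)
  est <- b[p]
  se <- sqrt(max(cov[p, p], 0))
  if (se <= 0) se <- .Machine$double.eps
  tq <- stats::qt((1 + level) / 2, df)
  tstat <- est / se
  .causal_estimate(direction, method, est, se,
                   ci_low = est - tq * se, ci_high = est + tq * se,
                   p_value = 2 * stats::pt(-abs(tstat), df),
                   k_hat = k)
}

# One direction of the LIML family. The naive variant omits the opposite
# instrument set entirely (unidirectional specification); the feedback-aware
# variant includes it as exogenous columns of both W and the structural design.
.liml_direction <- function(data, direction, bidirectional, covariates) {
  if (direction == "1->2") {
    outcome <- data$y2; endogenous <- data$y1; Xown <- data$X1; Xopp <- data$X2
  } else {
    outcome <- data$y1; endogenous <- data$y2; Xown <- data$X2; Xopp <- data$X1
  }
  included <- if (bidirectional) cbind(covariates, Xopp) else covariates
  prob <- kclass_problem(outcome, endogenous, excluded = Xown,
                         included = included)
  kclass_solve(prob, direction = direction,
               method = if (bidirectional) "biliml" else "liml")
}

#' Naive bidirectional application of the LIML method
#'
#' Estimates each directed effect with the unidirectional LIML specification:
#' the exposure's own instruments are the excluded instruments and the
#' opposite trait's instruments are omitted entirely. Under mutual causation
#' this mis-specifies both equations and biases the estimates.
#'
#' @param data A `bimr_data` cohort.
#' @param covariates Optional matrix of included exogenous covariates.
#' @return List with `est12` and `est21`, both `causal_estimate`s.
#' @export
naive_liml <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "bimr_data"))
  list(est12 = .liml_direction(data, "1->2", FALSE, covariates),
       est21 = .liml_direction(data, "2->1", FALSE, covariates))
}

#' Feedback-aware bidirectional LIML (BiLIML)
#'
#' Estimates each directed effect from the structural equation of the
#' feedback system paired with the converged reduced form of the other trait.
#' For the effect of trait 1 on trait 2: the structural design is
#' `[1, covariates, X2, y1]`, the full instrument design
#' `W = [1, covariates, X2, X1]`, and the restricted design
#' `C* = [1, covariates, X2]`; trait 2's instruments are included exogenous
#' columns while trait 1's are the excluded instruments. The direction
#' trait 2 on trait 1 mirrors this with the roles exchanged.
#'
#' @inheritParams naive_liml
#' @return List with `est12` and `est21`.
#' @export
biliml <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "bimr_data"))
  list(est12 = .liml_direction(data, "1->2", TRUE, covariates),
       est21 = .liml_direction(data, "2->1", TRUE, covariates))
}
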