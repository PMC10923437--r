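#' Structural parameters of the bidirectional MR model
#'
#' Collects every coefficient of the two-trait structural system
#' \deqn{Y_1 = \beta_{01} + \beta_{11} X_1 + \beta_{CY1} C + \gamma_{21} Y_2 + \epsilon_1}
#' \deqn{Y_2 = \beta_{02} + \beta_{22} X_2 + \beta_{CY2} C + \gamma_{12} Y_1 + \epsilon_2}
#' together with the genotype and noise settings needed to simulate from it.
#' Setting `gamma21 = 0` gives the unidirectional model (trait 1 causes
#' trait 2 only). The feedback loop induced by mutual causation converges only
#' when `|gamma12 * gamma21| < 1`; that condition is checked where it is
#' needed ([reduced_form()], [simulate_bmr()]), not here, so that
#' unidirectional configurations are never over-constrained.
#'
#' @param gamma12 Causal effect of trait 1 on trait 2 (unitless).
#' @param gamma21 Causal effect of trait 2 on trait 1.
#' @param beta11 Vector of instrument effects on trait 1 (length `k1`, one per
#'   SNP in the trait-1 instrument set). A scalar is recycled via `rep()` when
#'   `k1` is given.
#' @param beta22 Vector of instrument effects on trait 2 (length `k2`).
#' @param k1,k2 Optional instrument counts used to recycle scalar `beta11` /
#'   `beta22`.
#' @param beta01,beta02 Intercepts.
#' @param beta_c_y1,beta_c_y2 Effects of the confounder on each trait.
#' @param confounder_mean,confounder_sd Moments of the normal confounder.
#' @param maf Minor allele frequency of every instrument, in (0, 0.5].
#' @param n Cohort size (>= 10).
#' @param error_sd1,error_sd2 SDs of the structural errors (default 1,
#'   i.e. standard-normal errors).
#'
#' @return An object of class `bmr_params` (a named list).
#' @seealso [reduced_form()], [simulate_bmr()], [simulate_umr()]
#' @export
#' @examples
#' p <- bmr_params(gamma12 = -1.9, gamma21 = 0.5, beta11 = 2, beta22 = 2,
#'                 k1 = 20, k2 = 20)
#' reduced_form(p)$alpha11[1]  # 2 / (1 - (-1.9 * 0.5))
bmr_params <- function(gamma12, gamma21 = 0,
                       beta11 = 1, beta22 = 1, k1 = NULL, k2 = NULL,
                       beta01 = 1, beta02 = 1,
                       beta_c_y1 = 0.3, beta_c_y2 = 0.3,
                       confounder_mean = 1, confounder_sd = 1,
                       maf = 0.3, n = 1000,
                       error_sd1 = 1, error_sd2 = 1) {
  if (!is.null(k1)) {
    if (length(beta11) == 1L) beta11 <- rep(beta11, k1)
    if (length(beta11) != k1) stop("length(beta11) must equal k1")
  }
  if (!is.null(k2)) {
    if (length(beta22) == 1L) beta22 <- rep(beta22, k2)
    if (length(beta22) != k2) stop("length(beta22) must equal k2")
  }
  stopifnot(length(gamma12) == 1L, length(gamma21) == 1L,
            is.finite(gamma12), is.finite(gamma21))
  if (length(beta11) < 1L || length(beta22) < 1L)
    stop("each trait needs at least one instrument effect (k1 >= 1, k2 >= 1)")
  if (!(maf > 0 && maf <= 0.5)) stop("maf must lie in (0, 0.5]")
  if (n < 10) stop("n must be at least 10")
  if (error_sd1 <= 0 || error_sd2 <= 0 || confounder_sd <= 0)
    stop("all standard deviations must be positive")
  structure(list(
    gamma12 = gamma12, gamma21 = gamma21,
    beta01 = beta01, beta02 = beta02,
    beta11 = as.numeric(beta11), beta22 = as.numeric(beta22),
    beta_c_y1 = beta_c_y1, beta_c_y2 = beta_c_y2,
    confounder_mean = confounder_mean, confounder_sd = confounder_sd,
    maf = maf, n = as.integer(n),
    error_sd1 = error_sd1, error_sd2 = error_sd2
  ), class = "bmr_params")
}

#' @export
print.bmr_params <- function(x, ...) {
  cat("Bidirectional MR structural parameters\n")
  cat(sprintf("  gamma12 = %g, gamma21 = %g (|product| = %g)\n",
              x$gamma12, x$gamma21, abs(x$gamma12 * x$gamma21)))
  cat(sprintf("  instruments: k1 = %d (beta11 ~ %g), k2 = %d (beta22 ~ %g), MAF = %g\n",
              length(x$beta11), x$beta11[1], length(x$beta22), x$beta22[1], x$maf))
  cat(sprintf("  confounder N(%g, %g^2) with effects (%g, %g); error SDs (%g, %g); n = %d\n",
              x$confounder_mean, x$confounder_sd, x$beta_c_y1, x$beta_c_y2,
              x$error_sd1, x$error_sd2, x$n))
  invisible(x)
}

#' Converged reduced form of the bidirectional structural model
#'
#' Solves the two-equation feedback system for the phenotypes, yielding each
#' trait as a linear function of both instrument sets, the confounder and a
#' composite error. Writing `d = 1 - gamma12 * gamma21`, the trait-1 equation
#' has own-instrument coefficients `alpha11 = beta11 / d`, cross-instrument
#' coefficients `gamma23 = gamma21 * beta22 / d`, confounder coefficient
#' `(beta_c_y1 + gamma21 * beta_c_y2) / d`, and composite error
#' `delta1 = (eps1 + gamma21 * eps2) / d`; trait 2 mirrors with subscripts
#' exchanged. The feedback loop converges to this form only when
#' `|gamma12 * gamma21| < 1`.
#'
#' @param params A [bmr_params()] object.
#' @return An object of class `reduced_form` with components `alpha01`,
#'   `alpha02`, `alpha_c_y1`, `alpha_c_y2`, `alpha11`, `alpha22`, `gamma13`,
#'   `gamma23`, `delta1_sd`, `delta2_sd`, `delta_corr`.
#' @export
reduced_form <- function(params) {
  stopifnot(inherits(params, "bmr_params"))
  g12 <- params$gamma12; g21 <- params$gamma21
  if (abs(g12 * g21) >= 1)
    stop("non-convergent feedback loop: |gamma12 * gamma21| = ",
         format(abs(g12 * g21)), " >= 1")
  d <- 1 - g12 * g21
  s1 <- params$error_sd1; s2 <- params$error_sd2
  delta1_sd <- sqrt(s1^2 + g21^2 * s2^2) / abs(d)
  delta2_sd <- sqrt(s2^2 + g12^2 * s1^2) / abs(d)
  delta_cov <- (g12 * s1^2 + g21 * s2^2) / d^2
  structure(list(
    alpha01 = (params$beta01 + g21 * params$beta02) / d,
    alpha02 = (params$beta02 + g12 * params$beta01) / d,
    alpha_c_y1 = (params$beta_c_y1 + g21 * params$beta_c_y2) / d,
    alpha_c_y2 = (params$beta_c_y2 + g12 * params$beta_c_y1) / d,
    alpha11 = params$beta11 / d,
    alpha22 = params$beta22 / d,
    gamma13 = g12 * params$beta11 / d,
    gamma23 = g21 * params$beta22 / d,
    delta1_sd = delta1_sd,
    delta2_sd = delta2_sd,
    delta_corr = delta_cov / (delta1_sd * delta2_sd)
  ), class = "reduced_form")
}
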