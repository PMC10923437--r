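#' Simulate SNP dosages under Hardy-Weinberg proportions
#'
#' Each dosage is the sum of two independent Bernoulli(maf) allele draws,
#' i.e. Binomial(2, maf), so genotype frequencies follow Hardy-Weinberg
#' proportions ((1-p)^2, 2p(1-p), p^2) and column means converge to 2*maf.
#' Instruments are mutually independent (no linkage disequilibrium).
#'
#' @param n Number of individuals (>= 1).
#' @param k Number of SNPs (>= 1).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return An n x k integer dosage matrix with entries in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, k, maf, seed = NULL) {
  if (length(n) != 1L || n < 1) stop("n must be a positive count")
  if (length(k) != 1L || k < 1) stop("k must be a positive count")
  if (!(maf > 0 && maf <= 0.5)) stop("maf must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rbinom(n * k, size = 2L, prob = maf), nrow = n, ncol = k)
}

# Shared draw pathway for both generative models. Order matters: X1, X2, C,
# eps1, eps2, so that a bidirectional run with gamma21 = 0 consumes the random
# stream identically to a unidirectional run and yields the same cohort.
.draw_inputs <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  list(
    X1 = simulate_genotypes(n, length(params$beta11), params$maf),
    X2 = simulate_genotypes(n, length(params$beta22), params$maf),
    C  = stats::rnorm(n, params$confounder_mean, params$confounder_sd),
    eps1 = stats::rnorm(n, 0, params$error_sd1),
    eps2 = stats::rnorm(n, 0, params$error_sd2)
  )
}

#' Simulate a cohort from the unidirectional structural model
#'
#' Trait 1 is generated from its own instruments and the confounder only;
#' trait 2 receives its own instruments, the confounder and the causal
#' contribution `gamma12 * y1`. There is no feedback (`gamma21` is ignored and
#' treated as 0).
#'
#' @param params A [bmr_params()] object.
#' @param seed Optional integer seed.
#' @return A `bimr_data` cohort; the confounder is retained for diagnostics.
#' @export
simulate_umr <- function(params, seed = NULL) {
  stopifnot(inherits(params, "bmr_params"))
  d <- .draw_inputs(params, seed)
  y1 <- params$beta01 + drop(d$X1 %*% params$beta11) +
    params$beta_c_y1 * d$C + d$eps1
  y2 <- params$beta02 + drop(d$X2 %*% params$beta22) +
    params$beta_c_y2 * d$C + params$gamma12 * y1 + d$eps2
  bimr_dataset(y1, y2, d$X1, d$X2, confounder = d$C)
}

#' Simulate a cohort from the bidirectional structural model
#'
#' Draws genotypes, confounder and structural errors, then evaluates the
#' converged reduced form of the feedback system directly (closed form; see
#' [reduced_form()]). The composite errors are built from the same structural
#' error draws, so with `gamma21 = 0` the cohort is identical to
#' [simulate_umr()] under the same seed.
#'
#' @inheritParams simulate_umr
#' @return A `bimr_data` cohort.
#' @export
simulate_bmr <- function(params, seed = NULL) {
  stopifnot(inherits(params, "bmr_params"))
  rf <- reduced_form(params)  # errors out if |gamma12*gamma21| >= 1
  d <- .draw_inputs(params, seed)
  dd <- 1 - params$gamma12 * params$gamma21
  delta1 <- (d$eps1 + params$gamma21 * d$eps2) / dd
  delta2 <- (d$eps2 + params$gamma12 * d$eps1) / dd
  y1 <- rf$alpha01 + drop(d$X1 %*% rf$alpha11) + drop(d$X2 %*% rf$gamma23) +
    rf$alpha_c_y1 * d$C + delta1
  y2 <- rf$alpha02 + drop(d$X1 %*% rf$gamma13) + drop(d$X2 %*% rf$alpha22) +
    rf$alpha_c_y2 * d$C + delta2
  bimr_dataset(y1, y2, d$X1, d$X2, confounder = d$C)
}

#' Simulate a cohort from either generative model
#'
#' @inheritParams simulate_umr
#' @param model `"bmr"` for the bidirectional feedback model, `"umr"` for the
#'   unidirectional model.
#' @return A `bimr_data` cohort.
#' @export
simulate_cohort <- function(params, model = c("bmr", "umr"), seed = NULL) {
  model <- match.arg(model)
  if (model == "bmr") simulate_bmr(params, seed) else simulate_umr(params, seed)
}

#' Fixed-point iteration of the structural feedback loop
#'
#' Independent route to the bidirectional phenotypes: starting from zero,
#' alternately applies the two structural equations on given noise draws until
#' successive phenotype values change by less than `tol`. When
#' `|gamma12 * gamma21| < 1` this geometric recursion converges to the same
#' limit as the closed-form reduced form, which is the central correctness
#' property of the simulation engine.
#'
#' @param params A [bmr_params()] object.
#' @param eps1,eps2 Structural error draws (length n).
#' @param C Confounder draw (length n).
#' @param X1,X2 Dosage matrices matching `params`.
#' @param tol Convergence tolerance on the max absolute change (default 1e-10).
#' @param max_iter Iteration cap; exceeded only for non-convergent loops.
#' @return A list with components `y1`, `y2` and `iterations`.
#' @export
fixed_point_phenotypes <- function(params, eps1, eps2, C, X1, X2,
                                   tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(params, "bmr_params"))
  g1 <- params$beta01 + drop(X1 %*% params$beta11) + params$beta_c_y1 * C + eps1
  g2 <- params$beta02 + drop(X2 %*% params$beta22) + params$beta_c_y2 * C + eps2
  y1 <- numeric(length(g1)); y2 <- numeric(length(g2))
  for (it in seq_len(max_iter)) {
    y1_new <- g1 + params$gamma21 * y2
    y2_new <- g2 + params$gamma12 * y1_new
    delta <- max(abs(y1_new - y1), abs(y2_new - y2))
    y1 <- y1_new; y2 <- y2_new
    if (delta < tol) return(list(y1 = y1, y2 = y2, iterations = it))
  }
  stop("feedback loop did not converge within ", max_iter,
       " iterations (|gamma12 * gamma21| = ",
       format(abs(params$gamma12 * params$gamma21)), ")")
}
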