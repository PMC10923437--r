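# Independent oracles and small fixture builders used across the suite.
# These deliberately use the most transparent (explicit-matrix, brute-force)
# formulations so they stay independent of the package's computational paths.

# OLS via explicit normal equations.
ols_oracle <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Two-stage least squares via the explicit projection P_W = W (W'W)^-1 W'.
tsls_oracle <- function(y, X, W) {
  PW <- W %*% solve(t(W) %*% W) %*% t(W)
  drop(solve(t(X) %*% PW %*% X, t(X) %*% PW %*% y))
}

# LIML eigenvalue via 1-d minimisation of the variance-ratio objective
# kappa(g) = (y - g x)' M_Cstar (y - g x) / (y - g x)' M_W (y - g x),
# using explicit n x n annihilators.
kappa_grid_oracle <- function(y, x, W, Cstar, lower = -50, upper = 50) {
  n <- length(y)
  M <- function(A) diag(n) - A %*% solve(t(A) %*% A) %*% t(A)
  Mw <- M(W); Mc <- M(Cstar)
  obj <- function(g) {
    r <- y - g * x
    drop(t(r) %*% Mc %*% r) / drop(t(r) %*% Mw %*% r)
  }
  stats::optimize(obj, c(lower, upper), tol = 1e-10)$objective
}

# A noiseless bidirectional cohort: phenotypes generated exactly from the
# reduced form with zero structural errors and no confounder effect, so
# every consistent estimator must recover the truth exactly.
noiseless_bmr <- function(gamma12, gamma21, k1 = 1, k2 = 1, n = 60,
                          beta1 = 1, beta2 = 1, seed = 99) {
  p <- bmr_params(gamma12 = gamma12, gamma21 = gamma21,
                  beta11 = beta1, beta22 = beta2, k1 = k1, k2 = k2,
                  beta_c_y1 = 0, beta_c_y2 = 0, n = n)
  set.seed(seed)
  X1 <- simulate_genotypes(n, k1, 0.3)
  X2 <- simulate_genotypes(n, k2, 0.3)
  rf <- reduced_form(p)
  y1 <- rf$alpha01 + drop(X1 %*% rf$alpha11) + drop(X2 %*% rf$gamma23)
  y2 <- rf$alpha02 + drop(X1 %*% rf$gamma13) + drop(X2 %*% rf$alpha22)
  bimr_dataset(y1, y2, X1, X2)
}

# Random valid bidirectional parameters with |gamma12*gamma21| < 1.
random_params <- function(seed) {
  set.seed(seed)
  repeat {
    g12 <- stats::runif(1, -1.9, 1.9)
    g21 <- stats::runif(1, -0.95, 0.95)
    if (abs(g12 * g21) < 0.98) break
  }
  bmr_params(gamma12 = g12, gamma21 = g21,
             beta11 = stats::runif(2, 0.5, 2), beta22 = stats::runif(3, 0.5, 2),
             beta01 = stats::rnorm(1), beta02 = stats::rnorm(1),
             beta_c_y1 = stats::runif(1, -0.5, 0.5),
             beta_c_y2 = stats::runif(1, -0.5, 0.5),
             error_sd1 = stats::runif(1, 0.5, 2),
             error_sd2 = stats::runif(1, 0.5, 2),
             n = 40)
}

# Minimal VCF text fixture written to a temp file.
write_test_vcf <- function(path, with_missing = FALSE, with_ds = FALSE) {
  gt <- function(...) paste(..., sep = "\t")
  fmt <- if (with_ds) "GT:DS" else "GT"
  g <- function(gtv, dsv) if (with_ds) paste0(gtv, ":", dsv) else gtv
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ds) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    gt("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
       "SAMP1", "SAMP2", "SAMP3"),
    gt("1", "100", "rs1", "A", "G", ".", "PASS", ".", fmt,
       g("0/1", "0.73"), g("1|1", "2.0"), g("0/0", "0.1")),
    gt("1", "200", "rs2", "C", "T", ".", "PASS", ".", fmt,
       g("0/0", "0.0"), g(if (with_missing) "./." else "0/1", "1.0"),
       g("1/1", "1.9"))
  )
  writeLines(lines, path)
  path
}
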