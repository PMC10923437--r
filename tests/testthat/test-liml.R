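# Small random k-class instances shared across the checks below.
make_instance <- function(seed, k_excl = 3, k_incl = 1, n = 40) {
  set.seed(seed)
  Z <- matrix(rnorm(n * k_excl), n, k_excl)
  A <- if (k_incl > 0) matrix(rnorm(n * k_incl), n, k_incl) else NULL
  x <- drop(Z %*% runif(k_excl, 0.3, 1)) + rnorm(n)
  y <- 0.7 * x + rnorm(n) + if (k_incl > 0) drop(A %*% rep(0.5, k_incl)) else 0
  list(y = y, x = x, Z = Z, A = A,
       prob = kclass_problem(y, x, excluded = Z, included = A))
}

test_that("the LIML eigenvalue equals the variance-ratio minimiser and is at least 1", {
  for (s in 1:12) {
    inst <- make_instance(s)
    k <- kappa_hat(inst$prob)
    expect_gte(k, 1)
    Cstar <- cbind(1, inst$A)
    W <- cbind(Cstar, inst$Z)
    oracle <- kappa_grid_oracle(inst$y, inst$x, W, Cstar)
    expect_equal(k, oracle, tolerance = 1e-6)
  }
})

test_that("annihilators are idempotent and nested: y'M_W y <= y'M_C* y", {
  for (s in 1:8) {
    inst <- make_instance(20 + s)
    n <- length(inst$y)
    Cstar <- cbind(1, inst$A); W <- cbind(Cstar, inst$Z)
    Mw <- diag(n) - W %*% solve(crossprod(W)) %*% t(W)
    expect_equal(Mw %*% Mw, Mw, tolerance = 1e-9)
    expect_equal(Mw, t(Mw), tolerance = 1e-12)
    # QR-based annihilator product matches the explicit matrix formula
    expect_equal(qr.resid(inst$prob$qr_w, inst$y), drop(Mw %*% inst$y),
                 tolerance = 1e-10)
    qmw <- sum(qr.resid(inst$prob$qr_w, inst$y)^2)
    qmc <- sum(qr.resid(inst$prob$qr_c, inst$y)^2)
    expect_lte(qmw, qmc + 1e-10)
  }
})

test_that("just-identified LIML equals the single-instrument ratio exactly", {
  for (s in 1:6) {
    p <- bmr_params(gamma12 = runif(1, -1.5, 1.5), gamma21 = 0,
                    beta11 = 1, beta22 = 1, n = 200)
    d <- simulate_umr(p, seed = 60 + s)
    prob <- kclass_problem(d$y2, d$y1, excluded = d$X1)
    liml <- kclass_solve(prob)
    ratio <- ratio_single(d, "1->2", 1)
    expect_equal(liml$estimate, ratio$estimate, tolerance = 1e-10)
    expect_equal(kappa_hat(prob), 1, tolerance = 1e-8)
  }
})

test_that("k-class with k = 1 reproduces brute-force two-stage least squares", {
  for (s in 1:8) {
    inst <- make_instance(40 + s)
    fit <- kclass_solve(inst$prob, k = 1)
    X <- cbind(1, inst$A, inst$x)
    W <- cbind(1, inst$A, inst$Z)
    b <- tsls_oracle(inst$y, X, W)
    expect_equal(fit$estimate, b[length(b)], tolerance = 1e-9)
    expect_equal(fit$k_hat, 1)
  }
})

test_that("noiseless structural equations are recovered exactly by BiLIML", {
  d <- noiseless_bmr(gamma12 = -1.9, gamma21 = -0.5, k1 = 2, k2 = 2, n = 80)
  fit <- biliml(d)
  expect_equal(fit$est12$estimate, -1.9, tolerance = 1e-8)
  expect_equal(fit$est21$estimate, -0.5, tolerance = 1e-8)
})

test_that("swap symmetry holds for both LIML variants", {
  p <- bmr_params(gamma12 = 0.9, gamma21 = -0.4, beta11 = c(1, 1.5),
                  beta22 = c(0.8, 1.2), n = 300)
  d <- simulate_bmr(p, seed = 71)
  s <- swap_traits(d)
  for (fitter in list(naive_liml, biliml)) {
    a <- fitter(d); b <- fitter(s)
    expect_identical(a$est12$estimate, b$est21$estimate)
    expect_identical(a$est21$estimate, b$est12$estimate)
    expect_identical(a$est12$k_hat, b$est21$k_hat)
  }
})

test_that("degenerate and singular problems are rejected with clear errors", {
  y <- rnorm(30); x <- rnorm(30)
  expect_error(kclass_problem(y, x, excluded = matrix(nrow = 30, ncol = 0)),
               "degenerate direction")
  Z <- matrix(rnorm(30), 30, 1)
  expect_error(kclass_problem(y, x, excluded = Z, included = Z),
               "rank-deficient")
  # outcome collinear with the endogenous regressor given W
  expect_error(kappa_hat(kclass_problem(2 * x, x, excluded = Z)),
               "positive definite")
})

test_that("many weak instruments leave LIML near-unbiased while the ratio drifts", {
  p <- bmr_params(gamma12 = 1.9, gamma21 = 0, beta11 = 0.05, beta22 = 0.05,
                  k1 = 100, k2 = 100, n = 1000)
  liml_est <- ratio_est <- numeric(40)
  for (r in 1:40) {
    d <- simulate_umr(p, seed = 700 + r)
    liml_est[r] <- naive_liml(d)$est12$estimate
    ratio_est[r] <- naive_bidirectional_ratio(d)$est12$estimate
  }
  expect_lt(abs(median(liml_est) - 1.9), 0.05)
  expect_gt(abs(median(ratio_est) - 1.9), abs(median(liml_est) - 1.9))
})
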