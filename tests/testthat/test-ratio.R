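test_that("IVW combination reproduces hand-computed values", {
  # two instruments, unit weights: (1*1 + 3*1) / (1 + 1) = 2
  est <- ivw_combine(list(c(1, 1, 1), c(3, 1, 1)))
  expect_equal(est$estimate, 2)
  expect_equal(est$se, sqrt(1 / 2))

  # a single triple reduces to the plain ratio with delta-method SE
  one <- ivw_combine(list(c(1.2, 0.6, 0.04)))
  expect_equal(one$estimate, 1.2 / 0.6)
  expect_equal(one$se, sqrt(0.04) / 0.6)

  # m identical triples: same estimate, SE shrinks by 1/sqrt(m)
  m <- 9
  rep9 <- ivw_combine(rep(list(c(1.2, 0.6, 0.04)), m))
  expect_equal(rep9$estimate, one$estimate)
  expect_equal(rep9$se, one$se / sqrt(m))

  expect_error(ivw_combine(list()), "at least one")
  expect_error(ivw_combine(list(c(1, 1, 0))), "positive")
  expect_error(ivw_combine(list(c(1, 1))), "3 elements")
})

test_that("single-instrument ratio equals the IVW path and flags irrelevant instruments", {
  p <- bmr_params(gamma12 = 0.8, gamma21 = 0.4, beta11 = 1, beta22 = 1, n = 300)
  d <- simulate_bmr(p, seed = 41)
  rs <- ratio_single(d, "1->2", 1)
  ivw <- naive_bidirectional_ratio(d)$est12
  expect_equal(rs$estimate, ivw$estimate, tolerance = 1e-12)
  expect_equal(rs$se, ivw$se, tolerance = 1e-12)

  # an instrument orthogonal to the exposure triggers the denominator guard
  d2 <- d
  d2$y1 <- qr.resid(qr(cbind(1, drop(d$X1))), d$y1)  # exactly uncorrelated
  expect_error(ratio_single(d2, "1->2", 1), "irrelevant")
})

test_that("noiseless data are recovered exactly by the ratio family", {
  # unidirectional with no cross-instrument effect: plain ratio of exact
  # coefficients
  du <- noiseless_bmr(gamma12 = 1.9, gamma21 = 0, beta2 = 0)
  expect_equal(ratio_single(du, "1->2", 1)$estimate, 1.9, tolerance = 1e-9)

  # bidirectional: after cross adjustment the estimated coefficients are the
  # reduced-form pair (-1.9/0.05, 1/0.05) and the feedback factors cancel
  db <- noiseless_bmr(gamma12 = -1.9, gamma21 = -0.5)
  expect_equal(ratio_single(db, "1->2", 1, adjust_cross = TRUE)$estimate,
               -1.9, tolerance = 1e-9)
  expect_equal(ratio_single(db, "2->1", 1, adjust_cross = TRUE)$estimate,
               -0.5, tolerance = 1e-9)

  # multi-instrument noiseless: both feedback-aware directions exact
  dm <- noiseless_bmr(gamma12 = 0.9, gamma21 = -0.6, k1 = 3, k2 = 2, n = 80)
  fit <- biratio(dm)
  expect_equal(fit$est12$estimate, 0.9, tolerance = 1e-8)
  expect_equal(fit$est21$estimate, -0.6, tolerance = 1e-8)
})

test_that("swapping the traits exchanges the two directed ratio estimates bit-for-bit", {
  p <- bmr_params(gamma12 = -1.2, gamma21 = 0.6, beta11 = c(1, 2), beta22 = c(2, 1),
                  n = 400)
  d <- simulate_bmr(p, seed = 43)
  s <- swap_traits(d)
  for (fitter in list(naive_bidirectional_ratio, biratio)) {
    a <- fitter(d); b <- fitter(s)
    expect_identical(a$est12$estimate, b$est21$estimate)
    expect_identical(a$est21$estimate, b$est12$estimate)
    expect_identical(a$est12$se, b$est21$se)
  }
})

test_that("unidirectional data give a null reverse estimate and matching forward estimates", {
  p <- bmr_params(gamma12 = 1.9, gamma21 = 0, beta11 = 1, beta22 = 1, n = 1000)
  est12 <- est21 <- bi12 <- bi21 <- numeric(60)
  for (r in 1:60) {
    d <- simulate_umr(p, seed = 500 + r)
    nv <- naive_bidirectional_ratio(d)
    bi <- biratio(d)
    est12[r] <- nv$est12$estimate; est21[r] <- nv$est21$estimate
    bi12[r] <- bi$est12$estimate; bi21[r] <- bi$est21$estimate
  }
  expect_equal(median(est12), 1.9, tolerance = 0.03)
  expect_equal(median(est21), 0, tolerance = 0.05)
  expect_equal(median(bi12), 1.9, tolerance = 0.03)
  expect_equal(median(bi21), 0, tolerance = 0.05)
})
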