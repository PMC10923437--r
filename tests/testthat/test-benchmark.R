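test_that("median absolute bias matches hand-computed values and its half-normal limit", {
  expect_equal(mab(c(1.8, 1.9, 2.0), 1.9), 0.1)
  expect_equal(mab(rep(2.5, 5), 1.9), 0.6)
  expect_error(mab(numeric(0), 1), "at least one")

  # estimates ~ Normal(truth, sigma): MAB converges to the half-normal median
  set.seed(8)
  sigma <- 0.7
  expect_equal(mab(rnorm(40000, 1.9, sigma), 1.9),
               stats::qnorm(0.75) * sigma, tolerance = 0.02)
})

test_that("relative median absolute bias is undefined exactly at a zero truth", {
  expect_equal(rmab(0.1, 1.9), 0.1 / 1.9)
  expect_equal(rmab(0, 1.9), 0)
  expect_true(is.na(rmab(0.1, 0)))
  expect_false(is.na(rmab(0.1, 1e-12)))
})

test_that("a single-replicate benchmark reduces to the single estimate", {
  p <- bmr_params(gamma12 = -0.9, gamma21 = 0.3, beta11 = 1, beta22 = 1, n = 300)
  res <- run_benchmark(p, "bmr", methods = "biliml", n_reps = 1, base_seed = 5)
  d <- simulate_bmr(p, seed = 6)  # base_seed + 1
  fit <- biliml(d)
  r12 <- res[res$direction == "1->2", ]
  expect_equal(r12$median_estimate, fit$est12$estimate)
  expect_equal(r12$mab, abs(fit$est12$estimate - (-0.9)))
  expect_equal(r12$rmab, r12$mab / 0.9)
})

test_that("benchmarks are bit-identical under a repeated base seed", {
  p <- bmr_params(gamma12 = 0.9, gamma21 = -0.5, beta11 = 1, beta22 = 1, n = 200)
  a <- run_benchmark(p, "bmr", methods = c("ratio", "biliml"), n_reps = 5,
                     base_seed = 17)
  b <- run_benchmark(p, "bmr", methods = c("ratio", "biliml"), n_reps = 5,
                     base_seed = 17)
  expect_identical(a, b)
})

test_that("estimator failures are counted without contaminating other methods", {
  p <- bmr_params(gamma12 = 0.9, gamma21 = 0.2, beta11 = 1, beta22 = c(1, 1),
                  n = 100)
  # duplicate trait-2 instrument column: the rank-deficient cross-adjusted
  # designs break BiRatio, while plain marginal ratio regressions survive
  real_sim <- simulate_cohort
  testthat::local_mocked_bindings(
    simulate_cohort = function(params, model = "bmr", seed = NULL) {
      d <- real_sim(params, model, seed)
      d$X2[, 2] <- d$X2[, 1]
      d
    },
    .package = "feedbackMR"
  )
  res <- run_benchmark(p, "bmr", methods = c("ratio", "biratio"), n_reps = 3,
                       base_seed = 9)
  expect_equal(res$n_fail[res$method == "biratio"], c(3L, 3L))
  expect_true(all(is.na(res$median_estimate[res$method == "biratio"])))
  expect_equal(res$n_fail[res$method == "ratio"], c(0L, 0L))
  expect_true(all(is.finite(res$median_estimate[res$method == "ratio"])))
})

test_that("the results table renders the reported precision and undefined cells", {
  p <- bmr_params(gamma12 = 1.9, gamma21 = 0, beta11 = 1, beta22 = 1, n = 400)
  res <- run_benchmark(p, "umr", methods = c("ratio", "biliml"), n_reps = 3,
                       base_seed = 11)
  lines <- render_results_table(res)
  expect_length(lines, 3L)
  # reverse direction has truth 0: RMAB rendered as "-"
  expect_match(lines[3], "-", fixed = TRUE)
  # medians and MAB carry two decimals
  expect_match(lines[2], "\\d\\.\\d\\d")
  expect_error(render_results_table(res[0, ]), "no summaries")
})

test_that("scenario grids load the packaged study configurations", {
  g1 <- scenario_grid(1)
  expect_true(all(g1$gamma21 == 0))
  expect_true(all(g1$model == "umr"))
  expect_setequal(unique(g1$n_instruments), c(1, 20, 100))
  g3 <- scenario_grid(3)
  expect_true(all(g3$model == "bmr"))
  expect_true(all(g3$beta <= 0.05))
  expect_equal(nrow(g3), 5 * 4)
  expect_error(scenario_grid(4))
})

test_that("the confounder-visible mode adjusts for C and runs end to end", {
  p <- bmr_params(gamma12 = -0.9, gamma21 = 0.5, beta11 = 1, beta22 = 1, n = 300)
  res <- run_benchmark(p, "bmr", methods = "biliml", n_reps = 3, base_seed = 13,
                       confounder_visible = TRUE)
  expect_true(all(is.finite(res$median_estimate)))
})
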