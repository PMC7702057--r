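test_that("instantaneous growth matches hand evaluation and rejects bad input", {
  expect_identical(instantaneous_growth(1, 1, 10), 0)
  expect_equal(instantaneous_growth(1, 2, 7), log(2) / 7, tolerance = 1e-12)
  expect_equal(instantaneous_growth(2, 1, 5), -log(2) / 5, tolerance = 1e-12)
  expect_error(instantaneous_growth(0, 1, 5), "positive")
  expect_error(instantaneous_growth(1, -1, 5), "positive")
  expect_error(instantaneous_growth(1, 2, 0), "positive")
})

test_that("growth identity round-trips final mass to machine precision", {
  W1 <- exp(runif(50, -4, 2)); W2 <- exp(runif(50, -4, 2)); dt <- runif(50, 5, 30)
  g <- instantaneous_growth(W1, W2, dt)
  expect_equal(W1 * exp(g * dt), W2, tolerance = 1e-12)
})

test_that("cohort bootstrap is positive, degenerate when forced, and order-invariant", {
  d <- bootstrap_cohort_growth(rep(1, 10), rep(2, 8), 7, n_boot = 200, seed = 1)
  expect_boot_equal(d, log(2) / 7)
  expect_equal(unname(diff(ci(d))), 0)
  # overlapping distributions: constraint forces every replicate positive
  ov <- bootstrap_cohort_growth(c(1, 2, 3), c(1.5, 2.5, 3.5), 10,
                                n_boot = 300, seed = 2)
  expect_gt(min(ov$replicates), 0)
  # permuting individuals leaves the distribution unchanged (same seed)
  a <- bootstrap_cohort_growth(c(1, 2, 3, 4), c(3, 4, 5), 10, n_boot = 100, seed = 9)
  b <- bootstrap_cohort_growth(c(4, 2, 1, 3), c(5, 3, 4), 10, n_boot = 100, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_error(bootstrap_cohort_growth(c(2, 3), c(1, 1.5), 7),
               "no valid cohort")
  expect_error(bootstrap_cohort_growth(numeric(0), 1, 7), "non-empty")
})

test_that("cohort bootstrap mean matches brute-force enumeration", {
  # resample size 1 per date: g in {ln2/10, ln4/10} with equal probability
  d1 <- bootstrap_cohort_growth(1, c(2, 4), 10, n_boot = 1e5, seed = 3,
                                resample_size = 1)
  expect_lt(abs(mean(d1) - (log(2) + log(4)) / 20),
            3 * sd(d1$replicates) / sqrt(1e5))
  expect_setequal(round(unique(d1$replicates), 10),
                  round(c(log(2) / 10, log(4) / 10), 10))
  # observed-count resampling: mean final mass in {2,3,4} w.p. {1/4,1/2,1/4}
  d2 <- bootstrap_cohort_growth(1, c(2, 4), 10, n_boot = 2e4, seed = 4)
  exact <- (log(2) + 2 * log(3) + log(4)) / 40
  expect_lt(abs(mean(d2) - exact), 3 * sd(d2$replicates) / sqrt(2e4))
})

test_that("growth model recovers noise-free coefficients exactly", {
  obs <- make_exact_growth()
  fit <- fit_growth_model(obs)
  expect_equal(fit$a, -0.25, tolerance = 1e-8)
  expect_equal(fit$E_ind, 0.65, tolerance = 1e-8)
  expect_equal(fit$intercept, -3.5, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_excluded, 0L)
})

test_that("growth model excludes non-positive growth and flags collinearity", {
  obs <- make_exact_growth()
  shrunk <- obs[1, ]; shrunk$W_t_dt_mg <- shrunk$W_t_mg * 0.8  # mass loss
  fit <- fit_growth_model(rbind(obs, shrunk))
  expect_equal(fit$n_excluded, 1L)
  expect_equal(fit$a, -0.25, tolerance = 1e-8)
  one_temp <- make_exact_growth(temp_C = rep(12, 6))
  expect_error(fit_growth_model(one_temp), "collinear")
})

test_that("prediction obeys closed-form scaling and the fixed-point property", {
  fit <- fit_growth_model(make_exact_growth())
  # both regressors zero at M = 1 mg, 15 C
  expect_equal(predict(fit, 1, 15), exp(fit$intercept), tolerance = 1e-10)
  # a = -0.25: a 16-fold mass increase halves growth at fixed temperature
  expect_equal(predict(fit, 16, 10) / predict(fit, 1, 10), 0.5, tolerance = 1e-8)
  # refitting on noise-free predictions is a fixed point
  M <- c(0.1, 0.4, 1.2, 3); tc <- c(6, 11, 19, 24)
  g <- predict(fit, M, tc)
  refit <- fit_growth_model(data.frame(g = g, M_mg = M, temp_C = tc))
  expect_equal(coef(refit), coef(fit), tolerance = 1e-8)
})

test_that("stream-scoped model gives per-stream intercepts and predictions", {
  obs <- rbind(make_exact_growth(), make_exact_growth(ln_i0 = -3.0))
  obs$stream_id <- rep(c("cold", "warm"), each = 6)
  fit <- fit_growth_model(obs, scope = "stream")
  expect_equal(unname(fit$stream_intercepts["cold"]), -3.5, tolerance = 1e-8)
  expect_equal(unname(fit$stream_intercepts["warm"]), -3.0, tolerance = 1e-8)
  expect_equal(predict(fit, 1, 15, stream_id = "warm"), exp(-3), tolerance = 1e-8)
  expect_error(predict(fit, 1, 15, stream_id = "nope"), "unknown stream")
})

test_that("growth-model CIs cover the truth at nominal rate under noise", {
  n_seeds <- 40; hits_a <- hits_E <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    M <- exp(runif(300, -3, 2)); tc <- runif(300, 4, 28)
    x <- standardize_temperature(tc)
    g <- exp(-3.5 - 0.25 * log(M) + 0.65 * x + rnorm(300, 0, 0.4))
    fit <- fit_growth_model(data.frame(g = g, M_mg = M, temp_C = tc))
    cc <- confint(fit)
    hits_a <- hits_a + (cc["a", 1] <= -0.25 && -0.25 <= cc["a", 2])
    hits_E <- hits_E + (cc["E_ind", 1] <= 0.65 && 0.65 <= cc["E_ind", 2])
  }
  expect_gte(hits_a, 0.85 * n_seeds)
  expect_gte(hits_E, 0.85 * n_seeds)
})
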