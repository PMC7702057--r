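test_that("annual chlorophyll bootstrap: constant input, enumeration, unbiasedness", {
  chla <- data.frame(stream_id = "s1", date = rep(c(10, 40, 70), each = 2),
                     stone_id = rep(1:2, 3), chla_mg_m2 = 5)
  b <- annual_chla_bootstrap(chla, n_boot = 200, seed = 1)
  expect_boot_equal(b$s1, 5)
  # one stone per date, date means {2, 4, 6}: replicates are means of three
  # draws with replacement, i.e. multiples of 2/3 in [2, 6], expectation 4
  chla2 <- data.frame(stream_id = "s1", date = c(10, 40, 70), stone_id = 1,
                      chla_mg_m2 = c(2, 4, 6))
  b2 <- annual_chla_bootstrap(chla2, n_boot = 5000, seed = 2)$s1
  v <- b2$replicates
  expect_true(all(abs(v * 3 / 2 - round(v * 3 / 2)) < 1e-9))
  expect_true(all(v >= 2 & v <= 6))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(b2) - 4), 3 * se)
  expect_error(annual_chla_bootstrap(chla2[1:2, ]), "fewer than 3")
})

test_that("AICc matches hand arithmetic, its limit, and its guard", {
  expect_equal(aicc(-10, 3, 10), 30)
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-10, 9, 10), "undefined")
  # AICc is always above AIC for finite n
  expect_gt(aicc(-5, 2, 20), -2 * -5 + 2 * 2)
})

test_that("chla-driven production selects the resource model, corrected E covers 0", {
  set.seed(21)
  x <- seq(-1.45, 1.63, length.out = 6)
  lnchla <- rnorm(6, 2, 0.8)                 # resources unrelated to temperature
  P <- lapply(exp(1.2 * lnchla - 2), function(m) boot_dist(m * exp(rnorm(50, 0, 0.1))))
  chla <- lapply(exp(lnchla), function(m) boot_dist(m * exp(rnorm(50, 0, 0.1))))
  sel <- among_stream_selection(P, x, chla, n_rep = 300, seed = 4)
  expect_equal(sum(sel$freq), 1, tolerance = 1e-12)
  expect_equal(sel$modal, "chla")
  q <- ci(sel$E_corrected)
  expect_true(q[1] <= 0 && 0 <= q[2])
})

test_that("temperature-driven production selects the temperature model", {
  set.seed(22)
  x <- seq(-1.45, 1.63, length.out = 6)
  P <- lapply(exp(0.7 * x), function(m) boot_dist(m * exp(rnorm(50, 0, 0.05))))
  chla <- lapply(exp(rnorm(6, 2, 0.05)), function(m)
    boot_dist(m * exp(rnorm(50, 0, 0.05))))
  sel <- among_stream_selection(P, x, chla, n_rep = 300, seed = 5)
  expect_equal(sel$modal, "temp")
  expect_lt(abs(mean(sel$E_apparent) - 0.7), 0.15)
})

test_that("among-stream selection is deterministic given data and seed", {
  x <- seq(-1, 1, length.out = 4)
  P <- lapply(exp(x), function(m) boot_dist(m * exp(seq(-0.1, 0.1, length.out = 5))))
  ch <- lapply(1:4, function(i) boot_dist(rep(3, 5)))
  s1 <- among_stream_selection(P, x, ch, n_rep = 50, seed = 7)
  s2 <- among_stream_selection(P, x, ch, n_rep = 50, seed = 7)
  expect_identical(s1$freq, s2$freq)
  expect_identical(s1$E_corrected$replicates, s2$E_corrected$replicates)
})

test_that("within-stream selection recovers a strong additive structure", {
  set.seed(31)
  streams <- rep(c("a", "b", "c"), each = 8)
  x <- rep(seq(-0.8, 1, length.out = 8), 3)
  light <- exp(rnorm(24, 5, 0.6))
  lnchla <- rnorm(24, 2, 0.5)
  icpt <- c(a = 0, b = 1, c = -1)[streams]
  lnP <- icpt + 1.5 * x + 0.8 * lnchla + 0.5 * log(light) + rnorm(24, 0, 0.1)
  d <- data.frame(stream_id = streams, x = x, light = light)
  Pd <- lapply(exp(lnP), function(m) boot_dist(m * exp(rnorm(30, 0, 0.08))))
  ch <- lapply(exp(lnchla), function(m) boot_dist(m * exp(rnorm(30, 0, 0.08))))
  sel <- within_stream_selection(d, Pd, ch, n_rep = 30, seed = 6)
  expect_setequal(strsplit(sel$modal, " \\+ ")[[1]],
                  c("temp", "lnchla", "lnlight"))
  q <- ci(sel$E_within)
  expect_true(q[1] <= 1.5 && 1.5 <= q[2])
  expect_equal(sum(sel$freq), 1, tolerance = 1e-12)
})

test_that("a no-signal mixture selects the null fixed-effect structure", {
  set.seed(32)
  streams <- rep(c("a", "b"), each = 8)
  d <- data.frame(stream_id = streams,
                  x = rep(seq(-0.5, 0.5, length.out = 8), 2),
                  light = exp(rnorm(16, 5, 0.5)))
  icpt <- c(a = 0.5, b = -0.5)[streams]
  Pd <- lapply(exp(icpt + rnorm(16, 0, 0.05)), function(m)
    boot_dist(m * exp(rnorm(30, 0, 0.05))))
  ch <- lapply(exp(rnorm(16, 1, 0.4)), function(m)
    boot_dist(m * exp(rnorm(30, 0, 0.05))))
  sel <- within_stream_selection(d, Pd, ch, n_rep = 30, seed = 7)
  expect_equal(sel$modal, "null")
  expect_null(sel$E_within)
})

test_that("GPP model recovers noise-free coefficients and guards input", {
  set.seed(41)
  tc <- runif(12, 5, 25); x <- standardize_temperature(tc)
  light <- exp(rnorm(12, 5, 0.5)); chla <- exp(rnorm(12, 2, 0.4))
  gpp <- exp(0.5 + 1.37 * x + 1.0 * log(light) + 0.5 * log(chla))
  d <- data.frame(gpp = gpp, light = light, chla = chla, temp_C = tc)
  fit <- fit_gpp_model(d, n_boot = 200, seed = 1)
  expect_equal(unname(fit$coefficients["x"]), 1.37, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["log(light)"]), 1.0, tolerance = 1e-8)
  expect_lt(diff(unname(ci(fit$E_gpp))), 1e-6)
  expect_error(fit_gpp_model(d[1:5, ]), "at least 8")
  d$gpp[1] <- 0
  expect_error(fit_gpp_model(d), "non-positive")
})

test_that("resource correction is the independent-draw difference", {
  Ep <- boot_dist(rep(1.52, 10)); Egpp <- boot_dist(rep(1.37, 10))
  cor1 <- resource_correct_within(Ep, Egpp, n_boot = 100, seed = 1)
  expect_equal(cor1$E_mean, 0.15, tolerance = 1e-12)
  expect_equal(cor1$ci_high - cor1$ci_low, 0, tolerance = 1e-12)
  # identical distributions: difference centred on zero
  set.seed(2)
  z <- boot_dist(rnorm(2000, 0.8, 0.2))
  cor2 <- resource_correct_within(z, z, n_boot = 5000, seed = 3)
  se <- sd(cor2$slopes$replicates) / sqrt(5000)
  expect_lt(abs(cor2$E_mean), 3 * se + 0.02)
})
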