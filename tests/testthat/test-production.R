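test_that("interval production matches hand arithmetic and identities", {
  expect_identical(interval_production(0, 100, 200, 30), 0)
  expect_equal(interval_production(0.05, 100, 200, 30), 225)
  # constant biomass: P = g * dt * B exactly
  expect_equal(interval_production(0.02, 150, 150, 10), 0.02 * 10 * 150)
  expect_error(interval_production(-0.01, 1, 1, 1), "negative growth")
  expect_error(interval_production(0.1, -1, 1, 1), "non-negative")
  # boot_dist inputs stay paired
  g <- boot_dist(c(0.01, 0.02)); B <- boot_dist(c(100, 200))
  expect_equal(interval_production(g, B, B, 10)$replicates, c(10, 40))
})

test_that("identical replicate samples give a zero-width biomass distribution", {
  s <- make_samples(rep(4, 5), mass_mg = 2)
  bb <- biomass_from_samples(s, 1, n_boot = 200, seed = 1)
  expect_boot_equal(boot_dist(as.numeric(bb$B)), 4 / 0.023 * 2)
  expect_error(biomass_from_samples(s, 99), "no samples")
})

test_that("biomass bootstrap matches the binomial enumeration oracle", {
  # counts {0,0,0,0,10} at 1 mg: value = (k/5) * 10/0.023, k ~ Bin(5, 1/5)
  s <- make_samples(c(0, 0, 0, 0, 10))
  bb <- biomass_from_samples(s, 1, n_boot = 4000, seed = 2)
  v <- as.numeric(bb$B)
  unit <- 10 / 0.023 / 5
  expect_true(all(abs(v / unit - round(v / unit)) < 1e-9))
  se <- sd(v) / sqrt(length(v))
  expect_equal(mean(v), 10 / 0.023 / 5, tolerance = 3 * se / (10 / 0.023 / 5))
  # ~87.0 mg m^-2 as the expected community biomass
  expect_equal(10 / 0.023 / 5, 86.9565, tolerance = 1e-4)
})

test_that("subsample splits are expanded before resampling", {
  s1 <- make_samples(rep(8, 5), split_fraction = 1 / 4)
  s2 <- make_samples(rep(32, 5), split_fraction = 1)
  b1 <- biomass_from_samples(s1, 1, n_boot = 50, seed = 1)
  b2 <- biomass_from_samples(s2, 1, n_boot = 50, seed = 1)
  expect_equal(b1$B, b2$B)
})

test_that("population production reduces to the closed form when degenerate", {
  # two dates, identical replicates, growth from a noise-free model
  fit <- fit_growth_model(make_exact_growth())
  s <- rbind(make_samples(matrix(rep(5, 10), 2), dates = c(1, 31)))
  pop <- bootstrap_population_production(s, fit, interval_temp_C = 15,
                                         n_boot = 100, seed = 1)
  B <- 5 / 0.023 * 1
  g <- predict(fit, 1, 15)
  expect_boot_equal(boot_dist(pop$P[[1]]$tx1), g * 30 * B, tol = 1e-9)
})

test_that("community production is the exact replicate-wise sum over populations", {
  set.seed(42)
  counts1 <- matrix(rpois(10, 6), 2); counts2 <- matrix(rpois(10, 3), 2)
  s <- rbind(make_samples(counts1, taxon_id = "a", mass_mg = 0.5, dates = c(1, 31)),
             make_samples(counts2, taxon_id = "b", mass_mg = 1.5, dates = c(1, 31)))
  fit <- fit_growth_model(make_exact_growth())
  pop <- bootstrap_population_production(s, fit, interval_temp_C = 12,
                                         n_boot = 300, seed = 5)
  comm <- aggregate_community(pop)
  expect_equal(comm[[1]]$replicates, pop$P[[1]]$a + pop$P[[1]]$b, tolerance = 1e-12)
  # shuffling one population's replicates would break pairing: the pipeline
  # must never do it; the sum is order-sensitive while the mean is not
  shuffled <- pop$P[[1]]
  shuffled$a <- sample(shuffled$a)
  comm2 <- aggregate_community(list(shuffled))[[1]]
  expect_equal(mean(comm2), mean(comm[[1]]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(comm2$replicates, comm[[1]]$replicates)))
})

test_that("missing growth source fails loudly, naming the taxon", {
  s <- make_samples(matrix(rep(2, 10), 2), taxon_id = "mystery", dates = c(1, 31))
  expect_error(
    bootstrap_population_production(s, NULL, interval_temp_C = 10, n_boot = 10),
    "mystery")
})

test_that("measured growth distributions are used and resampled to n_boot", {
  s <- make_samples(matrix(rep(3, 10), 2), taxon_id = "coh", dates = c(1, 31))
  g_meas <- boot_dist(rep(0.01, 7))
  pop <- bootstrap_population_production(
    s, NULL, interval_temp_C = 10, n_boot = 50, seed = 1,
    measured_growth = list(coh = g_meas))
  B <- 3 / 0.023
  expect_boot_equal(boot_dist(pop$P[[1]]$coh), 0.01 * 30 * B, tol = 1e-9)
})

test_that("annual production sums intervals replicate-wise and warns on gaps", {
  p <- list(boot_dist(c(100, 200)), boot_dist(c(300, 500)))
  ann <- annual_production(p, dt_days = c(30, 30))
  expect_equal(ann$replicates, c(0.4, 0.7))  # g AFDM m^-2
  expect_warning(annual_production(p, dt_days = c(30, 60)), "gap")
  # constant daily production p over 365 d: annual = 365 p
  daily <- 2
  expect_equal(mean(annual_production(list(boot_dist(rep(daily * 365, 3))))),
               365 * daily / 1000)
})

test_that("P:B is the replicate-wise ratio with positivity enforced", {
  B <- boot_dist(c(10, 20, 40)); P <- B * 2
  expect_boot_equal(pb_ratio(P, B), 2)
  expect_equal((pb_ratio(P, B) * B)$replicates, P$replicates, tolerance = 1e-12)
  expect_error(pb_ratio(P, boot_dist(c(0, 1, 2))), "aggregate")
})

test_that("daily standardization recovers annual production replicate-wise", {
  p <- list(boot_dist(c(120, 240)), boot_dist(c(60, 90)))
  dt <- c(30, 20)
  daily <- lapply(seq_along(p), function(i) p[[i]] / dt[i])
  back <- bd_sum(lapply(seq_along(daily), function(i) daily[[i]] * dt[i]))
  expect_equal(back$replicates, bd_sum(p)$replicates, tolerance = 1e-12)
})

test_that("tiny two-point instance matches exhaustive enumeration", {
  # 2 size classes, two-point g and B distributions; enumeration over all
  # 2^3 equally likely combinations per class
  g1 <- c(0.01, 0.03); g2 <- c(0.02, 0.04)
  B1t <- c(50, 150); B1e <- c(100, 200); B2t <- c(20, 60); B2e <- c(40, 80)
  dt <- 25
  enum_mean <- function(g, Bt, Be) {
    combos <- expand.grid(g = g, Bt = Bt, Be = Be)
    mean(combos$g * dt * (combos$Bt + combos$Be) / 2)
  }
  exact <- enum_mean(g1, B1t, B1e) + enum_mean(g2, B2t, B2e)
  set.seed(11)
  n <- 1e5
  draw <- function(v) sample(v, n, replace = TRUE)
  P <- draw(g1) * dt * (draw(B1t) + draw(B1e)) / 2 +
    draw(g2) * dt * (draw(B2t) + draw(B2e)) / 2
  se <- sd(P) / sqrt(n)
  expect_equal(mean(P), exact, tolerance = 3 * se / exact)
})
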