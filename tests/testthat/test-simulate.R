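test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_streams = 1), "n_streams")
  expect_error(sim_config(mean_annual_temp_C = c(70, 10)), "plausible|\\[-2, 60\\]")
  expect_error(sim_config(mean_annual_temp_C = c(3, 10),
                          temp_seasonal_amplitude_C = 8), "below -2")
  expect_error(sim_config(noise_sd_log_chla = -1), "noise")
  expect_error(sim_config(sample_area_m2 = 0), "area")
})

test_that("a fixed seed reproduces the study bit-identically", {
  s1 <- simulate_study(sim_config(seed = 5))
  s2 <- simulate_study(sim_config(seed = 5))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$growth, s2$growth)
  expect_identical(s1$chla, s2$chla)
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$truth$P_annual_true_g, s2$truth$P_annual_true_g)
})

test_that("zero seasonal amplitude gives a constant temperature series", {
  cfg <- sim_config(seed = 2, temp_seasonal_amplitude_C = 0,
                    light_temp_correlation = 0)
  env <- simulate_environment(cfg)
  for (s in cfg$stream_ids) {
    tt <- env$temp_C[env$stream_id == s]
    expect_true(all(tt == tt[1]))
  }
  expect_equal(unique(env$temp_C[env$stream_id == "hver"]), 27.2)
})

test_that("realized light-temperature correlation hits its target", {
  n_ok <- 0; n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 300 + s, light_temp_correlation = 0.67)
    env <- simulate_environment(cfg)
    d <- env[env$stream_id == "st9", ]
    r <- cor(d$temp_C, d$light)
    n_ok <- n_ok + (r >= 0.52 && r <= 0.82)
  }
  expect_gte(n_ok, ceiling(0.95 * n_seeds))
  # annual mean is exact
  cfg <- sim_config(seed = 3)
  env <- simulate_environment(cfg)
  for (i in seq_along(cfg$stream_ids)) {
    expect_equal(mean(env$temp_C[env$stream_id == cfg$stream_ids[i]]),
                 cfg$mean_annual_temp_C[i], tolerance = 1e-9)
  }
})

test_that("noise-free chlorophyll sits exactly on the Boltzmann line", {
  cfg <- sim_config(seed = 4, noise_sd_log_chla = 0,
                    noise_sd_log_chla_stream = 0,
                    mean_annual_temp_C = c(15, unstandardize_temperature(1)),
                    n_streams = 2, stream_ids = c("ref", "warm"),
                    temp_seasonal_amplitude_C = 2)
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  ann <- aggregate(chla_mg_m2 ~ stream_id, ch, mean)
  ratio <- ann$chla_mg_m2[ann$stream_id == "warm"] /
    ann$chla_mg_m2[ann$stream_id == "ref"]
  expect_equal(ratio, exp(cfg$E_chla_true), tolerance = 1e-9)
  expect_true(all(ch$chla_mg_m2 > 0))
})

test_that("chlorophyll is never negative under heavy noise", {
  cfg <- sim_config(seed = 6, noise_sd_log_chla = 1.5)
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  expect_true(all(ch$chla_mg_m2 > 0))
})

test_that("community bookkeeping: taxon production sums to the stored truth", {
  cfg <- small_config(seed = 8, noise_sd_log_biomass = 0)
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  com <- simulate_community(cfg, env, ch)
  tr <- com$truth
  # recompute community production from the stored per-taxon g and B
  for (s in cfg$stream_ids[c(1, 4)]) {
    st <- com$states[com$states$stream_id == s, ]
    dates <- sort(unique(st$date))
    tot <- 0
    for (i in seq_len(length(dates) - 1L)) {
      dt <- dates[i + 1] - dates[i]
      it <- tr$interval_temp_C[[s]][i]
      g <- exp(cfg$ln_i0 + cfg$a_true * log(st$mean_mass_mg[st$date == dates[i]]) +
                 cfg$E_ind_true * standardize_temperature(it))
      B1 <- st$B_mg_m2[st$date == dates[i]]
      B2 <- st$B_mg_m2[st$date == dates[i + 1]]
      tot <- tot + sum(g * dt * (B1 + B2) / 2)
    }
    expect_equal(tot / 1000, unname(tr$P_annual_true_g[s]), tolerance = 1e-9)
  }
  expect_true(all(com$states$B_mg_m2 > 0))
})

test_that("surber sampling respects the mesh floor, splits, and expected counts", {
  cfg <- small_config(seed = 9)
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  com <- simulate_community(cfg, env, ch)
  smp <- sample_surber(com, cfg)
  expect_true(all(smp$length_bin_mm >= 0.25))
  expect_true(all(smp$split_fraction %in% c(1, 1/2, 1/4, 1/8, 1/16)))
  expect_true(all(smp$count >= 1))
  # expanded density matches the scaling rule: 8 counted at split 1/4 -> 32
  expect_equal(unique(smp$area_m2), 0.023)
  row <- smp[1, ]
  expect_equal(row$count / row$split_fraction / row$area_m2,
               row$count * (1 / row$split_fraction) / 0.023)
})

test_that("empirical surber counts match the generating density", {
  # single taxon, one date, known density: mean total count over many draws
  # is density x area x replicates
  cfg <- sim_config(seed = 10, n_streams = 2, stream_ids = c("a", "b"),
                    mean_annual_temp_C = c(10, 15),
                    sampling_dates = c(100, 200),
                    taxa = list(taxon_spec("t1")), split_threshold = 1e9)
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  com <- simulate_community(cfg, env, ch)
  st <- com$states[com$states$stream_id == "a" & com$states$date == 100, ]
  expected <- st$density_m2 * 0.023 * cfg$n_replicate_samples
  tots <- vapply(1:300, function(i) {
    smp <- sample_surber(com, cfg, seed = 5000 + i)
    sum(smp$count[smp$stream_id == "a" & smp$date == 100])
  }, numeric(1))
  se <- sd(tots) / sqrt(length(tots))
  expect_lt(abs(mean(tots) - expected), 3 * se)
})

test_that("zero density yields no sampled individuals", {
  cfg <- sim_config(seed = 11, n_streams = 2, stream_ids = c("a", "b"),
                    mean_annual_temp_C = c(10, 15), sampling_dates = c(50, 100),
                    taxa = list(taxon_spec("t1")))
  env <- simulate_environment(cfg)
  ch <- simulate_chlorophyll(cfg, env)
  com <- simulate_community(cfg, env, ch)
  com$states$density_m2 <- 0
  smp <- sample_surber(com, cfg)
  expect_true(is.null(smp) || nrow(smp) == 0)
})

test_that("noise-free chambers reproduce the growth surface to machine precision", {
  cfg <- small_config(seed = 12, noise_sd_log_growth = 0)
  env <- simulate_environment(cfg)
  gr <- simulate_growth_chambers(cfg, env, n_obs = 40)$growth
  g <- instantaneous_growth(gr$W_t_mg, gr$W_t_dt_mg, gr$dt_days)
  g_model <- exp(cfg$ln_i0 + cfg$a_true * log(gr$W_t_mg) +
                   cfg$E_ind_true * standardize_temperature(gr$temp_C))
  expect_equal(g, g_model, tolerance = 1e-10)
  expect_true(all(gr$dt_days >= 7 & gr$dt_days <= 15))
  # the generated final mass is consistent with g by construction
  expect_equal(gr$W_t_mg * exp(g * gr$dt_days), gr$W_t_dt_mg, tolerance = 1e-12)
})

test_that("chamber-based fit recovers the generating parameters under noise", {
  n_seeds <- 30; hit_a <- hit_E <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- small_config(seed = 400 + s)
    env <- simulate_environment(cfg)
    gr <- simulate_growth_chambers(cfg, env, n_obs = 300)$growth
    fit <- fit_growth_model(gr)
    cc <- confint(fit)
    hit_a <- hit_a + (cc["a", 1] <= cfg$a_true && cfg$a_true <= cc["a", 2])
    hit_E <- hit_E + (cc["E_ind", 1] <= cfg$E_ind_true &&
                        cfg$E_ind_true <= cc["E_ind", 2])
  }
  expect_gte(hit_a, 0.85 * n_seeds)
  expect_gte(hit_E, 0.85 * n_seeds)
})

test_that("cohort size-frequency series shift by the generating growth", {
  cfg <- small_config(seed = 13)
  env <- simulate_environment(cfg)
  sf <- simulate_growth_chambers(cfg, env, n_obs = 20, n_cohort_ind = 500)$lengths
  expect_false(is.null(sf))
  one <- sf[sf$stream_id == sf$stream_id[1] & sf$taxon_id == sf$taxon_id[1], ]
  d <- sort(unique(one$date))
  expect_gt(mean(one$length_mm[one$date == d[2]]),
            mean(one$length_mm[one$date == d[1]]))
})
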