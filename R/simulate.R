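#' Taxon specification for the synthetic-study generator
#'
#' Describes one simulated taxon: its length-mass allometry
#' `M = lm_a * L^lm_b` (mg AFDM from mm), its length distribution
#' (normal, truncated at the 0.25 mm mesh floor), its share of community
#' production, and whether it develops as a synchronous cohort (and so yields
#' size-frequency growth series).
#'
#' @param taxon_id label.
#' @param lm_a,lm_b length-mass coefficients; `lm_a > 0`, `lm_b` typically in
#'   2-4.
#' @param cohort_synchronous logical.
#' @param relative_abundance non-negative weight (share of community
#'   production; normalized across taxa).
#' @param mean_length_mm,sd_length_mm length-distribution parameters (mm).
#' @return list of class `taxon_spec`.
#' @export
taxon_spec <- function(taxon_id, lm_a = 0.002, lm_b = 2.8,
                       cohort_synchronous = FALSE, relative_abundance = 1,
                       mean_length_mm = 4, sd_length_mm = 1) {
  stopifnot(lm_a > 0, lm_b > 0, relative_abundance >= 0,
            mean_length_mm > 0.25, sd_length_mm > 0)
  structure(list(taxon_id = taxon_id, lm_a = lm_a, lm_b = lm_b,
                 cohort_synchronous = cohort_synchronous,
                 relative_abundance = relative_abundance,
                 mean_length_mm = mean_length_mm,
                 sd_length_mm = sd_length_mm),
            class = "taxon_spec")
}

#' Default simulated community: four common stream taxa
#'
#' A small chironomid-dominated assemblage typical of sub-arctic geothermal
#' streams: two chironomid morphotypes, a blackfly with synchronous cohorts,
#' and a lymnaeid snail.
#' @return list of [taxon_spec()].
#' @export
default_taxa <- function() {
  list(
    taxon_spec("chironomini", lm_a = 0.0018, lm_b = 2.62,
               relative_abundance = 0.45, mean_length_mm = 3.5, sd_length_mm = 1.0),
    taxon_spec("tanytarsini", lm_a = 0.0012, lm_b = 2.60,
               relative_abundance = 0.20, mean_length_mm = 2.2, sd_length_mm = 0.6),
    taxon_spec("simulium", lm_a = 0.0020, lm_b = 2.90, cohort_synchronous = TRUE,
               relative_abundance = 0.25, mean_length_mm = 4.5, sd_length_mm = 1.2),
    taxon_spec("radix", lm_a = 0.0200, lm_b = 2.80,
               relative_abundance = 0.10, mean_length_mm = 5.0, sd_length_mm = 1.5)
  )
}

#' Configuration of a synthetic study
#'
#' Bundles the generating conditions of a simulated multi-stream study:
#' stream temperatures, seasonal environment, sampling design, the community,
#' and the true scaling parameters that downstream estimators should recover.
#' Defaults emulate the study system the package targets: six streams
#' spanning 5-28 degrees C mean annual temperature, roughly monthly sampling
#' with five 0.023 m^2 replicate samples, growth following
#' `ln g = ln i0 + a ln M + E_ind x(T)` with `a = -0.25` and
#' `E_ind = 0.65 eV`, chlorophyll responding to annual temperature with
#' `E_chla = 0.53 eV`, and production driven by resources only (a log-log
#' chlorophyll elasticity of 1.2, temperature acting on production solely
#' through chlorophyll).
#'
#' @param n_streams number of streams (>= 2).
#' @param stream_ids labels.
#' @param mean_annual_temp_C per-stream mean annual temperature, degrees C.
#' @param temp_seasonal_amplitude_C amplitude of the seasonal temperature
#'   sinusoid (scalar or per stream).
#' @param light_temp_correlation target Pearson r between daily temperature
#'   and light (scalar or per stream).
#' @param sampling_dates day-of-year of the sampling occasions.
#' @param n_replicate_samples replicate benthic samples per occasion.
#' @param sample_area_m2 sampler area (default 0.023).
#' @param taxa list of [taxon_spec()].
#' @param E_ind_true,a_true,ln_i0 growth-model truth (eV, dimensionless,
#'   log d^-1).
#' @param E_chla_true activation energy of annual chlorophyll (eV).
#' @param resource_production_E_true temperature dependence of GPP (eV).
#' @param chla_elasticity log-log slope of annual production on annual
#'   chlorophyll (the resource-only production control).
#' @param chla_at_ref annual mean chlorophyll at the reference temperature
#'   (mg m^-2).
#' @param annual_P_at_ref annual community production at the reference
#'   chlorophyll (g AFDM m^-2 y^-1).
#' @param noise_sd_log_growth,noise_sd_log_chla,noise_sd_log_biomass
#'   natural-log-scale Gaussian noise SDs (>= 0).
#' @param noise_sd_log_chla_stream stream-level lognormal residual SD of
#'   annual chlorophyll around the Boltzmann temperature line (default 0.6,
#'   leaving roughly half the among-stream variance in log chlorophyll
#'   unexplained by temperature). Set to 0 for chlorophyll lying exactly on
#'   the line; note that then production becomes an exact function of
#'   temperature and the resource-only control is unidentifiable.
#' @param count_model `"nbinom"` (overdispersed field counts; default) or
#'   `"poisson"`.
#' @param dispersion negative-binomial size parameter (default 2; smaller is
#'   more overdispersed).
#' @param split_threshold expected count above which a record is subsampled
#'   with a split fraction in 1/2..1/16.
#' @param light_mean,light_rel_amplitude,noise_sd_log_light daily light
#'   series parameters (arbitrary intensity units).
#' @param T_ref_C reference temperature for standardization.
#' @param seed integer seed stored with the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_streams = 6,
                       stream_ids = c("hver", "st6", "st9", "st7", "oh2", "st14"),
                       mean_annual_temp_C = c(27.2, 17.6, 11.2, 5.8, 5.5, 5.0),
                       temp_seasonal_amplitude_C = 4,
                       light_temp_correlation = c(0.67, 0.62, 0.55, 0.45, 0.30, -0.09),
                       sampling_dates = seq(15, 345, by = 30),
                       n_replicate_samples = 5,
                       sample_area_m2 = 0.023,
                       taxa = default_taxa(),
                       E_ind_true = 0.65, a_true = -0.25, ln_i0 = -3.5,
                       E_chla_true = 0.53,
                       resource_production_E_true = 1.37,
                       chla_elasticity = 1.2,
                       chla_at_ref = 30, annual_P_at_ref = 3,
                       noise_sd_log_growth = 0.4,
                       noise_sd_log_chla = 0.3,
                       noise_sd_log_chla_stream = 0.6,
                       noise_sd_log_biomass = 0.2,
                       count_model = c("nbinom", "poisson"),
                       dispersion = 2, split_threshold = 30,
                       light_mean = 500, light_rel_amplitude = 0.8,
                       noise_sd_log_light = 0.4,
                       T_ref_C = 15, seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_streams < 2) stop("n_streams must be >= 2")
  stream_ids <- rep(stream_ids, length.out = n_streams)[seq_len(n_streams)]
  mean_annual_temp_C <- rep(mean_annual_temp_C, length.out = n_streams)
  temp_seasonal_amplitude_C <- rep(temp_seasonal_amplitude_C, length.out = n_streams)
  light_temp_correlation <- rep(light_temp_correlation, length.out = n_streams)
  if (any(mean_annual_temp_C < -2) || any(mean_annual_temp_C > 60)) {
    stop("mean annual temperatures must lie in [-2, 60] degrees C")
  }
  if (any(mean_annual_temp_C - temp_seasonal_amplitude_C < -2)) {
    stop("seasonal amplitude would push temperatures below -2 degrees C")
  }
  if (any(c(noise_sd_log_growth, noise_sd_log_chla, noise_sd_log_chla_stream,
            noise_sd_log_biomass, noise_sd_log_light) < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (sample_area_m2 <= 0) stop("sample_area_m2 must be > 0")
  if (abs(light_temp_correlation[1]) > 1) stop("correlation target out of [-1, 1]")
  cfg <- list(
    n_streams = n_streams, stream_ids = stream_ids,
    mean_annual_temp_C = mean_annual_temp_C,
    temp_seasonal_amplitude_C = temp_seasonal_amplitude_C,
    light_temp_correlation = light_temp_correlation,
    sampling_dates = as.integer(sampling_dates),
    n_replicate_samples = as.integer(n_replicate_samples),
    sample_area_m2 = sample_area_m2, taxa = taxa,
    E_ind_true = E_ind_true, a_true = a_true, ln_i0 = ln_i0,
    E_chla_true = E_chla_true,
    resource_production_E_true = resource_production_E_true,
    chla_elasticity = chla_elasticity,
    chla_at_ref = chla_at_ref, annual_P_at_ref = annual_P_at_ref,
    noise_sd_log_growth = noise_sd_log_growth,
    noise_sd_log_chla = noise_sd_log_chla,
    noise_sd_log_chla_stream = noise_sd_log_chla_stream,
    noise_sd_log_biomass = noise_sd_log_biomass,
    count_model = count_model, dispersion = dispersion,
    split_threshold = split_threshold,
    light_mean = light_mean, light_rel_amplitude = light_rel_amplitude,
    noise_sd_log_light = noise_sd_log_light,
    T_ref_C = T_ref_C, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d streams (%.1f-%.1f C), %d sampling dates, %d taxa, seed %d>\n",
              x$n_streams, min(x$mean_annual_temp_C), max(x$mean_annual_temp_C),
              length(x$sampling_dates), length(x$taxa), x$seed))
  invisible(x)
}

.season <- function(day, phase) sin(2 * pi * (day - phase) / 365)

#' Simulate daily temperature and light series
#'
#' Temperature and light are phase-shifted sinusoids over 365 days; light
#' peaks at the summer solstice and carries multiplicative lognormal daily
#' noise (cloud cover), while the temperature phase is solved numerically for
#' each stream so that the realized Pearson correlation between daily
#' temperature and light matches the configured target. The annual mean
#' temperature equals the configured mean exactly (the sinusoid sums to zero
#' over a full period).
#'
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to `config$seed`).
#' @return data frame with columns `stream_id`, `day` (1-365), `temp_C`,
#'   `light`.
#' @export
simulate_environment <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  day <- 1:365
  light_phase <- 81  # sinusoid peaks at day 172 (summer solstice)
  out <- vector("list", config$n_streams)
  for (s in seq_len(config$n_streams)) {
    sdl <- config$noise_sd_log_light
    light <- config$light_mean *
      (1 + config$light_rel_amplitude * .season(day, light_phase)) *
      exp(stats::rnorm(365, 0, sdl) - sdl^2 / 2)
    A <- config$temp_seasonal_amplitude_C[s]
    mu <- config$mean_annual_temp_C[s]
    if (A == 0) {
      temp <- rep(mu, 365)
    } else {
      r_target <- config$light_temp_correlation[s]
      obj <- function(phase) (stats::cor(mu + A * .season(day, phase), light) - r_target)^2
      # the correlation sweeps its full attainable range as the phase moves
      # through one period; pick the phase that lands closest to the target
      grid <- seq(light_phase - 182, light_phase + 182, by = 2)
      ph0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
      ph <- stats::optimize(obj, c(ph0 - 3, ph0 + 3))$minimum
      temp <- mu + A * .season(day, ph)
    }
    out[[s]] <- data.frame(stream_id = config$stream_ids[s], day = day,
                           temp_C = temp, light = light)
  }
  do.call(rbind, out)
}

.light_at_dates <- function(env, stream, dates, halfwidth = 15) {
  d <- env[env$stream_id == stream, ]
  vapply(dates, function(dd) {
    w <- d$day >= dd - halfwidth & d$day <= dd + halfwidth
    mean(d$light[w])
  }, numeric(1))
}

.temp_at_dates <- function(env, stream, dates, halfwidth = 15) {
  d <- env[env$stream_id == stream, ]
  vapply(dates, function(dd) {
    w <- d$day >= dd - halfwidth & d$day <= dd + halfwidth
    mean(d$temp_C[w])
  }, numeric(1))
}

#' Mean temperature of a stream over an interval of days
#' @param env environment data frame from [simulate_environment()].
#' @param stream stream id.
#' @param from,to day-of-year bounds (inclusive).
#' @export
interval_mean_temp <- function(env, stream, from, to) {
  d <- env[env$stream_id == stream & env$day >= from & env$day <= to, ]
  mean(d$temp_C)
}

#' Simulate chlorophyll a samples
#'
#' The expected log annual mean chlorophyll of a stream is linear in its
#' standardized annual temperature with slope `E_chla_true`, plus a
#' stream-level lognormal residual (`noise_sd_log_chla_stream`) representing
#' everything other than temperature that sets a stream's resource base --
#' this residual is what makes resource supply and temperature separable in
#' the among-stream model competition. Within a stream,
#' sampling-date means follow the seasonal light cycle (a power of the local
#' mean light, renormalized so the annual mean over sampling dates is exact),
#' with no direct seasonal temperature term. Five stones per date carry
#' multiplicative lognormal noise with unit mean.
#'
#' @param config a [sim_config()].
#' @param env daily series from [simulate_environment()].
#' @param n_stones stones scrubbed per date (default 5).
#' @param beta_light exponent of the seasonal light modulation (default 0.6).
#' @param seed optional seed (defaults to `config$seed + 1`).
#' @return data frame `stream_id`, `date` (day-of-year), `stone_id`,
#'   `chla_mg_m2`, with attribute `annual_mean` (the true per-stream annual
#'   means, mg m^-2).
#' @export
simulate_chlorophyll <- function(config, env, n_stones = 5, beta_light = 0.6,
                                 seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  x <- standardize_temperature(config$mean_annual_temp_C, config$T_ref_C)
  eps <- stats::rnorm(config$n_streams, 0, config$noise_sd_log_chla_stream)
  ann <- config$chla_at_ref * exp(config$E_chla_true * x + eps)
  names(ann) <- config$stream_ids
  sdc <- config$noise_sd_log_chla
  rows <- list()
  for (s in seq_len(config$n_streams)) {
    sid <- config$stream_ids[s]
    lt <- .light_at_dates(env, sid, config$sampling_dates)
    m <- (lt / mean(lt))^beta_light
    m <- m / mean(m)  # annual mean over sampling dates is exactly ann[s]
    for (j in seq_along(config$sampling_dates)) {
      v <- ann[s] * m[j] * exp(stats::rnorm(n_stones, 0, sdc) - sdc^2 / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        stream_id = sid, date = config$sampling_dates[j],
        stone_id = seq_len(n_stones), chla_mg_m2 = v)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "annual_mean") <- ann
  out
}

.taxon_bins <- function(tx) {
  lo <- 0.25
  hi <- max(tx$mean_length_mm + 4 * tx$sd_length_mm, lo + 0.25)
  edges <- seq(lo, ceiling(hi / 0.25) * 0.25, by = 0.25)
  p <- stats::pnorm(c(edges[-1], Inf), tx$mean_length_mm, tx$sd_length_mm) -
    stats::pnorm(edges, tx$mean_length_mm, tx$sd_length_mm)
  # truncate below the 250-um mesh: individuals shorter than 0.25 mm never appear
  p <- p / sum(p)
  mid <- edges + 0.125
  keep <- p > 1e-8
  data.frame(length_bin_mm = edges[keep], p = p[keep] / sum(p[keep]),
             mass_mg = tx$lm_a * mid[keep]^tx$lm_b)
}

.true_growth <- function(config, M, temp_C) {
  exp(config$ln_i0 + config$a_true * log(M) +
        config$E_ind_true * standardize_temperature(temp_C, config$T_ref_C))
}

#' Simulate the true community: biomass and size structure per taxon
#'
#' Implements the resource-only production control: each stream's true annual
#' community production is `annual_P_at_ref * (chla_ann / chla_at_ref) ^
#' chla_elasticity` -- temperature affects production solely through
#' chlorophyll. Within the year, production follows resource production: the
#' seasonal shape is GPP-like, `exp(E_gpp x(T_d)) * light_d`, renormalized to
#' mean one within each stream so that the annual level stays set by
#' chlorophyll alone (temperature steepens the seasons but never the
#' among-stream pattern). Standing biomass is back-calculated as production
#' over growth, so warmer streams carry less biomass at equal production (as
#' metabolic theory predicts), and the bookkeeping identity `sum over taxa of
#' g x B = community production` holds by construction. Sampling-date
#' biomasses carry multiplicative lognormal noise (`noise_sd_log_biomass`).
#'
#' @param config a [sim_config()].
#' @param env daily series from [simulate_environment()].
#' @param chla samples from [simulate_chlorophyll()] (its `annual_mean`
#'   attribute drives production).
#' @param seed optional seed (defaults to `config$seed + 2`).
#' @return list of class `sim_community`: `states` (data frame per stream x
#'   date x taxon: `B_mg_m2`, `density_m2`, `mean_mass_mg`), `bins` (per-taxon
#'   size-bin table), `truth` (a `synthetic_truth` record).
#' @export
simulate_community <- function(config, env, chla,
                               seed = config$seed + 2L) {
  if (!is.null(seed)) set.seed(seed)
  ann_chla <- attr(chla, "annual_mean")
  if (is.null(ann_chla)) {
    ag <- stats::aggregate(chla_mg_m2 ~ stream_id + date, chla, mean)
    ann_chla <- vapply(split(ag$chla_mg_m2, ag$stream_id), mean, numeric(1))
    ann_chla <- ann_chla[config$stream_ids]
  }
  P_ann_target <- 1000 * config$annual_P_at_ref *
    (ann_chla / config$chla_at_ref)^config$chla_elasticity  # mg m^-2 y^-1
  bins <- lapply(config$taxa, .taxon_bins)
  names(bins) <- vapply(config$taxa, `[[`, character(1), "taxon_id")
  Ebar_M <- vapply(bins, function(b) sum(b$p * b$mass_mg), numeric(1))
  w <- vapply(config$taxa, `[[`, numeric(1), "relative_abundance")
  w <- w / sum(w)
  dates <- config$sampling_dates
  sdb <- config$noise_sd_log_biomass
  states <- list(); truth_P <- numeric(config$n_streams)
  names(truth_P) <- config$stream_ids
  interval_temps <- list()
  for (s in seq_len(config$n_streams)) {
    sid <- config$stream_ids[s]
    d <- env[env$stream_id == sid, ]
    lt <- .light_at_dates(env, sid, dates)
    xt <- standardize_temperature(.temp_at_dates(env, sid, dates), config$T_ref_C)
    # GPP-shaped seasonality: temperature dependence E_gpp plus light,
    # renormalized so the annual level is set by chlorophyll alone
    wday <- exp(config$resource_production_E_true * (xt - mean(xt))) * (lt / mean(lt))
    wday <- wday / mean(wday)
    p_daily <- P_ann_target[s] / 365 * wday        # at sampling dates
    st <- list()
    for (j in seq_along(dates)) {
      temp_j <- d$temp_C[d$day == dates[j]]
      g_tx <- .true_growth(config, Ebar_M, temp_j)
      B_det <- w * p_daily[j] / g_tx
      B <- B_det * exp(stats::rnorm(length(B_det), 0, sdb) - sdb^2 / 2)
      st[[j]] <- data.frame(stream_id = sid, date = dates[j],
                            taxon_id = names(bins), B_mg_m2 = B,
                            density_m2 = B / Ebar_M, mean_mass_mg = Ebar_M,
                            row.names = NULL)
    }
    st <- do.call(rbind, st)
    states[[s]] <- st
    # realized true production over the sampling intervals, by the
    # instantaneous growth identity on the true g and realized B
    it <- vapply(seq_len(length(dates) - 1L), function(i)
      interval_mean_temp(env, sid, dates[i], dates[i + 1L]), numeric(1))
    interval_temps[[sid]] <- it
    Ptot <- 0
    for (i in seq_len(length(dates) - 1L)) {
      dt <- dates[i + 1L] - dates[i]
      g_tx <- .true_growth(config, Ebar_M, it[i])
      B1 <- st$B_mg_m2[st$date == dates[i]]
      B2 <- st$B_mg_m2[st$date == dates[i + 1L]]
      Ptot <- Ptot + sum(g_tx * dt * (B1 + B2) / 2)
    }
    truth_P[s] <- Ptot / 1000  # g AFDM m^-2 over the sampled span
  }
  truth <- structure(list(
    config = config,
    x_annual = standardize_temperature(config$mean_annual_temp_C, config$T_ref_C),
    chla_annual_true = ann_chla,
    P_annual_target_g = P_ann_target / 1000,
    P_annual_true_g = truth_P,
    interval_temp_C = interval_temps,
    taxon_mean_mass_mg = Ebar_M
  ), class = "synthetic_truth")
  structure(list(states = do.call(rbind, states), bins = bins, truth = truth),
            class = "sim_community")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  E_ind =", x$config$E_ind_true, " a =", x$config$a_true,
      " E_chla =", x$config$E_chla_true,
      " chla elasticity =", x$config$chla_elasticity, "\n")
  cat("  true annual P (g AFDM m^-2):",
      paste(sprintf("%s=%.2f", names(x$P_annual_true_g), x$P_annual_true_g),
            collapse = ", "), "\n")
  invisible(x)
}

#' Draw replicate benthic samples from the true community
#'
#' For every stream x date x replicate x taxon x 0.25 mm length bin, a count
#' is drawn from a negative-binomial (default, dispersion `config$dispersion`)
#' or Poisson distribution with mean `true density x bin probability x
#' sampler area`. Records whose expected full count exceeds
#' `config$split_threshold` are subsampled: a split fraction in
#' 1/2..1/16 is applied and only the binomially thinned count is recorded
#' (readers scale counts back up by `1/split_fraction`).
#'
#' @param community a `sim_community` from [simulate_community()].
#' @param config the [sim_config()].
#' @param seed optional seed (defaults to `config$seed + 3`).
#' @return data frame of size-class records: `stream_id`, `date`,
#'   `replicate`, `taxon_id`, `length_bin_mm`, `count`, `split_fraction`,
#'   `area_m2`, `mass_mg` (zero-count cells omitted).
#' @export
sample_surber <- function(community, config, seed = config$seed + 3L) {
  if (!is.null(seed)) set.seed(seed)
  st <- community$states
  area <- config$sample_area_m2
  R <- config$n_replicate_samples
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    b <- community$bins[[st$taxon_id[i]]]
    mu <- st$density_m2[i] * b$p * area
    nb <- length(mu)
    mu_all <- rep(mu, R)
    cnt <- if (config$count_model == "nbinom") {
      stats::rnbinom(nb * R, mu = mu_all, size = config$dispersion)
    } else {
      stats::rpois(nb * R, mu_all)
    }
    split <- rep(1, nb * R)
    big <- which(mu_all > config$split_threshold)
    if (length(big)) {
      split[big] <- 1 / 2^pmin(4, 1 + floor(log2(mu_all[big] / config$split_threshold)))
      cnt[big] <- stats::rbinom(length(big), cnt[big], split[big])
    }
    keep <- cnt > 0
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      stream_id = st$stream_id[i], date = st$date[i],
      replicate = rep(seq_len(R), each = nb)[keep],
      taxon_id = st$taxon_id[i],
      length_bin_mm = rep(b$length_bin_mm, R)[keep],
      count = cnt[keep], split_fraction = split[keep],
      area_m2 = area, mass_mg = rep(b$mass_mg, R)[keep],
      row.names = NULL)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Simulate chamber growth observations and cohort size-frequency series
#'
#' Chamber observations draw an initial mass from a taxon's size
#' distribution, an incubation length uniform on 7-15 days, and generate
#' `ln g = ln_i0 + a_true ln M + E_ind_true x(T) + noise`; the final mass is
#' `W_t exp(g dt)`, so the growth identity holds by construction (g may be
#' negative after noise). For taxa flagged `cohort_synchronous`, paired
#' size-frequency samples (individual lengths one month apart) are generated
#' whose mean mass shifts by the same growth model.
#'
#' @param config a [sim_config()].
#' @param env daily series from [simulate_environment()].
#' @param n_obs number of chamber observations (default 300).
#' @param n_cohort_ind individuals measured per size-frequency date
#'   (default 60).
#' @param seed optional seed (defaults to `config$seed + 4`).
#' @return list: `growth` (chamber table: `taxon_id`, `stream_id`, `method`,
#'   `date_t`, `date_t_dt`, `W_t_mg`, `W_t_dt_mg`, `dt_days`, `temp_C`) and
#'   `lengths` (size-frequency table: `taxon_id`, `stream_id`, `date`,
#'   `length_mm`).
#' @export
simulate_growth_chambers <- function(config, env, n_obs = 300,
                                     n_cohort_ind = 60,
                                     seed = config$seed + 4L) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- config$taxa
  ids <- vapply(taxa, `[[`, character(1), "taxon_id")
  w <- vapply(taxa, `[[`, numeric(1), "relative_abundance"); w <- w / sum(w)
  si <- sample.int(config$n_streams, n_obs, replace = TRUE)
  ti <- sample.int(length(taxa), n_obs, replace = TRUE, prob = w)
  dt <- sample(7:15, n_obs, replace = TRUE)
  day0 <- sample.int(340, n_obs, replace = TRUE)
  W1 <- g <- temp <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    tx <- taxa[[ti[i]]]
    L <- max(0.3, stats::rnorm(1, tx$mean_length_mm, tx$sd_length_mm))
    W1[i] <- tx$lm_a * L^tx$lm_b
    temp[i] <- interval_mean_temp(env, config$stream_ids[si[i]],
                                  day0[i], day0[i] + dt[i])
    g[i] <- exp(log(.true_growth(config, W1[i], temp[i])) +
                  stats::rnorm(1, 0, config$noise_sd_log_growth))
  }
  growth <- data.frame(
    taxon_id = ids[ti], stream_id = config$stream_ids[si], method = "chamber",
    date_t = day0, date_t_dt = day0 + dt,
    W_t_mg = W1, W_t_dt_mg = W1 * exp(g * dt), dt_days = dt, temp_C = temp)
  lengths <- list()
  for (tx in taxa[vapply(taxa, `[[`, logical(1), "cohort_synchronous")]) {
    for (s in config$stream_ids[seq_len(min(2, config$n_streams))]) {
      d1 <- 120; d2 <- 150
      tbar <- interval_mean_temp(env, s, d1, d2)
      L1 <- pmax(0.3, stats::rnorm(n_cohort_ind, 0.8 * tx$mean_length_mm,
                                   tx$sd_length_mm))
      gt <- .true_growth(config, tx$lm_a * (0.8 * tx$mean_length_mm)^tx$lm_b, tbar)
      shift <- exp(gt * (d2 - d1) / tx$lm_b)   # mass factor on the length scale
      L2 <- pmax(0.3, stats::rnorm(n_cohort_ind, 0.8 * tx$mean_length_mm * shift,
                                   tx$sd_length_mm))
      lengths[[length(lengths) + 1L]] <- data.frame(
        taxon_id = tx$taxon_id, stream_id = s,
        date = rep(c(d1, d2), each = n_cohort_ind),
        length_mm = c(L1, L2))
    }
  }
  list(growth = growth,
       lengths = if (length(lengths)) do.call(rbind, lengths) else NULL)
}

#' Simulate a monthly GPP series for two instrumented streams
#'
#' `ln GPP = b0 + E_gpp x(T) + 1.0 ln(light) + 0.5 ln(chla) + noise`, with
#' `E_gpp = resource_production_E_true`, at monthly resolution for the two
#' warmest streams.
#'
#' @param config a [sim_config()].
#' @param env,chla series from the corresponding generators.
#' @param noise_sd lognormal noise SD (default 0.15).
#' @param seed optional seed (defaults to `config$seed + 5`).
#' @return data frame `stream_id`, `date`, `gpp`, `light`, `temp_C`, `chla`.
#' @export
simulate_gpp <- function(config, env, chla, noise_sd = 0.15,
                         seed = config$seed + 5L) {
  if (!is.null(seed)) set.seed(seed)
  streams <- config$stream_ids[order(config$mean_annual_temp_C,
                                     decreasing = TRUE)][1:2]
  rows <- list()
  for (s in streams) {
    ag <- stats::aggregate(chla_mg_m2 ~ date, chla[chla$stream_id == s, ], mean)
    lt <- .light_at_dates(env, s, ag$date)
    tc <- vapply(ag$date, function(dd)
      interval_mean_temp(env, s, max(1, dd - 15), min(365, dd + 15)), numeric(1))
    x <- standardize_temperature(tc, config$T_ref_C)
    lgpp <- 0.5 + config$resource_production_E_true * x +
      1.0 * log(lt / config$light_mean) + 0.5 * log(ag$chla_mg_m2 / config$chla_at_ref) +
      stats::rnorm(nrow(ag), 0, noise_sd)
    rows[[s]] <- data.frame(stream_id = s, date = ag$date, gpp = exp(lgpp),
                            light = lt, temp_C = tc, chla = ag$chla_mg_m2)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Runs all generators in sequence under seeds derived from `config$seed` and
#' returns every table a real study would provide, together with the
#' `synthetic_truth` record of the generating parameters. Fixed seed gives a
#' bit-identical dataset.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `config`, `environment`, `chla`,
#'   `community`, `samples`, `growth`, `lengths`, `gpp`, `truth`.
#' @examples
#' study <- simulate_study(sim_config(seed = 42))
#' study$truth
#' @export
simulate_study <- function(config = sim_config()) {
  env <- simulate_environment(config)
  chla <- simulate_chlorophyll(config, env)
  community <- simulate_community(config, env, chla)
  samples <- sample_surber(community, config)
  gr <- simulate_growth_chambers(config, env)
  gpp <- simulate_gpp(config, env, chla)
  structure(list(config = config, environment = env, chla = chla,
                 community = community, samples = samples,
                 growth = gr$growth, lengths = gr$lengths, gpp = gpp,
                 truth = community$truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study: %d streams, %d sample records, %d growth obs, seed %d>\n",
              x$config$n_streams, nrow(x$samples), nrow(x$growth),
              x$config$seed))
  invisible(x)
}
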