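#' Bootstrap annual mean chlorophyll a per stream
#'
#' Each replicate resamples the sampling dates of a stream with replacement,
#' resamples the stones within each chosen date with replacement, and averages
#' the date means, giving a distribution of the annual mean standing stock
#' (mg m^-2).
#'
#' @param chla data frame with columns `stream_id`, `date`, `stone_id`,
#'   `chla_mg_m2` (all values >= 0).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return Named list of [boot_dist()] per stream.
#' @export
annual_chla_bootstrap <- function(chla, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  streams <- sort(unique(chla$stream_id))
  if (length(streams) == 0L) stop("no chlorophyll samples supplied")
  out <- list()
  for (s in streams) {
    d <- chla[chla$stream_id == s, , drop = FALSE]
    dates <- sort(unique(d$date))
    nd <- length(dates)
    if (nd < 3L) stop("stream '", s, "' has fewer than 3 chlorophyll sampling dates")
    by_date <- lapply(dates, function(dd) d$chla_mg_m2[d$date == dd])
    reps <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      di <- sample.int(nd, nd, replace = TRUE)
      dm <- vapply(di, function(i) {
        v <- by_date[[i]]
        mean(v[sample.int(length(v), length(v), replace = TRUE)])
      }, numeric(1))
      reps[b] <- mean(dm)
    }
    out[[s]] <- boot_dist(reps, seed = seed)
  }
  out
}

#' Bootstrap interval mean chlorophyll a
#'
#' For within-stream analyses, each sampling interval's chlorophyll level is
#' the mean of its two endpoint dates; replicates resample stones within each
#' endpoint date.
#'
#' @inheritParams annual_chla_bootstrap
#' @param date_t,date_t_dt interval endpoint dates (must exist in `chla` for
#'   the stream).
#' @param stream_id the stream.
#' @return [boot_dist()] of interval mean chlorophyll (mg m^-2).
#' @export
interval_chla_bootstrap <- function(chla, stream_id, date_t, date_t_dt,
                                    n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- chla[chla$stream_id == stream_id, , drop = FALSE]
  v1 <- d$chla_mg_m2[d$date == date_t]
  v2 <- d$chla_mg_m2[d$date == date_t_dt]
  if (length(v1) == 0L || length(v2) == 0L) {
    stop("no chlorophyll samples at an interval endpoint for stream ", stream_id)
  }
  reps <- vapply(seq_len(n_boot), function(b) {
    (mean(v1[sample.int(length(v1), length(v1), replace = TRUE)]) +
       mean(v2[sample.int(length(v2), length(v2), replace = TRUE)])) / 2
  }, numeric(1))
  boot_dist(reps, seed = seed)
}

#' Apparent temperature dependence of annual chlorophyll a
#'
#' Delegates to [fit_activation_energy()]: double-bootstrap OLS of
#' `ln(annual mean chlorophyll)` on annual mean standardized temperature.
#'
#' @param chla_annual named list of [boot_dist()] per stream, from
#'   [annual_chla_bootstrap()].
#' @param x annual mean standardized temperature per stream (eV^-1).
#' @param ... passed to [fit_activation_energy()] (`n_boot`, `seed`, ...).
#' @return An `activation_energy` with quantity `"chla"`.
#' @export
fit_chla_temperature <- function(chla_annual, x, ...) {
  fit_activation_energy(chla_annual, x, quantity = "chla", scope = "among", ...)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of estimated parameters (including the residual
#'   variance).
#' @param n_obs number of observations; must exceed `k_params + 1`.
#' @return the AICc value.
#' @examples
#' aicc(-10, 3, 10)  # 30
#' @export
aicc <- function(loglik, k_params, n_obs) {
  if (n_obs <= k_params + 1) {
    stop("AICc undefined: n_obs must exceed k_params + 1 (n = ", n_obs,
         ", k = ", k_params, ")")
  }
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

.aicc_lm <- function(fit, n) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  if (n <= k + 1) return(Inf)  # cannot be selected; correction undefined
  aicc(as.numeric(ll), k, n)
}

#' Among-stream model competition: temperature versus resource supply
#'
#' Compares OLS models of log annual community production on standardized
#' temperature and/or log annual chlorophyll a across streams:
#' `{null, temp, chla, temp + chla, temp x chla}`. Model selection by AICc is
#' repeated `n_rep` times on jointly resampled inner bootstrap replicates of
#' production and chlorophyll (temperature is a fixed covariate), and the
#' winner is tallied each time; ties go to the model with fewer parameters,
#' and models whose AICc correction is undefined at the given number of
#' streams are ineligible. The apparent temperature dependence is the `temp`
#' coefficient distribution of the temperature-only model and the
#' resource-corrected temperature dependence is the `temp` coefficient
#' distribution of the additive model, both accumulated over the same
#' `n_rep` resampled fits.
#'
#' @param P_annual named list of [boot_dist()] annual community production per
#'   stream (strictly positive).
#' @param x annual mean standardized temperature per stream (eV^-1).
#' @param chla_annual named list of [boot_dist()] annual mean chlorophyll per
#'   stream (strictly positive).
#' @param n_rep number of resampled model-selection replicates (default 1000).
#' @param seed optional integer seed.
#' @return Object of class `model_selection`: `freq` (winner frequencies,
#'   summing to 1), `modal`, `E_apparent` and `E_corrected`
#'   ([boot_dist()] of the temp coefficients), `winner_coefs` (matrix of
#'   modal-model coefficient draws), `candidates`, `n_rep`.
#' @export
among_stream_selection <- function(P_annual, x, chla_annual,
                                   n_rep = 1000, seed = NULL) {
  n <- length(P_annual)
  if (n < 4L) stop("need at least 4 streams for model competition")
  if (length(chla_annual) != n || length(x) != n) {
    stop("P_annual, chla_annual and x must align one-per-stream")
  }
  nm <- names(P_annual); if (is.null(nm)) nm <- as.character(seq_len(n))
  .check_positive_units(P_annual, nm)
  .check_positive_units(chla_annual, nm)
  if (!is.null(seed)) set.seed(seed)
  candidates <- list(
    null        = lnP ~ 1,
    temp        = lnP ~ temp,
    chla        = lnP ~ lnchla,
    `temp+chla` = lnP ~ temp + lnchla,
    `temp*chla` = lnP ~ temp * lnchla
  )
  k_order <- vapply(candidates, function(f) length(attr(stats::terms(f), "term.labels")), numeric(1))
  Pv <- lapply(P_annual, function(v) if (is.boot_dist(v)) v$replicates else v)
  Cv <- lapply(chla_annual, function(v) if (is.boot_dist(v)) v$replicates else v)
  tally <- stats::setNames(integer(length(candidates)), names(candidates))
  e_app <- e_cor <- numeric(n_rep)
  winner_coefs <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    d <- data.frame(
      lnP = log(vapply(Pv, function(v) v[sample.int(length(v), 1L)], numeric(1))),
      lnchla = log(vapply(Cv, function(v) v[sample.int(length(v), 1L)], numeric(1))),
      temp = x
    )
    fits <- lapply(candidates, stats::lm, data = d)
    a <- vapply(fits, .aicc_lm, numeric(1), n = n)
    if (all(!is.finite(a))) stop("no candidate has a defined AICc at n = ", n)
    best <- which(a <= min(a) + 1e-9)
    best <- best[which.min(k_order[best])]   # tie -> fewer parameters
    tally[best] <- tally[best] + 1L
    e_app[r] <- stats::coef(fits$temp)["temp"]
    e_cor[r] <- stats::coef(fits$`temp+chla`)["temp"]
    winner_coefs[[r]] <- stats::coef(fits[[best]])
  }
  modal <- names(tally)[which.max(tally)]
  modal_draws <- winner_coefs[vapply(winner_coefs, function(cf)
    identical(names(cf), names(stats::coef(stats::lm(candidates[[modal]],
      data = data.frame(lnP = log(vapply(Pv, mean, numeric(1))),
                        lnchla = log(vapply(Cv, mean, numeric(1))),
                        temp = x))))), logical(1))]
  structure(list(
    freq = tally / n_rep, modal = modal,
    E_apparent = boot_dist(e_app, seed = seed),
    E_corrected = boot_dist(e_cor, seed = seed),
    winner_coefs = if (length(modal_draws)) do.call(rbind, modal_draws) else NULL,
    candidates = names(candidates), n_rep = n_rep, n_streams = n
  ), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Among-stream model competition (AICc over", x$n_rep, "resampled datasets)\n")
  f <- sort(x$freq, decreasing = TRUE)
  for (m in names(f)) cat(sprintf("  %-10s %5.1f%%\n", m, 100 * f[m]))
  cat(sprintf("Modal winner: %s\n", x$modal))
  cat(sprintf("Apparent E (temp-only temp coef):      %.3f eV [%.3f, %.3f]\n",
              mean(x$E_apparent), ci(x$E_apparent)[1], ci(x$E_apparent)[2]))
  cat(sprintf("Resource-corrected E (additive temp):  %.3f eV [%.3f, %.3f]\n",
              mean(x$E_corrected), ci(x$E_corrected)[1], ci(x$E_corrected)[2]))
  invisible(x)
}

# all fixed-effect sub-models of temp * lnchla * lnlight that respect
# marginality (interactions only with their main effects present)
.within_candidates <- function() {
  t1 <- c("temp", "lnchla", "lnlight")
  combos <- list(character(0))
  for (k in 1:3) combos <- c(combos, utils::combn(t1, k, simplify = FALSE))
  out <- list()
  for (mains in combos) {
    pairs <- if (length(mains) >= 2) utils::combn(mains, 2, simplify = FALSE) else list()
    psets <- list(list())
    for (p in pairs) psets <- c(psets, lapply(psets, function(s) c(s, list(p))))
    for (ps in psets) {
      terms <- c(mains, vapply(ps, paste, character(1), collapse = ":"))
      if (length(ps) == 3 && length(mains) == 3) {
        out[[length(out) + 1L]] <- terms            # all two-way, no three-way
        terms <- c(terms, "temp:lnchla:lnlight")    # full factorial
      }
      out[[length(out) + 1L]] <- terms
    }
  }
  labs <- vapply(out, function(tt) if (length(tt) == 0) "null" else paste(tt, collapse = " + "), character(1))
  stats::setNames(out, labs)
}

#' Within-stream model competition with random stream intercepts
#'
#' Fits linear mixed-effects models of log daily community production on
#' interval mean standardized temperature, log chlorophyll a and log light,
#' with a random intercept per stream; all marginality-respecting fixed-effect
#' sub-models of `temp * lnchla * lnlight` are candidates. Selection uses
#' maximum likelihood and AICc, repeated `n_rep` times on resampled inner
#' replicates of production and chlorophyll; the modal winner is refit by
#' REML on `n_rep` further resampled datasets, and the temperature fixed
#' effect across those refits is the within-stream apparent activation energy
#' `E_p_within`.
#'
#' @param data data frame with one row per stream x interval: columns
#'   `stream_id`, `x` (standardized temperature), `light` (> 0); plus
#'   list-columns or separate arguments for the bootstrapped responses (see
#'   `P_daily`, `chla`).
#' @param P_daily list of [boot_dist()] daily production, one per row of
#'   `data` (strictly positive).
#' @param chla list of [boot_dist()] interval chlorophyll, one per row.
#' @param n_rep selection replicates (default 1000).
#' @param seed optional integer seed.
#' @param max_dropped_frac maximum tolerated fraction of replicates dropped
#'   for singular or failed fits (default 0.1).
#' @return Object of class `within_selection`: `freq`, `modal`, `E_within`
#'   ([boot_dist()] of the REML temperature coefficient; `NULL` when the
#'   modal model has no temperature term), `fixef_draws`, `reml_fit` (REML
#'   fit on replicate means), `n_dropped`, `n_rep`.
#' @export
within_stream_selection <- function(data, P_daily, chla, n_rep = 1000,
                                    seed = NULL, max_dropped_frac = 0.1) {
  if (length(unique(data$stream_id)) < 2L) stop("need at least 2 streams")
  tab <- table(data$stream_id)
  if (any(tab < 4L)) stop("need at least 4 intervals per stream")
  if (length(P_daily) != nrow(data) || length(chla) != nrow(data)) {
    stop("P_daily and chla must have one element per row of data")
  }
  .check_positive_units(P_daily, paste(data$stream_id, seq_len(nrow(data))))
  .check_positive_units(chla, paste(data$stream_id, seq_len(nrow(data))))
  if (any(data$light <= 0)) stop("light must be strictly positive (apply a floor first)")
  if (!is.null(seed)) set.seed(seed)
  cand <- .within_candidates()
  k_order <- lengths(cand)
  fmls <- lapply(cand, function(tt) {
    rhs <- if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
    stats::as.formula(paste("lnP ~", rhs, "+ (1 | stream_id)"))
  })
  Pv <- lapply(P_daily, function(v) if (is.boot_dist(v)) v$replicates else v)
  Cv <- lapply(chla, function(v) if (is.boot_dist(v)) v$replicates else v)
  n <- nrow(data)
  base <- data.frame(stream_id = data$stream_id, temp = data$x,
                     lnlight = log(data$light))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  draw_data <- function() {
    d <- base
    d$lnP <- log(vapply(Pv, function(v) v[sample.int(length(v), 1L)], numeric(1)))
    d$lnchla <- log(vapply(Cv, function(v) v[sample.int(length(v), 1L)], numeric(1)))
    d
  }
  tally <- stats::setNames(integer(length(cand)), names(cand))
  n_dropped <- 0L
  for (r in seq_len(n_rep)) {
    d <- draw_data()
    a <- rep(Inf, length(fmls))
    ok <- TRUE
    for (j in seq_along(fmls)) {
      fit <- tryCatch(
        suppressMessages(lme4::lmer(fmls[[j]], data = d, REML = FALSE, control = ctrl)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
        # singular/failed candidate: ineligible this replicate
        next
      }
      ll <- stats::logLik(fit)
      k <- attr(ll, "df")
      a[j] <- if (n > k + 1) aicc(as.numeric(ll), k, n) else Inf
    }
    if (all(!is.finite(a))) { n_dropped <- n_dropped + 1L; next }
    best <- which(a <= min(a) + 1e-9)
    best <- best[which.min(k_order[best])]
    tally[best] <- tally[best] + 1L
  }
  if (n_dropped > max_dropped_frac * n_rep) {
    stop(n_dropped, " of ", n_rep, " selection replicates dropped ",
         "(singular or failed fits); data too weak for mixed-model selection")
  }
  modal <- names(tally)[which.max(tally)]
  fml_modal <- fmls[[modal]]
  has_temp <- "temp" %in% cand[[modal]]
  fixef_draws <- vector("list", n_rep)
  reml_dropped <- 0L
  for (r in seq_len(n_rep)) {
    d <- draw_data()
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml_modal, data = d, REML = TRUE, control = ctrl)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) { reml_dropped <- reml_dropped + 1L; next }
    fixef_draws[[r]] <- lme4::fixef(fit)
  }
  fixef_draws <- do.call(rbind, fixef_draws[!vapply(fixef_draws, is.null, logical(1))])
  dmean <- base
  dmean$lnP <- log(vapply(Pv, mean, numeric(1)))
  dmean$lnchla <- log(vapply(Cv, mean, numeric(1)))
  reml_fit <- suppressMessages(lme4::lmer(fml_modal, data = dmean, REML = TRUE, control = ctrl))
  structure(list(
    freq = tally / sum(tally), modal = modal,
    E_within = if (has_temp) boot_dist(fixef_draws[, "temp"], seed = seed) else NULL,
    fixef_draws = fixef_draws, reml_fit = reml_fit,
    candidates = names(cand), n_rep = n_rep,
    n_dropped = n_dropped, reml_dropped = reml_dropped
  ), class = "within_selection")
}

#' @export
print.within_selection <- function(x, ...) {
  cat("Within-stream mixed-model competition (AICc, random stream intercepts)\n")
  f <- sort(x$freq, decreasing = TRUE)
  f <- f[f > 0]
  for (m in names(utils::head(f, 5))) cat(sprintf("  %-40s %5.1f%%\n", m, 100 * f[m]))
  cat(sprintf("Modal winner: %s\n", x$modal))
  if (!is.null(x$E_within)) {
    cat(sprintf("E_p_within = %.3f eV [%.3f, %.3f] (REML temp coefficient)\n",
                mean(x$E_within), ci(x$E_within)[1], ci(x$E_within)[2]))
  } else cat("Modal model contains no temperature term\n")
  invisible(x)
}

#' Log-linear model of gross primary production
#'
#' `ln(GPP) = b0 + E_gpp x + b_l ln(light) + b_c ln(chla)`, fitted by OLS;
#' the temperature coefficient is the within-stream temperature dependence of
#' GPP, with a case-bootstrap distribution for uncertainty.
#'
#' @param data data frame with columns `gpp` (> 0), `light` (> 0), `chla`
#'   (> 0) and `temp_C` (or `x` already standardized); at least 8 rows.
#' @param n_boot case-bootstrap replicates for the coefficient distribution
#'   (default 1000).
#' @param seed optional integer seed.
#' @param T_ref_C reference temperature (default 15).
#' @return Object of class `gpp_model`: `fit` (the `lm`), `E_gpp`
#'   ([boot_dist()]), `coefficients`, `sigma`.
#' @export
fit_gpp_model <- function(data, n_boot = 1000, seed = NULL, T_ref_C = 15) {
  d <- as.data.frame(data)
  if (nrow(d) < 8L) stop("need at least 8 GPP observations")
  if (any(d$gpp <= 0)) stop("non-positive GPP: log transform undefined")
  if (!"x" %in% names(d)) d$x <- standardize_temperature(d$temp_C, T_ref_C)
  fit <- stats::lm(log(gpp) ~ x + log(light) + log(chla), data = d)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  draws <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(stats::lm(log(gpp) ~ x + log(light) + log(chla), data = d[i, ]),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else stats::coef(f)["x"]
  }, numeric(1))
  draws <- draws[is.finite(draws)]
  structure(list(fit = fit, E_gpp = boot_dist(draws, seed = seed),
                 coefficients = stats::coef(fit),
                 sigma = suppressWarnings(summary(fit)$sigma), n_obs = n),
            class = "gpp_model")
}

#' @export
print.gpp_model <- function(x, ...) {
  cat("GPP model: ln(GPP) ~ x(T) + ln(light) + ln(chla)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("E_gpp = %.3f eV [%.3f, %.3f]  (n = %d, residual SD %.3f)\n",
              mean(x$E_gpp), ci(x$E_gpp)[1], ci(x$E_gpp)[2], x$n_obs, x$sigma))
  invisible(x)
}

#' @export
coef.gpp_model <- function(object, ...) object$coefficients

#' Resource-corrected within-stream temperature dependence
#'
#' Subtracts the temperature dependence of resource production (GPP) from the
#' apparent within-stream temperature dependence of secondary production:
#' `corrected = E_p_within - E_gpp_within`, by independent draws from the two
#' bootstrap distributions.
#'
#' @param Ep [boot_dist()] (or `activation_energy` / `within_selection`
#'   result) of the apparent within-stream temperature dependence (eV).
#' @param Egpp [boot_dist()] (or `gpp_model`) of the GPP temperature
#'   dependence (eV).
#' @param n_boot number of difference draws (default 10000).
#' @param seed optional integer seed.
#' @return An `activation_energy` object (quantity
#'   `"P_resource_corrected"`, `r2 = NA`).
#' @export
resource_correct_within <- function(Ep, Egpp, n_boot = 10000, seed = NULL) {
  as_reps <- function(z) {
    if (is.boot_dist(z)) z$replicates
    else if (inherits(z, "activation_energy")) z$slopes$replicates
    else if (inherits(z, "within_selection")) z$E_within$replicates
    else if (inherits(z, "gpp_model")) z$E_gpp$replicates
    else as.numeric(z)
  }
  e1 <- as_reps(Ep); e2 <- as_reps(Egpp)
  if (length(e1) == 0L || length(e2) == 0L) stop("empty distribution")
  if (!is.null(seed)) set.seed(seed)
  diff <- e1[sample.int(length(e1), n_boot, replace = TRUE)] -
    e2[sample.int(length(e2), n_boot, replace = TRUE)]
  q <- stats::quantile(diff, c(0.025, 0.975), names = FALSE)
  structure(list(E_mean = mean(diff), ci_low = q[1], ci_high = q[2],
                 r2 = NA_real_, n_boot = n_boot,
                 slopes = boot_dist(diff, seed = seed),
                 quantity = "P_resource_corrected", scope = "within",
                 n_units = NA_integer_, n_dropped = 0L,
                 point_slope = mean(e1) - mean(e2)),
            class = "activation_energy")
}
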