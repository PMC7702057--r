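#' Instantaneous mass-specific growth rate
#'
#' `g = ln(W_{t+dt} / W_t) / dt`, the instantaneous growth rate (d^-1) implied
#' by a change in individual (or mean cohort) body mass over an interval.
#' Negative values are legitimate for chamber observations where individuals
#' lost mass.
#'
#' @param W_t initial mass, mg AFDM; must be > 0.
#' @param W_t_dt final mass, mg AFDM; must be > 0.
#' @param dt_days interval length in days; must be > 0.
#' @return growth rate(s), d^-1.
#' @examples
#' instantaneous_growth(1, 2, 7)   # ln(2)/7
#' @export
instantaneous_growth <- function(W_t, W_t_dt, dt_days) {
  if (any(W_t <= 0) || any(W_t_dt <= 0)) stop("masses must be strictly positive")
  if (any(dt_days <= 0)) stop("dt_days must be strictly positive")
  log(W_t_dt / W_t) / dt_days
}

#' Bootstrap growth rate of a synchronous cohort from size-frequency data
#'
#' For taxa that develop synchronously, growth between two sampling dates is
#' estimated from the shift in the size-frequency distribution: individual
#' masses on each date are resampled with replacement (resample size equal to
#' the observed count on that date), the mean masses are converted to a growth
#' rate via [instantaneous_growth()], and the pair is redrawn whenever the
#' resampled final mean does not exceed the initial mean, so every replicate
#' growth rate is strictly positive. Rejection resampling (rather than
#' truncating masses) preserves the marginal size distributions.
#'
#' @param masses_t,masses_t_dt numeric vectors of individual masses
#'   (mg AFDM) observed at the start and end of the interval.
#' @param dt_days interval length, days.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed optional integer seed.
#' @param max_attempts redraw cap per replicate before declaring the cohort
#'   invalid (default 1000).
#' @param resample_size resample size per date; default `NULL` uses the
#'   observed count on each date.
#' @return A [boot_dist()] of growth rates (d^-1), all replicates > 0.
#' @export
bootstrap_cohort_growth <- function(masses_t, masses_t_dt, dt_days,
                                    n_boot = 500, seed = NULL,
                                    max_attempts = 1000,
                                    resample_size = NULL) {
  if (length(masses_t) == 0L || length(masses_t_dt) == 0L) {
    stop("size-frequency distributions must be non-empty")
  }
  if (any(masses_t <= 0) || any(masses_t_dt <= 0)) {
    stop("masses must be strictly positive")
  }
  if (dt_days <= 0) stop("dt_days must be strictly positive")
  if (max(masses_t_dt) <= min(masses_t)) {
    stop("no valid cohort: all final masses <= all initial masses; ",
         "positive growth cannot be resampled")
  }
  if (!is.null(seed)) set.seed(seed)
  # canonical order: the estimate depends on the multiset of masses only
  masses_t <- sort(masses_t); masses_t_dt <- sort(masses_t_dt)
  n1 <- length(masses_t); n2 <- length(masses_t_dt)
  k1 <- if (is.null(resample_size)) n1 else resample_size
  k2 <- if (is.null(resample_size)) n2 else resample_size
  g <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      m1 <- mean(masses_t[sample.int(n1, k1, replace = TRUE)])
      m2 <- mean(masses_t_dt[sample.int(n2, k2, replace = TRUE)])
      if (m2 > m1) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("no valid cohort: could not resample W_t_dt > W_t within ",
           max_attempts, " attempts")
    }
    g[b] <- log(m2 / m1) / dt_days
  }
  boot_dist(g, seed = seed)
}

#' Fit the mass-temperature scaling model of individual growth
#'
#' Ordinary least squares of `ln g` on `ln M` and standardized inverse
#' Boltzmann temperature:
#' `ln(g) = ln(i0) + a ln(M) + E_ind x(T)`,
#' the linearised Boltzmann-Arrhenius growth model. The mass exponent `a` is
#' expected near -0.25 and the apparent activation energy `E_ind` near
#' 0.6-0.7 eV under metabolic scaling theory. Observations with non-positive
#' growth cannot enter the log-linear fit; they are dropped and counted in
#' `n_excluded`.
#'
#' @param observations data frame with columns `W_t_mg`, `W_t_dt_mg`,
#'   `dt_days`, `temp_C` and optionally `stream_id` (required for
#'   `scope = "stream"`). Alternatively columns `g` (d^-1) and `M_mg` may be
#'   supplied directly.
#' @param T_ref_C reference temperature for standardization (default 15).
#' @param scope `"global"` for a single equation, `"stream"` to add
#'   stream-specific intercepts (stream-specific growth equations for taxa
#'   without direct measurements).
#' @return An object of class `growth_model`: the underlying `lm` fit plus
#'   named coefficients `intercept` (ln i0), `a`, `E_ind`, their covariance,
#'   `r2`, `scope` and `n_excluded`.
#' @examples
#' obs <- data.frame(g = exp(-3.5 - 0.25 * log(c(1, 2, 4, 8)) +
#'                           0.65 * standardize_temperature(c(5, 10, 20, 25))),
#'                   M_mg = c(1, 2, 4, 8))
#' obs$temp_C <- c(5, 10, 20, 25)
#' fit <- fit_growth_model(obs)
#' coef(fit)
#' @export
fit_growth_model <- function(observations, T_ref_C = 15,
                             scope = c("global", "stream")) {
  scope <- match.arg(scope)
  d <- as.data.frame(observations)
  if (!"g" %in% names(d)) {
    d$g <- instantaneous_growth(d$W_t_mg, d$W_t_dt_mg, d$dt_days)
  }
  if (!"M_mg" %in% names(d)) d$M_mg <- d$W_t_mg
  keep <- d$g > 0
  n_excluded <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 observations with positive growth")
  d$x <- standardize_temperature(d$temp_C, T_ref_C)
  d$lnM <- log(d$M_mg)
  if (stats::var(d$x) < .Machine$double.eps * 100) {
    stop("collinear design: temperatures do not vary; ",
         "E_ind is not identifiable")
  }
  fml <- if (scope == "stream") {
    if (is.null(d$stream_id)) stop("scope = 'stream' requires a stream_id column")
    log(g) ~ 0 + factor(stream_id) + lnM + x
  } else {
    log(g) ~ lnM + x
  }
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design: growth model coefficients not identifiable")
  }
  cf <- stats::coef(fit)
  out <- list(
    fit = fit,
    intercept = if (scope == "global") unname(cf["(Intercept)"]) else NA_real_,
    stream_intercepts = if (scope == "stream") {
      si <- cf[grepl("^factor\\(stream_id\\)", names(cf))]
      names(si) <- sub("^factor\\(stream_id\\)", "", names(si))
      si
    } else NULL,
    a = unname(cf["lnM"]),
    E_ind = unname(cf["x"]),
    vcov = suppressWarnings(stats::vcov(fit)),  # exact fits are legitimate
    r2 = suppressWarnings(summary(fit)$r.squared),  # exact fits are legitimate
    scope = scope,
    T_ref_C = T_ref_C,
    n_obs = nrow(d),
    n_excluded = n_excluded
  )
  class(out) <- "growth_model"
  out
}

#' @export
print.growth_model <- function(x, digits = 4, ...) {
  cat("Boltzmann-Arrhenius growth model: ln(g) ~ ln(M) + x(T)\n")
  cat(sprintf("  scope: %s   n = %d (excluded g <= 0: %d)   r2 = %.3f\n",
              x$scope, x$n_obs, x$n_excluded, x$r2))
  cat(sprintf("  a (mass exponent)   = %s\n", format(x$a, digits = digits)))
  cat(sprintf("  E_ind (eV)          = %s\n", format(x$E_ind, digits = digits)))
  if (x$scope == "global") {
    cat(sprintf("  intercept ln(i0)    = %s\n", format(x$intercept, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.growth_model <- function(object, ...) {
  if (object$scope == "global") {
    c(intercept = object$intercept, a = object$a, E_ind = object$E_ind)
  } else {
    c(object$stream_intercepts, a = object$a, E_ind = object$E_ind)
  }
}

#' @export
vcov.growth_model <- function(object, ...) object$vcov

#' @export
summary.growth_model <- function(object, ...) {
  s <- summary(object$fit)
  cf <- s$coefficients
  ci <- stats::confint(object$fit)
  cat("Boltzmann-Arrhenius growth model\n")
  print(cbind(cf[, 1:2, drop = FALSE], ci))
  cat(sprintf("r2 = %.3f, n = %d, excluded (g <= 0) = %d\n",
              object$r2, object$n_obs, object$n_excluded))
  invisible(s)
}

#' Confidence intervals for growth-model scaling coefficients
#' @param object a `growth_model`.
#' @param parm,level as in [stats::confint()].
#' @param ... unused.
#' @export
confint.growth_model <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level)
  rownames(ci) <- sub("^lnM$", "a", sub("^x$", "E_ind", rownames(ci)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict growth rate from a fitted growth model
#'
#' @param object a `growth_model` from [fit_growth_model()].
#' @param M body mass, mg AFDM (> 0).
#' @param temp_C temperature, degrees Celsius.
#' @param stream_id stream label(s); required when the model was fitted with
#'   `scope = "stream"`.
#' @param ... unused.
#' @return predicted growth rate(s), d^-1; strictly positive.
#' @export
predict.growth_model <- function(object, M, temp_C, stream_id = NULL, ...) {
  if (any(M <= 0)) stop("mass must be strictly positive")
  x <- standardize_temperature(temp_C, object$T_ref_C)
  b0 <- if (object$scope == "global") {
    object$intercept
  } else {
    if (is.null(stream_id)) stop("stream-scoped model requires stream_id")
    b <- object$stream_intercepts[as.character(stream_id)]
    if (anyNA(b)) stop("unknown stream_id: ",
                       paste(setdiff(as.character(stream_id),
                                     names(object$stream_intercepts)),
                             collapse = ", "))
    unname(b)
  }
  exp(b0 + object$a * log(M) + object$E_ind * x)
}
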