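#' Biomass-weighted mean community body mass
#'
#' `M_c = sum(B_i * M_i) / sum(B_i)` over taxa, computed per bootstrap
#' replicate, so the community mass carries the same pairing as the biomass
#' bootstrap it was derived from. Zero-biomass taxa do not contribute.
#'
#' @param B taxon biomasses: matrix (taxa x replicates), list of paired
#'   [boot_dist()] per taxon, or plain numeric vector.
#' @param M taxon mean individual masses (mg AFDM): numeric vector (one per
#'   taxon) or matrix paired with `B`.
#' @return [boot_dist()] of M_c (or a scalar for plain numeric input).
#' @export
weighted_community_mass <- function(B, M) {
  if (is.list(B) && all(vapply(B, is.boot_dist, logical(1)))) {
    B <- do.call(rbind, lapply(B, `[[`, "replicates"))
  }
  if (is.matrix(B)) {
    Mm <- if (is.matrix(M)) M else matrix(M, nrow(B), ncol(B))
    tot <- colSums(B)
    if (any(tot <= 0)) stop("all-zero community biomass in some replicate")
    boot_dist(colSums(B * Mm) / tot)
  } else {
    if (sum(B) <= 0) stop("all-zero community biomass")
    sum(B * M) / sum(B)
  }
}

#' Remove (or apply) the theoretical body-size scaling from B or P:B
#'
#' Metabolic theory predicts standing biomass scales as `M^+0.25` and biomass
#' turnover as `M^-0.25`. To compare communities of different mean body size
#' on a common footing, the theoretical mass effect is removed by dividing by
#' `M_c^exponent` (so corrected B = B / M_c^0.25, corrected P:B =
#' P:B * M_c^0.25, and the two corrections cancel in the product, leaving P
#' unchanged). `direction = "multiply"` applies the factor instead of
#' removing it.
#'
#' @param value quantity to correct (numeric or [boot_dist()]).
#' @param M_c community mass, mg AFDM (numeric or [boot_dist()] paired with
#'   `value`).
#' @param exponent theoretical mass exponent: `+0.25` for biomass, `-0.25`
#'   for P:B. Other magnitudes are accepted with a warning.
#' @param direction `"remove"` (default; divide by `M_c^exponent`) or
#'   `"multiply"`.
#' @return corrected value, same class as `value`.
#' @export
mass_correct <- function(value, M_c, exponent,
                         direction = c("remove", "multiply")) {
  direction <- match.arg(direction)
  if (abs(abs(exponent) - 0.25) > 1e-12) {
    warning("mass-correction exponent |", exponent,
            "| differs from the theoretical 0.25")
  }
  f <- if (is.boot_dist(M_c)) boot_dist(M_c$replicates^exponent) else M_c^exponent
  if (direction == "remove") value / f else value * f
}

.check_positive_units <- function(values, unit_names) {
  for (u in seq_along(values)) {
    v <- if (is.boot_dist(values[[u]])) values[[u]]$replicates else values[[u]]
    if (any(v <= 0)) {
      stop("non-positive value in unit '", unit_names[u],
           "': log transform undefined")
    }
  }
}

#' Apparent activation energy by double-bootstrap OLS regression
#'
#' Estimates the slope of `ln(value)` on standardized inverse Boltzmann
#' temperature `x` across units (streams, or sampling intervals within a
#' stream). Each of `n_boot` outer replicates draws one inner bootstrap
#' replicate of the value for every unit and fits the OLS slope; the mean and
#' 2.5/97.5 percentiles of the resulting slope distribution are reported,
#' together with the r-squared of the point fit on unit means. Uncertainty in
#' the unit-level estimates therefore propagates into the slope. Inner draws
#' are a deterministic function of the seed and the unit structure, so two
#' quantities bootstrapped under the same seed share their replicate pairing
#' (e.g. `E(P) = E(B_corr) + E(PB_corr)` holds replicate by replicate when
#' `P = B x P:B`).
#'
#' @param values list (one element per unit) of [boot_dist()] objects or
#'   numeric replicate vectors; strictly positive.
#' @param x standardized temperature of each unit (eV^-1), from
#'   [standardize_temperature()].
#' @param n_boot outer bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @param resample_units also resample the units themselves with replacement
#'   in each outer replicate (default FALSE: with few units, unit resampling
#'   produces frequent degenerate single-unit draws).
#' @param quantity,scope labels stored in the result.
#' @return Object of class `activation_energy` with fields `E_mean`,
#'   `ci_low`, `ci_high`, `r2`, `n_boot`, `slopes` (a [boot_dist()]),
#'   `quantity`, `scope`, `n_units`, `n_dropped` (degenerate outer
#'   replicates, only possible under `resample_units = TRUE`).
#' @export
fit_activation_energy <- function(values, x, n_boot = 10000, seed = NULL,
                                  resample_units = FALSE, quantity = NULL,
                                  scope = "among") {
  n_units <- length(values)
  if (n_units < 3L) stop("need at least 3 units to estimate a slope")
  if (length(x) != n_units) stop("x must have one entry per unit")
  unit_names <- names(values)
  if (is.null(unit_names)) unit_names <- as.character(seq_len(n_units))
  .check_positive_units(values, unit_names)
  if (stats::var(x) == 0) stop("temperatures do not vary across units")
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(values, function(v) if (is.boot_dist(v)) v$replicates else v)
  # inner draws: one replicate per unit per outer iteration, drawn
  # unit-by-unit so the index pattern depends only on (seed, unit structure)
  Y <- matrix(NA_real_, n_units, n_boot)
  for (u in seq_len(n_units)) {
    v <- reps[[u]]
    Y[u, ] <- log(v[sample.int(length(v), n_boot, replace = TRUE)])
  }
  n_dropped <- 0L
  if (resample_units) {
    U <- matrix(sample.int(n_units, n_units * n_boot, replace = TRUE),
                n_units, n_boot)
    X <- matrix(x[U], n_units, n_boot)
    Yu <- matrix(Y[cbind(as.vector(U), rep(seq_len(n_boot), each = n_units))],
                 n_units, n_boot)
    xbar <- colMeans(X); ybar <- colMeans(Yu)
    sxx <- colSums(X^2) - n_units * xbar^2
    sxy <- colSums(X * Yu) - n_units * xbar * ybar
    slopes <- sxy / sxx
    bad <- !is.finite(slopes)
    n_dropped <- sum(bad)
    if (n_dropped > 0) slopes <- slopes[!bad]
  } else {
    cx <- x - mean(x)
    sxx <- sum(cx^2)
    slopes <- colSums(cx * Y) / sxx
  }
  means <- vapply(reps, mean, numeric(1))
  pointfit <- stats::lm(log(means) ~ x)
  q <- stats::quantile(slopes, c(0.025, 0.975), names = FALSE)
  structure(list(
    E_mean = mean(slopes), ci_low = q[1], ci_high = q[2],
    r2 = suppressWarnings(summary(pointfit)$r.squared),
    n_boot = n_boot, slopes = boot_dist(slopes, seed = seed),
    quantity = quantity, scope = scope, n_units = n_units,
    n_dropped = n_dropped, point_slope = unname(stats::coef(pointfit)[2])
  ), class = "activation_energy")
}

#' @export
print.activation_energy <- function(x, digits = 3, ...) {
  cat(sprintf("Apparent activation energy%s (%s)\n",
              if (!is.null(x$quantity)) paste0(" of ", x$quantity) else "",
              x$scope))
  cat(sprintf("  E = %s eV  [95%% CI %s, %s]   r2 = %.2f   (%d units, n_boot = %d)\n",
              format(x$E_mean, digits = digits),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              x$r2, x$n_units, x$n_boot))
  invisible(x)
}

#' @export
coef.activation_energy <- function(object, ...) c(E = object$E_mean)

#' Within-stream (intra-annual) apparent activation energy
#'
#' Same estimator as [fit_activation_energy()], applied to the sampling
#' intervals of a single stream against interval mean temperature.
#'
#' @param interval_values list of [boot_dist()] per interval (e.g. daily
#'   production, mg AFDM m^-2 d^-1); at least 4 intervals.
#' @param interval_x interval mean standardized temperatures (eV^-1).
#' @param stream_id label stored in the result's scope.
#' @inheritParams fit_activation_energy
#' @param ... passed to [fit_activation_energy()].
#' @export
within_stream_E <- function(interval_values, interval_x, stream_id,
                            n_boot = 10000, seed = NULL, quantity = "P", ...) {
  if (length(interval_values) < 4L) {
    stop("need at least 4 intervals per stream")
  }
  fit_activation_energy(interval_values, interval_x, n_boot = n_boot,
                        seed = seed, quantity = quantity,
                        scope = paste0("within:", stream_id), ...)
}

#' Convert an activation energy to a proportional change per degree Celsius
#'
#' `exp(E * [1/(k T_ref) - 1/(k (T_ref + 1))]) - 1`, the fractional change in
#' a rate with activation energy `E` over a one-degree warming at the
#' reference temperature.
#'
#' @param E activation energy, eV.
#' @param T_ref_C reference temperature, degrees Celsius (default 15).
#' @return fraction per degree C (e.g. 0.098 for E = 0.67 eV at 15 C).
#' @export
percent_change_per_degC <- function(E, T_ref_C = 15) {
  T_K <- T_ref_C + 273.15
  exp(E * (1 / (boltzmann_k * T_K) - 1 / (boltzmann_k * (T_K + 1)))) - 1
}

#' Elasticity implied by a log-log slope
#'
#' For a log-log regression slope `b`, a `pct`% increase in the predictor
#' multiplies the response by `(1 + pct/100)^b`; the elasticity is that
#' factor minus one (e.g. slope 1.2 and a 10% resource increase give a
#' 12.1% production increase).
#'
#' @param slope log-log regression slope.
#' @param pct percent increase in the predictor (default 10).
#' @return fractional change in the response.
#' @export
elasticity_percent <- function(slope, pct = 10) {
  (1 + pct / 100)^slope - 1
}
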