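#' Interval secondary production by the instantaneous growth method
#'
#' `P = g * dt * (B_t + B_t_dt) / 2`: mass-specific growth times mean standing
#' biomass over the interval times interval length. Inputs may be plain
#' numerics or paired [boot_dist()] objects (computed replicate-wise).
#'
#' @param g mass-specific growth rate, d^-1; must be >= 0 in the population
#'   context (bootstrapped cohort growth guarantees positivity).
#' @param B_t,B_t_dt standing biomass at the interval endpoints, mg AFDM m^-2.
#' @param dt_days interval length, days.
#' @return production over the interval, mg AFDM m^-2 (same class as inputs).
#' @examples
#' interval_production(0.05, 100, 200, 30)  # 225
#' @export
interval_production <- function(g, B_t, B_t_dt, dt_days) {
  gv <- if (is.boot_dist(g)) g$replicates else g
  bv1 <- if (is.boot_dist(B_t)) B_t$replicates else B_t
  bv2 <- if (is.boot_dist(B_t_dt)) B_t_dt$replicates else B_t_dt
  if (any(gv < 0)) stop("negative growth rate in population production context")
  if (any(bv1 < 0) || any(bv2 < 0)) stop("biomass must be non-negative")
  if (any(dt_days <= 0)) stop("dt_days must be strictly positive")
  out <- gv * dt_days * (bv1 + bv2) / 2
  if (is.boot_dist(g) || is.boot_dist(B_t) || is.boot_dist(B_t_dt)) {
    boot_dist(out)
  } else out
}

.expand_density <- function(records) {
  # counted individuals scaled back through the subsample split and to m^-2
  records$count / records$split_fraction / records$area_m2
}

#' Bootstrap standing biomass from replicate benthic samples
#'
#' For one stream and date, resamples the replicate field samples (e.g. the
#' five Surber samples) with replacement and averages density x mass within
#' each taxon x length-bin. Subsample splits are expanded before resampling
#' (a record counted under `split_fraction` f represents `count / f`
#' individuals). All taxa and bins share the same resampled set of field
#' replicates within a bootstrap replicate, preserving spatial covariance.
#'
#' @param records data frame of size-class records for one stream with columns
#'   `date`, `replicate`, `taxon_id`, `length_bin_mm`, `count`,
#'   `split_fraction`, `area_m2`, `mass_mg`.
#' @param date the sampling date to bootstrap (must be present in `records`).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return Object of class `biomass_boot`: `key` (data frame taxon_id,
#'   length_bin_mm, mass_mg), `B` (matrix, rows = key, cols = replicates;
#'   mg AFDM m^-2), `A` (same shape; individuals m^-2), `date`,
#'   `n_replicates`.
#' @export
biomass_from_samples <- function(records, date, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- records[records$date == date, , drop = FALSE]
  if (nrow(d) == 0L) stop("no samples on date ", format(date))
  # replicate IDs are taken over the whole record set: a field replicate with
  # zero catch on this date is a genuine zero, not a missing sample
  reps <- sort(unique(records$replicate))
  R <- length(reps)
  d$density <- .expand_density(d)
  key <- unique(d[, c("taxon_id", "length_bin_mm", "mass_mg")])
  key <- key[order(key$taxon_id, key$length_bin_mm), , drop = FALSE]
  rownames(key) <- NULL
  K <- nrow(key)
  # density per key x field replicate
  dens <- matrix(0, K, R)
  ik <- match(paste(d$taxon_id, d$length_bin_mm),
              paste(key$taxon_id, key$length_bin_mm))
  ir <- match(d$replicate, reps)
  for (i in seq_len(nrow(d))) dens[ik[i], ir[i]] <- dens[ik[i], ir[i]] + d$density[i]
  idx <- matrix(sample.int(R, R * n_boot, replace = TRUE), R, n_boot)
  # weight matrix: how often each field replicate enters each bootstrap draw
  W <- matrix(0, R, n_boot)
  for (j in seq_len(n_boot)) {
    t <- tabulate(idx[, j], nbins = R)
    W[, j] <- t / R
  }
  A <- dens %*% W                      # individuals m^-2
  B <- (dens * key$mass_mg) %*% W      # mg AFDM m^-2
  structure(list(key = key, B = B, A = A, date = date,
                 n_replicates = R, n_boot = n_boot),
            class = "biomass_boot")
}

#' @export
print.biomass_boot <- function(x, ...) {
  cat(sprintf("<biomass_boot: %s, %d taxon x size-class keys, n_boot = %d>\n",
              format(x$date), nrow(x$key), x$n_boot))
  cat(sprintf("  community biomass mean %.2f mg AFDM m^-2\n",
              mean(colSums(x$B))))
  invisible(x)
}

.growth_for <- function(taxon, mass, temp_C, interval_name, growth_model,
                        measured_growth, stream_id, n_boot) {
  src <- measured_growth[[taxon]]
  if (!is.null(src)) {
    g <- if (is.boot_dist(src)) src
    else if (is.list(src) && !is.null(src[[interval_name]])) src[[interval_name]]
    else if (is.list(src)) NULL
    else stop("measured_growth entries must be boot_dist or lists of boot_dist")
    if (!is.null(g)) {
      gv <- g$replicates
      if (length(gv) != n_boot) {
        gv <- gv[sample.int(length(gv), n_boot, replace = TRUE)]
      }
      return(gv)
    }
  }
  if (is.null(growth_model)) {
    stop("no growth source for taxon '", taxon,
         "': supply a measured distribution or a growth model")
  }
  rep(predict(growth_model, M = mass, temp_C = temp_C,
              stream_id = if (growth_model$scope == "stream") stream_id),
      length.out = 1)
}

#' Bootstrap population production for one stream
#'
#' Runs the paired bootstrap of the instantaneous growth method for every
#' taxon over every sampling interval of one stream: standing biomass is
#' bootstrapped at each date from the replicate field samples
#' ([biomass_from_samples()]), a growth rate is attached to each taxon x
#' size class (a measured bootstrap distribution where available, otherwise a
#' prediction from the fitted growth model at the size-class mass and the
#' interval mean temperature), and replicate-paired size-class production
#' `g * dt * meanB` is summed over size classes.
#'
#' @param records size-class records for one stream (see
#'   [biomass_from_samples()]), with a `stream_id` column.
#' @param growth_model a [fit_growth_model()] fit used for taxa without
#'   measured growth (may be `NULL` if `measured_growth` covers all taxa).
#' @param interval_temp_C mean temperature (degrees C) of each sampling
#'   interval, length `n_dates - 1`.
#' @param measured_growth optional named list `taxon_id -> boot_dist` (or
#'   `taxon_id -> list(interval_label -> boot_dist)`) of measured growth-rate
#'   distributions; resampled to `n_boot` replicates if lengths differ.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return List of class `population_production`: `intervals` data frame,
#'   `taxa`, `P` (list: interval -> taxon -> replicate vector, mg m^-2 per
#'   interval), `biomass` (list of `biomass_boot` per date), `stream_id`,
#'   `n_boot`.
#' @export
bootstrap_population_production <- function(records, growth_model = NULL,
                                            interval_temp_C,
                                            measured_growth = list(),
                                            n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stream <- unique(records$stream_id)
  if (length(stream) != 1L) stop("records must belong to a single stream")
  dates <- sort(unique(records$date))
  if (length(dates) < 2L) stop("need at least two sampling dates")
  n_int <- length(dates) - 1L
  interval_temp_C <- rep(interval_temp_C, length.out = n_int)
  bio <- lapply(dates, function(dd)
    biomass_from_samples(records, dd, n_boot = n_boot))
  names(bio) <- as.character(dates)
  taxa <- sort(unique(records$taxon_id))
  dt <- as.numeric(diff(dates))
  P <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    iname <- as.character(dates[i])
    b1 <- bio[[i]]; b2 <- bio[[i + 1L]]
    Pi <- list()
    for (tx in taxa) {
      k1 <- which(b1$key$taxon_id == tx)
      k2 <- which(b2$key$taxon_id == tx)
      bins <- sort(unique(c(b1$key$length_bin_mm[k1], b2$key$length_bin_mm[k2])))
      if (length(bins) == 0L) { Pi[[tx]] <- numeric(n_boot); next }
      acc <- numeric(n_boot)
      for (bn in bins) {
        r1 <- k1[b1$key$length_bin_mm[k1] == bn]
        r2 <- k2[b2$key$length_bin_mm[k2] == bn]
        Bt <- if (length(r1)) b1$B[r1, ] else numeric(n_boot)
        Btdt <- if (length(r2)) b2$B[r2, ] else numeric(n_boot)
        mass <- if (length(r1)) b1$key$mass_mg[r1] else b2$key$mass_mg[r2]
        g <- .growth_for(tx, mass, interval_temp_C[i], iname, growth_model,
                         measured_growth, stream, n_boot)
        acc <- acc + g * dt[i] * (Bt + Btdt) / 2
      }
      Pi[[tx]] <- acc
    }
    P[[i]] <- Pi
  }
  structure(list(
    stream_id = stream,
    intervals = data.frame(date_t = dates[-length(dates)], date_t_dt = dates[-1],
                           dt_days = dt, temp_C = interval_temp_C),
    taxa = taxa, P = P, biomass = bio, n_boot = n_boot
  ), class = "population_production")
}

#' @export
print.population_production <- function(x, ...) {
  cat(sprintf("<population_production: stream %s, %d taxa, %d intervals, n_boot = %d>\n",
              x$stream_id, length(x$taxa), nrow(x$intervals), x$n_boot))
  invisible(x)
}

#' Aggregate population production to the community level
#'
#' Replicate-wise sum across populations within each interval: replicate `i`
#' of community production is the sum of replicates `i` of every population,
#' preserving the bootstrap pairing (never re-ordering replicate vectors).
#'
#' @param pop a `population_production` from
#'   [bootstrap_population_production()], or a list of per-population interval
#'   replicate vectors sharing `n_boot`.
#' @return List of [boot_dist()] community production per interval
#'   (mg AFDM m^-2 per interval), named by interval start date.
#' @export
aggregate_community <- function(pop) {
  Plist <- if (inherits(pop, "population_production")) pop$P else pop
  out <- lapply(Plist, function(Pi) {
    n <- vapply(Pi, length, integer(1))
    if (length(unique(n)) != 1L) stop("mismatched n_boot across populations")
    boot_dist(Reduce(`+`, Pi))
  })
  if (inherits(pop, "population_production")) {
    names(out) <- as.character(pop$intervals$date_t)
  }
  out
}

#' Annual production from interval productions
#'
#' Replicate-wise sum across the intervals of one stream-year, reported in
#' g AFDM m^-2 y^-1. Gaps longer than `max_gap_days` between consecutive
#' sampling dates trigger a warning (interpolation over long gaps is
#' unreliable) but do not stop the computation.
#'
#' @param interval_P list of [boot_dist()] interval productions
#'   (mg AFDM m^-2 per interval) sharing `n_boot`.
#' @param dt_days interval lengths, days (used for the gap check); optional.
#' @param max_gap_days warning threshold (default 45).
#' @return [boot_dist()] of annual production, g AFDM m^-2 y^-1.
#' @export
annual_production <- function(interval_P, dt_days = NULL, max_gap_days = 45) {
  if (!is.null(dt_days) && any(dt_days > max_gap_days)) {
    warning(sum(dt_days > max_gap_days),
            " sampling gap(s) exceed ", max_gap_days, " days")
  }
  bd_sum(interval_P) / 1000
}

#' Production-to-biomass ratio from paired bootstrap distributions
#'
#' Replicate-wise `P / B` (biomass turnover rate, y^-1 when `P` is annual and
#' `B` the annual mean standing biomass).
#'
#' @param P [boot_dist()] of production.
#' @param B [boot_dist()] of mean biomass, paired with `P` (same run, same
#'   replicate order).
#' @return [boot_dist()] of P:B.
#' @export
pb_ratio <- function(P, B) {
  stopifnot(is.boot_dist(P), is.boot_dist(B))
  if (any(B$replicates <= 0)) {
    stop("zero or negative biomass replicate: P:B undefined; ",
         "aggregate to a level with non-zero biomass in every replicate")
  }
  P / B
}
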