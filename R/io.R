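.study_origin <- as.Date("2011-01-01")

.day_to_date <- function(day) .study_origin + as.integer(day) - 1L

.date_to_day <- function(x, what) {
  if (is.numeric(x)) return(as.integer(x))
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("non-ISO-8601 dates in ", what, " at row(s) ",
         paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  }
  as.integer(d - .study_origin) + 1L
}

.check_schema <- function(d, required, what) {
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(d), required)
  if (length(extra)) {
    stop(what, ": unknown column(s) ", paste(extra, collapse = ", "))
  }
  invisible(d)
}

.allowed_splits <- c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16)

#' Read and validate study tables
#'
#' Readers for the CSV schemas the package writes and consumes. Dates are
#' ISO-8601 in the files and converted to study day-of-year on read (single
#' study-year convention). Validation failures name the offending rows.
#'
#' `read_samples`: size-class records (`stream_id, date, replicate, taxon_id,
#' length_bin_mm, count, split_fraction, area_m2, mass_mg`); counts must be
#' non-negative integers and split fractions in 1, 1/2, ..., 1/16.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(d, c("stream_id", "date", "replicate", "taxon_id",
                     "length_bin_mm", "count", "split_fraction", "area_m2",
                     "mass_mg"), "samples")
  d$date <- .date_to_day(d$date, "samples")
  bad <- which(d$count < 0)
  if (length(bad)) stop("samples: negative count at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  badf <- which(!vapply(d$split_fraction, function(f)
    any(abs(f - .allowed_splits) < 1e-9), logical(1)))
  if (length(badf)) stop("samples: invalid split_fraction at row(s) ",
                         paste(utils::head(badf, 5), collapse = ", "))
  if (any(d$area_m2 <= 0)) stop("samples: non-positive area_m2")
  if (any(d$mass_mg <= 0)) stop("samples: non-positive mass_mg")
  d
}

#' @rdname read_samples
#' @export
read_growth <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(d, c("taxon_id", "stream_id", "method", "date_t", "date_t_dt",
                     "W_t_mg", "W_t_dt_mg", "dt_days", "temp_C"), "growth")
  d$date_t <- .date_to_day(d$date_t, "growth")
  d$date_t_dt <- .date_to_day(d$date_t_dt, "growth")
  bad <- which(d$W_t_mg <= 0 | d$W_t_dt_mg <= 0 | d$dt_days <= 0)
  if (length(bad)) stop("growth: non-positive mass or duration at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  d
}

#' @rdname read_samples
#' @export
read_chla <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(d, c("stream_id", "date", "stone_id", "chla_mg_m2"), "chla")
  d$date <- .date_to_day(d$date, "chla")
  bad <- which(d$chla_mg_m2 < 0)
  if (length(bad)) stop("chla: negative chlorophyll at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  d
}

#' @rdname read_samples
#' @export
read_environment <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(d, c("stream_id", "date", "temp_C", "light"), "environment")
  d$day <- .date_to_day(d$date, "environment")
  d$date <- NULL
  if (any(d$temp_C < -2 | d$temp_C > 60)) {
    stop("environment: temperatures outside the physically plausible range")
  }
  d
}

#' @rdname read_samples
#' @export
read_gpp <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(d, c("stream_id", "date", "gpp", "light", "temp_C", "chla"),
                "gpp")
  d$date <- .date_to_day(d$date, "gpp")
  if (any(d$gpp <= 0)) stop("gpp: non-positive GPP")
  d
}

#' Write a simulated study to a directory of CSV files plus truth.json
#'
#' Writes `samples.csv`, `growth.csv`, `lengths.csv`, `chla.csv`,
#' `environment.csv`, `gpp.csv` (ISO-8601 dates) and `truth.json` (the
#' generating parameters).
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, file, datecols) {
    for (cc in datecols) d[[cc]] <- .day_to_date(d[[cc]])
    utils::write.csv(d, file.path(dir, file), row.names = FALSE)
  }
  w(study$samples, "samples.csv", "date")
  w(study$growth, "growth.csv", c("date_t", "date_t_dt"))
  if (!is.null(study$lengths)) w(study$lengths, "lengths.csv", "date")
  w(study$chla[, c("stream_id", "date", "stone_id", "chla_mg_m2")],
    "chla.csv", "date")
  env <- study$environment
  env$date <- .day_to_date(env$day %||% env$day)
  env <- data.frame(stream_id = env$stream_id, date = .day_to_date(env$day),
                    temp_C = env$temp_C, light = env$light)
  utils::write.csv(env, file.path(dir, "environment.csv"), row.names = FALSE)
  if (!is.null(study$gpp)) w(study$gpp, "gpp.csv", "date")
  tr <- study$truth
  tr_out <- list(
    config = unclass_config(tr$config),
    x_annual = tr$x_annual, chla_annual_true = as.list(tr$chla_annual_true),
    P_annual_target_g = as.list(tr$P_annual_target_g),
    P_annual_true_g = as.list(tr$P_annual_true_g),
    taxon_mean_mass_mg = as.list(tr$taxon_mean_mass_mg)
  )
  jsonlite::write_json(tr_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$taxa <- lapply(cfg$taxa, unclass)
  cfg
}

#' Read a study directory written by [write_study()]
#'
#' @param dir directory containing the study CSVs.
#' @return list with elements `samples`, `growth`, `chla`, `environment`,
#'   and, when present, `gpp` and `truth` (parsed truth.json).
#' @export
read_study <- function(dir) {
  out <- list(
    samples = read_samples(file.path(dir, "samples.csv")),
    growth = read_growth(file.path(dir, "growth.csv")),
    chla = read_chla(file.path(dir, "chla.csv")),
    environment = read_environment(file.path(dir, "environment.csv"))
  )
  gp <- file.path(dir, "gpp.csv")
  if (file.exists(gp)) out$gpp <- read_gpp(gp)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}

#' Run the full estimation pipeline on a study directory
#'
#' Reads the study tables, runs [estimate_study()], and writes
#' `production_intervals.csv`, `production_annual.csv`,
#' `activation_energies.csv`, `selection_report.csv`, `corrected_E.csv` and a
#' `manifest.json` recording the package version, seed, bootstrap sizes and
#' an md5 checksum of the configuration. Deterministic given (inputs, seed).
#'
#' @param input_dir study directory (as written by [write_study()]).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_boot,n_slope,n_rep_among,n_rep_within,stages passed to
#'   [estimate_study()].
#' @return the [estimate_study()] result, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, seed = 1L, n_boot = 1000,
                         n_slope = 10000, n_rep_among = 1000,
                         n_rep_within = 1000,
                         stages = c("scaling", "resources", "within", "gpp")) {
  study <- read_study(input_dir)
  est <- estimate_study(study, n_boot = n_boot, n_slope = n_slope,
                        n_rep_among = n_rep_among,
                        n_rep_within = n_rep_within, seed = seed,
                        stages = stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  iv <- do.call(rbind, lapply(est$streams, function(s) {
    ps <- est$per_stream[[s]]
    cbind(stream_id = s, ps$intervals[, c("date_t", "date_t_dt", "dt_days")],
          do.call(rbind, lapply(seq_along(ps$P_daily), function(i)
            bd_summary(ps$P_daily[[i]]))))
  }))
  iv$seed <- seed
  utils::write.csv(iv, file.path(out_dir, "production_intervals.csv"),
                   row.names = FALSE)
  an <- do.call(rbind, lapply(est$streams, function(s) {
    ps <- est$per_stream[[s]]
    cbind(stream_id = s, quantity = c("P_annual_g_m2_y", "B_annual_mg_m2", "PB_y"),
          rbind(bd_summary(ps$P_annual), bd_summary(ps$B_annual),
                bd_summary(ps$PB)))
  }))
  an$seed <- seed
  utils::write.csv(an, file.path(out_dir, "production_annual.csv"),
                   row.names = FALSE)
  ae <- activation_energy_table(est)
  if (!is.null(ae)) {
    ae$seed <- seed
    utils::write.csv(ae, file.path(out_dir, "activation_energies.csv"),
                     row.names = FALSE)
  }
  if (!is.null(est$among_selection)) {
    sel <- data.frame(scope = "among",
                      model = names(est$among_selection$freq),
                      frequency = as.numeric(est$among_selection$freq))
    if (!is.null(est$within_selection)) {
      sel <- rbind(sel, data.frame(scope = "within",
                                   model = names(est$within_selection$freq),
                                   frequency = as.numeric(est$within_selection$freq)))
    }
    sel$seed <- seed
    utils::write.csv(sel, file.path(out_dir, "selection_report.csv"),
                     row.names = FALSE)
  }
  ce <- list()
  if (!is.null(est$among_selection)) {
    ce[[1]] <- cbind(quantity = "E_among_corrected",
                     bd_summary(est$among_selection$E_corrected))
    ce[[2]] <- cbind(quantity = "E_among_apparent",
                     bd_summary(est$among_selection$E_apparent))
  }
  if (!is.null(est$E_within_corrected)) {
    ec <- est$E_within_corrected
    ce[[length(ce) + 1L]] <- data.frame(
      quantity = "E_within_corrected", mean = ec$E_mean, ci_low = ec$ci_low,
      ci_high = ec$ci_high, n_boot = ec$n_boot)
  }
  if (length(ce)) {
    ced <- do.call(rbind, ce); ced$seed <- seed
    utils::write.csv(ced, file.path(out_dir, "corrected_E.csv"),
                     row.names = FALSE)
  }
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- list(input_dir = input_dir, seed = seed, n_boot = n_boot,
              n_slope = n_slope, n_rep_among = n_rep_among,
              n_rep_within = n_rep_within, stages = stages)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "streamprod",
    version = as.character(utils::packageVersion("streamprod")),
    r_version = as.character(getRversion()),
    seed = seed, config = cfg,
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(est)
}
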