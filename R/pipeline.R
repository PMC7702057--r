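#' Estimate production, temperature dependences and resource corrections
#'
#' Runs the full estimation chain on a study's tables: fit the growth model
#' from chamber observations; bootstrap standing biomass and population /
#' community production per stream; sum to annual production; mass-correct
#' biomass and P:B by the biomass-weighted community body mass; estimate
#' among-stream and within-stream apparent activation energies by
#' double-bootstrap OLS; bootstrap annual chlorophyll and its temperature
#' dependence; run the among-stream AICc model competition (temperature vs.
#' chlorophyll); run the within-stream mixed-model competition; fit the GPP
#' model and compute the resource-corrected within-stream temperature
#' dependence.
#'
#' @param study a `sim_study` from [simulate_study()], or a list with the
#'   same tables (`samples`, `growth`, `chla`, `environment`, optionally
#'   `gpp`) read from files.
#' @param n_boot production/biomass bootstrap replicates (default 1000).
#' @param n_slope outer replicates for activation-energy slopes
#'   (default 10000).
#' @param n_rep_among among-stream model-selection replicates (default 1000).
#' @param n_rep_within within-stream mixed-model selection replicates
#'   (default 1000; the dominant cost -- each replicate fits every candidate
#'   mixed model).
#' @param seed integer seed for all estimation randomness.
#' @param T_ref_C reference temperature (default 15).
#' @param growth_scope `"global"` or `"stream"` for [fit_growth_model()].
#' @param stages character vector of optional stages to run; any of
#'   `"scaling"`, `"resources"`, `"within"` (the mixed-model stage),
#'   `"gpp"`. Defaults to all.
#' @param resample_units passed to [fit_activation_energy()].
#' @return list of class `study_estimates`; see the package vignette for the
#'   contents of each element.
#' @export
estimate_study <- function(study, n_boot = 1000, n_slope = 10000,
                           n_rep_among = 1000, n_rep_within = 1000,
                           seed = 1L, T_ref_C = 15,
                           growth_scope = "global",
                           stages = c("scaling", "resources", "within", "gpp"),
                           resample_units = FALSE) {
  set.seed(seed)
  env <- study$environment
  samples <- study$samples
  streams <- sort(unique(samples$stream_id))
  x_annual <- vapply(streams, function(s)
    standardize_temperature(mean(env$temp_C[env$stream_id == s]), T_ref_C),
    numeric(1))

  growth_model <- fit_growth_model(study$growth, T_ref_C = T_ref_C,
                                   scope = growth_scope)

  per_stream <- list()
  for (s in streams) {
    rec <- samples[samples$stream_id == s, , drop = FALSE]
    dates <- sort(unique(rec$date))
    it <- vapply(seq_len(length(dates) - 1L), function(i)
      interval_mean_temp(env, s, dates[i], dates[i + 1L]), numeric(1))
    pop <- bootstrap_population_production(rec, growth_model,
                                           interval_temp_C = it,
                                           n_boot = n_boot)
    comm <- aggregate_community(pop)
    dt <- pop$intervals$dt_days
    P_daily <- lapply(seq_along(comm), function(i) comm[[i]] / dt[i])
    P_ann <- annual_production(comm, dt_days = dt)          # g AFDM m^-2 y^-1
    # community and per-taxon annual mean biomass, replicate-wise
    nB <- length(pop$biomass)
    Bcomm <- Reduce(`+`, lapply(pop$biomass, function(b) colSums(b$B))) / nB
    taxa <- pop$taxa
    Btx <- Atx <- matrix(0, length(taxa), n_boot, dimnames = list(taxa, NULL))
    for (b in pop$biomass) {
      for (k in seq_along(taxa)) {
        rows <- which(b$key$taxon_id == taxa[k])
        if (length(rows)) {
          Btx[k, ] <- Btx[k, ] + colSums(b$B[rows, , drop = FALSE])
          Atx[k, ] <- Atx[k, ] + colSums(b$A[rows, , drop = FALSE])
        }
      }
    }
    Mtx <- Btx / Atx
    Mtx[Atx == 0] <- 0
    M_c <- weighted_community_mass(Btx / nB, Mtx)
    B_ann <- boot_dist(Bcomm)
    PB <- pb_ratio(P_ann * 1000, B_ann)                     # y^-1
    per_stream[[s]] <- list(
      pop = pop, community_interval_P = comm, P_daily = P_daily,
      P_annual = P_ann, B_annual = B_ann, PB = PB, M_c = M_c,
      B_corrected = mass_correct(B_ann, M_c, +0.25),
      PB_corrected = mass_correct(PB, M_c, -0.25),
      interval_x = standardize_temperature(it, T_ref_C),
      intervals = pop$intervals
    )
  }

  out <- list(streams = streams, x_annual = x_annual,
              growth_model = growth_model, per_stream = per_stream,
              n_boot = n_boot, seed = seed, T_ref_C = T_ref_C)

  if ("scaling" %in% stages) {
    P_list <- lapply(per_stream, `[[`, "P_annual")
    Bc_list <- lapply(per_stream, `[[`, "B_corrected")
    PBc_list <- lapply(per_stream, `[[`, "PB_corrected")
    out$E_p_among <- fit_activation_energy(P_list, x_annual, n_boot = n_slope,
                                           seed = seed, quantity = "P",
                                           resample_units = resample_units)
    out$E_b_among <- fit_activation_energy(Bc_list, x_annual, n_boot = n_slope,
                                           seed = seed, quantity = "B_corrected",
                                           resample_units = resample_units)
    out$E_pb_among <- fit_activation_energy(PBc_list, x_annual, n_boot = n_slope,
                                            seed = seed, quantity = "PB_corrected",
                                            resample_units = resample_units)
    out$E_p_within_stream <- lapply(streams, function(s) {
      ps <- per_stream[[s]]
      within_stream_E(ps$P_daily, ps$interval_x, s, n_boot = n_slope,
                      seed = seed)
    })
    names(out$E_p_within_stream) <- streams
  }

  if (any(c("resources", "within", "gpp") %in% stages)) {
    chla_ann <- annual_chla_bootstrap(study$chla, n_boot = n_boot)
    chla_ann <- chla_ann[streams]
    out$chla_annual <- chla_ann
    out$E_chla <- fit_chla_temperature(chla_ann, x_annual, n_boot = n_slope,
                                       seed = seed)
  }
  if ("resources" %in% stages) {
    out$among_selection <- among_stream_selection(
      lapply(per_stream, `[[`, "P_annual"), x_annual, chla_ann,
      n_rep = n_rep_among)
  }
  if ("within" %in% stages) {
    rows <- list(); Pd <- list(); Cd <- list()
    pos_light <- env$light[env$light > 0]
    light_floor <- if (length(pos_light)) min(pos_light) / 2 else 1e-6
    for (s in streams) {
      ps <- per_stream[[s]]
      iv <- ps$intervals
      for (i in seq_len(nrow(iv))) {
        lt <- .interval_mean_light(env, s, iv$date_t[i], iv$date_t_dt[i])
        if (lt <= 0) {
          message("zero-light interval in stream ", s, "; floor applied")
          lt <- light_floor
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stream_id = s, x = ps$interval_x[i], light = lt)
        Pd[[length(Pd) + 1L]] <- ps$P_daily[[i]]
        Cd[[length(Cd) + 1L]] <- interval_chla_bootstrap(
          study$chla, s, iv$date_t[i], iv$date_t_dt[i], n_boot = n_boot)
      }
    }
    out$within_selection <- within_stream_selection(
      do.call(rbind, rows), Pd, Cd, n_rep = n_rep_within)
  }
  if ("gpp" %in% stages && !is.null(study$gpp)) {
    out$gpp_model <- fit_gpp_model(study$gpp, n_boot = n_boot, seed = seed,
                                   T_ref_C = T_ref_C)
    if (!is.null(out$within_selection) && !is.null(out$within_selection$E_within)) {
      out$E_within_corrected <- resource_correct_within(
        out$within_selection$E_within, out$gpp_model$E_gpp,
        n_boot = n_slope, seed = seed)
    }
  }
  class(out) <- "study_estimates"
  out
}

.interval_mean_light <- function(env, stream, from, to) {
  d <- env[env$stream_id == stream & env$day >= from & env$day <= to, ]
  mean(d$light)
}

#' @export
print.study_estimates <- function(x, ...) {
  cat("Study estimates (", length(x$streams), " streams, n_boot = ",
      x$n_boot, ", seed = ", x$seed, ")\n", sep = "")
  ann <- vapply(x$per_stream, function(p) mean(p$P_annual), numeric(1))
  cat("Annual community production (g AFDM m^-2 y^-1):\n")
  for (s in x$streams) cat(sprintf("  %-6s %8.2f\n", s, ann[s]))
  if (!is.null(x$E_p_among)) print(x$E_p_among)
  if (!is.null(x$E_chla)) print(x$E_chla)
  if (!is.null(x$among_selection)) {
    cat(sprintf("Among-stream modal model: %s; corrected E = %.3f eV [%.3f, %.3f]\n",
                x$among_selection$modal, mean(x$among_selection$E_corrected),
                ci(x$among_selection$E_corrected)[1],
                ci(x$among_selection$E_corrected)[2]))
  }
  if (!is.null(x$E_within_corrected)) print(x$E_within_corrected)
  invisible(x)
}

#' Tabulate activation-energy estimates from a `study_estimates` object
#'
#' @param est a [estimate_study()] result.
#' @return data frame with columns quantity, scope, E_mean, ci_low, ci_high,
#'   r2, n_boot.
#' @export
activation_energy_table <- function(est) {
  rows <- list()
  add <- function(ae) {
    if (is.null(ae)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = ae$quantity %||% "", scope = ae$scope, E_mean = ae$E_mean,
      ci_low = ae$ci_low, ci_high = ae$ci_high, r2 = ae$r2, n_boot = ae$n_boot)
  }
  add(est$E_p_among); add(est$E_b_among); add(est$E_pb_among); add(est$E_chla)
  for (ae in est$E_p_within_stream) add(ae)
  add(est$E_within_corrected)
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
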