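# Small fixtures built in code, shared across test files.

# A tiny sampling table: one stream, `dates` dates, `R` replicate samples,
# counts supplied per taxon x bin via `cells` = data.frame(taxon_id,
# length_bin_mm, mass_mg, counts = matrix R wide per date ...).
make_samples <- function(counts, mass_mg = 1, taxon_id = "tx1",
                         length_bin_mm = 1, dates = 1, stream_id = "s1",
                         split_fraction = 1, area_m2 = 0.023) {
  # counts: vector (one date) or matrix (dates x replicates)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  rows <- list()
  for (d in seq_len(nrow(counts))) {
    for (r in seq_len(ncol(counts))) {
      rows[[length(rows) + 1L]] <- data.frame(
        stream_id = stream_id, date = dates[d], replicate = r,
        taxon_id = taxon_id, length_bin_mm = length_bin_mm,
        count = counts[d, r], split_fraction = split_fraction,
        area_m2 = area_m2, mass_mg = mass_mg)
    }
  }
  do.call(rbind, rows)
}

# growth observations lying exactly on the model surface (noise-free)
make_exact_growth <- function(ln_i0 = -3.5, a = -0.25, E = 0.65,
                              M = c(0.05, 0.2, 1, 5, 0.5, 2),
                              temp_C = c(5, 9, 13, 17, 21, 25),
                              dt = 10) {
  x <- standardize_temperature(temp_C)
  g <- exp(ln_i0 + a * log(M) + E * x)
  data.frame(taxon_id = "tx", stream_id = "s1", method = "chamber",
             date_t = 1, date_t_dt = 1 + dt,
             W_t_mg = M, W_t_dt_mg = M * exp(g * dt),
             dt_days = dt, temp_C = temp_C)
}

# small simulation config for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             sampling_dates = seq(20, 340, by = 40),
             taxa = default_taxa()[c(1, 3)],
             ...)
}

expect_boot_equal <- function(bd, value, tol = 1e-10) {
  expect_true(is.boot_dist(bd))
  expect_true(all(abs(bd$replicates - value) < tol))
}
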