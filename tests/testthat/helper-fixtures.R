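# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# Minimal well-formed PSMC text with two iterations.
psmc_two_iteration_text <- function() {
  c("CC just a comment",
    "RD 0",
    "TR 0.010 0.002",
    "RS 0 0.0 1.0",
    "RS 1 0.4 1.5",
    "//",
    "RD 1",
    "TR 0.008 0.002",
    "RS 0 0.0 1.0",
    "RS 1 0.5 2.0",
    "//")
}

# Identifiable-regime generator for recovery experiments: well-separated
# change times, contrasted migration rates, moderate deme counts.
recovery_config <- function(c, seed) {
  generator_config(n_range = c(4, 30), deme_size_range = c(500, 2e4),
                   components_range = c(c, c), migration_range = c(0.5, 5),
                   time_range = c(0.05, 5), noise = "none",
                   min_change_factor = 3, min_time_factor = 4, seed = seed)
}

# A noise-free (years, Ne) target spanning a scenario's observable window.
scenario_target <- function(sc, k = 64, t_lo_coal = 0.01,
                            t_hi_coal = 4 * sc$n_islands) {
  grid <- make_log_grid(coalescent_to_years(t_lo_coal, sc$deme_size),
                        coalescent_to_years(t_hi_coal, sc$deme_size),
                        k, unit = "years")
  exact_iicr(sc, grid)
}

# Parameter-recovery comparison at the default validation tolerances.
recovered_ok <- function(truth, est, scaling = scaling_config(),
                         tol = list(n = 1, N = 0.10, t = 0.10, M = 0.20)) {
  if (abs(est$n_islands - truth$n_islands) > tol$n) return(FALSE)
  if (abs(est$deme_size / truth$deme_size - 1) > tol$N) return(FALSE)
  if (length(truth$change_times) != length(est$change_times)) return(FALSE)
  if (length(truth$change_times) > 0) {
    t1 <- coalescent_to_years(truth$change_times, truth$deme_size, scaling)
    t2 <- coalescent_to_years(est$change_times, est$deme_size, scaling)
    if (any(abs(log(t2 / t1)) > log1p(tol$t))) return(FALSE)
  }
  if (truth$n_islands > 1 &&
      any(abs(est$migration_rates / truth$migration_rates - 1) > tol$M))
    return(FALSE)
  TRUE
}
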