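#' Configuration of the synthetic-scenario generator
#'
#' Ranges and noise settings for [random_scenario()] and [noisy_target()].
#' Defaults span the regime the fitting stage is designed for: 2-100 demes,
#' deme sizes 1e2-1e6, 1-8 migration components, scaled migration rates
#' 0.05-50, change times log-uniform on 0.01-20 coalescent units.
#' `min_change_factor` optionally forces adjacent components' migration rates
#' to differ by at least that factor, so that every change time is a genuine
#' connectivity change rather than a near-no-op.
#'
#' @param n_range integer range for the deme count.
#' @param deme_size_range range for N (log-uniform draw).
#' @param components_range integer range for the component count c.
#' @param migration_range range for M (log-uniform draw).
#' @param time_range range for change times, coalescent units (log-uniform).
#' @param noise `"none"`, `"finite_t2"` (empirical IICR of a finite T2
#'   sample — realistic, correlated noise; the default target mode) or
#'   `"lognormal"` (iid multiplicative noise).
#' @param noise_size T2 sample size for `finite_t2` (default 100000).
#' @param noise_sigma sd of log-normal noise (natural-log scale).
#' @param min_change_factor minimum ratio between adjacent migration rates
#'   (1 = unconstrained).
#' @param min_time_factor minimum ratio between consecutive change times
#'   (1 = unconstrained).
#' @param seed integer root seed (required).
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_range = c(2, 100),
                             deme_size_range = c(1e2, 1e6),
                             components_range = c(1, 8),
                             migration_range = c(0.05, 50),
                             time_range = c(0.01, 20),
                             noise = c("finite_t2", "none", "lognormal"),
                             noise_size = 1e5, noise_sigma = 0.05,
                             min_change_factor = 1, min_time_factor = 1,
                             seed) {
  noise <- match.arg(noise)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  rng <- list(n_range = n_range, deme_size_range = deme_size_range,
              components_range = components_range,
              migration_range = migration_range, time_range = time_range)
  for (nm in names(rng))
    if (length(rng[[nm]]) != 2 || rng[[nm]][1] > rng[[nm]][2])
      stop("empty or unordered range: ", nm, call. = FALSE)
  structure(c(rng, list(noise = noise, noise_size = as.integer(noise_size),
                        noise_sigma = noise_sigma,
                        min_change_factor = min_change_factor,
                        min_time_factor = min_time_factor,
                        seed = as.integer(seed))),
            class = "generator_config")
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Draw a random piecewise-stationary scenario
#'
#' Samples a valid [island_scenario()] within the configured ranges: integer
#' uniform deme and component counts, log-uniform deme size, migration rates
#' and change times (sorted).  Deterministic given `(config, index)`; the
#' `index` selects an independent sub-stream of the root seed so scenarios
#' can be enumerated.
#'
#' @param config a [generator_config()].
#' @param index scenario index (>= 1) under the root seed.
#' @return an [island_scenario()] that passes [validate_scenario()].
#' @export
random_scenario <- function(config, index = 1L) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 7919L * (as.integer(index) - 1L), {
    # sample.int on the range width: sample(a:a, 1) would draw from 1:a
    c <- config$components_range[1] +
      sample.int(config$components_range[2] - config$components_range[1] + 1L, 1L) - 1L
    n <- config$n_range[1] +
      sample.int(config$n_range[2] - config$n_range[1] + 1L, 1L) - 1L
    N <- runif_log(1, config$deme_size_range)
    for (try in 1:200) {
      tt <- sort(runif_log(c - 1, config$time_range))
      ok_t <- c == 1 || all(tt[-1] / tt[-length(tt)] >= config$min_time_factor)
      if (length(tt) > 0 && any(diff(tt) <= 0)) ok_t <- FALSE
      M <- runif_log(c, config$migration_range)
      r <- if (c > 1) M[-1] / M[-c] else numeric(0)
      ok_m <- c == 1 || all(pmax(r, 1 / r) >= config$min_change_factor)
      if (ok_t && ok_m) break
    }
    if (!ok_t || !ok_m)
      stop("could not satisfy separation constraints within 200 draws",
           call. = FALSE)
    island_scenario(n, N, tt, M)
  })
}

#' Generate a (possibly noisy) target curve from a scenario
#'
#' Produces the target a fitting run would see: the exact IICR under
#' `noise = "none"`, the empirical IICR of a finite T2 sample under
#' `"finite_t2"` (the realistic mode — noise is correlated across the grid
#' the way finite-genome PSMC estimates are), or the exact IICR with iid
#' log-normal perturbation under `"lognormal"`.
#'
#' @param scenario an [island_scenario()].
#' @param config a [generator_config()] (noise mode, size/sigma, seed).
#' @param grid optional coalescent-unit [time_grid()] (default as in
#'   [empirical_iicr()] for `finite_t2`, else 64 log points on 0.01-20).
#' @param index sub-stream index, as in [random_scenario()].
#' @return an [iicr_curve()] in coalescent units (dimensionless values).
#' @export
noisy_target <- function(scenario, config, grid = NULL, index = 1L) {
  stopifnot(inherits(config, "generator_config"))
  seed <- config$seed + 104729L * (as.integer(index) - 1L) + 1L
  if (config$noise == "finite_t2") {
    sm <- sample_t2(scenario, n_samples = config$noise_size, seed = seed)
    return(empirical_iicr(sm, grid))
  }
  if (is.null(grid)) grid <- make_log_grid(0.01, 20, 64)
  ex <- exact_iicr(scenario, grid, value_unit = "coalescent")
  if (config$noise == "none") return(ex)
  noisy <- with_seed(seed,
    ex$values * exp(stats::rnorm(length(ex$values), 0, config$noise_sigma)))
  iicr_curve(grid, noisy, value_unit = "coalescent", step = FALSE)
}

#' Build a pseudo-PSMC fixture from a known history or scenario
#'
#' Writes `.psmc` text whose final block encodes the source as a step
#' function over the atomic time intervals of a PSMC `-p` pattern (t_0 = 0,
#' then log-spaced in units of 2 N0 generations).  A panmictic history is
#' sampled directly; an island scenario contributes its *exact IICR* in Ne
#' units evaluated at each interval's geometric midpoint — producing the
#' "PSMC of a structured population" test input with fully known truth.
#' Reading the fixture back with [read_psmc()] + [scale_psmc()] recovers the
#' encoded steps to full precision.
#'
#' @param source a [panmictic_history()] or an [island_scenario()].
#' @param theta0 scaled mutation rate per bin (sets N0 = theta0 / (4 mu s)).
#' @param scaling a [scaling_config()].
#' @param pattern PSMC atomic-interval pattern (see [pattern_to_intervals()]).
#' @param t_min,t_max first positive boundary and last boundary, in units of
#'   2 N0 generations.
#' @param file optional output path.
#' @return character vector of `.psmc` lines (invisibly if `file` given).
#' @export
make_psmc_fixture <- function(source, theta0 = 0.0048,
                              scaling = scaling_config(),
                              pattern = "4+25*2+4+6",
                              t_min = 0.01, t_max = 15, file = NULL) {
  K <- pattern_to_intervals(pattern)$total
  if (K < 2) stop("pattern must span at least 2 atomic intervals", call. = FALSE)
  N0 <- theta0 / (4 * scaling$mu * scaling$bin_size)
  tk <- c(0, exp(seq(log(t_min), log(t_max), length.out = K - 1L)))
  mids <- sqrt(pmax(tk, t_min / 10) * c(tk[-1], t_max * 2))  # geometric midpoints
  if (inherits(source, "panmictic_history")) {
    gen <- mids * 2 * N0
    idx <- findInterval(gen, source$start_generations)
    idx[idx < 1L] <- 1L
    ne <- source$ne[idx]
  } else if (inherits(source, "island_scenario")) {
    t_coal <- mids * N0 / source$deme_size   # 2N0-generation -> 2N-generation units
    ne <- exact_iicr(source, time_grid(t_coal),
                     value_unit = "effective_size")$values
  } else stop("source must be a panmictic_history or island_scenario",
              call. = FALSE)
  lines <- c("RD 0",
             sprintf("TR %.17g %.17g", theta0, theta0 / 4),
             sprintf("RS %d %.17g %.17g", seq_along(tk) - 1L, tk, ne / N0),
             "//")
  attr(lines, "t_mid") <- mids      # sampling points, units of 2 N0 generations
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}

#' Study-style scenario presets
#'
#' Named 6-component n-island templates emulating the published mouse-lemur
#' connectivity-change fits: `"murinus"` (n = 84; changes at 129.1, 42.7,
#' 30.7, 13.7 and 5.1 kyr) and `"ravelobensis"` (n = 61; changes at 338.9,
#' 135.6, 27.1, 20.1 and 7.9 kyr), under mu = 1.2e-8 and g = 2.5 years.
#' The deme size and the migration rates were never published; the defaults
#' here (N = 1000; M alternating 0.5 / 5 youngest-component-first, low
#' connectivity in the most recent component) are illustrative choices that
#' reproduce the direction of the reported connectivity bar, not inferred
#' values.
#'
#' @param species `"murinus"` or `"ravelobensis"`.
#' @param deme_size illustrative deme size N.
#' @param migration_rates illustrative per-component rates, youngest first
#'   (length 6).
#' @param scaling a [scaling_config()] used to convert the kyr change times
#'   into coalescent units of 2N generations.
#' @return an [island_scenario()] with attribute `change_times_kyr`.
#' @export
study_preset <- function(species = c("murinus", "ravelobensis"),
                         deme_size = 1000,
                         migration_rates = rep(c(0.5, 5), 3),
                         scaling = scaling_config()) {
  species <- match.arg(species)
  kyr <- switch(species,
    murinus = c(5.1, 13.7, 30.7, 42.7, 129.1),
    ravelobensis = c(7.9, 20.1, 27.1, 135.6, 338.9))
  n <- switch(species, murinus = 84L, ravelobensis = 61L)
  tt <- years_to_coalescent(kyr * 1000, deme_size, scaling)
  sc <- island_scenario(n, deme_size, tt, migration_rates)
  attr(sc, "change_times_kyr") <- kyr
  attr(sc, "species") <- species
  sc
}
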