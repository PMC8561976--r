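#' Piecewise-stationary symmetric n-island scenario
#'
#' Constructs a demographic scenario in which `n_islands` demes of constant
#' diploid size `deme_size` exchange migrants symmetrically, with the scaled
#' migration rate M = 4Nm held constant within each of `c` time components and
#' changing at the component boundaries `change_times`.  Time is measured in
#' coalescent units of 2N generations, as ages before the present (present =
#' 0, increasing into the past).
#'
#' A scenario with `c` components has `c - 1` change times and `c` migration
#' rates; `migration_rates[i]` applies on the interval
#' `[change_times[i-1], change_times[i])` (with the obvious conventions at the
#' ends).  For a panmictic scenario (`n_islands = 1`) migration is meaningless
#' and is stored as zero.
#'
#' @param n_islands integer number of demes (>= 1).
#' @param deme_size effective diploid individuals per deme, N (> 0).
#' @param change_times strictly increasing positive times (coalescent units of
#'   2N generations) at which the migration rate changes; may be empty.
#' @param migration_rates scaled migration rates M = 4Nm, one per component
#'   (`length(change_times) + 1`); all must be > 0 when `n_islands > 1`.
#' @return An object of class `"island_scenario"`.
#' @seealso [validate_scenario()], [exact_iicr()], [sample_t2()]
#' @examples
#' # two components: migration drops from 10 to 0.5 one coalescent unit ago
#' sc <- island_scenario(n_islands = 20, deme_size = 1000,
#'                       change_times = 1, migration_rates = c(10, 0.5))
#' sc
#' @export
island_scenario <- function(n_islands, deme_size, change_times = numeric(0),
                            migration_rates = numeric(0)) {
  n_islands <- as.integer(n_islands)
  change_times <- as.numeric(change_times)
  if (n_islands == 1L) {
    # panmictic: rates are meaningless, stored as zeros of matching length
    migration_rates <- rep(0, length(change_times) + 1L)
  }
  x <- structure(list(n_islands = n_islands,
                      deme_size = as.numeric(deme_size),
                      change_times = change_times,
                      migration_rates = as.numeric(migration_rates)),
                 class = "island_scenario")
  bad <- validate_scenario(x)
  if (length(bad) > 0)
    stop("invalid island_scenario: ", paste(bad, collapse = "; "), call. = FALSE)
  x
}

#' Diagnose invariant violations of a scenario
#'
#' Checks the structural invariants of an [island_scenario()] and returns a
#' character vector of human-readable violations (empty when the scenario is
#' valid).  Unlike the constructor this never throws, so it can be used to
#' screen candidate parameter vectors.
#'
#' @param scenario an `island_scenario` (or a bare list with the same fields).
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_scenario <- function(scenario) {
  v <- character(0)
  n <- scenario$n_islands
  N <- scenario$deme_size
  tt <- scenario$change_times
  M <- scenario$migration_rates
  if (length(n) != 1 || is.na(n) || n < 1)
    v <- c(v, "n_islands: must be a single integer >= 1")
  if (length(N) != 1 || !is.finite(N) || N <= 0)
    v <- c(v, "deme_size: must be a single finite positive number")
  if (length(tt) > 0) {
    if (any(!is.finite(tt)) || any(tt <= 0))
      v <- c(v, "change_times: must be finite and > 0")
    else if (any(diff(tt) <= 0))
      v <- c(v, "change_times: non-increasing")
  }
  if (length(M) != length(tt) + 1L)
    v <- c(v, "migration_rates: length must be length(change_times) + 1")
  if (length(n) == 1 && !is.na(n)) {
    if (n == 1L) {
      if (length(M) > 0 && any(M != 0))
        v <- c(v, "migration_rates: must be stored as 0 when n_islands = 1")
    } else {
      if (any(!is.finite(M)) || any(M <= 0))
        v <- c(v, paste("migration_rates: absorbing structure (all M_i must be",
                        "> 0 when n_islands > 1)"))
    }
  }
  v
}

#' @export
print.island_scenario <- function(x, ...) {
  c <- length(x$migration_rates)
  cat("Piecewise-stationary n-island scenario\n")
  cat("  demes (n):     ", x$n_islands, "\n")
  cat("  deme size (N): ", format(x$deme_size), " diploids\n", sep = "")
  cat("  components:    ", c, "\n")
  if (x$n_islands > 1L) {
    bounds <- c(0, x$change_times, Inf)
    for (i in seq_len(c))
      cat(sprintf("    [%g, %g): M = %g\n", bounds[i], bounds[i + 1],
                  x$migration_rates[i]))
    cat("  (times in coalescent units of 2N generations, ages before present)\n")
  } else {
    cat("  panmictic (migration ignored)\n")
  }
  invisible(x)
}

#' Mutation-rate / generation-time scaling configuration
#'
#' Bundles the constants used to move between coalescent-scaled and physical
#' units: the per-site per-generation mutation rate `mu`, the generation time
#' in years, and the PSMC bin size `s` (bases per PSMC input bin, used in
#' N0 = theta0 / (4 mu s)).  Defaults are the mouse-lemur values used
#' throughout the package: mu = 1.2e-8 and g = 2.5 years, with the standard
#' 100-bp PSMC binning.
#'
#' @param mu per-site per-generation mutation rate (> 0).
#' @param generation_time generation time in years (> 0).
#' @param bin_size bases per PSMC bin (> 0).
#' @return An object of class `"scaling_config"`.
#' @export
scaling_config <- function(mu = 1.2e-8, generation_time = 2.5, bin_size = 100) {
  stopifnot(is.finite(mu), mu > 0,
            is.finite(generation_time), generation_time > 0,
            is.finite(bin_size), bin_size > 0)
  structure(list(mu = mu, generation_time = generation_time,
                 bin_size = bin_size),
            class = "scaling_config")
}

#' @export
print.scaling_config <- function(x, ...) {
  cat("scaling: mu =", format(x$mu), "/site/generation, g =",
      x$generation_time, "years, PSMC bin =", x$bin_size, "bp\n")
  invisible(x)
}

#' Convert coalescent time to years (and back)
#'
#' One coalescent unit is 2N generations (N = diploid deme size), so
#' `years = 2 * N_ref * t * g`.  `years_to_coalescent()` is the exact
#' algebraic inverse, and `coalescent_to_generations()` the intermediate step.
#'
#' @param t_coal time in coalescent units (2 `N_ref` generations); >= 0.
#' @param N_ref reference diploid size (> 0).
#' @param scaling a [scaling_config()] supplying the generation time.
#' @return numeric vector of times in the requested unit.
#' @examples
#' coalescent_to_years(1, 10000)           # 50000 years under g = 2.5
#' years_to_coalescent(50000, 10000)       # back to 1
#' @export
coalescent_to_years <- function(t_coal, N_ref, scaling = scaling_config()) {
  stopifnot(N_ref > 0)
  if (any(t_coal < 0)) stop("negative time", call. = FALSE)
  2 * N_ref * t_coal * scaling$generation_time
}

#' @rdname coalescent_to_years
#' @param years time in years (>= 0).
#' @export
years_to_coalescent <- function(years, N_ref, scaling = scaling_config()) {
  stopifnot(N_ref > 0)
  if (any(years < 0)) stop("negative time", call. = FALSE)
  years / (2 * N_ref * scaling$generation_time)
}

#' @rdname coalescent_to_years
#' @export
coalescent_to_generations <- function(t_coal, N_ref) {
  stopifnot(N_ref > 0)
  if (any(t_coal < 0)) stop("negative time", call. = FALSE)
  2 * N_ref * t_coal
}

#' Time grids
#'
#' A time grid is a strictly increasing vector of positive times tagged with
#' its unit (`"coalescent"`, `"generations"` or `"years"`).
#' `make_log_grid()` builds the log-uniform grid used throughout: `k` points
#' from `t_min` to `t_max` inclusive, equally spaced in log time.
#'
#' @param times strictly increasing positive finite times (>= 2 points).
#' @param unit one of `"coalescent"`, `"generations"`, `"years"`.
#' @return An object of class `"time_grid"`: the numeric times with a
#'   `unit` attribute.
#' @export
time_grid <- function(times, unit = c("coalescent", "generations", "years")) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  if (length(times) < 2) stop("a time grid needs at least 2 points", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("grid times must be finite and > 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("grid times must be strictly increasing", call. = FALSE)
  structure(times, unit = unit, class = "time_grid")
}

#' @rdname time_grid
#' @param t_min,t_max positive grid endpoints, `t_min < t_max`.
#' @param k number of points (>= 2).
#' @export
make_log_grid <- function(t_min, t_max, k = 64,
                          unit = c("coalescent", "generations", "years")) {
  if (!is.finite(t_min) || !is.finite(t_max) || t_min <= 0 || t_max <= t_min)
    stop("need 0 < t_min < t_max", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  time_grid(exp(seq(log(t_min), log(t_max), length.out = k)),
            unit = match.arg(unit))
}

grid_unit <- function(grid) attr(grid, "unit") %||% "coalescent"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Piecewise-constant panmictic size history
#'
#' The panmictic reading of a step curve: epochs starting at
#' `start_generations` (first must be 0, strictly increasing, ages before
#' present) with diploid effective size `ne` in each epoch.
#'
#' @param start_generations epoch start times in generations; first must be 0.
#' @param ne diploid effective size per epoch (> 0), same length.
#' @return An object of class `"panmictic_history"`.
#' @export
panmictic_history <- function(start_generations, ne) {
  start_generations <- as.numeric(start_generations)
  ne <- as.numeric(ne)
  if (length(start_generations) != length(ne))
    stop("start_generations and ne must have equal length", call. = FALSE)
  if (length(ne) < 1) stop("need at least one epoch", call. = FALSE)
  if (start_generations[1] != 0)
    stop("first epoch must start at 0 generations", call. = FALSE)
  if (any(diff(start_generations) <= 0))
    stop("epoch starts must be strictly increasing", call. = FALSE)
  if (any(!is.finite(ne)) || any(ne <= 0))
    stop("ne must be finite and > 0", call. = FALSE)
  structure(list(start_generations = start_generations, ne = ne),
            class = "panmictic_history")
}

#' @export
print.panmictic_history <- function(x, ...) {
  cat("Panmictic size history (", length(x$ne), " epochs, ages in generations)\n",
      sep = "")
  ends <- c(x$start_generations[-1], Inf)
  for (i in seq_along(x$ne))
    cat(sprintf("  [%g, %g): Ne = %g\n", x$start_generations[i], ends[i], x$ne[i]))
  invisible(x)
}
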