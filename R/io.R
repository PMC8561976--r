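#' Read and write scenario files
#'
#' Scenarios are exchanged as flat YAML with keys `n_islands`, `deme_size`,
#' `change_times`, `change_time_unit` (`"coalescent"` or `"years"`) and
#' `migration_rates`.  Change times given in years are converted to
#' coalescent units of 2N generations on read, using the file's own
#' `deme_size` and the supplied `scaling`.
#'
#' @param file path to a YAML scenario file.
#' @param scaling a [scaling_config()] (for year-tagged change times).
#' @return `read_scenario()`: an [island_scenario()]; `write_scenario()`:
#'   `file`, invisibly.
#' @export
read_scenario <- function(file, scaling = scaling_config()) {
  y <- yaml::read_yaml(file)
  for (k in c("n_islands", "deme_size"))
    if (is.null(y[[k]])) stop("scenario file missing key: ", k, call. = FALSE)
  tt <- as.numeric(y$change_times %||% numeric(0))
  unit <- y$change_time_unit %||% "coalescent"
  if (identical(unit, "years"))
    tt <- years_to_coalescent(tt, y$deme_size, scaling)
  else if (!identical(unit, "coalescent"))
    stop("change_time_unit must be 'coalescent' or 'years'", call. = FALSE)
  M <- as.numeric(y$migration_rates %||% numeric(0))
  if (length(M) == 0 && y$n_islands == 1) M <- rep(0, length(tt) + 1)
  island_scenario(y$n_islands, y$deme_size, tt, M)
}

#' @rdname read_scenario
#' @param scenario an [island_scenario()].
#' @param unit unit in which to store the change times.
#' @export
write_scenario <- function(scenario, file, unit = c("coalescent", "years"),
                           scaling = scaling_config()) {
  unit <- match.arg(unit)
  tt <- scenario$change_times
  if (unit == "years")
    tt <- coalescent_to_years(tt, scenario$deme_size, scaling)
  yaml::write_yaml(list(n_islands = scenario$n_islands,
                        deme_size = scenario$deme_size,
                        change_times = as.numeric(tt),
                        change_time_unit = unit,
                        migration_rates = as.numeric(scenario$migration_rates)),
                   file)
  invisible(file)
}
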