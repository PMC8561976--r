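#' IICR curves
#'
#' An IICR curve is a positive function of time sampled on a [time_grid()].
#' Values carry a unit tag: `"coalescent"` (the dimensionless ratio whose
#' panmictic value is 1) or `"effective_size"` (diploid Ne).  Curves can be
#' steps (PSMC output, right-continuous) or smooth (exact IICR, interpolated
#' log-log linearly between grid points).
#'
#' @param grid a [time_grid()] (or a numeric vector, taken as coalescent times).
#' @param values positive finite values, one per grid point.
#' @param value_unit `"coalescent"` or `"effective_size"`.
#' @param step logical: is the curve a right-continuous step function?
#' @return An object of class `"iicr_curve"`.
#' @export
iicr_curve <- function(grid, values, value_unit = c("coalescent", "effective_size"),
                       step = FALSE) {
  value_unit <- match.arg(value_unit)
  if (!inherits(grid, "time_grid")) grid <- time_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop("values and grid must have equal length", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("IICR values must be finite and > 0", call. = FALSE)
  structure(list(times = as.numeric(grid), values = values,
                 time_unit = grid_unit(grid), value_unit = value_unit,
                 step = isTRUE(step)),
            class = "iicr_curve")
}

#' @export
print.iicr_curve <- function(x, ...) {
  cat(sprintf("IICR curve: %d points, t in [%g, %g] %s, values in [%g, %g] (%s, %s)\n",
              length(x$times), min(x$times), max(x$times), x$time_unit,
              min(x$values), max(x$values), x$value_unit,
              if (x$step) "step" else "smooth"))
  invisible(x)
}

#' @export
as.data.frame.iicr_curve <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' Evaluate a curve at arbitrary times
#'
#' Step curves are evaluated right-continuously (the value of the step whose
#' start is the largest grid time <= t; times before the first step take the
#' first value).  Smooth curves are interpolated linearly in (log t, log v)
#' and extrapolated flat beyond the grid.
#'
#' @param curve an [iicr_curve()].
#' @param times times (same unit as the curve's grid).
#' @return numeric vector of curve values at `times`.
#' @export
eval_curve <- function(curve, times) {
  stopifnot(inherits(curve, "iicr_curve"))
  tt <- curve$times; vv <- curve$values
  if (curve$step) {
    idx <- findInterval(times, tt)
    idx[idx < 1L] <- 1L
    vv[idx]
  } else {
    lt <- log(times)
    out <- stats::approx(log(tt), log(vv), xout = lt, rule = 2)$y
    exp(out)
  }
}

#' Convert an IICR curve between unit systems
#'
#' Rescales the time axis (coalescent <-> generations <-> years) and/or the
#' value axis (coalescent ratio <-> diploid Ne) using a reference size
#' `N_ref` and a [scaling_config()].
#'
#' @param curve an [iicr_curve()].
#' @param time_unit,value_unit target units.
#' @param N_ref reference diploid size used for both axes.
#' @param scaling a [scaling_config()].
#' @return the converted [iicr_curve()].
#' @export
convert_curve <- function(curve, time_unit = curve$time_unit,
                          value_unit = curve$value_unit,
                          N_ref, scaling = scaling_config()) {
  stopifnot(inherits(curve, "iicr_curve"))
  tt <- curve$times
  g <- scaling$generation_time
  if (!identical(time_unit, curve$time_unit)) {
    to_years <- switch(curve$time_unit,
      coalescent = 2 * N_ref * g, generations = g, years = 1)
    from_years <- switch(time_unit,
      coalescent = 2 * N_ref * g, generations = g, years = 1)
    tt <- tt * to_years / from_years
  }
  vv <- curve$values
  if (!identical(value_unit, curve$value_unit)) {
    vv <- if (value_unit == "effective_size") vv * N_ref else vv / N_ref
  }
  iicr_curve(time_grid(tt, unit = time_unit), vv, value_unit = value_unit,
             step = curve$step)
}

#' Read and write two-column curve tables
#'
#' Plain-text interchange format: a one-line header
#' `# time_unit=<u> value_unit=<u> step=<TRUE|FALSE>` followed by
#' whitespace-separated `time value` rows.
#'
#' @param curve an [iicr_curve()].
#' @param file path (or connection) to write to / read from.
#' @return `write_curve()` returns `file` invisibly; `read_curve()` returns
#'   an [iicr_curve()].
#' @export
write_curve <- function(curve, file) {
  stopifnot(inherits(curve, "iicr_curve"))
  header <- sprintf("# time_unit=%s value_unit=%s step=%s",
                    curve$time_unit, curve$value_unit, curve$step)
  writeLines(c(header,
               sprintf("%.17g\t%.17g", curve$times, curve$values)),
             file)
  invisible(file)
}

#' @rdname write_curve
#' @export
read_curve <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("curve table needs a header and >= 2 rows", call. = FALSE)
  hdr <- lines[1]
  get <- function(key, default) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ \t]+"), hdr))
    if (length(m) == 0) default else sub(paste0(key, "="), "", m)
  }
  time_unit <- get("time_unit", "coalescent")
  value_unit <- get("value_unit", "coalescent")
  step <- as.logical(get("step", "FALSE"))
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(body), "[ \t]+")
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  iicr_curve(time_grid(mat[1, ], unit = time_unit), mat[2, ],
             value_unit = value_unit, step = step)
}

#' @export
plot.iicr_curve <- function(x, add = FALSE, log = "xy", col = "black",
                            lwd = 2, xlab = NULL, ylab = NULL, ...) {
  if (is.null(xlab)) xlab <- paste0("time (", x$time_unit, ", before present)")
  if (is.null(ylab)) ylab <- if (x$value_unit == "effective_size")
    "IICR (diploid Ne)" else "IICR (coalescent units)"
  f <- if (x$step) function(...) graphics::lines(..., type = "s") else graphics::lines
  if (!add) {
    graphics::plot(x$times, x$values, type = "n", log = log,
                   xlab = xlab, ylab = ylab, ...)
  }
  if (x$step) graphics::lines(x$times, x$values, type = "s", col = col, lwd = lwd)
  else graphics::lines(x$times, x$values, col = col, lwd = lwd)
  invisible(x)
}
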