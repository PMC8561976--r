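#' Read an IICR curve as a panmictic size history
#'
#' The panmictic interpretation of a PSMC/IICR curve: under random mating the
#' IICR *is* the effective-size trajectory, so a step curve maps one-to-one
#' onto epochs (step starts become epoch starts in generations, values become
#' Ne) and a smooth curve is discretized onto its own grid as steps.  Applied
#' to the IICR of a structured population of constant size, this reading
#' manufactures size changes that never happened — the central confound this
#' package exists to expose.
#'
#' @param curve an [iicr_curve()] with `effective_size` values and a `years`
#'   or `generations` time axis.
#' @param scaling a [scaling_config()] (for the years -> generations step).
#' @return a [panmictic_history()].
#' @export
iicr_as_ne_history <- function(curve, scaling = scaling_config()) {
  stopifnot(inherits(curve, "iicr_curve"))
  if (curve$value_unit != "effective_size")
    stop("curve values must carry the effective_size unit tag", call. = FALSE)
  if (!curve$time_unit %in% c("years", "generations"))
    stop("curve time axis must be years or generations (coalescent times ",
         "need a reference size; use convert_curve())", call. = FALSE)
  starts_years <- attr(curve, "step_starts_years")  # PSMC curves keep t0 = 0
  if (!is.null(starts_years) && length(starts_years) == length(curve$times)) {
    gen <- starts_years / scaling$generation_time
  } else if (curve$time_unit == "years") {
    gen <- curve$times / scaling$generation_time
  } else {
    gen <- curve$times
  }
  ne <- curve$values
  if (gen[1] > 0) {           # a grid starting after 0 pins the present epoch
    gen <- c(0, gen)
    ne <- c(ne[1], ne)
  }
  keep <- c(TRUE, diff(gen) > 0)
  gen <- gen[keep]; ne <- ne[keep]
  # canonical form: merge adjacent epochs with identical size
  runs <- c(TRUE, ne[-1] != ne[-length(ne)])
  panmictic_history(gen[runs], ne[runs])
}

#' Side-by-side panmictic vs structured reading of a curve
#'
#' Runs both interpretations of a target IICR/PSMC curve: the direct
#' panmictic identification (curve = size history) and a structured
#' connectivity-change fit via [fit_islands()], scoring both against the
#' target with the same log10 distance.  The report deliberately ranks
#' neither reading — the point is that both can explain the same curve — and
#' carries the re-inference identifiability check for the structured fit.
#'
#' @param target an [iicr_curve()] (years or generations, effective_size).
#' @param n_components component count for the structured fit.
#' @param bounds,control,scaling,seed passed to [fit_islands()].
#' @param validate run [validate_by_reinference()] on the structured fit?
#' @param annotations optional data.frame of labelled time windows
#'   (`label`, `start_years`, `end_years`), e.g. LIG 132-112 kyr, LGM
#'   26.5-19 kyr, AHP 15-5 kyr; carried through for plotting only, never used
#'   in computation.
#' @return An object of class `"interpretation_report"`.
#' @export
interpretation_report <- function(target, n_components, bounds = list(),
                                  control = fit_control(),
                                  scaling = scaling_config(), seed,
                                  validate = TRUE, annotations = NULL) {
  stopifnot(inherits(target, "iicr_curve"))
  fit <- fit_islands(target, n_components, bounds = bounds, control = control,
                     scaling = scaling, seed = seed)
  pan <- iicr_as_ne_history(target, scaling)
  # the panmictic reading re-encoded as a step curve, scored like the fit
  g <- scaling$generation_time
  st <- pan$start_generations * g
  ne <- pan$ne
  if (length(st) == 1L) {              # flat history: constant two-point step
    st <- range(fit$grid_years)
    ne <- rep(ne, 2)
  } else {
    st[1] <- min(fit$grid_years[1], st[2] / 100)
  }
  pan_curve <- iicr_curve(time_grid(st, unit = "years"), ne,
                          value_unit = "effective_size", step = TRUE)
  grid <- time_grid(fit$grid_years, unit = "years")
  pan_dist <- curve_distance(pan_curve, fit$target, grid = grid)
  rep <- if (validate) validate_by_reinference(fit) else NULL
  structure(list(target = target, panmictic = pan,
                 panmictic_distance = pan_dist,
                 structured = fit, structured_distance = fit$distance,
                 reinference = rep, annotations = annotations),
            class = "interpretation_report")
}

#' @export
print.interpretation_report <- function(x, ...) {
  cat("Two readings of the same curve (neither is declared true):\n\n")
  cat(sprintf("Panmictic reading: %d size epochs, distance to target %.4g\n",
              length(x$panmictic$ne), x$panmictic_distance))
  rng <- range(x$panmictic$ne)
  cat(sprintf("  Ne range %.4g - %.4g\n", rng[1], rng[2]))
  cat(sprintf("\nStructured reading: distance to target %.4g\n",
              x$structured_distance))
  print(x$structured$scenario)
  tl <- connectivity_timeline(x$structured$scenario, x$structured$scaling)
  if (nrow(tl) > 0) {
    cat("  Connectivity changes (oldest first):\n")
    print(tl, row.names = FALSE)
  }
  if (!is.null(x$reinference)) {
    cat("\n")
    print(x$reinference)
  }
  invisible(x)
}

#' @export
plot.interpretation_report <- function(x, ...) {
  fit <- x$structured
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(fit, main = "structured reading")
  g <- fit$scaling$generation_time
  st <- pmax(x$panmictic$start_generations * g, fit$grid_years[1])
  plot(fit$target, col = "grey40", main = "panmictic reading")
  graphics::lines(st, x$panmictic$ne, type = "s", col = "darkgreen", lwd = 2)
  if (!is.null(x$annotations))
    graphics::rect(x$annotations$start_years, graphics::par("usr")[3],
                   x$annotations$end_years, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  invisible(x)
}
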