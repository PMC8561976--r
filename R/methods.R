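#' @export
print.island_fit <- function(x, ...) {
  cat("Fitted n-island connectivity-change scenario\n")
  cat(sprintf("  components: %d   distance: %.4g   candidate evaluations: %d   seed: %s\n",
              x$n_components, x$distance, x$evals, format(x$seed)))
  print(x$scenario)
  invisible(x)
}

#' @export
coef.island_fit <- function(object, ...) {
  sc <- object$scenario
  out <- c(n = sc$n_islands, N = sc$deme_size)
  if (length(sc$change_times) > 0) {
    ty <- coalescent_to_years(sc$change_times, sc$deme_size, object$scaling)
    names(ty) <- paste0("t", seq_along(ty), "_years")
    out <- c(out, ty)
  }
  if (sc$n_islands > 1L) {
    M <- sc$migration_rates
    names(M) <- paste0("M", seq_along(M))
    out <- c(out, M)
  }
  out
}

#' Model IICR of a fitted scenario
#'
#' @param object an [fit_islands()] result.
#' @param times times in years (default: the fit's comparison grid).
#' @param ... unused.
#' @return an [iicr_curve()] in (years, effective_size).
#' @export
predict.island_fit <- function(object, times = object$grid_years, ...) {
  exact_iicr(object$scenario, time_grid(times, unit = "years"),
             sampling = object$sampling, scaling = object$scaling,
             value_unit = "effective_size")
}

#' @export
fitted.island_fit <- function(object, ...) {
  predict(object)$values
}

#' @export
residuals.island_fit <- function(object, ...) {
  log10(object$target_values) - log10(fitted(object))
}

#' @export
summary.island_fit <- function(object, ...) {
  structure(list(fit = object,
                 coef = coef(object),
                 timeline = connectivity_timeline(object$scenario,
                                                  object$scaling),
                 rmse_log10 = sqrt(object$distance)),
            class = "summary.island_fit")
}

#' @export
print.summary.island_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMS log10 misfit on grid: %.4g\n", x$rmse_log10))
  if (nrow(x$timeline) > 0) {
    cat("  Connectivity changes (oldest first):\n")
    print(x$timeline, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.island_fit <- function(x, show_changes = TRUE, ...) {
  tgt <- x$target
  mod <- predict(x)
  yl <- range(tgt$values, mod$values)
  plot(tgt, col = "grey40", ylim = yl, ...)
  plot(mod, add = TRUE, col = "firebrick")
  if (show_changes && length(x$scenario$change_times) > 0) {
    ty <- coalescent_to_years(x$scenario$change_times, x$scenario$deme_size,
                              x$scaling)
    graphics::abline(v = ty, lty = 3, col = "steelblue")
  }
  graphics::legend("topleft", legend = c("target", "fitted scenario"),
                   col = c("grey40", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate coalescence times from a fitted scenario
#'
#' @param object an [fit_islands()] result.
#' @param nsim number of T2 draws.
#' @param seed integer seed (default: the fit's seed).
#' @param ... unused.
#' @return a [sample_t2()] object.
#' @export
simulate.island_fit <- function(object, nsim = 1e5, seed = object$seed, ...) {
  sample_t2(object$scenario, n_samples = nsim, sampling = object$sampling,
            seed = seed)
}
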