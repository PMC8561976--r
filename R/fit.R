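#' Distance between two IICR curves
#'
#' Weighted mean squared difference of log10 values over a comparison grid —
#' the metric PSMC-style log-log plots suggest.  Step curves are evaluated
#' right-continuously, smooth curves log-log interpolated (see
#' [eval_curve()]).  The distance is symmetric and zero iff the curves agree
#' on the grid.
#'
#' @param model,target [iicr_curve()]s in the same units.
#' @param grid optional [time_grid()]; default: 64 log points spanning the
#'   overlap of the two curves' time ranges.
#' @param weights optional non-negative per-point weights (default uniform).
#' @return non-negative scalar.
#' @export
curve_distance <- function(model, target, grid = NULL, weights = NULL) {
  stopifnot(inherits(model, "iicr_curve"), inherits(target, "iicr_curve"))
  if (!identical(model$value_unit, target$value_unit) ||
      !identical(model$time_unit, target$time_unit))
    stop("curves must share time and value units", call. = FALSE)
  if (is.null(grid)) {
    lo <- max(min(model$times), min(target$times))
    hi <- min(max(model$times), max(target$times))
    if (!(lo < hi)) stop("curves do not overlap in time", call. = FALSE)
    grid <- make_log_grid(lo, hi, 64, unit = model$time_unit)
  }
  a <- eval_curve(model, as.numeric(grid))
  b <- eval_curve(target, as.numeric(grid))
  if (any(a <= 0) || any(b <= 0)) stop("non-positive curve values", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(grid))
  stats::weighted.mean((log10(a) - log10(b))^2, weights)
}

#' Optimizer control for scenario fitting
#'
#' Settings of the seeded differential-evolution search used by
#' [fit_islands()]: population size (default `max(40, 20 d)` for `d` free
#' parameters), number of generations, the DE mutation-factor floor `F`
#' (each mutation dithers its factor uniformly on `[F, 1]`), the crossover
#' rate `CR`, an optional early-stopping distance, and the size of the
#' comparison grid.
#'
#' @param pop population size (default chosen from the dimension).
#' @param iters number of DE generations.
#' @param F mutation-factor floor in (0, 1].
#' @param CR crossover probability in (0, 1].
#' @param min_distance stop early once the best distance falls below this.
#' @param grid_points number of log-grid points for the distance.
#' @return list of class `"fit_control"`.
#' @export
fit_control <- function(pop = NULL, iters = 400, F = 0.5, CR = 0.9,
                        min_distance = 0, grid_points = 64) {
  if (iters < 1) stop("budget must be >= 1 generation", call. = FALSE)
  structure(list(pop = pop, iters = as.integer(iters), F = F, CR = CR,
                 min_distance = min_distance,
                 grid_points = as.integer(grid_points)),
            class = "fit_control")
}

# Decode a DE parameter vector into an island_scenario.
# Layout: (n_cont, log10 N, log10 t_years[1..c-1], log10 M[1..c]).
decode_candidate <- function(par, c, n_bounds, g) {
  n <- as.integer(round(par[1]))
  n <- max(n_bounds[1], min(n_bounds[2], n))
  N <- 10^par[2]
  t_years <- if (c > 1) sort(10^par[3:(1 + c)]) else numeric(0)
  M <- 10^par[(2 + c):(1 + 2 * c)]
  t_coal <- t_years / (2 * N * g)
  # enforce strict increase after sorting (ties have measure zero but guard)
  if (c > 1 && any(diff(t_coal) <= 0))
    t_coal <- cummax(t_coal) * (1 + 1e-12 * seq_along(t_coal))
  list(n = n, N = N, t_coal = t_coal, t_years = t_years, M = M)
}

# Model IICR (diploid Ne) at times given in years; NA beyond support.
model_values_years <- function(cand, years, sampling, g) {
  if (cand$n == 1L) return(rep(cand$N, length(years)))
  sc <- list(n_islands = cand$n, deme_size = cand$N,
             change_times = cand$t_coal, migration_rates = cand$M)
  t_coal <- years / (2 * cand$N * g)
  p <- state_probs_sd(sc, t_coal, sampling)
  surv <- p[1, ] + p[2, ]
  out <- ifelse(surv < 1e-12, NA_real_, cand$N * surv / p[1, ])
  out
}

#' Fit a connectivity-change n-island scenario to a target IICR
#'
#' Searches for the piecewise-stationary n-island scenario (deme count `n`,
#' deme size `N`, change times `t_i`, migration rates `M_i`) whose exact IICR
#' is closest — in mean squared log10 distance on a log time grid — to a
#' target curve (typically a rescaled PSMC curve or a simulated IICR).  The
#' search is a seeded, bound-constrained differential evolution over
#' (`N`, `t_i`, `M_i`) in log10 space with the integer `n` relaxed to a
#' rounded continuous coordinate; it is fully reproducible given `seed`, and
#' with a fixed seed a larger budget can only improve the returned distance.
#'
#' @param target an [iicr_curve()] in `effective_size` values with a `years`
#'   or `generations` time axis (convert coalescent-unit curves with
#'   [convert_curve()] first).
#' @param n_components number of migration components `c` (>= 1); the
#'   scenario has `c - 1` change times.  Fixed per run; see
#'   [fit_components_sweep()] for a convenience sweep.
#' @param bounds list of box bounds: `n` (integer pair), `N`, `M` (shared box
#'   for every component, or a 2 x c matrix), and `t` in years (shared box
#'   for every change time; default: the target's time range).
#' @param control a [fit_control()].
#' @param scaling a [scaling_config()].
#' @param sampling lineage sampling configuration of the model IICR.
#' @param seed integer seed (required).
#' @param weights optional per-point distance weights.
#' @return An object of class `"island_fit"` with the fitted
#'   [island_scenario()], the achieved distance, the number of candidate
#'   evaluations, and the data needed by its methods (`print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`, `simulate`).
#' @examples
#' sc <- island_scenario(10, 1000, change_times = 1, migration_rates = c(1, 5))
#' tg <- exact_iicr(sc, make_log_grid(500, 5e5, 64, unit = "years"))
#' fit <- fit_islands(tg, n_components = 2, seed = 1,
#'                    control = fit_control(iters = 40))
#' coef(fit)
#' @export
fit_islands <- function(target, n_components,
                        bounds = list(), control = fit_control(),
                        scaling = scaling_config(),
                        sampling = c("same_deme", "different_demes"),
                        seed, weights = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(target, "iicr_curve"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (target$value_unit != "effective_size")
    stop("target values must be in effective_size units", call. = FALSE)
  if (target$time_unit == "coalescent")
    stop("target time axis must be years or generations; use convert_curve()",
         call. = FALSE)
  g <- scaling$generation_time
  tgt <- if (target$time_unit == "generations") {
    iicr_curve(time_grid(target$times * g, unit = "years"), target$values,
               value_unit = "effective_size", step = target$step)
  } else target
  c <- as.integer(n_components)
  if (c < 1) stop("n_components must be >= 1", call. = FALSE)

  b <- list(n = bounds$n %||% c(1, 100),
            N = bounds$N %||% c(1e2, 1e6),
            M = bounds$M %||% c(0.05, 50),
            t = bounds$t %||% range(tgt$times))
  for (nm in names(b))
    if (any(b[[nm]][1] >= b[[nm]][2]))
      stop("infeasible bounds for ", nm, " (need low < high)", call. = FALSE)
  d <- 1L + 1L + (c - 1L) + c
  lo <- c(b$n[1] - 0.49, log10(b$N[1]), rep(log10(b$t[1]), c - 1L),
          rep(log10(b$M[1]), c))
  hi <- c(b$n[2] + 0.49, log10(b$N[2]), rep(log10(b$t[2]), c - 1L),
          rep(log10(b$M[2]), c))

  # step targets (PSMC curves) are sampled once per step at its geometric
  # centre — the point where a step value represents its interval — which
  # avoids the transition-time quantization bias a fixed log grid would
  # introduce; smooth targets use a plain log grid
  grid <- if (tgt$step && length(tgt$times) > 2) {
    mids <- sqrt(tgt$times[-length(tgt$times)] * tgt$times[-1])
    if (length(mids) > control$grid_points)
      mids <- mids[unique(round(seq(1, length(mids),
                                    length.out = control$grid_points)))]
    time_grid(mids, unit = "years")
  } else {
    make_log_grid(min(tgt$times), max(tgt$times), control$grid_points,
                  unit = "years")
  }
  tv <- eval_curve(tgt, as.numeric(grid))
  ltv <- log10(tv)
  w <- weights %||% rep(1, length(grid))
  w <- w / sum(w)
  gy <- as.numeric(grid)

  objective <- function(par) {
    cand <- decode_candidate(par, c, b$n, g)
    mv <- model_values_years(cand, gy, sampling, g)
    bad <- is.na(mv)
    if (any(bad)) return(1e6 + sum(bad))      # beyond-support penalty
    sum(w * (log10(mv) - ltv)^2)
  }

  P <- control$pop %||% max(40L, 20L * d)
  G <- control$iters
  Fm <- control$F; CR <- control$CR
  evals <- 0L
  res <- with_seed(seed, {
    X <- matrix(stats::runif(P * d, rep(lo, each = P), rep(hi, each = P)),
                nrow = P)
    fx <- apply(X, 1, objective)
    evals <- P
    trace <- numeric(G)
    gb <- which.min(fx)
    gbest_par <- X[gb, ]; gbest_val <- fx[gb]   # global best, restart-proof
    cur_best <- gbest_val                       # best of the current era
    last_gain <- 0L
    for (gen in seq_len(G)) {
      # stall-triggered full restart: a population whose own best has not
      # improved for 80 generations has collapsed into a basin; a fresh
      # random population explores anew while the best-so-far is kept aside.
      # The trigger watches the current era's best (not the global one), so
      # a fresh population converging toward a deep optimum is never wiped
      # mid-descent.  It is a deterministic function of the trajectory, so
      # runs stay reproducible and a longer budget replays a shorter one
      # exactly.
      if (gen - last_gain >= 80L && gbest_val > control$min_distance) {
        X <- matrix(stats::runif(P * d, rep(lo, each = P), rep(hi, each = P)),
                    nrow = P)
        fx <- apply(X, 1, objective)
        evals <- evals + P
        cur_best <- min(fx)
        last_gain <- gen
      }
      for (i in seq_len(P)) {
        r <- sample.int(P - 1L, 3L)
        r <- r + (r >= i)                      # three indices distinct from i
        # F dithered per mutation: protects against population collapse on
        # multimodal landscapes while keeping full reproducibility
        Fi <- stats::runif(1, Fm, 1)
        mut <- X[r[1], ] + Fi * (X[r[2], ] - X[r[3], ])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mut, X[i, ])
        trial <- pmin(pmax(trial, lo), hi)
        ft <- objective(trial)
        evals <- evals + 1L
        if (ft <= fx[i]) { X[i, ] <- trial; fx[i] <- ft }
      }
      gen_best <- which.min(fx)
      if (fx[gen_best] < cur_best * (1 - 1e-9)) {
        cur_best <- fx[gen_best]
        last_gain <- gen
      }
      if (fx[gen_best] < gbest_val) {
        gbest_val <- fx[gen_best]
        gbest_par <- X[gen_best, ]
      }
      trace[gen] <- gbest_val
      if (gbest_val <= control$min_distance) { trace <- trace[seq_len(gen)]; break }
    }
    list(par = gbest_par, value = gbest_val, trace = trace)
  })

  cand <- decode_candidate(res$par, c, b$n, g)
  scenario <- if (cand$n == 1L) island_scenario(1L, cand$N)
              else island_scenario(cand$n, cand$N, cand$t_coal, cand$M)
  structure(list(scenario = scenario, distance = res$value, evals = evals,
                 seed = seed, n_components = c, bounds = b, control = control,
                 scaling = scaling, sampling = sampling,
                 target = tgt, grid_years = gy, target_values = tv,
                 weights = w, trace = res$trace,
                 t_years = cand$t_years),
            class = "island_fit")
}

#' Sweep the component count of a scenario fit
#'
#' Convenience wrapper: fits the target for each component count in `c_values`
#' and reports the achieved distance per `c`.  No penalized model selection is
#' performed — the sweep only exposes the distance-vs-complexity trade-off.
#'
#' @inheritParams fit_islands
#' @param c_values integer vector of component counts to try.
#' @return list with `fits` (one [fit_islands()] result per c) and `summary`
#'   (data.frame of c, distance, evals).
#' @export
fit_components_sweep <- function(target, c_values, bounds = list(),
                                 control = fit_control(),
                                 scaling = scaling_config(),
                                 sampling = "same_deme", seed) {
  fits <- lapply(seq_along(c_values), function(i)
    fit_islands(target, c_values[i], bounds = bounds, control = control,
                scaling = scaling, sampling = sampling, seed = seed + i - 1L))
  list(fits = fits,
       summary = data.frame(c = c_values,
                            distance = vapply(fits, `[[`, 0, "distance"),
                            evals = vapply(fits, `[[`, 0L, "evals")))
}

#' Timeline of inferred connectivity changes
#'
#' Flattens a scenario into its change events: for each change time, the
#' migration rate on the older side (`M_before`), on the younger side
#' (`M_after`), and whether connectivity increased or decreased going forward
#' in time (past to present).  Times are reported in kyr before present.
#'
#' @param scenario an [island_scenario()].
#' @param scaling a [scaling_config()].
#' @param order `"oldest_first"` (default) or `"youngest_first"`.
#' @return data.frame with columns `time_kyr`, `M_before`, `M_after`,
#'   `direction`; zero rows for single-component scenarios.
#' @export
connectivity_timeline <- function(scenario, scaling = scaling_config(),
                                  order = c("oldest_first", "youngest_first")) {
  order <- match.arg(order)
  tt <- scenario$change_times
  if (length(tt) == 0)
    return(data.frame(time_kyr = numeric(0), M_before = numeric(0),
                      M_after = numeric(0), direction = character(0)))
  kyr <- coalescent_to_years(tt, scenario$deme_size, scaling) / 1000
  M <- scenario$migration_rates
  before <- M[seq_along(tt) + 1L]   # older component
  after <- M[seq_along(tt)]         # younger component
  out <- data.frame(time_kyr = kyr, M_before = before, M_after = after,
                    direction = ifelse(after > before, "increase", "decrease"))
  if (order == "oldest_first") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a fitted scenario by re-inference
#'
#' The self-consistency check used to decide whether a fitted scenario can be
#' trusted: the exact IICR of the fitted scenario becomes a new, noise-free
#' target; the fit is re-run from a fresh seed; and the re-inferred
#' parameters are compared with the fitted ones — deme count within an
#' absolute band, deme size and migration rates by relative error, change
#' times on the log scale.  A scenario whose parameters the method cannot
#' recover from its own IICR is weakly identified and should not be
#' over-interpreted.
#'
#' @param fit an [fit_islands()] result.
#' @param tolerances list with elements `n` (absolute), `N`, `t`, `M`
#'   (relative); defaults 1, 0.10, 0.10, 0.20.
#' @param seed seed for the re-inference run (default: the fit's seed + 1000).
#' @param control optional [fit_control()] (default: the fit's own).
#' @return An object of class `"reinference_report"`.
#' @export
validate_by_reinference <- function(fit,
                                    tolerances = list(n = 1, N = 0.10,
                                                      t = 0.10, M = 0.20),
                                    seed = NULL, control = NULL) {
  stopifnot(inherits(fit, "island_fit"))
  seed <- seed %||% (fit$seed + 1000L)
  control <- control %||% fit$control
  sc1 <- fit$scenario
  new_target <- exact_iicr(sc1, time_grid(fit$grid_years, unit = "years"),
                           sampling = fit$sampling, scaling = fit$scaling,
                           value_unit = "effective_size")
  refit <- fit_islands(new_target, fit$n_components, bounds = fit$bounds,
                       control = control, scaling = fit$scaling,
                       sampling = fit$sampling, seed = seed)
  sc2 <- refit$scenario
  errs <- list(); pass <- list(); notes <- character(0)
  errs$n <- abs(sc2$n_islands - sc1$n_islands)
  pass$n <- errs$n <= tolerances$n
  errs$N <- abs(sc2$deme_size / sc1$deme_size - 1)
  pass$N <- errs$N <= tolerances$N
  if (sc1$n_islands > 1L && sc2$n_islands > 1L &&
      length(sc1$change_times) == length(sc2$change_times)) {
    t1 <- coalescent_to_years(sc1$change_times, sc1$deme_size, fit$scaling)
    t2 <- coalescent_to_years(sc2$change_times, sc2$deme_size, fit$scaling)
    errs$t <- if (length(t1) > 0) abs(log(t2 / t1)) else numeric(0)
    pass$t <- all(errs$t <= log1p(tolerances$t))
    errs$M <- abs(sc2$migration_rates / sc1$migration_rates - 1)
    pass$M <- all(errs$M <= tolerances$M)
  } else if (sc1$n_islands == 1L && sc2$n_islands == 1L) {
    errs$t <- numeric(0); errs$M <- numeric(0)
    pass$t <- TRUE; pass$M <- TRUE
    notes <- c(notes, "panmictic scenario: only n and N compared")
  } else {
    errs$t <- NA_real_; errs$M <- NA_real_
    pass$t <- FALSE; pass$M <- FALSE
    notes <- c(notes, "structural mismatch between original and re-inferred scenario")
  }
  verdict <- all(unlist(pass))
  if (!verdict && (!pass$n || !pass$N))
    notes <- c(notes, "weakly identified: deme count and deme size trade off")
  structure(list(original = sc1, reinferred = sc2, refit = refit,
                 errors = errs, tolerances = tolerances, pass = pass,
                 verdict = verdict, notes = notes, seed = seed),
            class = "reinference_report")
}

#' @export
print.reinference_report <- function(x, ...) {
  cat("Re-inference validation:", if (x$verdict) "PASS" else "FAIL", "\n")
  cat(sprintf("  n:  %d -> %d (|diff| = %g, tol %g) %s\n",
              x$original$n_islands, x$reinferred$n_islands, x$errors$n,
              x$tolerances$n, if (x$pass$n) "ok" else "FAIL"))
  cat(sprintf("  N:  %.4g -> %.4g (rel err %.3g, tol %g) %s\n",
              x$original$deme_size, x$reinferred$deme_size, x$errors$N,
              x$tolerances$N, if (x$pass$N) "ok" else "FAIL"))
  if (length(x$errors$t) > 0 && !anyNA(x$errors$t))
    cat(sprintf("  t:  max |log ratio| %.3g (tol %.3g) %s\n",
                max(x$errors$t), log1p(x$tolerances$t),
                if (isTRUE(x$pass$t)) "ok" else "FAIL"))
  if (length(x$errors$M) > 0 && !anyNA(x$errors$M))
    cat(sprintf("  M:  max rel err %.3g (tol %g) %s\n", max(x$errors$M),
                x$tolerances$M, if (isTRUE(x$pass$M)) "ok" else "FAIL"))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
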