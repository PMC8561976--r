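# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate pairwise coalescence times under a scenario
#'
#' Draws T2 — the coalescence time of two gene copies — by direct simulation
#' of the two-lineage jump chain: exponential waiting times with the current
#' component's rates (S: total rate 1 + M, coalescing with probability
#' 1/(1+M); D: rate M/(n-1)), truncated at each component boundary and
#' resumed with the next component's rates (exact by memorylessness).
#' All draws are generated in one vectorized pass from a single root seed, so
#' a call is reproducible and independent of any chunking.
#'
#' @param scenario an [island_scenario()].
#' @param n_samples number of draws (default 100000, the sample size used for
#'   well-estimated empirical IICR curves).
#' @param sampling `"same_deme"` (default; one diploid individual) or
#'   `"different_demes"`.
#' @param seed integer seed (required for reproducibility).
#' @return An object of class `"t2_sample"`: list with `draws` (coalescent
#'   units), `scenario`, `sampling`, `seed`.
#' @export
sample_t2 <- function(scenario, n_samples = 1e5,
                      sampling = c("same_deme", "different_demes"),
                      seed) {
  sampling <- match.arg(sampling)
  bad <- validate_scenario(scenario)
  if (length(bad) > 0) stop("invalid scenario: ", paste(bad, collapse = "; "),
                            call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  n_samples <- as.integer(n_samples)
  n <- scenario$n_islands
  if (sampling == "different_demes" && n < 2)
    stop("different_demes sampling requires n_islands >= 2", call. = FALSE)

  draws <- with_seed(seed, {
    if (n == 1L) {
      stats::rexp(n_samples)
    } else {
      bounds <- c(scenario$change_times, Inf)
      state <- rep(if (sampling == "same_deme") 1L else 2L, n_samples) # 1=S 2=D
      tt <- numeric(n_samples)
      done <- logical(n_samples)
      for (j in seq_along(scenario$migration_rates)) {
        M <- scenario$migration_rates[j]
        q <- M / (n - 1)
        b <- bounds[j]
        repeat {
          idx <- which(!done & tt < b)
          if (length(idx) == 0) break
          rate <- ifelse(state[idx] == 1L, 1 + M, q)
          tn <- tt[idx] + stats::rexp(length(idx), rate)
          cross <- tn >= b
          if (any(cross)) tt[idx[cross]] <- b   # resume under next component
          stay <- idx[!cross]
          if (length(stay) > 0) {
            tt[stay] <- tn[!cross]
            st0 <- state[stay]                # states before this round's jumps
            inS <- stay[st0 == 1L]
            if (length(inS) > 0) {
              coal <- stats::runif(length(inS)) < 1 / (1 + M)
              done[inS[coal]] <- TRUE
              state[inS[!coal]] <- 2L
            }
            state[stay[st0 == 2L]] <- 1L
          }
        }
        if (all(done)) break
      }
      tt
    }
  })
  structure(list(draws = draws, scenario = scenario, sampling = sampling,
                 seed = seed),
            class = "t2_sample")
}

#' @export
print.t2_sample <- function(x, ...) {
  cat(sprintf("T2 sample: %d draws (%s sampling, seed %s)\n",
              length(x$draws), x$sampling, format(x$seed)))
  cat(sprintf("  mean %.4g, quartiles %.4g / %.4g / %.4g (coalescent units)\n",
              mean(x$draws), stats::quantile(x$draws, .25),
              stats::median(x$draws), stats::quantile(x$draws, .75)))
  invisible(x)
}

#' Empirical IICR from simulated coalescence times
#'
#' Estimates the IICR by a discrete hazard on a log time grid: with empirical
#' survival \eqn{\hat S}, the value attributed to the interval
#' \eqn{[t_k, t_{k+1})} is the central (midpoint-corrected) inverse hazard
#' \deqn{(t_{k+1}-t_k)\,(\hat S_k + \hat S_{k+1}) / (2(\hat S_k - \hat S_{k+1})),}
#' whose discretization bias is second order in the interval width.  Intervals
#' containing no coalescence events are merged rightward until non-empty
#' (trailing empty intervals inherit the last estimate).  The returned curve
#' carries one value per grid point: the estimate of the interval starting
#' there, the final point repeating its predecessor.
#'
#' @param sample a [sample_t2()] result (or a bare numeric vector of draws).
#' @param grid optional [time_grid()] (coalescent units); the default is 64
#'   log-spaced points from 0.01 to the sample's 99.9th percentile.
#' @return an [iicr_curve()] in coalescent units.
#' @export
empirical_iicr <- function(sample, grid = NULL) {
  draws <- if (inherits(sample, "t2_sample")) sample$draws else as.numeric(sample)
  size <- length(draws)
  if (size < 1) stop("empty sample", call. = FALSE)
  if (is.null(grid))
    grid <- make_log_grid(0.01, stats::quantile(draws, 0.999, names = FALSE), 64)
  if (!inherits(grid, "time_grid")) grid <- time_grid(grid)
  tt <- as.numeric(grid)
  k <- length(tt)
  sorted <- sort(draws)
  S <- 1 - findInterval(tt, sorted) / size   # P(T2 > t), right-continuous
  if (S[k] < 10 / size)
    stop(sprintf("grid beyond support: survival %.3g at t_max = %g (< 10/size)",
                 S[k], tt[k]), call. = FALSE)
  vals <- rep(NA_real_, k)
  i <- 1L
  while (i < k) {
    j <- i + 1L
    while (j < k && S[j] == S[i]) j <- j + 1L   # merge empty intervals rightward
    if (S[j] == S[i]) {                         # trailing run with no events
      if (i == 1L)
        stop("no coalescence events fall on the grid", call. = FALSE)
      vals[i:k] <- vals[i - 1L]                 # inherit last estimate
      break
    }
    v <- (tt[j] - tt[i]) * (S[i] + S[j]) / (2 * (S[i] - S[j]))
    vals[i:(j - 1L)] <- v
    i <- j
  }
  if (is.na(vals[k])) vals[k] <- vals[k - 1L]
  iicr_curve(grid, vals, value_unit = "coalescent", step = TRUE)
}

#' Analytic vs Monte-Carlo IICR discrepancy
#'
#' Cross-checks the exact chain against simulation: simulates T2 draws,
#' estimates the empirical IICR on a log grid, evaluates the exact IICR at
#' each interval midpoint, and reports the per-interval log10 ratio.  The
#' comparison is restricted to the *interior* of the grid — intervals whose
#' coalescence-event count is at least `min_events` — so that the statistic
#' probes the agreement of the two computations rather than the shot noise
#' of near-empty bins.  The default floor is derived from the 0.05-log10
#' agreement band this check is used with: the binomial standard error of a
#' bin with e events is about 1/(sqrt(e) ln 10) log10 units, so e >= 1200
#' places the band at >= 4 standard errors.
#'
#' @param scenario an [island_scenario()].
#' @param n_samples number of T2 draws (default 100000).
#' @param seed integer seed.
#' @param grid optional grid (coalescent units); defaults as in
#'   [empirical_iicr()].
#' @param min_events minimum coalescence events per compared interval.
#' @param sampling `"same_deme"` or `"different_demes"`.
#' @return list with `max_abs_log10` (the discrepancy statistic) and a
#'   data.frame `detail` (interval midpoint, event count, empirical, exact,
#'   log10 ratio).
#' @export
iicr_mc_check <- function(scenario, n_samples = 1e5, seed, grid = NULL,
                          min_events = 1200,
                          sampling = c("same_deme", "different_demes")) {
  sampling <- match.arg(sampling)
  sm <- sample_t2(scenario, n_samples = n_samples, sampling = sampling,
                  seed = seed)
  if (is.null(grid))
    grid <- make_log_grid(0.01, stats::quantile(sm$draws, 0.999, names = FALSE), 64)
  if (!inherits(grid, "time_grid")) grid <- time_grid(grid)
  emp <- empirical_iicr(sm, grid)
  tt <- emp$times
  k <- length(tt)
  sorted <- sort(sm$draws)
  S <- 1 - findInterval(tt, sorted) / length(sorted)
  events <- (S[-k] - S[-1]) * length(sorted)
  keep <- which(events >= min_events)
  if (length(keep) == 0)
    stop("no interval reaches min_events on this grid", call. = FALSE)
  mid <- (tt[keep] + tt[keep + 1L]) / 2
  ex <- exact_iicr(scenario, time_grid(mid), sampling = sampling,
                   value_unit = "coalescent")$values
  lr <- log10(emp$values[keep] / ex)
  list(max_abs_log10 = max(abs(lr)),
       detail = data.frame(midpoint = mid, events = events[keep],
                           empirical = emp$values[keep],
                           exact = ex, log10_ratio = lr))
}
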