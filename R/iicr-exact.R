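#' Two-lineage transition-rate generator of the n-island model
#'
#' Rate matrix of the structured coalescent for two gene copies in a symmetric
#' n-island model, over the states S (both copies in the same deme), D
#' (different demes) and C (coalesced), in time units of 2N generations.
#' With M = 4Nm, each lineage migrates at rate M/2, so S -> D at rate M,
#' D -> S at rate M/(n-1) (the migrant must hit the other lineage's deme),
#' S -> C at rate 1 (within-deme coalescence), and C is absorbing.
#'
#' @param n number of demes (>= 2; panmixia is handled separately).
#' @param M scaled migration rate 4Nm (> 0).
#' @return 3x3 rate matrix with dimnames S, D, C; rows sum to zero.
#' @export
transition_generator <- function(n, M) {
  if (n < 2) stop("n must be >= 2 (panmictic case is handled separately)",
                  call. = FALSE)
  if (!is.finite(M) || M <= 0) stop("M must be > 0", call. = FALSE)
  q <- M / (n - 1)
  matrix(c(-(1 + M), M,  1,
           q,       -q,  0,
           0,        0,  0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("S", "D", "C"), c("S", "D", "C")))
}

# Closed-form propagation of the column state (pS, pD) under one stationary
# component.  The master equation is p' = A p with A the *transpose* of the
# S/D block of the rate matrix: pS' = -(1+M) pS + q pD, pD' = M pS - q pD,
# q = M/(n-1).  A has real distinct eigenvalues (discriminant
# ((1+M)-q)^2 + 4Mq > 0 for M > 0), so exp(A t) is evaluated by closed-form
# eigen-decomposition.  `dt` may be a vector; returns a 2 x length(dt) matrix.
epoch_kernel <- function(n, M, dt, p0) {
  q <- M / (n - 1)
  tr <- -(1 + M + q)
  disc <- tr * tr - 4 * q          # det(A) = q
  sq <- sqrt(disc)
  lam1 <- (tr + sq) / 2
  lam2 <- (tr - sq) / 2
  c1 <- (lam1 + 1 + M) / q         # eigenvector (1, c_i)
  c2 <- (lam2 + 1 + M) / q
  a <- (p0[2] - p0[1] * c2) / (c1 - c2)
  b <- p0[1] - a
  e1 <- exp(lam1 * dt)
  e2 <- exp(lam2 * dt)
  rbind(a * e1 + b * e2,
        a * c1 * e1 + b * c2 * e2)
}

# (pS, pD) at each time in `t` (coalescent units, any order) for a scenario.
state_probs_sd <- function(scenario, t, sampling = "same_deme") {
  n <- scenario$n_islands
  p0 <- if (identical(sampling, "same_deme")) c(1, 0) else c(0, 1)
  if (n == 1L) {
    if (!identical(sampling, "same_deme"))
      stop("different_demes sampling requires n_islands >= 2", call. = FALSE)
    return(rbind(exp(-pmax(t, 0)), rep(0, length(t))))
  }
  bounds <- c(0, scenario$change_times, Inf)
  M <- scenario$migration_rates
  out <- matrix(NA_real_, 2, length(t))
  p_epoch <- p0                          # state at the start of each component
  for (j in seq_along(M)) {
    sel <- t >= bounds[j] & t < bounds[j + 1]
    if (any(sel))
      out[, sel] <- epoch_kernel(n, M[j], t[sel] - bounds[j], p_epoch)
    if (is.finite(bounds[j + 1]))
      p_epoch <- drop(epoch_kernel(n, M[j], bounds[j + 1] - bounds[j], p_epoch))
  }
  out
}

#' State distribution of two lineages at a time
#'
#' Propagates the two-lineage structured-coalescent chain of a scenario to
#' times `t` (coalescent units), switching the per-component generator exactly
#' at each change time.  The initial state is S for `"same_deme"` sampling and
#' D for `"different_demes"`.
#'
#' @param scenario an [island_scenario()].
#' @param t times >= 0, coalescent units (2N generations).
#' @param sampling `"same_deme"` or `"different_demes"`.
#' @return matrix with columns `S`, `D`, `C` (one row per time); rows sum to 1.
#' @export
propagate_lineages <- function(scenario, t,
                               sampling = c("same_deme", "different_demes")) {
  sampling <- match.arg(sampling)
  bad <- validate_scenario(scenario)
  if (length(bad) > 0) stop("invalid scenario: ", paste(bad, collapse = "; "),
                            call. = FALSE)
  if (sampling == "different_demes" && scenario$n_islands < 2)
    stop("different_demes sampling requires n_islands >= 2", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- state_probs_sd(scenario, t, sampling)
  m <- cbind(S = p[1, ], D = p[2, ], C = pmax(1 - p[1, ] - p[2, ], 0))
  m
}

#' Exact IICR of a piecewise-stationary n-island scenario
#'
#' The inverse instantaneous coalescence rate of a sample of two gene copies:
#' IICR(t) = P(T2 > t) / f_T2(t).  In the n-island chain the coalescence flux
#' is the within-deme occupancy (rate 1 in units of 2N generations), so in
#' coalescent units IICR(t) = (pS + pD) / pS; in `effective_size` units the
#' curve is N times that ratio.  Under panmixia (n = 1) the curve is
#' identically N.
#'
#' @param scenario an [island_scenario()].
#' @param grid a [time_grid()]; coalescent-unit grids are used directly,
#'   `generations`/`years` grids are converted internally via the scenario's
#'   deme size and `scaling`.
#' @param sampling `"same_deme"` (one diploid individual, the PSMC
#'   configuration) or `"different_demes"`.
#' @param scaling a [scaling_config()] (used only for grid-unit conversion).
#' @param value_unit `"effective_size"` (default: diploid Ne) or
#'   `"coalescent"` (the dimensionless ratio).
#' @return an [iicr_curve()] on `grid`.
#' @examples
#' sc <- island_scenario(10, 1000, change_times = 1, migration_rates = c(5, 0.5))
#' exact_iicr(sc, make_log_grid(0.01, 10, 32))
#' @export
exact_iicr <- function(scenario, grid,
                       sampling = c("same_deme", "different_demes"),
                       scaling = scaling_config(),
                       value_unit = c("effective_size", "coalescent")) {
  sampling <- match.arg(sampling)
  value_unit <- match.arg(value_unit)
  bad <- validate_scenario(scenario)
  if (length(bad) > 0) stop("invalid scenario: ", paste(bad, collapse = "; "),
                            call. = FALSE)
  if (!inherits(grid, "time_grid")) grid <- time_grid(grid)
  N <- scenario$deme_size
  t_coal <- switch(grid_unit(grid),
    coalescent = as.numeric(grid),
    generations = as.numeric(grid) / (2 * N),
    years = years_to_coalescent(as.numeric(grid), N, scaling))
  if (scenario$n_islands == 1L) {
    ratio <- rep(1, length(t_coal))
  } else {
    p <- state_probs_sd(scenario, t_coal, sampling)
    surv <- p[1, ] + p[2, ]
    if (any(surv < 1e-12)) {
      i <- which(surv < 1e-12)[1]
      stop(sprintf("grid beyond support: survival < 1e-12 at t = %g (%s)",
                   as.numeric(grid)[i], grid_unit(grid)), call. = FALSE)
    }
    ratio <- surv / p[1, ]
  }
  vals <- if (value_unit == "effective_size") N * ratio else ratio
  iicr_curve(grid, vals, value_unit = value_unit, step = FALSE)
}

#' Expected pairwise coalescence time of a scenario
#'
#' E[T2] in coalescent units (2N generations), integrating the two-lineage
#' survival in closed form: over each component with sub-generator A and
#' entry state p, the survival integral is 1' A^-1 (e^{A dt} - I) p, and
#' -1' A^-1 p over the final, unbounded component.  For a single-component
#' island model with same-deme sampling the result is exactly the deme count
#' n, independent of the migration rate — the classic strong-structure
#' identity used as a correctness check on the chain.
#'
#' @inheritParams propagate_lineages
#' @return expected T2 in coalescent units.
#' @export
mean_t2 <- function(scenario, sampling = c("same_deme", "different_demes")) {
  sampling <- match.arg(sampling)
  if (scenario$n_islands == 1L) return(1)
  n <- scenario$n_islands
  p <- if (identical(sampling, "same_deme")) c(1, 0) else c(0, 1)
  bounds <- c(0, scenario$change_times, Inf)
  M <- scenario$migration_rates
  total <- 0
  for (j in seq_along(M)) {
    q <- M[j] / (n - 1)
    A <- matrix(c(-(1 + M[j]), q, M[j], -q), 2, 2, byrow = TRUE)
    dt <- bounds[j + 1] - bounds[j]
    if (is.finite(dt)) {
      pe <- drop(epoch_kernel(n, M[j], dt, p))
      total <- total + sum(solve(A, pe - p))
      p <- pe
    } else {
      total <- total - sum(solve(A, p))
    }
  }
  total
}
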