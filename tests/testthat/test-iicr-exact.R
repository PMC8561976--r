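test_that("the two-lineage generator has the island-model rates", {
  Q <- transition_generator(2, 1)
  expect_equal(Q["S", ], c(S = -2, D = 1, C = 1))
  expect_equal(Q["D", ], c(S = 1, D = -1, C = 0))
  expect_equal(Q["C", ], c(S = 0, D = 0, C = 0))
  expect_equal(transition_generator(11, 2)["D", "S"], 0.2)
  expect_error(transition_generator(1, 1), "n must be")
  expect_error(transition_generator(5, 0), "M must be")

  set.seed(7)
  for (i in 1:100) {
    Q <- transition_generator(sample(2:200, 1), exp(runif(1, -4, 4)))
    expect_equal(rowSums(Q), c(S = 0, D = 0, C = 0), tolerance = 1e-12)
  }
})

test_that("propagation starts from the sampling configuration and absorbs monotonically", {
  sc <- island_scenario(10, 1000, 1, c(5, 0.5))
  expect_equal(propagate_lineages(sc, 0)[1, ], c(S = 1, D = 0, C = 0))
  expect_equal(propagate_lineages(sc, 0, "different_demes")[1, ],
               c(S = 0, D = 1, C = 0))
  expect_error(propagate_lineages(island_scenario(1, 100), 1, "different_demes"),
               "different_demes")

  # P(C) non-decreasing over any grid, for random scenarios
  cfg <- generator_config(seed = 21, components_range = c(1, 5))
  for (i in 1:10) {
    scn <- random_scenario(cfg, i)
    p <- propagate_lineages(scn, exp(seq(log(1e-3), log(50), length.out = 200)))
    expect_true(all(diff(p[, "C"]) >= -1e-12))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-10)
  }
})

test_that("exact absorption matches Monte-Carlo survival at fixed times", {
  sc <- island_scenario(6, 1000, migration_rates = 1)
  draws <- sample_t2(sc, 1e6, seed = 99)$draws
  p <- propagate_lineages(sc, c(0.5, 1, 5))
  for (j in seq_along(c(0.5, 1, 5))) {
    t <- c(0.5, 1, 5)[j]
    phat <- mean(draws <= t)
    se <- sqrt(phat * (1 - phat) / length(draws))
    expect_lt(abs(p[j, "C"] - phat), 3 * se + 1e-12)
  }
})

test_that("exact IICR: panmictic constant, zero-time limit, MC agreement", {
  g <- make_log_grid(0.01, 10, 32)
  expect_equal(exact_iicr(island_scenario(1, 5000), g)$values,
               rep(5000, 32))

  # only same-deme pairs can coalesce instantly, so IICR(0+) = N
  v0 <- exact_iicr(island_scenario(17, 2500, migration_rates = 3),
                   time_grid(c(1e-9, 1e-8)))$values
  expect_equal(v0, c(2500, 2500), tolerance = 1e-6)

  # island scenario against a 1e6-draw empirical IICR: 2% at t = 0.1, 1, 10,
  # estimating the local inverse hazard over a +/- 25% window so the
  # comparison carries tens of thousands of events at each time
  sc <- island_scenario(10, 1000, migration_rates = 1)
  draws <- sample_t2(sc, 1e6, seed = 5)$draws
  S <- function(t) mean(draws > t)
  inv_hazard <- function(surv_fun, t, a = 1.25) {
    s1 <- surv_fun(t / a); s2 <- surv_fun(t * a)
    (t * a - t / a) * (s1 + s2) / (2 * (s1 - s2))
  }
  exact_surv <- function(t) {
    p <- propagate_lineages(sc, t)
    p[, "S"] + p[, "D"]
  }
  for (t in c(0.1, 1, 10))
    expect_lt(abs(inv_hazard(S, t) / inv_hazard(exact_surv, t) - 1), 0.02)
  # and the grid-wide discrepancy stays inside the oracle band
  expect_lt(iicr_mc_check(sc, 1e6, seed = 5)$max_abs_log10, 0.05)
})

test_that("mean T2 equals the deme count for any single-component island model", {
  # independent oracle: numerical integration of the survival function
  surv_integral <- function(sc) {
    surv <- function(t) {
      p <- propagate_lineages(sc, t)
      p[, "S"] + p[, "D"]
    }
    upper <- 1
    while (surv(upper) > 1e-13) upper <- upper * 2
    stats::integrate(surv, 0, upper, rel.tol = 1e-9,
                     subdivisions = 2000L)$value
  }
  for (par in list(c(4, 0.2), c(10, 1), c(10, 40), c(60, 2.5))) {
    sc <- island_scenario(par[1], 1000, migration_rates = par[2])
    expect_lt(abs(surv_integral(sc) / par[1] - 1), 0.005)
    expect_equal(mean_t2(sc), par[1], tolerance = 1e-8)
  }
  # and the Monte-Carlo mean agrees within 3 standard errors
  sc <- island_scenario(10, 1000, migration_rates = 0.5)
  d <- sample_t2(sc, 5e4, seed = 12)$draws
  expect_lt(abs(mean(d) - 10), 3 * sd(d) / sqrt(length(d)))
})

test_that("strong migration approaches the panmictic n*N constant", {
  g <- make_log_grid(0.05, 10, 40)
  for (n in c(2, 7, 30)) {
    v <- exact_iicr(island_scenario(n, 1000, migration_rates = 1e4), g)$values
    expect_lt(max(abs(v / (n * 1000) - 1)), 0.01)
  }
})

test_that("the coalescent-unit IICR never touches the deme size", {
  g <- make_log_grid(0.01, 15, 50)
  a <- exact_iicr(island_scenario(12, 100, 0.7, c(4, 0.4)), g,
                  value_unit = "coalescent")$values
  b <- exact_iicr(island_scenario(12, 1e5, 0.7, c(4, 0.4)), g,
                  value_unit = "coalescent")$values
  expect_identical(a, b)
})

test_that("grids beyond the numerical support are rejected by name", {
  sc <- island_scenario(3, 1000, migration_rates = 5)
  expect_error(exact_iicr(sc, make_log_grid(1, 500, 8)), "grid beyond support")
})
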