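test_that("the curve distance is a symmetric log10 mean square", {
  g <- make_log_grid(100, 1e5, 32, unit = "years")
  a <- iicr_curve(g, rep(1000, 32), "effective_size")
  b <- iicr_curve(g, rep(10000, 32), "effective_size")
  expect_equal(curve_distance(a, a, g), 0)
  expect_equal(curve_distance(a, b, g), 1.0)     # mean of (log10 10)^2

  set.seed(4)
  for (i in 1:5) {
    x <- iicr_curve(g, exp(rnorm(32, 8)), "effective_size")
    y <- iicr_curve(g, exp(rnorm(32, 8)), "effective_size")
    expect_equal(curve_distance(x, y, g), curve_distance(y, x, g))
  }
})

test_that("a constant target with panmixia in the bounds collapses to it", {
  g <- make_log_grid(1000, 1e6, 48, unit = "years")
  target <- iicr_curve(g, rep(5000, 48), "effective_size")
  fit <- fit_islands(target, 1, bounds = list(n = c(1, 20), N = c(1e3, 1e5)),
                     control = fit_control(iters = 60), seed = 2)
  expect_lt(fit$distance, 1e-6)
  expect_equal(fit$scenario$n_islands, 1L)
  expect_equal(fit$scenario$deme_size, 5000, tolerance = 1e-3)
})

test_that("a known two-component scenario is recovered from its own IICR", {
  truth <- island_scenario(10, 1000, 1, c(1, 5))
  target <- exact_iicr(truth, make_log_grid(100, 2e5, 64, unit = "years"))
  fit <- fit_islands(target, 2, seed = 1, control = fit_control(iters = 250))
  expect_true(recovered_ok(truth, fit$scenario))
  expect_lt(fit$distance, 1e-4)
  # the fit object carries its bookkeeping
  expect_gt(fit$evals, 0)
  expect_equal(fit$seed, 1)
})

test_that("with a fixed seed, doubling the budget never increases the distance", {
  truth <- island_scenario(8, 2000, 0.5, c(0.5, 3))
  target <- exact_iicr(truth, make_log_grid(500, 3e5, 64, unit = "years"))
  d30 <- fit_islands(target, 2, seed = 9, control = fit_control(iters = 30))$distance
  d60 <- fit_islands(target, 2, seed = 9, control = fit_control(iters = 60))$distance
  expect_lte(d60, d30)
})

test_that("fitting is equivariant under the family's joint size-and-time scaling", {
  # In an n-island scenario the deme size sets both the curve's vertical
  # scale and its time scale (IICR(0+) = N, plateau ~ n N, transitions at
  # multiples of 2N generations), so the family's exact symmetry multiplies
  # values AND times by k: the scaled target is the IICR of (n, kN, same
  # coalescent change times, same M).  The fit must transform accordingly.
  truth <- island_scenario(10, 1000, 1, c(1, 5))
  g <- make_log_grid(100, 2e5, 64, unit = "years")
  target <- exact_iicr(truth, g)
  k <- 10
  scaled <- iicr_curve(time_grid(target$times * k, unit = "years"),
                       target$values * k, "effective_size")
  ctl <- fit_control(iters = 250)
  f1 <- fit_islands(target, 2, bounds = list(N = c(1e2, 1e5)),
                    control = ctl, seed = 3)
  f2 <- fit_islands(scaled, 2, bounds = list(N = c(1e2, 1e5) * k),
                    control = ctl, seed = 3)
  expect_equal(f2$scenario$n_islands, f1$scenario$n_islands)
  expect_equal(f2$scenario$deme_size, k * f1$scenario$deme_size,
               tolerance = 0.02)
  expect_equal(f2$scenario$migration_rates, f1$scenario$migration_rates,
               tolerance = 0.02)
  expect_equal(f2$scenario$change_times, f1$scenario$change_times,
               tolerance = 0.02)
})

test_that("fit objects expose the standard modelling methods", {
  truth <- island_scenario(10, 1000, 1, c(1, 5))
  target <- exact_iicr(truth, make_log_grid(100, 2e5, 64, unit = "years"))
  fit <- fit_islands(target, 2, seed = 1, control = fit_control(iters = 150))

  cf <- coef(fit)
  expect_named(cf, c("n", "N", "t1_years", "M1", "M2"))
  pr <- predict(fit, times = c(1000, 10000))
  expect_s3_class(pr, "iicr_curve")
  expect_length(pr$values, 2)
  expect_length(residuals(fit), 64)
  expect_lt(max(abs(residuals(fit))), 0.05)
  sm <- simulate(fit, nsim = 500, seed = 77)
  expect_s3_class(sm, "t2_sample")
  expect_length(sm$draws, 500)
  s <- summary(fit)
  expect_s3_class(s, "summary.island_fit")
  expect_equal(nrow(s$timeline), 1)
  expect_output(print(fit), "components: 2")
})

test_that("re-inference validates identifiable fits and flags near-panmictic ones", {
  truth <- island_scenario(10, 1000, 1, c(1, 5))
  target <- exact_iicr(truth, make_log_grid(100, 2e5, 64, unit = "years"))
  fit <- fit_islands(target, 2, seed = 1, control = fit_control(iters = 250))
  rep <- validate_by_reinference(fit)
  expect_true(rep$verdict)

  # trivial single-component pass
  g <- make_log_grid(1000, 1e6, 48, unit = "years")
  cfit <- fit_islands(iicr_curve(g, rep(5000, 48), "effective_size"), 1,
                      bounds = list(n = c(1, 20), N = c(1e3, 1e5)),
                      control = fit_control(iters = 60), seed = 2)
  expect_true(validate_by_reinference(cfit)$verdict)

  # strong migration: the IICR is ~ n * N, so n and N trade off freely and
  # the scenario cannot be re-inferred reliably
  near_pan <- island_scenario(10, 1000, 1, c(500, 500))
  tnp <- exact_iicr(near_pan, make_log_grid(100, 3e5, 64, unit = "years"))
  fnp <- fit_islands(tnp, 2, seed = 4, control = fit_control(iters = 120))
  rnp <- validate_by_reinference(fnp)
  expect_false(rnp$verdict)
})

test_that("connectivity timelines order events and round-trip their times", {
  expect_equal(nrow(connectivity_timeline(island_scenario(9, 500,
                                                          migration_rates = 1))), 0)
  sc <- island_scenario(20, 1000, c(0.5, 2), c(0.3, 4, 0.8))
  tl <- connectivity_timeline(sc)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$time_kyr, c(10, 2.5))             # oldest first
  expect_equal(tl$direction, c("increase", "decrease"))
  back <- years_to_coalescent(rev(tl$time_kyr) * 1000, 1000)
  expect_equal(back, sc$change_times, tolerance = 1e-12)
})
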