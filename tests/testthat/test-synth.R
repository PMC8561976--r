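test_that("the scenario generator is deterministic and closed under validation", {
  cfg <- generator_config(seed = 17)
  expect_identical(random_scenario(cfg, 3), random_scenario(cfg, 3))
  expect_false(identical(random_scenario(cfg, 3), random_scenario(cfg, 4)))

  for (i in 1:1000) {
    sc <- random_scenario(cfg, i)
    expect_length(validate_scenario(sc), 0)
  }

  # range constraints
  cfg1 <- generator_config(components_range = c(1, 1), seed = 5)
  for (i in 1:10)
    expect_length(random_scenario(cfg1, i)$migration_rates, 1)
  cfg2 <- generator_config(min_change_factor = 2, components_range = c(3, 3),
                           seed = 6)
  for (i in 1:10) {
    M <- random_scenario(cfg2, i)$migration_rates
    r <- M[-1] / M[-3]
    expect_true(all(pmax(r, 1 / r) >= 2))
  }
})

test_that("target generation honours its noise mode", {
  sc <- island_scenario(10, 1000, 1, c(5, 0.5))
  grid <- make_log_grid(0.05, 10, 48)

  none <- generator_config(noise = "none", seed = 8)
  expect_equal(noisy_target(sc, none, grid),
               exact_iicr(sc, grid, value_unit = "coalescent"))

  # finite-T2 noise stays within 5% of the exact curve on dense intervals
  ft <- generator_config(noise = "finite_t2", noise_size = 1e5, seed = 8)
  tgt <- noisy_target(sc, ft, grid)
  draws <- sample_t2(sc, 1e5, seed = 8 + 104729L * 0L + 1L)$draws
  tt <- tgt$times
  S <- 1 - findInterval(tt, sort(draws)) / length(draws)
  events <- (S[-length(S)] - S[-1]) * length(draws)
  dense <- which(events >= 1200)
  mids <- (tt[dense] + tt[dense + 1L]) / 2
  ex <- exact_iicr(sc, time_grid(mids), value_unit = "coalescent")$values
  expect_lt(max(abs(tgt$values[dense] / ex - 1)), 0.05)

  # log-normal noise: log10 residual spread matches sigma / ln 10
  ln <- generator_config(noise = "lognormal", noise_sigma = 0.05, seed = 9)
  tgt2 <- noisy_target(sc, ln, grid)
  resid <- log10(tgt2$values) -
    log10(exact_iicr(sc, grid, value_unit = "coalescent")$values)
  expect_equal(sd(resid), 0.05 / log(10), tolerance = 0.35)
})

test_that("pseudo-PSMC fixtures encode their sources exactly", {
  s <- scaling_config()
  # constant history under the uniform pattern: all lambdas equal
  txt <- make_psmc_fixture(panmictic_history(0, 20000), theta0 = 0.0048,
                           pattern = "64*1")
  rs <- txt[startsWith(txt, "RS")]
  expect_length(rs, 64)
  lam <- vapply(strsplit(rs, " "), function(f) as.numeric(f[4]), 0)
  expect_equal(lam, rep(lam[1], 64))

  # round-trip: the curve discretized at the atomic-interval sampling points
  # is recovered to full precision
  h <- panmictic_history(c(0, 3000, 60000), c(8000, 1500, 25000))
  fx <- make_psmc_fixture(h, 0.0048)
  cv <- scale_psmc(read_psmc(fx), s)
  mid_gen <- attr(fx, "t_mid") * 2 * attr(cv, "N0")
  idx <- findInterval(mid_gen, h$start_generations)
  expect_equal(cv$values, h$ne[pmax(idx, 1)], tolerance = 1e-9)

  # structured source: lambdas encode the exact IICR at interval midpoints
  sc <- island_scenario(10, 1000, 1, c(5, 0.5))
  theta <- 4 * s$mu * s$bin_size * sc$deme_size      # N0 = deme size
  txt2 <- make_psmc_fixture(sc, theta0 = theta, t_min = 0.01, t_max = 30)
  cv2 <- scale_psmc(read_psmc(txt2), s)
  expect_equal(attr(cv2, "N0"), 1000)
  mids <- attr(txt2, "t_mid")          # N0 = deme size, so already coalescent
  ex <- exact_iicr(sc, time_grid(mids))$values
  expect_equal(cv2$values, ex, tolerance = 1e-9)
})

test_that("study presets carry the reported change ages and deme counts", {
  mur <- study_preset("murinus")
  rav <- study_preset("ravelobensis")
  expect_equal(mur$n_islands, 84L)
  expect_equal(rav$n_islands, 61L)
  expect_length(mur$change_times, 5)
  tl <- connectivity_timeline(mur)
  expect_equal(tl$time_kyr, c(129.1, 42.7, 30.7, 13.7, 5.1))
  expect_equal(connectivity_timeline(rav)$time_kyr,
               c(338.9, 135.6, 27.1, 20.1, 7.9))
  expect_length(validate_scenario(mur), 0)
})

test_that("generated fixtures close the loop through reading and fitting", {
  s <- scaling_config()
  cfg <- recovery_config(2, seed = 303)
  ok <- 0L; n_cases <- 6L
  for (i in seq_len(n_cases)) {
    truth <- random_scenario(cfg, i)
    theta <- 4 * s$mu * s$bin_size * truth$deme_size
    txt <- make_psmc_fixture(truth, theta0 = theta,
                             t_min = 0.01, t_max = 4 * truth$n_islands)
    target <- scale_psmc(read_psmc(txt), s)
    fit <- fit_islands(target, 2, seed = 400 + i,
                       control = fit_control(iters = 500))
    if (recovered_ok(truth, fit$scenario)) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.8 * n_cases))
})
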