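test_that("PSMC text parses into theta and the final step function", {
  doc <- read_psmc(c("RD 0", "TR 0.008 0.002", "RS 0 0.0 1.0", "RS 1 0.5 2.0"))
  fin <- doc$iterations[[doc$final]]
  expect_equal(fin$theta0, 0.008)
  expect_equal(fin$t, c(0, 0.5))
  expect_equal(fin$lambda, c(1.0, 2.0))

  # multi-iteration file: the last RD block wins, earlier ones are retained
  doc2 <- read_psmc(psmc_two_iteration_text())
  expect_equal(doc2$final, 2L)
  expect_equal(doc2$iterations[[doc2$final]]$theta0, 0.008)
  expect_equal(doc2$iterations[[1]]$theta0, 0.010)

  expect_error(read_psmc(character(0)), "empty")
  expect_error(read_psmc(c("RD 0", "RS 0 0.0 1.0")), "missing TR")
  expect_error(read_psmc(c("RD 0", "TR 0.01 0.002")), "missing RS")
  expect_warning(read_psmc(c("RD 0", "TR 0.01 0.002", "RS 0 0.0 1.0",
                             "RS 1 1 1", "XY strange")), "unknown")
})

test_that("theta-based rescaling gives N0 = theta/(4 mu s) and linear steps", {
  s <- scaling_config()                       # mu 1.2e-8, g 2.5, s 100
  doc <- read_psmc(c("RD 0", "TR 0.0048 0.001", "RS 0 0.0 1.0", "RS 1 0.1 2.0"))
  cv <- scale_psmc(doc, s)
  expect_equal(attr(cv, "N0"), 0.0048 / (4 * 1.2e-8 * 100))  # 1e6
  expect_equal(cv$values[1], attr(cv, "N0"))                  # lambda = 1 at t = 0

  # t_k = 0.1 under N0 = 1e4 starts at 2 * 1e4 * 0.1 * 2.5 = 5000 years
  theta <- 4 * 1.2e-8 * 100 * 1e4
  doc2 <- read_psmc(c("RD 0", sprintf("TR %.10g 0.001", theta),
                      "RS 0 0.0 1.0", "RS 1 0.1 0.5"))
  cv2 <- scale_psmc(doc2, s)
  expect_equal(attr(cv2, "step_starts_years")[2], 5000)

  # doubling lambda doubles Ne, step by step
  doc3 <- read_psmc(c("RD 0", sprintf("TR %.10g 0.001", theta),
                      "RS 0 0.0 2.0", "RS 1 0.1 1.0"))
  expect_equal(scale_psmc(doc3, s)$values, 2 * cv2$values)
})

test_that("write -> read -> scale round-trips histories to full precision", {
  s <- scaling_config()
  cases <- list(
    constant = panmictic_history(0, 12000),
    bottleneck = panmictic_history(c(0, 5000), c(2000, 30000)),
    staircase = panmictic_history(c(0, round(exp(seq(log(100), log(1e6),
                                                     length.out = 63)))),
                                  exp(seq(log(5e3), log(5e4), length.out = 64))))
  for (h in cases) {
    txt <- write_psmc(h, theta0 = 0.006, scaling = s)
    back <- iicr_as_ne_history(scale_psmc(read_psmc(txt), s), s)
    expect_equal(back$start_generations, h$start_generations, tolerance = 1e-9)
    expect_equal(back$ne, h$ne, tolerance = 1e-9)
    # parse -> serialize is bitwise idempotent
    canon <- format(read_psmc(txt))
    expect_identical(format(read_psmc(canon)), canon)
  }
})

test_that("rescaling is invariant under joint theta and mu scaling", {
  h <- panmictic_history(c(0, 2000), c(8000, 2500))
  base <- scale_psmc(read_psmc(write_psmc(h, 0.004)), scaling_config())
  for (c in c(0.5, 3)) {
    s2 <- scaling_config(mu = 1.2e-8 * c)
    doubled <- scale_psmc(read_psmc(write_psmc(h, 0.004 * c, scaling = s2)), s2)
    expect_equal(attr(doubled, "N0"), attr(base, "N0"))
    expect_equal(doubled$values, base$values)
    expect_equal(attr(doubled, "step_starts_years"),
                 attr(base, "step_starts_years"))
  }
})

test_that("atomic-interval patterns sum like the PSMC -p grammar", {
  p <- pattern_to_intervals("4+25*2+4+6")
  expect_equal(p$total, 64)                      # 4 + 50 + 4 + 6, by hand
  expect_equal(p$groups$n_groups, c(4, 25, 4, 6))
  expect_equal(pattern_to_intervals("64*1")$total, 64)
  expect_equal(pattern_to_intervals("1")$total, 1)
  expect_equal(pattern_to_intervals(" 4 + 25*2 + 4 + 6 ")$total, 64)
  expect_error(pattern_to_intervals("4+2a*2"), "malformed")
  expect_error(pattern_to_intervals("4+*2"), "malformed")
})
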