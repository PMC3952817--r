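test_that("model scale handles graded, flat and degenerate outputs", {
  expect_equal(model_scale(c(0, 2, 4)), 4)
  expect_equal(model_scale(c(5, 5, 5)), 5)
  expect_equal(model_scale(c(0, 0, 0)), 1)
  expect_error(model_scale(c(1, NA)), "finite")
})

test_that("minimum range and gap respect the 75% budget", {
  mg <- min_range_and_gap(2, 1)
  expect_equal(mg$delta_min, 0.1875)
  expect_equal(mg$gap_min, 0.1875)
  expect_lte(2 * mg$delta_min + mg$gap_min, 0.75)
  mg1 <- min_range_and_gap(1, 1)
  expect_equal(mg1$delta_min, 0.375)
  # budget bound holds across category counts and scales with S
  for (n in c(1:10, 50, 1000)) {
    mg <- min_range_and_gap(n, 2.5)
    expect_lte(n * mg$delta_min + (n - 1) * mg$gap_min, 0.75 * 2.5)
  }
  expect_error(min_range_and_gap(2, 0), "positive")
})

test_that("surrogates clip to the nearest interval boundary", {
  iv <- list(lower = c(0.2), upper = c(0.8))
  expect_equal(clip_surrogates(0.5, iv, 1L), 0.5)
  expect_equal(clip_surrogates(1.0, iv, 1L), 0.8)
  expect_equal(clip_surrogates(0.0, iv, 1L), 0.2)
  expect_error(clip_surrogates(0.5, iv, 2L), "rank without")
})

test_that("scaling error matches direct evaluation of the formula", {
  cfg <- scaling_config()
  y <- c(1, 0.9, 0.2, 0.1)
  s <- rep(0.55, 4)
  nu <- sum(abs(diff(y)))                      # 0.9
  eps <- cfg$epsilon_fraction * model_scale(y) # 1e-6 * 0.9
  expected <- sqrt(mean(((y - s) / (nu + eps))^2))
  expect_equal(scaling_error(y, s, list(1:4), cfg), expected)
  # perfect fit
  expect_equal(scaling_error(y, y, list(1:4), cfg), 0)
  # flat output: error ~ |y - s| / eps, very large
  yf <- rep(1, 3)
  e <- scaling_error(yf, rep(0.5, 3), list(1:3), cfg, y_full = yf)
  expect_gt(e, 1e5)
  expect_error(scaling_error(y, s, list(integer(0)), cfg), "empty")
})

test_that("solve_scaling separates consistent ranks at zero error", {
  s <- solve_scaling(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 2, 2))
  expect_equal(s$error, 0)
  expect_true(s$feasible_zero)
  # surrogates inside their intervals
  expect_true(all(s$surrogates >= s$intervals$lower[c(1, 1, 2, 2)] - 1e-12))
  expect_true(all(s$surrogates <= s$intervals$upper[c(1, 1, 2, 2)] + 1e-12))
  # conflicting ranks give positive error
  s2 <- solve_scaling(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 2, 2))
  expect_gt(s2$error, 0)
})

test_that("solve_scaling is scale invariant", {
  set.seed(42)
  for (k in 1:5) {
    inst <- random_scaling_instance()
    e1 <- solve_scaling(inst$y, inst$ranks, inst$n_cat)$error
    for (c_ in c(0.01, 7, 1e3)) {
      e2 <- solve_scaling(c_ * inst$y, inst$ranks, inst$n_cat)$error
      expect_equal(e2, e1, tolerance = 1e-6)
    }
  }
})

test_that("zero error coincides with the direct feasibility check", {
  set.seed(7)
  for (k in 1:40) {
    inst <- random_scaling_instance()
    sol <- solve_scaling(inst$y, inst$ranks, inst$n_cat)
    feas <- brute_zero_feasible(inst$y, inst$ranks, inst$n_cat)
    expect_equal(sol$error < 1e-9, feas,
                 info = sprintf("y=%s ranks=%s",
                                paste(round(inst$y, 3), collapse = ","),
                                paste(inst$ranks, collapse = ",")))
  }
})

test_that("relaxing the constraint budget never increases the error", {
  set.seed(11)
  for (k in 1:8) {
    inst <- random_scaling_instance()
    errs <- vapply(c(0.75, 0.5, 0.25, 0.1), function(b) {
      cfg <- scaling_config(min_range_fraction_budget = b)
      solve_scaling(inst$y, inst$ranks, inst$n_cat, cfg = cfg)$error
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-6),
                info = paste(round(errs, 6), collapse = " "))
  }
})

test_that("solve_scaling agrees with the nested-grid oracle", {
  set.seed(3)
  for (k in 1:12) {
    inst <- random_scaling_instance()
    a <- solve_scaling(inst$y, inst$ranks, inst$n_cat)$error
    b <- solve_scaling_oracle(inst$y, inst$ranks, inst$n_cat)$error
    if (b == 0) expect_lt(a, 1e-9) else
      expect_lt(abs(a - b) / b, 1e-3)
  }
})

test_that("per-domain averaging weighs regions equally", {
  # two domains of unequal size: error is sqrt of the sum of domain means
  cfg <- scaling_config()
  y <- c(0, 0, 0, 1)
  s <- c(0.3, 0, 0, 1)
  nu <- 1
  e_cell <- ((y - s) / (nu + cfg$epsilon_fraction))^2
  expect_equal(scaling_error(y, s, list(1:3, 4L), cfg),
               sqrt(mean(e_cell[1:3]) + e_cell[4]))
})
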