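# Euler-Maruyama integration, sampling schedule, tipping-triggered stopping,
# and the sweep machinery.

test_that("noise-free integration stays on an equilibrium to machine precision", {
  m <- model_spec("double_well", sigma = 0)
  tr <- euler_maruyama(m, u = 0, duration = 2, record_every = 0.5)
  expect_equal(unname(tr$x[, 1]), rep(1, 5), tolerance = 1e-12)
})

test_that("trajectories are reproducible under a fixed seed", {
  a <- euler_maruyama("double_well", u = 1, duration = 1, seed = 31)
  b <- euler_maruyama("double_well", u = 1, duration = 1, seed = 31)
  expect_identical(a$x, b$x)
  c_ <- euler_maruyama("double_well", u = 1, duration = 1, seed = 32)
  expect_false(identical(a$x, c_$x))
})

test_that("sampling schedule discards the transient and spaces samples by t_skip", {
  set.seed(5)
  o <- sample_observable("double_well", u = 1, L = 100L, t_skip = 1, transient = 10)
  expect_length(o$samples, 100L)
  expect_equal(o$times[1], 11)    # first sample one t_skip after the transient
  expect_equal(o$times[100], 110) # last sample at transient + L * t_skip
})

test_that("sample_variance is the unbiased estimator", {
  expect_equal(sample_variance(c(1, 1, 1)), 0)
  expect_equal(sample_variance(c(0, 2)), 2)  # denominator L - 1 = 1
  expect_error(sample_variance(3), "at least 2")
  set.seed(1)
  x <- rnorm(2e5, 0, 0.25)
  se <- 0.0625 * sqrt(2 / (2e5 - 1))
  expect_lt(abs(sample_variance(x) - 0.0625), 3 * se)
})

test_that("runs beyond the fold tip instead of returning samples", {
  set.seed(2)
  o <- sample_observable("double_well", u = 3.2)  # past the saddle-node
  expect_true(o$tipped)
  expect_length(o$samples, 0L)
})

test_that("equal-grid sweeps span the range and cap at the bifurcation point", {
  s <- run_sweep(cheap_ou_config(seed = 1))
  expect_s3_class(s, "variance_series")
  expect_length(s$u, 12L)               # no tipping rule: never truncated
  expect_false(s$truncated_by_tipping)
  expect_equal(s$u[1], 0.01)
  expect_equal(s$u[12], 2)

  # the double-well grid is capped exactly at the deterministic fold
  cfg <- suppressWarnings(sweep_config("double_well", n_u = 5, L = 5,
                                       dt = 0.01, transient = 0.5, seed = 1))
  grid <- attr(run_sweep(cfg), "u_grid")
  expect_equal(grid[1], 0)
  expect_equal(grid[5], deterministic_bifurcation_point("double_well"))
  expect_equal(diff(grid), rep(grid[5] / 4, 4))
})

test_that("random grids are sorted in the sweep direction and seed-stable", {
  cfg <- cheap_ou_config(seed = 9)
  cfg$u_grid_mode <- "random_sorted"
  s1 <- run_sweep(cfg)
  s2 <- run_sweep(cfg)
  expect_identical(s1$u, s2$u)
  expect_identical(s1$v_hat, s2$v_hat)
  expect_true(all(diff(s1$u) > 0))
  expect_true(all(s1$u >= 0.01 & s1$u <= 2))
})

test_that("a noise-free double-well sweep has zero variance and never tips", {
  cfg <- suppressWarnings(sweep_config(model_spec("double_well", sigma = 0),
                                       n_u = 8, L = 10, dt = 1e-3,
                                       transient = 5, seed = 4))
  # stay safely below the fold so relaxation is fast and escape impossible
  cfg$spec$sweep_range <- c(0, 2.5)
  s <- run_sweep(cfg)
  expect_length(s$u, 8L)
  expect_false(s$truncated_by_tipping)
  expect_lt(max(s$v_hat), 1e-12)
})

test_that("truncation records the tipping point inside the swept range", {
  cfg <- sweep_config("double_well", seed = 7)
  s <- run_sweep(cfg)
  expect_true(s$truncated_by_tipping)
  expect_lt(s$tipping_u, deterministic_bifurcation_point("double_well"))
  expect_lt(max(s$u), s$tipping_u)
  expect_gt(length(s$u), 8)
})

test_that("colored-noise mode runs for the double-well and differs from white", {
  w <- sample_observable("double_well", u = 1, L = 30L, seed = 77)
  c_ <- sample_observable("double_well", u = 1, L = 30L, seed = 77,
                          noise_mode = "colored")
  expect_length(c_$samples, 30L)
  expect_false(identical(w$samples, c_$samples))
  expect_error(sweep_config("ou_null", noise_mode = "colored"), "double-well")
})

test_that("t_skip leaves samples near-uncorrelated where relaxation is fast", {
  acf1 <- function(x) stats::cor(x[-1], x[-length(x)])
  # models whose |lambda| * t_skip >> 1 at mid-range u: the samples decorrelate
  fast <- list(double_well = 1.5, ou_null = 1, mutualistic = 0.5)
  for (nm in names(fast)) {
    m <- model_spec(nm)
    vals <- vapply(1:3, function(r) {
      set.seed(400 + r)
      acf1(sample_observable(m, fast[[nm]])$samples)
    }, numeric(1))
    expect_lt(mean(vals), 0.2)
  }
  # slower models keep some serial correlation at T_skip but far less than
  # adjacent integration steps would have (acf per step ~ 1 - |lambda| dt)
  set.seed(410)
  oh <- acf1(sample_observable("over_harvest", 1.8)$samples)
  expect_lt(oh, 0.75)
})

test_that("variance series validate monotonicity and direction", {
  expect_error(variance_series(c(1, 1, 2), c(1, 2, 3)), "monotone")
  expect_error(variance_series(c(1, 3, 2), c(1, 2, 3)), "monotone")
  expect_error(variance_series(c(1, 2), c(1, -2)), "non-negative")
  s <- variance_series(c(3, 2, 1), c(1, 2, 3))
  expect_equal(s$direction, "decreasing")
  expect_error(variance_series(c(1, 2), c(1, 2), direction = "decreasing"),
               "direction")
  p <- series_prefix(s, 2)
  expect_equal(p$u, c(3, 2))
})
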