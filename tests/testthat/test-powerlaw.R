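# Linear and constrained power-law fitting, and AICc model comparison.

test_that("the linear fit solves the normal equations", {
  s <- variance_series(0:5, 2 * (0:5) + 1)
  f <- fit_linear(s)
  expect_equal(f$alpha, 2)
  expect_equal(f$beta, 1)
  expect_equal(f$rss, 0)

  s2 <- variance_series(1:4, rep(3, 4))
  f2 <- fit_linear(s2)
  expect_equal(f2$alpha, 0)
  expect_equal(f2$beta, 3)

  # arbitrary points against the closed-form normal equations
  u <- c(0.3, 1.1, 1.7, 2.2, 3.4)
  v <- c(0.9, 0.4, 1.3, 0.8, 2.1)
  f3 <- fit_linear(variance_series(u, v))
  X <- cbind(1, u)
  beta_hat <- solve(t(X) %*% X, t(X) %*% v)
  expect_equal(c(f3$beta, f3$alpha), c(beta_hat), tolerance = 1e-10)
  expect_equal(f3$rss, sum((v - X %*% beta_hat)^2), tolerance = 1e-10)

  expect_error(fit_linear(variance_series(1:2, c(1, 2))), "at least 3")
})

test_that("noise-free power laws are recovered exactly", {
  u <- seq(0, 4, by = 0.5)
  f <- fit_power_law(variance_series(u, 2 / (5 - u) + 1), seed = 1)
  expect_equal(f$u_c_hat, 5, tolerance = 1e-2)
  expect_equal(f$gamma, 1, tolerance = 1e-2)
  expect_equal(f$a, 2, tolerance = 1e-2)
  expect_equal(f$b, 1, tolerance = 1e-2)
  expect_equal(f$rho, -1, tolerance = 1e-4)
  expect_lt(f$rss, 1e-4)

  # saddle-node exponent gamma = 1/2
  s <- make_power_series(30, 0, 2.7, a = 0.05, u_c = 3, gamma = 0.5, b = 0.1)
  f2 <- fit_power_law(s, seed = 1)
  expect_equal(f2$gamma, 0.5, tolerance = 0.02)
  expect_equal(f2$u_c_hat, 3, tolerance = 0.05)
})

test_that("decreasing sweeps use the mirrored form V = a (u - u_c)^(-gamma) + b", {
  s <- make_power_series(25, 0.15, 1, a = 0.08, u_c = 0.1, gamma = 0.7, b = 0.02,
                         decreasing = TRUE)
  f <- fit_power_law(s, seed = 2)
  expect_equal(f$u_c_hat, 0.1, tolerance = 0.02)
  expect_equal(f$gamma, 0.7, tolerance = 0.05)
  expect_lt(f$u_c_hat, min(s$u))  # divergence beyond the data in sweep direction
})

test_that("every fit honors the (u_c, b) box and positivity constraints", {
  eps <- 1e-5
  for (k in 1:12) {
    s <- make_power_series(15, 0, 2, a = runif(1, 0.02, 0.3),
                           u_c = runif(1, 2.2, 3.5), gamma = runif(1, 0.4, 1.5),
                           b = runif(1, 0.01, 0.2),
                           noise_sd = 0.002, seed = 500 + k)
    f <- fit_power_law(s, seed = k)
    u_l <- s$u[length(s$u)]
    expect_gte(f$u_c_hat, u_l + eps)
    expect_lte(f$u_c_hat, u_l + 10 * (u_l - s$u[1]) + 1e-9)
    expect_lte(f$b, min(s$v_hat) - eps + 1e-12)
    expect_gte(f$b, min(s$v_hat) - (max(s$v_hat) - min(s$v_hat)) / 2 - 1e-9)
    expect_gt(f$a, 0)
    expect_gt(f$gamma, 0)
    expect_gte(f$rho, -1)
    expect_lte(f$rho, 0)
  }
})

test_that("the optimizer matches an exhaustive grid over the same box", {
  for (k in 1:5) {
    s <- make_power_series(18, 0, 2.5, a = runif(1, 0.03, 0.2),
                           u_c = runif(1, 2.8, 4), gamma = runif(1, 0.5, 1.2),
                           b = runif(1, 0.02, 0.15),
                           noise_sd = 0.004, seed = 600 + k)
    f <- fit_power_law(s, seed = k)
    g <- grid_min_objective(s, ng = 250L)
    expect_lte(f$rho, g + 1e-3)
  }
})

test_that("fits are scale-equivariant in the variance", {
  s <- make_power_series(20, 0, 2.5, a = 0.06, u_c = 3.1, gamma = 0.8, b = 0.05,
                         noise_sd = 0.001, seed = 42)
  f1 <- fit_power_law(s, seed = 9)
  c_ <- 37
  s2 <- variance_series(s$u, c_ * s$v_hat)
  f2 <- fit_power_law(s2, seed = 9)
  expect_equal(f2$u_c_hat, f1$u_c_hat, tolerance = 0.02)
  expect_equal(f2$gamma, f1$gamma, tolerance = 0.02)
  expect_equal(f2$a, c_ * f1$a, tolerance = 0.05 * c_ * f1$a)
  expect_equal(f2$b, c_ * f1$b, tolerance = 0.05 * abs(c_ * f1$b) + 1e-3)
})

test_that("recovery error shrinks with the noise level on V-hat", {
  # the correlation-objective estimator is consistent but noise-sensitive:
  # observation noise pulls u_c_hat toward the data and biases gamma low,
  # with errors scaling roughly linearly in the noise amplitude
  u_c <- 3; u1 <- 0; v_range <- 0.110
  n_seeds <- 20
  run_level <- function(noise_frac) {
    e_uc <- e_g <- numeric(n_seeds)
    for (k in seq_len(n_seeds)) {
      s <- make_power_series(30, u1, 2.7, a = 0.05, u_c = u_c, gamma = 0.8,
                             b = 0.1, noise_sd = noise_frac * v_range,
                             seed = 700 + k)
      f <- fit_power_law(s, seed = k)
      e_uc[k] <- abs(f$u_c_hat - u_c)
      e_g[k] <- abs(f$gamma - 0.8)
    }
    list(uc = e_uc, g = e_g)
  }
  lo <- run_level(0.005)
  expect_gte(mean(lo$uc <= 0.05 * (u_c - u1)), 0.9)
  expect_gte(mean(lo$g <= 0.3), 0.9)
  hi <- run_level(0.02)
  expect_gte(mean(hi$uc <= 0.10 * (u_c - u1)), 0.9)
  expect_gte(mean(hi$g <= 0.6), 0.9)
  # errors grow with noise, i.e. the low-noise fits really are sharper
  expect_lt(stats::median(lo$uc), stats::median(hi$uc))
})

test_that("AICc matches hand evaluation and its edge cases", {
  expect_equal(aicc(1, 10, 2), 10 * log(0.1) + 4 + 12 / 7, tolerance = 1e-10)
  expect_equal(aicc(1, 10, 2), -17.3116, tolerance = 1e-4)
  expect_equal(aicc(1, 10, 4), 10 * log(0.1) + 8 + 8, tolerance = 1e-10)
  expect_equal(aicc(1, 10, 4), -7.0259, tolerance = 1e-4)
  # equal-RSS penalty difference at n = 10 and n = 20
  expect_equal(aicc(1, 10, 4) - aicc(1, 10, 2), 10.2857, tolerance = 1e-4)
  expect_equal(aicc(0.3, 20, 4) - aicc(0.3, 20, 2),
               2 * 2 + 2 * (4 * 5 / 15 - 2 * 3 / 17), tolerance = 1e-10)
  expect_identical(aicc(0, 12, 4), -Inf)
  expect_error(aicc(1, 5, 4), "undefined")
})

test_that("model comparison prefers the true model decisively", {
  # near-linear data: the k = 4 penalty keeps the power law behind
  set.seed(11)
  u <- seq(0.1, 2, length.out = 20)
  s_lin <- variance_series(u, 0.1 * u + 0.2 + rnorm(20, 0, 1e-4))
  cmp_lin <- compare_fits(s_lin, seed = 3)
  expect_gt(cmp_lin$delta_aicc, 0)

  # near-exact power law: the power fit wins by far more than 10
  s_pow <- make_power_series(20, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                             noise_sd = 2e-4, seed = 12)
  cmp_pow <- compare_fits(s_pow, seed = 3)
  expect_lt(cmp_pow$delta_aicc, -10)
  expect_equal(cmp_pow$delta_aicc, cmp_pow$aicc_power - cmp_pow$aicc_linear)
})

test_that("degenerate series are rejected", {
  expect_error(fit_power_law(variance_series(1:10, rep(0.5, 10))), "spread")
  expect_error(fit_power_law(variance_series(1:3, c(1, 2, 3))), "at least 4")
})
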