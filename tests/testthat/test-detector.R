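# The sequential monitor: crossing rule, causality, and detection scoring.

test_that("a linear series never raises an alarm", {
  set.seed(21)
  u <- seq(0, 3, length.out = 50)
  s <- variance_series(u, 0.1 * u + 0.2 + rnorm(50, 0, 1e-3))
  d <- tipmoc_monitor(s, seed = 21)
  expect_false(d$detected)
  expect_equal(d$stop_reason, "exhausted")
  expect_equal(nrow(d$delta_aicc_trace), 50 - 8 + 1)
  expect_true(is.na(d$u_det))
})

test_that("a diverging power law is detected before the series end", {
  hits <- 0; u_c_hats <- c()
  for (k in 1:10) {
    s <- make_power_series(45, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                           noise_sd = 0.01 * 0.15, seed = 800 + k)
    d <- tipmoc_monitor(s, seed = k, warn_rho = FALSE)
    if (d$detected) {
      hits <- hits + 1
      expect_lte(d$u_det, 2.7)
      expect_gt(d$u_c_hat, d$u_det)  # forecast beyond the alarm point
      u_c_hats <- c(u_c_hats, d$u_c_hat)
    }
  }
  expect_equal(hits, 10)
  # forecasts scatter around the true divergence point; alarms that fire
  # early in the series carry weakly constrained forecasts, so the spread
  # is wide even at 1% observation noise
  expect_lt(stats::median(abs(u_c_hats - 3)), 1)
  expect_gte(mean(u_c_hats >= 2.4 & u_c_hats <= 4), 0.6)
})

test_that("too-short series return an empty, non-detected result with a warning", {
  s <- variance_series(1:7, (1:7) / 10)
  expect_warning(d <- tipmoc_monitor(s), "ell0")
  expect_false(d$detected)
  expect_equal(nrow(d$delta_aicc_trace), 0)
})

test_that("the result is prefix-causal and replayable", {
  s <- make_power_series(45, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                         noise_sd = 0.003, seed = 900)
  d <- tipmoc_monitor(s, seed = 55, warn_rho = FALSE)
  expect_true(d$detected)
  k <- d$detection_index
  expect_equal(d$u_det, s$u[k])

  # appending observations after the detection index changes nothing
  longer <- variance_series(c(s$u, 2.75, 2.8), c(s$v_hat, 1, 2))
  d2 <- tipmoc_monitor(longer, seed = 55, warn_rho = FALSE)
  expect_equal(d2$u_det, d$u_det)
  expect_equal(d2$u_c_hat, d$u_c_hat)
  expect_equal(d2$delta_aicc_trace, d$delta_aicc_trace)

  # re-running on exactly the consumed prefix reproduces the detection
  d3 <- tipmoc_monitor(series_prefix(s, k), seed = 55, warn_rho = FALSE)
  expect_true(d3$detected)
  expect_equal(d3$u_det, d$u_det)
  expect_equal(d3$u_c_hat, d$u_c_hat)
  expect_equal(d3$gamma_hat, d$gamma_hat)
})

test_that("the trace marks threshold crossings at consecutive indices", {
  s <- make_power_series(45, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                         noise_sd = 0.003, seed = 901)
  d <- tipmoc_monitor(s, seed = 5, warn_rho = FALSE)
  expect_true(d$detected)
  tr <- d$delta_aicc_trace
  last3 <- utils::tail(tr$delta_aicc, 3)
  expect_true(all(last3 < d$threshold))
  expect_equal(utils::tail(tr$u, 1), d$u_det)
})

test_that("a failed fit counts as a non-crossing and resets the streak", {
  # first 8 values constant: V_max = V_min, so the power-law fit errors there
  u <- seq(0, 3, length.out = 40)
  v <- c(rep(0.2, 8), 0.05 / (3.2 - u[9:40]) + 0.19)
  s <- variance_series(u, v)
  d <- suppressWarnings(tipmoc_monitor(s, seed = 8, warn_rho = FALSE))
  expect_true(is.na(d$delta_aicc_trace$delta_aicc[1]))  # logged as skipped
  expect_true(d$detected)          # recovers once the fit becomes possible
  expect_gt(d$detection_index, 11)
})

test_that("detection scoring computes errors and the closed tolerance band", {
  s <- make_power_series(45, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                         noise_sd = 0.003, seed = 902)
  d <- tipmoc_monitor(s, seed = 1, warn_rho = FALSE)
  u_c <- 3.079; u_1 <- 0

  ev <- evaluate_detection(d, u_c, u_1)
  expect_true(ev$success)
  expect_equal(ev$band, c(0.9 * u_c, 1.1 * u_c))
  expect_equal(ev$rel_error, ev$abs_error / u_c)

  # perfect forecast
  d0 <- d; d0$u_c_hat <- u_c
  ev0 <- evaluate_detection(d0, u_c, u_1)
  expect_equal(ev0$abs_error, 0)
  expect_true(ev0$in_band)

  # exactly on the closed band edge counts as in-band; just beyond does not
  d_edge <- d; d_edge$u_c_hat <- u_c + 0.1 * u_c
  expect_true(evaluate_detection(d_edge, u_c, u_1)$in_band)
  d_out <- d; d_out$u_c_hat <- 3.5
  expect_false(evaluate_detection(d_out, u_c, u_1)$in_band)

  # non-detected results score as failures with NA errors
  dn <- suppressWarnings(tipmoc_monitor(variance_series(1:7, (1:7) / 10)))
  evn <- evaluate_detection(dn, u_c, u_1)
  expect_false(evn$success)
  expect_true(is.na(evn$abs_error))
})

test_that("a weak log-linear fit at detection triggers the audit warning", {
  found <- FALSE
  for (k in 1:12) {
    s <- make_power_series(30, 0, 2.7, a = 0.05, u_c = 3, gamma = 1, b = 0.1,
                           noise_sd = 0.02, seed = 950 + k)
    d <- tipmoc_monitor(s, seed = k, warn_rho = FALSE)
    if (d$detected && d$rho > -0.8) {
      expect_warning(tipmoc_monitor(s, seed = k, warn_rho = TRUE), "-0.8")
      found <- TRUE
      break
    }
  }
  if (!found) succeed("no weak-rho detection arose in these replicates")
})
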