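# Replicated evaluation of the monitor: Kendall's tau baseline, detection
# rates, and forecast-accuracy summaries over seeded sweep replicates.

#' Kendall rank correlation of a variance series
#'
#' The classical scalar early-warning performance measure: Kendall's tau
#' (tie-corrected, tau-b) between the control parameter and the sample
#' variance. For decreasing sweeps, benchmarks conventionally report `-tau`
#' so that a large value is always the desirable outcome; set
#' `sign_adjust = TRUE` for that convention.
#'
#' @param series A [variance_series()] (or data frame with `u`, `v_hat`) of
#'   at least 2 points.
#' @param sign_adjust Flip the sign for decreasing sweeps.
#' @return Kendall's tau in [-1, 1].
#' @export
kendall_tau <- function(series, sign_adjust = FALSE) {
  d <- as.data.frame(series)
  if (nrow(d) < 2L) stop("need at least 2 points")
  tau <- suppressWarnings(stats::cor(d$u, d$v_hat, method = "kendall"))
  if (is.na(tau)) stop("Kendall's tau undefined: all values tied")
  if (sign_adjust && inherits(series, "variance_series") &&
      series$direction == "decreasing") -tau else tau
}

#' The benchmark scenario matrix
#'
#' The nine model/scenario combinations of the evaluation suite: the
#' double-well system under three observation regimes (equally spaced u with
#' white noise, random u with white noise, random u with colored noise), the
#' four other bifurcating systems, and the two non-bifurcating controls
#' (Ornstein-Uhlenbeck null and over-harvesting with K = 2).
#'
#' @return Data frame with columns `model`, `K`, `grid_mode`, `noise_mode`,
#'   `bifurcating`.
#' @export
scenario_matrix <- function() {
  data.frame(
    model = c("double_well", "double_well", "double_well", "over_harvest",
              "linear_grazing", "rosenzweig_macarthur", "mutualistic",
              "ou_null", "over_harvest"),
    K = c(NA, NA, NA, 10, NA, NA, NA, NA, 2),
    grid_mode = c("equal", "random_sorted", "random_sorted", "equal", "equal",
                  "equal", "equal", "equal", "equal"),
    noise_mode = c("white", "white", "colored", "white", "white", "white",
                   "white", "white", "white"),
    bifurcating = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Run replicate sweeps and summarize detection performance
#'
#' Executes `n_runs` independently seeded sweeps of one model/scenario, runs
#' the monitor on each, and aggregates: mean and SD of Kendall's tau (all
#' runs, sign-adjusted for decreasing sweeps), the detection percentage, the
#' mean and SD of the forecast bifurcation point over detected runs, the
#' fraction of detected runs whose forecast falls in the band
#' `u_c +- 0.1 |u_c - u_1|`, and the Pearson correlation between the alarm
#' point and the forecast over detected runs. Runs whose series is truncated
#' below `ell0` points count as missed detections. In random-grid mode the
#' detector is, by default, handed relabeled u values (the equally spaced
#' design grid), mimicking the realistic situation where the actual u values
#' are unknown and presumed equidistant.
#'
#' @param model A `model_spec` or model name.
#' @param grid_mode,noise_mode See [sweep_config()].
#' @param n_runs Number of replicate sweeps.
#' @param root_seed Root seed; per-run seeds are derived from it.
#' @param n_u,L,dt,transient Sweep protocol overrides (defaults are the study
#'   protocol).
#' @param ell0,threshold,consecutive Detector settings, see [tipmoc_monitor()].
#' @param control Optimizer settings for the fits.
#' @param relabel_random_u Hand the detector equally spaced u values in
#'   random-grid mode.
#' @return An object of class `benchmark_summary`; the per-run results are in
#'   `$runs`.
#' @export
run_benchmark <- function(model, grid_mode = c("equal", "random_sorted"),
                          noise_mode = c("white", "colored"), n_runs = 20L,
                          root_seed = 1L, n_u = 50L, L = 100L, dt = 1e-3,
                          transient = 10, ell0 = 8L, threshold = -10,
                          consecutive = 3L, control = powerlaw_control(),
                          relabel_random_u = TRUE) {
  spec <- .as_model_spec(model)
  grid_mode <- match.arg(grid_mode)
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_runs >= 1L)
  u_c_true <- deterministic_bifurcation_point(spec)
  bounds <- .sweep_bounds(spec)
  u_1 <- bounds[1]
  design_grid <- seq(bounds[1], bounds[2], length.out = n_u)

  set.seed(root_seed)
  run_seeds <- sample.int(2147483646L, n_runs, replace = TRUE)

  runs <- data.frame(run = seq_len(n_runs), seed = run_seeds, n_points = NA_integer_,
                     truncated = NA, tau = NA_real_, detected = FALSE,
                     u_det = NA_real_, u_c_hat = NA_real_, gamma_hat = NA_real_,
                     in_band = NA)
  for (i in seq_len(n_runs)) {
    cfg <- sweep_config(spec, n_u = n_u, u_grid_mode = grid_mode, dt = dt,
                        transient = transient, L = L, noise_mode = noise_mode,
                        seed = run_seeds[i])
    series <- run_sweep(cfg)
    np <- length(series$u)
    runs$n_points[i] <- np
    runs$truncated[i] <- series$truncated_by_tipping
    if (np >= 2L) runs$tau[i] <- kendall_tau(series, sign_adjust = TRUE)
    if (np < ell0) next  # too little data before tipping: missed detection
    det_series <- series
    if (grid_mode == "random_sorted" && relabel_random_u) {
      # pretend the u values are unknown and equidistant on the design grid
      det_series <- variance_series(design_grid[seq_len(np)], series$v_hat,
                                    direction = series$direction,
                                    model = series$model)
    }
    det <- tipmoc_monitor(det_series, ell0 = ell0, threshold = threshold,
                          consecutive = consecutive, seed = run_seeds[i],
                          control = control, warn_rho = FALSE)
    runs$detected[i] <- det$detected
    if (det$detected) {
      runs$u_det[i] <- det$u_det
      runs$u_c_hat[i] <- det$u_c_hat
      runs$gamma_hat[i] <- det$gamma_hat
      if (!is.na(u_c_true))
        runs$in_band[i] <- evaluate_detection(det, u_c_true, u_1)$in_band
    }
  }

  det_runs <- runs[runs$detected, , drop = FALSE]
  nd <- nrow(det_runs)
  band <- if (!is.na(u_c_true))
    c(u_c_true - 0.1 * abs(u_c_true - u_1), u_c_true + 0.1 * abs(u_c_true - u_1))
  else c(NA_real_, NA_real_)
  structure(list(
    model_name = spec$name,
    scenario = paste(grid_mode, noise_mode, sep = "/"),
    n_runs = n_runs,
    tau_mean = mean(runs$tau, na.rm = TRUE),
    tau_sd = if (n_runs > 1L) stats::sd(runs$tau, na.rm = TRUE) else NA_real_,
    pct_detected = 100 * nd / n_runs,
    u_c_true = u_c_true,
    u_c_hat_mean = if (nd) mean(det_runs$u_c_hat) else NA_real_,
    u_c_hat_sd = if (nd > 1L) stats::sd(det_runs$u_c_hat) else NA_real_,
    band = band,
    pct_in_band = if (nd && !is.na(u_c_true))
      100 * mean(det_runs$in_band) else NA_real_,
    corr_udet_uchat = if (nd > 2L)
      suppressWarnings(stats::cor(det_runs$u_det, det_runs$u_c_hat))
    else NA_real_,
    root_seed = root_seed,
    runs = runs
  ), class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> ", x$model_name, " (", x$scenario, "), ",
      x$n_runs, " runs\n", sep = "")
  cat(sprintf("  tau = %.3f +- %.3f, detected %.0f%%\n",
              x$tau_mean, x$tau_sd, x$pct_detected))
  if (!is.na(x$u_c_true)) {
    cat(sprintf("  u_c true %.4g, forecast %.4g +- %.3g (%.0f%% in [%.4g, %.4g])\n",
                x$u_c_true, x$u_c_hat_mean, x$u_c_hat_sd,
                x$pct_in_band, x$band[1], x$band[2]))
    if (!is.na(x$corr_udet_uchat))
      cat(sprintf("  Corr(u_det, u_c_hat) = %.3f\n", x$corr_udet_uchat))
  }
  invisible(x)
}
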