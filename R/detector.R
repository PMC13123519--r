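# The sequential monitor: consume a variance series prefix by prefix, compare
# the power-law and linear fits at each step, and raise the alarm at the third
# consecutive decisive crossing.

#' Sequential tipping-point monitor
#'
#' For growing prefixes `l = ell0, ell0 + 1, ...` of the series, both models
#' are fitted and `delta AICc = AICc_power - AICc_linear` is recorded. When
#' `delta AICc < threshold` at `consecutive` consecutive indices (the default
#' three guards against isolated outliers), an impending bifurcation is
#' declared: the alarm point `u_det` is the u of the third crossing, and the
#' forecast bifurcation point `u_c_hat` and exponent `gamma_hat` are taken
#' from the power-law fit at that prefix. No later observations are consumed.
#' If the rule never fires, the series is exhausted and no bifurcation is
#' reported. A failed fit at some prefix counts as a non-crossing and resets
#' the consecutive counter.
#'
#' @param series A [variance_series()].
#' @param ell0 First prefix length at which models are compared (default 8;
#'   shorter prefixes would make the comparison meaningless).
#' @param threshold Decision threshold on `delta AICc` (default -10, a
#'   conservative evidence level).
#' @param consecutive Number of consecutive crossings required (default 3).
#' @param seed Integer; each prefix's stochastic fit gets a seed derived from
#'   it, so results are reproducible and prefix-causal.
#' @param epsilon,control Passed to [fit_power_law()].
#' @param warn_rho Warn when the achieved log-linear correlation at detection
#'   is above -0.8 (a weak fit worth auditing).
#' @return An object of class `detection_result` with fields `detected`,
#'   `u_det`, `u_c_hat`, `gamma_hat`, `rho`, `delta_aicc_trace` (data frame of
#'   `u` and `delta_aicc` for each prefix examined), `detection_index`,
#'   `stop_reason` (`"detected"` or `"exhausted"`), and the rule parameters.
#' @export
tipmoc_monitor <- function(series, ell0 = 8L, threshold = -10, consecutive = 3L,
                           seed = 0L, epsilon = 1e-5,
                           control = powerlaw_control(), warn_rho = TRUE) {
  stopifnot(inherits(series, "variance_series"), ell0 >= 6L, consecutive >= 1L)
  n <- length(series$u)
  empty_trace <- data.frame(u = numeric(0), delta_aicc = numeric(0))
  base <- list(detected = FALSE, u_det = NA_real_, u_c_hat = NA_real_,
               gamma_hat = NA_real_, rho = NA_real_,
               delta_aicc_trace = empty_trace, detection_index = NA_integer_,
               stop_reason = "exhausted", ell0 = as.integer(ell0),
               threshold = threshold, consecutive = as.integer(consecutive),
               direction = series$direction, n_available = n)
  if (n < ell0) {
    warning("series has ", n, " < ell0 = ", ell0,
            " points; detection not attempted")
    return(structure(base, class = "detection_result"))
  }

  trace_u <- numeric(0)
  trace_delta <- numeric(0)
  streak <- 0L
  for (l in seq.int(ell0, n)) {
    fit_seed <- (as.numeric(seed) + 104729 * l) %% 2147483647
    cmp <- tryCatch(
      compare_fits(series_prefix(series, l), epsilon = epsilon,
                   seed = as.integer(fit_seed), control = control),
      error = function(e) {
        warning("fit failed at prefix length ", l, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(cmp)) {
      trace_u <- c(trace_u, series$u[l])
      trace_delta <- c(trace_delta, NA_real_)
      streak <- 0L
      next
    }
    trace_u <- c(trace_u, series$u[l])
    trace_delta <- c(trace_delta, cmp$delta_aicc)
    crossed <- !is.nan(cmp$delta_aicc) && cmp$delta_aicc < threshold
    streak <- if (isTRUE(crossed)) streak + 1L else 0L
    if (streak >= consecutive) {
      base$detected <- TRUE
      base$u_det <- series$u[l]
      base$u_c_hat <- cmp$power$u_c_hat
      base$gamma_hat <- cmp$power$gamma
      base$rho <- cmp$power$rho
      base$detection_index <- l
      base$stop_reason <- "detected"
      if (warn_rho && cmp$power$rho > -0.8)
        warning(sprintf(
          "weak log-linear fit at detection (rho = %.3f > -0.8)",
          cmp$power$rho))
      break
    }
  }
  base$delta_aicc_trace <- data.frame(u = trace_u, delta_aicc = trace_delta)
  structure(base, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<detection_result> impending bifurcation detected at u_det = %.4g\n",
      x$u_det))
    cat(sprintf("  forecast u_c = %.4g, gamma = %.3g (rho = %.3f)\n",
                x$u_c_hat, x$gamma_hat, x$rho))
  } else {
    cat("<detection_result> no impending bifurcation detected (",
        x$stop_reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Score a detection against the true bifurcation point
#'
#' Computes whether the alarm came strictly before the true bifurcation point
#' in sweep direction, the absolute and relative forecast errors, and whether
#' the forecast falls inside the tolerance band
#' `[u_c - 0.1 |u_c - u_1|, u_c + 0.1 |u_c - u_1|]` (closed interval), whose
#' width is tied to the swept range because the absolute scale of u is
#' arbitrary.
#'
#' @param result A `detection_result`.
#' @param u_c_true True (deterministic) bifurcation point.
#' @param u_1 First value of the control-parameter sweep.
#' @return List with `success`, `abs_error`, `rel_error`, `in_band`, `band`.
#' @export
evaluate_detection <- function(result, u_c_true, u_1) {
  stopifnot(inherits(result, "detection_result"), is.finite(u_c_true))
  delta <- 0.1 * abs(u_c_true - u_1)
  band <- c(u_c_true - delta, u_c_true + delta)
  if (!result$detected) {
    return(list(success = FALSE, abs_error = NA_real_, rel_error = NA_real_,
                in_band = NA, band = band))
  }
  before <- if (result$direction == "decreasing") result$u_det > u_c_true
    else result$u_det < u_c_true
  abs_err <- abs(result$u_c_hat - u_c_true)
  list(success = isTRUE(before),
       abs_error = abs_err,
       rel_error = abs_err / abs(u_c_true - u_1),
       in_band = result$u_c_hat >= band[1] && result$u_c_hat <= band[2],
       band = band)
}
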