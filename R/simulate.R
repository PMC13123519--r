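# Euler-Maruyama integration, stationary sampling, and control-parameter
# sweeps. The heavy stepping runs in compiled code (src/sde.cpp); these
# wrappers manage schedules, seeding and tipping-triggered truncation.

#' Sweep configuration
#'
#' Bundles everything needed to run one control-parameter sweep: the model,
#' the u grid (50 equally spaced values by default, or values drawn uniformly
#' at random and sorted), the integration step `dt = 1e-3`, the discarded
#' transient (10 time units), the number of samples per u (`L = 100`), the
#' sampling interval `t_skip` (model default), and the noise mode.
#'
#' @param model A `model_spec` or model name.
#' @param n_u Number of control-parameter values (default 50).
#' @param u_grid_mode `"equal"` (equally spaced) or `"random_sorted"` (drawn
#'   uniformly on the sweep range, then sorted in the sweep direction).
#' @param dt Euler-Maruyama time step.
#' @param transient Time units discarded before sampling.
#' @param L Samples per control-parameter value.
#' @param t_skip Time units between samples; defaults to the model's value.
#' @param noise_mode `"white"` or `"colored"` (colored only for the
#'   double-well model: the white-noise term is replaced by an
#'   Ornstein-Uhlenbeck driver with relaxation time `colored_t0`).
#' @param colored_t0 Relaxation time of the colored-noise driver.
#' @param colored_sigma Amplitude of the driver noise; defaults to the model's
#'   white-noise sigma so the experiments are comparable.
#' @param seed Root seed of the sweep; per-u streams are derived from it, so
#'   the same seed reproduces the sweep exactly.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(model, n_u = 50L, u_grid_mode = c("equal", "random_sorted"),
                         dt = 1e-3, transient = 10, L = 100L, t_skip = NULL,
                         noise_mode = c("white", "colored"), colored_t0 = 1,
                         colored_sigma = NULL, seed = 1L) {
  spec <- .as_model_spec(model)
  u_grid_mode <- match.arg(u_grid_mode)
  noise_mode <- match.arg(noise_mode)
  if (is.null(t_skip)) t_skip <- spec$t_skip
  if (noise_mode == "colored" && spec$name != "double_well")
    stop("colored noise is implemented for the double-well model only")
  if (is.null(colored_sigma)) colored_sigma <- spec$parameters$sigma
  stopifnot(n_u >= 2L, dt > 0, dt < t_skip, L >= 2L, transient >= 0,
            colored_t0 > 0)
  if (n_u < 11L)
    warning("n_u < 11: too few points for detection with ell0 = 8")
  structure(list(spec = spec, n_u = as.integer(n_u), u_grid_mode = u_grid_mode,
                 dt = dt, transient = transient, L = as.integer(L),
                 t_skip = t_skip, noise_mode = noise_mode,
                 colored_t0 = colored_t0, colored_sigma = colored_sigma,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Integrate a model trajectory with Euler-Maruyama
#'
#' White noise adds independent Gaussian increments of standard deviation
#' `sigma * sqrt(dt)` to every coordinate; in colored mode an auxiliary OU
#' driver `d xi = -(xi/t0) dt + sigma_c dW` (initialized at zero) is
#' integrated alongside and `xi * dt` replaces the white-noise increment.
#'
#' @inheritParams sweep_config
#' @param u Control-parameter value (held fixed).
#' @param x0 Initial state; defaults to the model's initialization rule.
#' @param duration Integration time in time units.
#' @param record_every Time between recorded states (default: every step).
#' @return A list with `time` and a states matrix `x` (rows are recorded
#'   times, including the initial state), class `em_trajectory`.
#' @export
euler_maruyama <- function(model, u, x0 = NULL, duration, dt = 1e-3,
                           noise_mode = c("white", "colored"), colored_t0 = 1,
                           colored_sigma = NULL, record_every = NULL,
                           seed = NULL) {
  spec <- .as_model_spec(model)
  noise_mode <- match.arg(noise_mode)
  if (is.null(x0)) x0 <- init_state(spec, u)
  if (length(x0) != spec$dimension) stop("x0 has the wrong dimension")
  stopifnot(duration > 0, dt > 0)
  if (is.null(record_every)) record_every <- dt
  if (is.null(colored_sigma)) colored_sigma <- spec$parameters$sigma
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  stride <- max(1L, round(record_every / dt))
  e <- .cpp_edges(spec)
  states <- em_traj_cpp(spec$cpp_id, .cpp_params(spec), spec$parameters$sigma,
                        e$i, e$j, u, as.numeric(x0), n_steps, dt, stride,
                        if (noise_mode == "colored") 1L else 0L,
                        colored_t0, colored_sigma)
  structure(list(time = seq(0, by = stride * dt, length.out = nrow(states)),
                 x = states, model = spec$name, u = u),
            class = "em_trajectory")
}

#' Sample the stationary observable of a model at fixed u
#'
#' Initializes the state by the model's rule, integrates and discards the
#' transient, then records the scalar observable every `t_skip` time units
#' until `L` samples are collected (the first sample at `transient + t_skip`).
#' The tipping rule is checked at every integration step of both phases; if it
#' fires, the partial sample with `tipped = TRUE` is returned instead.
#'
#' @param model A `model_spec` or model name.
#' @param u Control-parameter value.
#' @param config A `sweep_config` supplying the schedule; when `NULL`,
#'   defaults are used with the remaining arguments.
#' @inheritParams sweep_config
#' @param seed Optional seed for this single run.
#' @return List with `samples`, `times`, `tipped`, `tip_time`; class
#'   `observable_sample`.
#' @export
sample_observable <- function(model, u, config = NULL, dt = 1e-3, transient = 10,
                              L = 100L, t_skip = NULL,
                              noise_mode = c("white", "colored"),
                              colored_t0 = 1, colored_sigma = NULL,
                              seed = NULL) {
  if (is.null(config)) {
    spec <- .as_model_spec(model)
    noise_mode <- match.arg(noise_mode)
    if (is.null(t_skip)) t_skip <- spec$t_skip
    if (is.null(colored_sigma)) colored_sigma <- spec$parameters$sigma
  } else {
    stopifnot(inherits(config, "sweep_config"))
    spec <- config$spec
    dt <- config$dt; transient <- config$transient; L <- config$L
    t_skip <- config$t_skip; noise_mode <- config$noise_mode
    colored_t0 <- config$colored_t0; colored_sigma <- config$colored_sigma
  }
  if (!is.null(seed)) set.seed(seed)
  e <- .cpp_edges(spec)
  res <- em_run_cpp(spec$cpp_id, .cpp_params(spec), spec$parameters$sigma,
                    e$i, e$j, u, as.numeric(init_state(spec, u)), dt,
                    transient, L, t_skip,
                    if (noise_mode == "colored") 1L else 0L,
                    colored_t0, colored_sigma, check_tipping = TRUE)
  structure(list(samples = res$samples[seq_len(res$n)],
                 times = res$times[seq_len(res$n)],
                 tipped = res$tipped, tip_time = res$tip_time,
                 model = spec$name, u = u),
            class = "observable_sample")
}

#' Unbiased sample variance
#'
#' @param samples Numeric vector of at least two observations.
#' @return `sum((x - mean(x))^2) / (length(x) - 1)`.
#' @export
sample_variance <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  stats::var(samples)
}

#' Ordered series of (u, sample variance) pairs
#'
#' The sole input the detector needs. `u` must be strictly monotone in the
#' stated sweep direction; when `direction` is omitted it is inferred.
#'
#' @param u Control-parameter values.
#' @param v_hat Sample variances, same length, non-negative.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param truncated_by_tipping Whether the sweep stopped early on a tipping
#'   event.
#' @param tipping_u The u value at which tipping occurred (or `NA`).
#' @param model Optional model name carried along for bookkeeping.
#' @return An object of class `variance_series`.
#' @export
variance_series <- function(u, v_hat, direction = NULL,
                            truncated_by_tipping = FALSE, tipping_u = NA_real_,
                            model = NA_character_) {
  stopifnot(is.numeric(u), is.numeric(v_hat), length(u) == length(v_hat))
  if (anyNA(u) || anyNA(v_hat)) stop("u and v_hat must not contain NA")
  if (any(v_hat < 0)) stop("v_hat must be non-negative")
  if (length(u) >= 2L) {
    d <- diff(u)
    inferred <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
      else stop("u is not strictly monotone")
    if (is.null(direction)) direction <- inferred
    else if (direction != inferred) stop("direction does not match ordering of u")
  } else if (is.null(direction)) direction <- "increasing"
  structure(list(u = as.numeric(u), v_hat = as.numeric(v_hat),
                 direction = direction,
                 truncated_by_tipping = isTRUE(truncated_by_tipping),
                 tipping_u = tipping_u, model = model),
            class = "variance_series")
}

#' @export
print.variance_series <- function(x, ...) {
  cat("<variance_series> ", length(x$u), " points, ", x$direction,
      if (x$truncated_by_tipping) ", truncated by tipping" else "", "\n", sep = "")
  if (length(x$u)) {
    cat("  u in [", format(min(x$u)), ", ", format(max(x$u)), "], v_hat in [",
        format(min(x$v_hat)), ", ", format(max(x$v_hat)), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.variance_series <- function(x, ...) {
  data.frame(u = x$u, v_hat = x$v_hat)
}

#' First l points of a variance series
#' @param series A `variance_series`.
#' @param l Prefix length.
#' @return A `variance_series` of length `l`.
#' @export
series_prefix <- function(series, l) {
  stopifnot(inherits(series, "variance_series"), l >= 1L, l <= length(series$u))
  variance_series(series$u[seq_len(l)], series$v_hat[seq_len(l)],
                  direction = if (l >= 2L) series$direction else series$direction,
                  truncated_by_tipping = FALSE, model = series$model)
}

#' Run a control-parameter sweep
#'
#' Builds the u grid (equal spacing across the sweep range, capped at the
#' deterministic bifurcation point when one exists; or uniform random draws,
#' sorted), and at each u in sweep order re-initializes the state, integrates,
#' and computes the unbiased sample variance of the observable. The sweep
#' stops and the series is truncated at the first u whose run tips.
#'
#' @param config A `sweep_config`; alternatively pass a model (name or spec)
#'   and configuration arguments via `...` which are forwarded to
#'   [sweep_config()].
#' @param ... Passed to [sweep_config()] when `config` is not a
#'   `sweep_config`.
#' @return A [variance_series()] (possibly of zero length if tipping occurred
#'   at the very first u), with the config attached as attribute `"config"`.
#' @export
run_sweep <- function(config, ...) {
  if (!inherits(config, "sweep_config")) config <- sweep_config(config, ...)
  spec <- config$spec
  decreasing <- spec$direction == "decreasing"
  bounds <- .sweep_bounds(spec)
  u_start <- bounds[1]
  u_end <- bounds[2]

  set.seed(config$seed)
  run_seeds <- sample.int(2147483646L, config$n_u, replace = TRUE)
  u_grid <- if (config$u_grid_mode == "equal") {
    seq(u_start, u_end, length.out = config$n_u)
  } else {
    sort(stats::runif(config$n_u, min(u_start, u_end), max(u_start, u_end)),
         decreasing = decreasing)
  }

  v_hat <- numeric(0)
  u_used <- numeric(0)
  tipped <- FALSE
  tipping_u <- NA_real_
  for (i in seq_len(config$n_u)) {
    set.seed(run_seeds[i])
    obs <- sample_observable(spec, u_grid[i], config = config)
    if (obs$tipped) {
      tipped <- TRUE
      tipping_u <- u_grid[i]
      break
    }
    u_used <- c(u_used, u_grid[i])
    v_hat <- c(v_hat, sample_variance(obs$samples))
  }
  out <- variance_series(u_used, v_hat, direction = spec$direction,
                         truncated_by_tipping = tipped, tipping_u = tipping_u,
                         model = spec$name)
  attr(out, "config") <- config
  attr(out, "u_grid") <- u_grid
  out
}
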