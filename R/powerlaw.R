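# Power-law versus linear fitting of a variance series prefix, and AICc
# model comparison. The power law V(u) = a (u_c - u)^(-gamma) + b is fitted by
# a constrained 2-D global search over (u_c, b): for each candidate, the
# log-linear transform ln(V - b) = ln a - gamma ln(u_c - u) must be as close
# to linear as possible, so the search minimizes the Pearson correlation
# between ln(u_c - u) and ln(V - b) toward -1; a and gamma then follow by
# ordinary least squares at the optimum. Direct 4-parameter nonlinear least
# squares is deliberately avoided (it rarely converges on this problem).

#' Optimizer settings for the power-law fit
#'
#' The (u_c, b) search uses a differential-evolution global optimizer
#' (rand/1/bin, population `np`, at most `maxiter` generations, stopping when
#' the population spread falls below `reltol` relative to the mean objective)
#' followed by an optional L-BFGS-B polish of the best member.
#'
#' @param np Population size.
#' @param maxiter Maximum generations.
#' @param reltol Relative convergence tolerance on the population energies.
#' @param cr Crossover probability.
#' @param polish Run a bounded local polish from the best member.
#' @return A list of class `powerlaw_control`.
#' @export
powerlaw_control <- function(np = 32L, maxiter = 300L, reltol = 1e-7,
                             cr = 0.9, polish = TRUE) {
  stopifnot(np >= 8L, maxiter >= 1L, reltol > 0, cr > 0, cr <= 1)
  structure(list(np = as.integer(np), maxiter = as.integer(maxiter),
                 reltol = reltol, cr = cr, polish = isTRUE(polish)),
            class = "powerlaw_control")
}

# Differential evolution (rand/1/bin with dithered weight and reflecting
# bounds) for a vectorized objective fn(matrix) -> vector. Returns the best
# member; deliberately minimal -- the search space here is always a 2-D box.
.de_optim <- function(fn, lower, upper, control, init = NULL) {
  np <- control$np
  dim <- length(lower)
  span <- upper - lower
  pop <- matrix(stats::runif(np * dim), np, dim) * rep(span, each = np) +
    rep(lower, each = np)
  if (!is.null(init)) {
    k <- min(nrow(init), np %/% 2)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  fv <- fn(pop)
  iters <- 0L
  for (it in seq_len(control$maxiter)) {
    iters <- it
    fw <- stats::runif(1, 0.5, 1)
    r1 <- sample.int(np)
    r2 <- (r1 + sample.int(np - 1L, np, replace = TRUE) - 1L) %% np + 1L
    r3 <- (r2 + sample.int(np - 1L, np, replace = TRUE) - 1L) %% np + 1L
    mut <- pop[r1, , drop = FALSE] + fw * (pop[r2, , drop = FALSE] -
                                             pop[r3, , drop = FALSE])
    mask <- matrix(stats::runif(np * dim) < control$cr, np, dim)
    mask[cbind(seq_len(np), sample.int(dim, np, replace = TRUE))] <- TRUE
    trial <- pop
    trial[mask] <- mut[mask]
    # reflect out-of-box candidates back inside, then clamp
    for (k in seq_len(dim)) {
      lo <- trial[, k] < lower[k]
      trial[lo, k] <- 2 * lower[k] - trial[lo, k]
      hi <- trial[, k] > upper[k]
      trial[hi, k] <- 2 * upper[k] - trial[hi, k]
      trial[, k] <- pmin(pmax(trial[, k], lower[k]), upper[k])
    }
    ft <- fn(trial)
    better <- ft <= fv
    pop[better, ] <- trial[better, , drop = FALSE]
    fv[better] <- ft[better]
    if (stats::sd(fv) <= control$reltol * abs(mean(fv)) + 1e-12) break
  }
  ord <- order(fv)
  list(par = pop[ord[1], ], value = fv[ord[1]], iterations = iters,
       runners_up = pop[ord[2:min(4, np)], , drop = FALSE])
}

# Vectorized objective: Pearson correlation between ln|u_c - u| and
# ln(V - b) for a population of (u_c, b) rows. Degenerate candidates (fewer
# than 3 distinct values in either transformed variable) score +1, the worst
# possible value.
.make_powerlaw_objective <- function(u, v, decreasing) {
  n <- length(u)
  function(theta) {
    uc <- theta[, 1]
    b <- theta[, 2]
    X <- if (decreasing) log(outer(-uc, u, `+`)) else log(outer(uc, -u, `+`))
    Y <- log(outer(-b, v, `+`))
    Xc <- X - rowMeans(X)
    Yc <- Y - rowMeans(Y)
    sx <- rowSums(Xc * Xc)
    sy <- rowSums(Yc * Yc)
    r <- rowSums(Xc * Yc) / sqrt(sx * sy)
    r[!is.finite(r) | sx < n * 1e-24 | sy < n * 1e-24] <- 1
    r
  }
}

#' Linear fit of a variance series
#'
#' Ordinary least squares of `V(u) = alpha u + beta`, the non-diverging
#' baseline the power law is compared against.
#'
#' @param series_prefix A [variance_series()] (or anything [as.data.frame()]
#'   coercible with columns `u`, `v_hat`) with at least 3 points.
#' @return List with `alpha` (slope), `beta` (intercept), `rss`; class
#'   `linear_fit`.
#' @export
fit_linear <- function(series_prefix) {
  d <- as.data.frame(series_prefix)
  if (nrow(d) < 3L) stop("need at least 3 points for the linear fit")
  if (length(unique(d$u)) < 2L) stop("degenerate u values")
  fit <- stats::lm.fit(cbind(1, d$u), d$v_hat)
  structure(list(alpha = unname(fit$coefficients[2]),
                 beta = unname(fit$coefficients[1]),
                 rss = sum(fit$residuals^2),
                 n_points = nrow(d)),
            class = "linear_fit")
}

#' Constrained power-law fit of a variance series
#'
#' Fits `V(u) = a (u_c - u)^(-gamma) + b` (for increasing sweeps; mirrored to
#' `a (u - u_c)^(-gamma) + b` for decreasing sweeps) to the first `l`
#' observations by a global search over the 2-D box
#' `u_l + eps <= u_c <= u_l + 10 (u_l - u_1)` and
#' `V_min - (V_max - V_min)/2 <= b <= V_min - eps`, minimizing the Pearson
#' correlation between `ln(u_c - u)` and `ln(V - b)` toward -1. `ln a` and
#' `gamma` are then obtained by least squares on the log-linear relation, and
#' the residual sum of squares is recomputed in the original (u, V) plane so
#' that the power-law and linear fits are scored on the same likelihood
#' surface.
#'
#' @inheritParams fit_linear
#' @param epsilon Margin `eps` keeping `u_c` beyond the data and `b` below it.
#' @param seed Optional integer seed for the stochastic search (the RNG state
#'   is restored afterwards); `NULL` uses the current RNG stream.
#' @param control A [powerlaw_control()].
#' @return List with `a`, `u_c_hat`, `gamma`, `b`, `rss`, `rho` (the achieved
#'   correlation), `n_points`, `direction`; class `power_law_fit`.
#' @examples
#' u <- seq(0, 4, by = 0.5)
#' s <- variance_series(u, 2 / (5 - u) + 1)
#' fit_power_law(s, seed = 1)   # recovers u_c = 5, gamma = 1, a = 2, b = 1
#' @export
fit_power_law <- function(series_prefix, epsilon = 1e-5, seed = NULL,
                          control = powerlaw_control()) {
  s <- if (inherits(series_prefix, "variance_series")) series_prefix else {
    d <- as.data.frame(series_prefix)
    variance_series(d$u, d$v_hat)
  }
  u <- s$u
  v <- s$v_hat
  n <- length(u)
  if (n < 4L) stop("need at least 4 points for the power-law fit")
  v_min <- min(v)
  v_max <- max(v)
  if (v_max <= v_min) stop("degenerate series: v_hat has no spread")
  decreasing <- s$direction == "decreasing"
  u_l <- u[n]
  u_1 <- u[1]
  span <- abs(u_l - u_1)
  if (span <= 0) stop("degenerate u values")
  lower <- c(if (decreasing) u_l - 10 * span else u_l + epsilon,
             v_min - (v_max - v_min) / 2)
  upper <- c(if (decreasing) u_l - epsilon else u_l + 10 * span,
             v_min - epsilon)
  if (lower[2] > upper[2]) stop("epsilon too large for the spread of v_hat")

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  obj <- .make_powerlaw_objective(u, v, decreasing)
  # seed the population with a coarse grid scan plus the box corners: the
  # optimum can sit in a narrow sliver against a bound (e.g. b near V_min)
  # that uniform random initialization is unlikely to sample
  shrink <- 1e-6 * c(upper - lower)
  gx <- seq(lower[1] + shrink[1], upper[1] - shrink[1], length.out = 12L)
  gy <- seq(lower[2] + shrink[2], upper[2] - shrink[2], length.out = 12L)
  coarse <- cbind(rep(gx, times = 12L), rep(gy, each = 12L))
  fc <- obj(coarse)
  init <- coarse[order(fc)[1:8], , drop = FALSE]
  opt <- .de_optim(obj, lower, upper, control, init = init)
  if (control$polish) {
    # local polish from the best members: on noise-dominated prefixes the
    # objective surface is flat and multimodal, so one start is not enough
    scalar_obj <- function(th) obj(matrix(th, 1L))
    for (start in seq_len(1L + nrow(opt$runners_up))) {
      par0 <- if (start == 1L) opt$par else opt$runners_up[start - 1L, ]
      pol <- tryCatch(
        stats::optim(par0, scalar_obj, method = "L-BFGS-B",
                     lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < opt$value) {
        opt$par <- pol$par
        opt$value <- pol$value
      }
    }
  }

  u_c <- opt$par[1]
  b <- opt$par[2]
  X <- log(abs(u_c - u))
  Y <- log(v - b)
  slope <- stats::cov(X, Y) / stats::var(X)
  gamma <- -slope
  a <- exp(mean(Y) - slope * mean(X))
  pred <- a * abs(u_c - u)^(-gamma) + b
  structure(list(a = a, u_c_hat = u_c, gamma = gamma, b = b,
                 rss = sum((v - pred)^2), rho = opt$value, n_points = n,
                 direction = s$direction, epsilon = epsilon,
                 iterations = opt$iterations),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> V(u) = a |u_c - u|^(-gamma) + b on ", x$n_points,
      " points\n", sep = "")
  cat(sprintf("  a = %.4g, u_c = %.4g, gamma = %.4g, b = %.4g\n",
              x$a, x$u_c_hat, x$gamma, x$b))
  cat(sprintf("  rss = %.4g, rho = %.4f\n", x$rss, x$rho))
  invisible(x)
}

#' Corrected Akaike information criterion from a residual sum of squares
#'
#' Under i.i.d. Gaussian residuals, `-2 ln L = n ln(RSS/n)` up to an additive
#' constant that depends only on `n` and therefore cancels in any AICc
#' difference between models fitted to the same data; that constant is
#' dropped. A perfect fit (`rss = 0`) maps to `-Inf`.
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n Number of observations; must exceed `k + 1`.
#' @param k Number of model parameters (2 for the linear fit, 4 for the power
#'   law).
#' @return `n log(rss/n) + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(rss, n, k) {
  stopifnot(rss >= 0, k >= 1)
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  if (rss == 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare the power-law and linear fits on a series prefix
#'
#' Runs both fits on the same points and computes
#' `delta_aicc = AICc_power - AICc_linear` with `k = 4` for the power law and
#' `k = 2` for the linear baseline. A strongly negative value (below -10 under
#' the default detection rule) is decisive support for the diverging power
#' law.
#'
#' @inheritParams fit_power_law
#' @return List with both fits, `aicc_linear`, `aicc_power`, `delta_aicc`;
#'   class `fit_comparison`.
#' @export
compare_fits <- function(series_prefix, epsilon = 1e-5, seed = NULL,
                         control = powerlaw_control()) {
  lin <- fit_linear(series_prefix)
  pow <- fit_power_law(series_prefix, epsilon = epsilon, seed = seed,
                       control = control)
  n <- pow$n_points
  a_l <- aicc(lin$rss, n, 2L)
  a_p <- aicc(pow$rss, n, 4L)
  structure(list(linear = lin, power = pow, aicc_linear = a_l, aicc_power = a_p,
                 delta_aicc = a_p - a_l, n_points = n),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("<fit_comparison> n = %d: AICc linear %.2f, power %.2f, delta %.2f\n",
              x$n_points, x$aicc_linear, x$aicc_power, x$delta_aicc))
  invisible(x)
}
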