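# Shared fixtures and independent oracles, built in code at test time.

# Synthetic diverging-variance series V(u) = a |u_c - u|^(-gamma) + b.
make_power_series <- function(n, u_min, u_max, a, u_c, gamma, b,
                              noise_sd = 0, seed = NULL, decreasing = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  u <- seq(u_min, u_max, length.out = n)
  if (decreasing) u <- rev(u)
  v <- a * abs(u_c - u)^(-gamma) + b
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  variance_series(u, pmax(v, 1e-8))
}

# O(n^2) pair-counting Kendall tau-b oracle, independent of stats::cor.
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) { tx <- tx + 1; next }
      if (sy == 0) { ty <- ty + 1; next }
      if (sx * sy > 0) conc <- conc + 1 else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Exhaustive fine-grid minimum of the log-linear correlation objective over
# the same (u_c, b) box the fitter searches; the independent optimizer oracle.
grid_min_objective <- function(series, epsilon = 1e-5, ng = 400L) {
  u <- series$u
  v <- series$v_hat
  n <- length(u)
  decreasing <- series$direction == "decreasing"
  u_l <- u[n]; u_1 <- u[1]
  v_min <- min(v); v_max <- max(v)
  span <- abs(u_l - u_1)
  ucs <- if (decreasing) seq(u_l - 10 * span, u_l - epsilon, length.out = ng)
         else seq(u_l + epsilon, u_l + 10 * span, length.out = ng)
  bs <- seq(v_min - (v_max - v_min) / 2, v_min - epsilon, length.out = ng)
  X <- if (decreasing) log(outer(-ucs, u, `+`)) else log(outer(ucs, -u, `+`))
  Y <- log(outer(-bs, v, `+`))
  std_rows <- function(M) {
    M <- M - rowMeans(M)
    M / sqrt(rowSums(M * M))
  }
  R <- std_rows(X) %*% t(std_rows(Y))
  min(R[is.finite(R)])
}

# Small, fast sweep settings for structural tests (not the study protocol).
cheap_ou_config <- function(seed, n_u = 12L) {
  suppressWarnings(sweep_config("ou_null", n_u = n_u, dt = 0.01, transient = 1,
                                L = 20L, t_skip = 0.5, seed = seed))
}
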