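#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model ids shared with the R wrappers (see R/models.R):
//   1 double_well           params: r1, r2, r3
//   2 over_harvest          params: r, K, x_tilde
//   3 linear_grazing        params: r, K
//   4 rosenzweig_macarthur  params: r, g, h, e, m     (u is the carrying capacity K)
//   5 mutualistic           params: B, C, D_tilde, E, H, K, u_tilde  (u is the coupling D)
//   6 ou_null               params: (none)            dx = -x/u dt + sigma dW
//   7 hopf_linear           params: (none)            linearized Hopf normal form, u < 0
// The noise amplitude sigma is passed separately; `params` holds drift constants only.

static void drift_eval(const int model, const double* p, const double u,
                       const double* x, double* f, const int d,
                       const int* ei, const int* ej, const int ne) {
  switch (model) {
  case 1:
    f[0] = -(x[0] - p[0]) * (x[0] - p[1]) * (x[0] - p[2]) + u;
    break;
  case 2: {
    const double xt2 = p[2] * p[2];
    f[0] = p[0] * x[0] * (1.0 - x[0] / p[1]) - u * x[0] * x[0] / (x[0] * x[0] + xt2);
    break;
  }
  case 3:
    f[0] = p[0] * x[0] * (1.0 - x[0] / p[1]) - u * x[0];
    break;
  case 4: {
    const double fr = x[0] + p[2];
    f[0] = p[0] * x[0] * (1.0 - x[0] / u) - p[1] * x[0] * x[1] / fr;
    f[1] = p[3] * p[1] * x[0] * x[1] / fr - p[4] * x[1];
    break;
  }
  case 5: {
    const double B = p[0], C = p[1], Dt = p[2], E = p[3], H = p[4], K = p[5], ut = p[6];
    for (int i = 0; i < d; ++i)
      f[i] = B + x[i] * (1.0 - x[i] / K) * (x[i] / C - 1.0) + ut;
    for (int e = 0; e < ne; ++e) {
      const int i = ei[e], j = ej[e];
      f[i] += u * x[i] * x[j] / (Dt + E * x[i] + H * x[j]);
      f[j] += u * x[j] * x[i] / (Dt + E * x[j] + H * x[i]);
    }
    break;
  }
  case 6:
    f[0] = -x[0] / u;
    break;
  case 7:
    f[0] = u * x[0] - x[1];
    f[1] = x[0] + u * x[1];
    break;
  default:
    Rcpp::stop("unknown model id");
  }
}

// Regime-shift predicates checked at every integration step.
static inline bool tipped_state(const int model, const double* p, const double* x,
                                const int d) {
  switch (model) {
  case 1: return x[0] > p[1];      // past the middle (unstable) root r2
  case 2: return x[0] < 0.0;       // resource biomass collapsed
  case 3: return x[0] <= 0.0;      // biomass extinct
  case 5: {
    for (int i = 0; i < d; ++i) if (x[i] < 0.1) return true;
    return false;
  }
  default: return false;           // rosenzweig_macarthur, ou_null, hopf_linear
  }
}

static inline void em_step(const int model, const double* p, const double sigma,
                           const double u, double* x, double* f, const int d,
                           const int* ei, const int* ej, const int ne,
                           const double dt, const double sqdt,
                           const int noise_mode, const double t0,
                           const double sigma_c, double* xi) {
  drift_eval(model, p, u, x, f, d, ei, ej, ne);
  if (noise_mode == 1) {
    // colored noise: an auxiliary OU driver replaces the white-noise term on x[0]
    x[0] += f[0] * dt + (*xi) * dt;
    *xi += -(*xi) / t0 * dt + sigma_c * sqdt * norm_rand();
  } else if (sigma > 0.0) {
    for (int i = 0; i < d; ++i) x[i] += f[i] * dt + sigma * sqdt * norm_rand();
  } else {
    for (int i = 0; i < d; ++i) x[i] += f[i] * dt;
  }
  if (model == 4) {                // clamp negative biomasses to zero
    if (x[0] < 0.0) x[0] = 0.0;
    if (x[1] < 0.0) x[1] = 0.0;
  }
}

static inline void check_finite(const double* x, const int d, const double t) {
  for (int i = 0; i < d; ++i)
    if (!R_finite(x[i]))
      Rcpp::stop("numerical blow-up: non-finite state at t = %g", t);
}

// Integrate past the transient, then record the observable (coordinate 1) every
// t_skip time units, up to L samples. Tipping is checked at every step of both
// phases; on tipping the partial record is returned with tipped = TRUE.
// [[Rcpp::export]]
List em_run_cpp(int model, NumericVector params, double sigma,
                IntegerVector edge_i, IntegerVector edge_j,
                double u, NumericVector x0, double dt, double transient,
                int L, double t_skip, int noise_mode, double colored_t0,
                double colored_sigma, bool check_tipping) {
  const int d = x0.size();
  const int ne = edge_i.size();
  std::vector<double> x(x0.begin(), x0.end()), f(d);
  const long trans_steps = (long)std::lround(transient / dt);
  const long skip_steps = (long)std::lround(t_skip / dt);
  const double sqdt = std::sqrt(dt);
  double xi = 0.0;
  NumericVector samples(L);
  NumericVector times(L);
  bool tip = false;
  double tip_t = NA_REAL;
  long step = 0;
  const double* pp = params.begin();
  const int* ei = edge_i.begin();
  const int* ej = edge_j.begin();

  for (long s = 0; s < trans_steps && !tip; ++s) {
    em_step(model, pp, sigma, u, x.data(), f.data(), d, ei, ej, ne,
            dt, sqdt, noise_mode, colored_t0, colored_sigma, &xi);
    ++step;
    if (check_tipping && tipped_state(model, pp, x.data(), d)) {
      tip = true; tip_t = step * dt;
    }
  }
  check_finite(x.data(), d, step * dt);

  int got = 0;
  for (int l = 0; l < L && !tip; ++l) {
    for (long s = 0; s < skip_steps && !tip; ++s) {
      em_step(model, pp, sigma, u, x.data(), f.data(), d, ei, ej, ne,
              dt, sqdt, noise_mode, colored_t0, colored_sigma, &xi);
      ++step;
      if (check_tipping && tipped_state(model, pp, x.data(), d)) {
        tip = true; tip_t = step * dt;
      }
    }
    check_finite(x.data(), d, step * dt);
    if (!tip) {
      samples[got] = x[0];
      times[got] = step * dt;
      ++got;
    }
  }

  return List::create(_["samples"] = samples, _["times"] = times,
                      _["n"] = got, _["tipped"] = tip, _["tip_time"] = tip_t);
}

// Full-state trajectory recorded every rec_stride steps (row 1 = initial state).
// [[Rcpp::export]]
NumericMatrix em_traj_cpp(int model, NumericVector params, double sigma,
                          IntegerVector edge_i, IntegerVector edge_j,
                          double u, NumericVector x0, long n_steps, double dt,
                          long rec_stride, int noise_mode, double colored_t0,
                          double colored_sigma) {
  const int d = x0.size();
  const int ne = edge_i.size();
  std::vector<double> x(x0.begin(), x0.end()), f(d);
  const double sqdt = std::sqrt(dt);
  double xi = 0.0;
  const long n_rec = n_steps / rec_stride;
  NumericMatrix out(n_rec + 1, d);
  for (int i = 0; i < d; ++i) out(0, i) = x[i];
  const double* pp = params.begin();
  const int* ei = edge_i.begin();
  const int* ej = edge_j.begin();

  long row = 1;
  for (long s = 1; s <= n_steps; ++s) {
    em_step(model, pp, sigma, u, x.data(), f.data(), d, ei, ej, ne,
            dt, sqdt, noise_mode, colored_t0, colored_sigma, &xi);
    if (s % rec_stride == 0 && row <= n_rec) {
      check_finite(x.data(), d, s * dt);
      for (int i = 0; i < d; ++i) out(row, i) = x[i];
      ++row;
    }
  }
  return out;
}
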