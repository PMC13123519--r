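# tipmoc

Detecting and forecasting tipping points from the sample variance alone.

Slowly forced nonlinear systems — lake ecosystems, harvested populations,
networked mutualistic communities — can lose their operating state abruptly
when a drifting control parameter `u` crosses a bifurcation point `u_c`.
Approaching codimension-one bifurcations, critical slowing down inflates the
stationary variance of fluctuations as a power law,

    V(u) = a * (u_c - u)^(-gamma) + b,

with `gamma = 1/2` for a saddle-node and `gamma = 1` for transcritical,
pitchfork and Hopf bifurcations. **tipmoc** implements TIPMOC (tipping via
power-law fits and model comparison), a sequential monitor for scientists
who already track variance-based early-warning signals: as each new pair
`(u, V̂)` arrives it fits both the diverging power law and a linear baseline
`V(u) = alpha*u + beta`, compares them with the small-sample corrected AIC

    AICc = n*log(RSS/n) + 2k + 2k(k+1)/(n-k-1)      (k = 4 vs k = 2),

and raises an alarm when `AICc_power - AICc_linear < -10` at three
consecutive steps. At the alarm point `u_det` it reports the divergence
location `u_c_hat` of the fitted power law as the forecast bifurcation
point, together with the fitted exponent `gamma`. Unlike a Kendall-tau
trend test, the monitor both *decides* whether a bifurcation is being
approached (with a low false-positive rate on trending nulls) and *says
where* it will happen.

The power-law fit avoids ill-conditioned 4-parameter least squares: it
searches only `(u_c_hat, b)` inside the constrained box
`u_l + 1e-5 <= u_c_hat <= u_l + 10*(u_l - u_1)`,
`V_min - (V_max - V_min)/2 <= b <= V_min - 1e-5`, minimizing the Pearson
correlation between `log(u_c_hat - u)` and `log(V̂ - b)` toward -1 with a
differential-evolution search, then reads `log a` and `gamma` off the
log-linear regression.

The package also ships the full simulation test bed used to validate the
method: six stochastic dynamical systems (double-well, over-harvesting with
saturating and with linear grazing, Rosenzweig–MacArthur, a mutualistic
network model, and an Ornstein–Uhlenbeck null), an Euler–Maruyama integrator
(compiled), white and colored dynamical noise, even and uneven control
grids, tipping-triggered sweep truncation, and replicate benchmarking with
Kendall's tau, detection rates and forecast-error summaries.

## A worked example

Sweep the stochastic double-well system `dx = [-(x-1)(x-3)(x-5) + u]dt +
0.25 dW` toward its saddle-node bifurcation at `u ≈ 3.079`, then monitor the
resulting variance series:

```r
library(tipmoc)

series <- run_sweep(sweep_config("double_well", seed = 7))
series
#> <variance_series> 44 points, increasing, truncated by tipping
#>   u in [0, 2.702156], v_hat in [0.003320204, 0.01785424]

kendall_tau(series)
#> [1] 0.794926

result <- tipmoc_monitor(series, seed = 7)
result
#> <detection_result> impending bifurcation detected at u_det = 2.388
#>   forecast u_c = 2.847, gamma = 0.543 (rho = -0.920)

evaluate_detection(result, u_c_true = 3.079, u_1 = 0)$in_band
#> [1] TRUE
```

Reading the output: noise kicked this run out of the shallow well at
`u = 2.765`, so 44 of the 50 planned points were observed, all strictly
before tipping. Variance rose from about 0.0033 to 0.018 (Kendall tau 0.79
— high, but by itself uninformative about *whether* or *where*). The monitor
declared an impending bifurcation at `u_det = 2.39`, forecasting the
bifurcation at `u_c_hat = 2.85` with exponent 0.54 (theory: 0.5 for a
saddle-node) — inside the ±10%-of-range tolerance band around the true
3.079. The achieved log-linear correlation -0.92 marks a trustworthy fit.

Replicated evaluation, e.g. false positives on the no-bifurcation null:

```r
run_benchmark("ou_null", n_runs = 10, root_seed = 7)
#> <benchmark_summary> ou_null (equal/white), 10 runs
#>   tau = 0.864 +- 0.026, detected 0%
```

A thin command-line wrapper with `simulate`, `fit`, `detect` (including a
streaming stdin mode) and `benchmark` subcommands is installed at
`inst/scripts/tipmoc`.

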