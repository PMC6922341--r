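# setpointr

Extracts the topology of nonlinear dynamical systems — set points and
the local dynamics around them — from multivariate time series, using
quantile regression forests fitted to difference-equation outcomes.

## The problem

Flexible machine-learning regressions predict where a time series goes
next but say little about the *structure* of the dynamics: where the
equilibria are, which attract, which repel, where the system merely
slows down, and where it cycles. `setpointr` closes that gap for anyone
modeling biomedical or behavioral time series (accelerometry,
physiological channels, symptom trajectories) without a known governing
equation. It treats the data as a first-order difference equation

```
Y[t+1] - Y[t] = F(Y[t], C[t]) + e[t]
```

fits `F` with a random forest, and then interrogates the fitted machine:

- **Set points** are grid coordinates where a quantile pseudo-confidence
  interval of predicted change (e.g. the 40th–60th percentiles, computed
  Meinshausen-style from the forest's leaf co-membership weights)
  contains zero — for multi-equation systems, simultaneously in every
  equation.
- **Dynamics classes** come from probing predicted change slightly below
  and above each set point (attractor / repeller / transient) and from
  the eigenvalues of a least-squares Jacobian estimated around it
  (attraction, repulsion, saddle, rotation/cycle).
- **Robustness** is read off a sweep over 24 quantile pairs: the more
  pairs bracket zero at a coordinate, the more credible the set point.

A stochastic cusp-catastrophe simulator (`simulate_cusp()`), a
maximum-likelihood cusp density fit with Cobb's pseudo-R² (the measure
that sees the fold a linear R² ignores), a Monte Carlo driver, and
surrogate generators with known topology (point attractor vs limit
cycle) round out the package and make every claim testable.

## Worked example

```r
library(setpointr)

ts <- simulate_cusp(1000, sd_e = 0.05, seed = 1)   # cusp series, 5% noise
prop_error(ts)
#> [1] 0.1230657

frame <- make_diff_frame(ts, modeled = "y", controls = c("a", "b"))
fit <- fit_forest(frame, d_y, params = forest_params(n_trees = 200, seed = 1))
fit
#> <qrforest> outcome: d_y | predictors: y, a, b
#>   trees: 200, min leaf: 5, OOB R^2: 0.874

sp <- find_setpoints(fit, cusp_grid())   # 18081 candidate coordinates
nrow(sp)
#> [1] 1538

cls <- classify_setpoints(fit, sp, delta = 0.05)
count_by_class(cls)
#>   class            n
#> 1 attractor      568
#> 2 repeller         8
#> 3 transient      962
#> 4 cycle            0
#> 5 unclassified     0

mle <- fit_cusp_mle(sp)
c(linear = linear_r2(sp), cusp = cobb_r2(sp, mle))
#>    linear      cusp
#> 0.8220772 0.9016193
```

About 8.5% of the grid is flagged as set points; they trace the folded
cusp surface. The cusp-aware pseudo-R² (0.90) clearly exceeds the
planar fit (0.82) because the flagged points follow the fold, while both
statistics are ≈ 0 on the raw series — the recovered structure lives in
the set points, not in the raw data. `plot_setpoints(cls)` shows the
classified cloud in control-parameter slices; `plot_setpoints_3d()`
writes the 3-D view; for two-channel systems `quantile_sweep()` +
`plot_heatmap_vectors()` produce a support heat map with predicted-flow
arrows.

A command-line front end covering simulation, surrogate generation,
full analysis runs and the Monte Carlo lives at
`system.file("cli", "setpointr", package = "setpointr")`.

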