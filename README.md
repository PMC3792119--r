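# tvgrn — time-varying gene regulatory networks from expression time series

Gene regulatory networks rewire across physiological stages: the
interactions driving a fly embryo are not those maintaining the adult, and
a yeast network under drug stress is not the untreated one. Given a single
genes × time expression matrix, `tvgrn` answers two questions in order:
*when* does the active network change, and *what* is the network on each
stationary stretch?

The data model is a switching first-order vector autoregression

    x(t) = A_{r(t)} x(t-1) + w(t-1),    w ~ iid N(mu, Sigma_w),

whose coefficient matrix switches among A_1..A_K at unknown change points;
A_k[i, j] ≠ 0 means gene j regulates gene i during segment k.

**Step 1 — change-point detection.** Recursive least squares on the
stacked coefficients is algebraically a Kalman filter, and its whitened
innovations z(t) = L⁻¹ e(t) (L the Cholesky factor of the predicted
innovation covariance) are iid standard normal exactly while the data come
from one fixed network. The cumulative statistic Q = Σ zᵀz is then
chi-square with n·m degrees of freedom; the detector tests Q against the
(1−α) quantile at every step, records the first exceedance as a change
point, and restarts there. An intercept block in the regressor absorbs the
nonzero noise mean; Σ_w can be supplied or estimated first by
forgetting-factor RLS on the whole series.

**Step 2 — per-segment inference.** Each segment gets a static directed
network: either IOTA (inner composition alignment), the rank statistic
τ(l→k) = 1 − (#inversions of the target series after sorting by the
regulator)/(M(M−1)/2), suited to very short series; or a per-target-gene
lasso, 0.5·‖x_g(t+1) − aᵀx(t) − b‖² + λ‖a‖₁, solved by coordinate descent
with soft-thresholding (penalty fixed or chosen per segment by 5-fold CV).
Rankings are evaluated against DREAM-format gold standards by AUROC
(Mann–Whitney form) and AUPR (precision–recall step curve).

## Worked example

Simulate the built-in calibration benchmark — 10 genes, 60 samples, the
active sub-network (10 interactions) replaced at time instant 31 by
another (18 interactions), driving noise mean 2 and variance 0.5 — then
run the two-step pipeline with the true noise covariance:

```r
library(tvgrn)

bm  <- make_benchmark_two_regime(benchmark_spec(seed = 7))
cfg <- pipeline_config(
  detection = detection_config(alpha = 0.05, sigma_w = bm$model$noise_cov),
  inference_method = "iota", seed = 7)
res <- run_two_step(bm$series, cfg)

res$change_points$change_points
#> [1] 31

evaluate_against_gold(
  res, lapply(1:2, function(k) true_adjacency(bm$model, k))
)[, c("segment", "start", "end", "auroc", "aupr")]
#>  segment start end     auroc      aupr
#>        1     1  30 0.6632373 0.3711993
#>        2    31  60 0.4120000 0.1722967
```

The switch is detected on the exact change sample, so the series is split
into its two true regimes. The IOTA ranking recovers segment 1's edges
well above chance (AUROC 0.66); segment 2 of this draw ranks below chance
because most of its true interactions are repressive and the τ score
deliberately ranks anti-monotone pairs low — use
`inference_method = "lasso"` for signed inference in that situation. The
`q_trace` inside `res$change_points` holds the full (t, Q, dof, threshold)
trajectory for plotting.

Real data enter as TSV (`gene<TAB>t1..tT`) via `read_expression_table()`;
with unknown noise use `detection_config(sigma_w = "estimate")`, which
reproduces the estimate-then-detect ordering used for microarray
compendia. A thin command-line wrapper with `simulate`, `estimate-noise`,
`detect`, `infer`, `run` and `evaluate` subcommands is installed at
`system.file("cli", "tvgrn.R", package = "tvgrn")`.

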