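# varcross

Monte-Carlo machinery for a classic model-selection question in
intensive-longitudinal research (experience sampling, ecological momentary
assessment): given a short multivariate time series, when is the full
first-order vector autoregression worth its extra parameters, and when is
the per-variable autoregression the better bet?

Both models are special cases of

> x_t = Φ x_{t−1} + ε_t,  ε_t ~ N(0, diag(σ²₁, …, σ²_p)),

with the AR(1) constraining Φ to its diagonal. Against a true Φ with
cross-lagged (off-diagonal) effects, the AR fit is biased but low-variance
(p parameters), the VAR fit unbiased but high-variance (p² parameters).
`varcross` measures this trade-off directly by simulation:

* **populations** of stationary true models — a multilevel (mixed-VAR)
  generator with entry-wise random effects around fixed effects, stratified
  on the D–O plane (D = mean |diagonal|, O = mean |off-diagonal| of Φ) with
  population-probability weights;
* **error curves** — estimation error (mean squared deviation over all p²
  coefficients; AR structural zeros included) and one-step out-of-sample
  prediction error of both fits, over a grid of sample sizes n, averaged
  across replicate training series (prefix design, hierarchical seeding);
* **crossovers** — n_e and n_p, the first n at which the VAR's estimation /
  prediction error drops below the AR's, their gap n_gap = n_e − n_p, and
  weighted distribution summaries across a model collection;
* **selection rules** — minimum prediction error vs the one-standard-error
  rule (prefer AR unless its prediction error exceeds the VAR's by more
  than one SD across training sets), scored by estimation-error regret and
  compared through EE_comp.

Everything is tibble-in / tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods for fitted objects and reports, `autoplot()` /
`plot_*()` figures, and a one-call pipeline writing long-format CSV + JSON.

## A worked example

Where does the VAR overtake the AR for a 3-variable process with
autoregressive effects 0.3 and cross-lagged effects 0.08?

```r
library(varcross)

phi <- matrix(0.08, 3, 3)
diag(phi) <- 0.3
m <- var_model(phi)
characteristics(m)
#> # A tibble: 1 × 2
#>       D     O
#>   <dbl> <dbl>
#> 1   0.3  0.08

cfg <- experiment_config(n_grid = seq(8, 300, 4), reps = 30, n_test = 500,
                         burn_in = 100, master_seed = 7)
curves <- run_model_experiment(m, cfg)
crossing_summary(curves)
#> # A tibble: 1 × 7
#>   model_id   n_e   n_p n_gap n_e_censored n_p_censored n_gap_censored
#>      <int> <int> <int> <int> <lgl>        <lgl>        <lgl>
#> 1        1   148   132    16 FALSE        FALSE       FALSE
```

Read: averaged over 30 replicate series, the VAR's prediction error drops
below the AR's from n = 132 onwards, but its estimation error only from
n = 148 — below that the AR's bias is cheaper than the VAR's variance. The
positive gap (16) is the window in which prediction error already favours
the VAR while estimation error still favours the AR, which is exactly where
an AR-leaning selection rule pays off. `plot_error_curves(curves)` draws
the four curves.

Population-level studies run through the pipeline:

```r
out <- run_pipeline(default_config(master_seed = 1), out_dir = "run1")
```

which samples ~150 stratified models from the default 6-variable
population, computes their error curves, crossover summaries and the
rule comparison, and writes CSV/JSON outputs plus a run manifest
(`sample-models`, `run-curves`, `crossings`, `compare-rules`, `report`
stages; each re-runnable via `stage =`).

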