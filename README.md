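# strfkit

Sparse spectro-temporal receptive field (STRF) estimation for auditory
neuroscience: penalized Poisson and log-Gaussian encoding models fitted
by proximal gradient, with group sparsity, permutation-based selection
of the regularization weight, and nested-model tests for the
contribution of spike history.

## Who this is for

Electrophysiologists and computational neuroscientists characterizing
frequency–time tuning from responses to random gammatone chord stimuli —
binned spike counts from sorted units, or log high-gamma (70–150 Hz)
band power extracted from local field potentials. The package also
contains a complete stimulus generator (ERB-scaled cochleotopic map,
gammatone kernels, Bernoulli chord schedules, rendered audio) and a
forward encoding simulator, so the entire pipeline runs and is tested
without any external recordings.

## The model

Responses on a common bin grid (default 50 ms) are linked to the binary
stimulus-state matrix `x_f(t)` through a generalized linear model with
an STRF grid `β_f(τ)` (default 50 channels × 40 lags = 2 s) and spike
history weights `α_h`:

    λ(t | H_t) = exp{ β₀ + Σ_f Σ_τ β_f(τ) x_f(t−τ) + Σ_{h=1..H} α_h r(t−h) }

for Poisson spike counts, and the same linear predictor with Gaussian
errors (history from `h = 0`) for log high-gamma power. Estimation
minimizes the penalized negative log-likelihood

    −ℓ(β) + λ‖β‖₁        (lasso)   or   −ℓ(β) + λ Σ_g ‖β_g‖₂   (group lasso)

by ISTA/FISTA with backtracking; groups are non-overlapping 4 × 4
frequency–time patches (130 groups on the default grid) plus one group
for the history block. The penalty weight λ* is the median of the
smallest all-zeroing weight λ_max over 200 random permutations of the
response — the weight at which a chance-only STRF would vanish
entirely. Spike-history contributions are tested by deviance (χ²) or F
statistics on companion unpenalized fits, with Benjamini–Hochberg FDR
adjustment across sites.

## Worked example

Simulate five minutes of the default experiment and recover the ground
truth STRF:

```r
library(strfkit)
map    <- make_cochleotopic_map()          # 50 channels, 100-12207 Hz
lags   <- lag_grid()                       # 40 lags x 50 ms = 2 s
sched  <- draw_chord_schedule(seed = 1)    # 6000 bins, p = 0.02
truth  <- make_bump_strf(map, lags)        # bump at 1 kHz, 150 ms
counts <- simulate_counts(truth, sched, seed = 2)

design <- build_design(sched, lags)
groups <- build_group_map(50, 40)
null   <- permutation_lambda_null(design, counts, "poisson", "group",
                                  groups, n_reps = 200, seed = 3)
fit    <- fit_penalized_glm(design, counts, "poisson",
                            penalty_spec("group", null$selected_lambda,
                                         groups))
fit
#> <strf_fit> poisson family, group penalty (lambda = 44.21)
#>   df = 33  deviance = 4799.92  iterations = 61 (converged)

cosine_similarity(fit$coefficients$beta, truth$beta)
#> [1] 0.9723114
cosine_similarity(sta(sched, counts, lags), truth$beta)   # STA baseline
#> [1] 0.2119009

extract_features(fit, map, lags)
#> # A tibble: 1 x 6
#>   component best_frequency_hz bandwidth_octaves peak_latency_s peak_value ...
#> 1         1              987.             0.258            0.1       1.69
```

Out of 2000 STRF cells the selected fit keeps 32 (df = 33 including the
intercept), all in patches around the true bump: the group-sparse fit
recovers the truth with cosine similarity 0.97 where the spike-triggered
average reaches 0.21 on the same data. The features table reads the
tuning off the fitted grid: best frequency ≈ 987 Hz (truth: 1 kHz, one
channel resolution), peak latency 0.10 s, bandwidth 0.26 octaves.
`autoplot(fit, map = map)` draws the fitted STRF;
`autoplot(null)` shows the permutation histogram with the selected λ.

A command-line interface over the same functions is installed as
`exec/strftools` (subcommands `stimgen`, `simulate`, `fit`,
`select-lambda`, `history-test`, `features`, `extract-hg`).

## Layout

| Path | Contents |
|---|---|
| `R/stimulus.R` | ERB map, gammatone kernels, chord schedules, audio |
| `R/design.R` | lagged design matrix, group map |
| `R/simulate.R` | forward encoding simulator, bump ground truth |
| `R/signals.R` | high-gamma extraction, spike binning, transient repair |
| `R/estimate.R` | STA, proximal solver, deviance, prediction |
| `R/selection.R` | λ_max, permutation selection, nested tests, FDR |
| `R/features.R` | best frequency, bandwidth, latency |
| `vignettes/` | methods vignette (model, defaults, limitations) |
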