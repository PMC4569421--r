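---
title: "Sparse spectro-temporal receptive field estimation with strfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse spectro-temporal receptive field estimation with strfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strfkit)
```

## The estimation problem

A spectro-temporal receptive field (STRF) describes how a neuron's (or a
neural population signal's) response depends on recent acoustic energy at
each frequency: a coefficient grid $\beta_f(\tau)$ over frequency channels
$f$ and time lags $\tau$. strfkit estimates STRFs from responses to a
*random gammatone chord* stimulus: on a grid of 50 ms bins, each of $F$
frequency channels independently turns on a gammatone blip with
probability $p$ per bin (a Bernoulli process), giving a binary
stimulus-state matrix $x_f(t)$. With the defaults ($F = 50$, $p = 0.02$,
50 ms bins) the expected aggregate blip rate is $50 \times 0.02 / 0.05 =
20$ blips/s, and five minutes of stimulation is 6000 bins.

Channels are spaced uniformly on the human cochlea. The equivalent
rectangular bandwidth (ERB) at center frequency $F_c$ is
$\mathrm{ERB} = ((F_c/Q_{ear})^n + bw_{min}^n)^{1/n}$ with
$Q_{ear} = 9.26447$, $bw_{min} = 24.7$ Hz and order $n = 1$, and the
center frequencies follow the exponential-with-offset cochleotopic
spacing implemented in `make_cochleotopic_map()`; the identities
$F_c(0) = F_{high}$ and $F_c(N) = F_{low}$ hold algebraically and are
asserted in the tests. Gammatone kernels are
$g(t) = a\,t^{n-1}\cos(2\pi F_c t + \varphi)\,e^{-2\pi\,bw\,t}$ with
$bw = 1.019\,\mathrm{ERB}$. We use the decaying-exponential envelope:
the growing-exponential variant that sometimes appears in print diverges
and cannot be a filter impulse response.

## Encoding models

Two generalized linear models link the stimulus to the response. For
binned spike counts $r(t)$, an inhomogeneous Poisson process with a
log link and spike-history feedback:

$$\lambda(t \mid H_t) = \exp\Big\{\beta_0 + \sum_{f=1}^{F}
\sum_{\tau=0}^{T-1} \beta_f(\tau)\, x_f(t-\tau) +
\sum_{h=1}^{H} \alpha_h\, r(t-h)\Big\},$$

where $\lambda$ is the expected count per bin. For the log high-gamma
band power of the local field potential, the same linear predictor with
a Gaussian error model, and with the history sum starting at $h = 0$ so
the same-bin spike count is conditioned on. The history block serves two
purposes: it absorbs intrinsic dynamics (refractoriness,
self-excitation, spike-power coupling) that would otherwise leak into
the STRF, and its contribution can be tested formally (below).

Defaults: $T = 40$ lags of 50 ms (a 2 s impulse response) and $H = 15$
history covariates. One common bin grid (default 50 ms) is used for
stimulus, lags and response; mixing finer spike bins with coarser
stimulus bins is supported by rebinning the response, not by a
heterogeneous design. Rows with $t - \tau < 1$ are zero-padded rather
than dropped, so the design always has one row per bin.

## Sparse fitting

With $1 + F\,T + H$ coefficients (2016 at the defaults) and a few
thousand bins, unregularized maximum likelihood overfits badly. The
package fits

$$\hat\beta_\lambda = \arg\min_\beta\; -\ell(\beta) +
\lambda P(\beta),$$

with $P$ either the elementwise L1 norm (lasso) or the grouped L1/L2
norm $\sum_g \lVert \beta_g \rVert_2$ (group lasso). Groups tile the
$F \times T$ grid with non-overlapping 4 × 4 patches — 130 groups for
the 50 × 40 default — plus one extra group holding all history
covariates. The group norm removes or retains whole patches, which
suits receptive fields that are localized regions in frequency–time
rather than scattered single cells; the intercept is never penalized.

The solver is proximal gradient (ISTA) with backtracking line search,
with FISTA acceleration on by default. Because any convergent proximal
scheme reaches the same minimizer of this convex objective, correctness
is asserted at the solution (KKT conditions, agreement with an IRLS
oracle at $\lambda = 0$) rather than on iteration trajectories. FISTA
momentum is restarted whenever a step would increase the objective, so
the recorded objective trace is non-increasing in both modes.
Convergence is declared at a relative objective change below $10^{-8}$
(cap 5000 iterations); these values are the package's own choice.
Columns are not standardized: the stimulus regressors are binary and
share a common scale, and coefficients are reported on that scale. The
design matrix is stored sparse (about 2% density at the default
stimulus statistics), which keeps the default problem comfortably in
memory and each gradient step cheap.

## Choosing the penalty weight by permutation

Rather than cross-validation or information criteria (aimed at
prediction), the penalty weight is chosen by a discovery criterion: how
strong must the penalty be to delete *everything* when there is nothing
to find? The response is randomly permuted (destroying the
stimulus–response association while preserving the count distribution),
and the smallest all-zeroing weight $\lambda_{max}$ of the permuted
problem is recorded; over 200 permutations these values form a null
distribution, and its median is the selected $\lambda^{*}$.
$\lambda_{max}$ has a closed form from the KKT conditions at the
intercept-only fit — the largest absolute gradient entry (L1) or group
gradient norm (grouped) — so the 200 permutations cost almost nothing;
the tests verify the closed form against an explicit 31-point
regularization-path search. For an even number of permutations the
median is the mean of the central pair.

## Testing the spike-history contribution

Whether history matters is decided by classical nested-model tests: the
deviance difference $\Delta D$ between fits with and without the
history block, referred to $\chi^2(H)$ for the Poisson model, and an F
statistic $F(H,\, n - p_{full})$ for the Gaussian model, with
Benjamini–Hochberg adjustment across recording sites. These null
distributions assume unshrunk maximum-likelihood estimates, so the
tests are computed on companion unpenalized fits (`fit_glm_ml()`, IRLS
/ least squares) rather than on the penalized fits used for STRF
display. This is a deliberate design choice: under L1/L2 shrinkage the
classical reference distributions do not hold.

## High-gamma extraction and spike binning

`extract_high_gamma()` resamples the raw trace to 400 Hz, applies a
zero-phase FIR bandpass over 70–150 Hz (windowed-sinc Hamming design,
129 taps, forward and reverse), takes the squared magnitude of the
Hilbert analytic signal, low-passes and decimates to 40 Hz, and
log-transforms. The anti-alias low-pass before decimation is required
because the power envelope's bandwidth exceeds the 20 Hz output
Nyquist. The log is floored at $10^{-12}$ times the median power so
silence does not produce $-\infty$. The filter order and the log floor
are package choices. Adaptive line-noise removal is out of scope; large
amplitude transients can be repaired with `remove_transients()`
(iterative z-score marking at $|z| > 10$, interpolation, Hamming
smoothing). Spike times are binned into half-open intervals
(`bin_spikes()`), a spike on a bin edge belonging to the later bin.

## What the simulator emulates — and what it does not

`simulate_counts()` and `simulate_log_gamma()` generate responses from
the two encoding models with known ground truth, strictly causally (the
history terms use already-generated counts). The default ground truth
(`make_bump_strf()`) is a two-dimensional Gaussian excitatory bump
(amplitude 2, sd 1.5 channels × 1 bin, centered at 1 kHz and 150 ms)
with a preceding suppressive side-lobe (−0.8), on a baseline of
$\beta_0 = \log 0.2$ (≈ 4 spikes/s at 50 ms bins) — chosen once as
representative of auditory cortex receptive-field morphology and firing
rates. A linear predictor above 10 raises an error: with a log link,
positive history weights make the process self-exciting, and the cap
distinguishes a diverging parameterization from a slow simulation.

The simulator realizes exactly the model class the estimator assumes.
Passing recovery tests therefore demonstrates the correctness of the
estimation machinery — not that real cortical responses follow a
log-linear Poisson model with binary-stimulus covariates. Real
recordings add model misspecification, non-stationarity, correlated
noise and spike-sorting errors that no test here exercises. The
Gaussian noise on the log high-gamma series is likewise a modeling
choice; only the conditional mean structure of that signal is specified
by the encoding model.

## Problem sizes used in the tests

The test suite verifies solver correctness (IRLS agreement, KKT
residuals below $10^{-4}$, monotone objectives, monotone df paths) on
instances of a few hundred bins; STRF recovery at the full default
conditions (50 × 40 grid, 6000 bins, 10 seeds), where the group lasso
at $\lambda^{*}$ attains cosine similarity above 0.9 with the truth
versus roughly 0.2 for the spike-triggered average; null calibration of
the $\chi^2$ history test over 500 reduced-size simulations (10 × 10
grid, 1000 bins); and held-out prediction on 10 replicates of a 20 × 15
problem, where the regularized fit beats the unregularized one in all
replicates. These sizes are the package's choices for a thorough but
quick default run; all are configurable.

## Numerical conventions and edge cases

* Poisson negative log-likelihood omits the $\log r!$ constant; the
  deviance restores comparability through the saturated model.
* Degrees of freedom = number of nonzero coefficients (+1 for the
  intercept); the group prox zeroes a group exactly when its norm falls
  below the threshold, so df is well-defined without a tolerance.
* `lambda_max` of a zero-variance response is 0.
* Bandwidth of a single-channel excitatory run is reported at
  one-channel resolution (octave span between geometric midpoints to
  the neighbouring channels) and flagged `single_channel = TRUE`.
  Multiple disjoint excitatory components can be reported separately
  (`all_components = TRUE`), ranked by peak value; the half-height
  fraction (default 0.5) is configurable.
* Ties in the connected-component peak are broken by column-major
  order; positive rescaling of the grid leaves all features unchanged.
* Audio blips are noise-excited kernels seeded per blip index, so a
  rendered stimulus is reproducible and exactly linear in its blips.

## A worked example

```{r example, eval = FALSE}
map  <- make_cochleotopic_map()          # 50 channels, 100-12207 Hz
lags <- lag_grid()                       # 40 lags x 50 ms
sched <- draw_chord_schedule(seed = 1)   # 6000 bins at p = 0.02
truth <- make_bump_strf(map, lags)
counts <- simulate_counts(truth, sched, seed = 2)

design <- build_design(sched, lags)
groups <- build_group_map(50, 40)
null  <- permutation_lambda_null(design, counts, "poisson", "group",
                                 groups, n_reps = 200, seed = 3)
fit   <- fit_penalized_glm(design, counts, "poisson",
                           penalty_spec("group", null$selected_lambda,
                                        groups))
glance(fit)
cosine_similarity(fit$coefficients$beta, truth$beta)
extract_features(fit, map, lags)
autoplot(fit, map = map)
```

## Known limitations

* Groups are non-overlapping, so group-sparse STRFs can look truncated
  at patch boundaries; overlapping groups are not implemented.
* The nested history tests are asymptotic; at very low counts and small
  $n$ the $\chi^2$ approximation degrades (the calibration test runs at
  1000 bins, where it holds).
* The permutation selection assumes exchangeability of the response
  bins under the null; strong slow non-stationarity would violate it.
* No spike sorting, line-noise removal, or anatomical mapping: the
  package consumes spike times and field-potential traces produced
  elsewhere.
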