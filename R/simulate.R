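#' STRF coefficient container
#'
#' Holds the ground-truth or estimated parameters of an encoding model:
#' intercept `beta0` (log rate per bin for the Poisson family, mean log
#' power for the log-Gaussian family), the `F x T` STRF grid `beta`
#' (frequency ascending by row, lag ascending by column), and the
#' spike-history weights `alpha` with their declared lag range.
#'
#' @param beta0 intercept.
#' @param beta `F x T` numeric matrix.
#' @param alpha numeric history weights (possibly length 0).
#' @param family `"poisson"` or `"log_gaussian"`.
#' @param history_lags integer lags the `alpha` entries refer to
#'   (`1..H`, or `0..H-1` when the same-bin count is included).
#' @return A list of class `strf_coefficients`.
#' @export
strf_coefficients <- function(beta0, beta, alpha = numeric(0),
                              family = c("poisson", "log_gaussian"),
                              history_lags = seq_len(length(alpha))) {
  family <- match.arg(family)
  stopifnot(is.matrix(beta), length(alpha) == length(history_lags))
  structure(list(beta0 = beta0, beta = beta, alpha = as.numeric(alpha),
                 family = family,
                 history_lags = as.integer(history_lags)),
            class = "strf_coefficients")
}

#' Gaussian-bump ground-truth STRF
#'
#' Builds a smooth localized STRF for simulation studies: a positive
#' two-dimensional Gaussian bump centered at (`center_freq_hz`,
#' `center_lag_s`), optionally preceded (earlier lag) by a negative
#' side-lobe, emulating the suppression-then-excitation morphology seen in
#' auditory cortex receptive fields. Values below 1% of the amplitude are
#' zeroed so the truth is itself sparse.
#'
#' @param map a [make_cochleotopic_map()] result.
#' @param lags a [lag_grid()] result.
#' @param center_freq_hz bump center frequency (must lie inside the map
#'   range).
#' @param center_lag_s bump center lag in seconds (inside the lag span).
#' @param width_channels Gaussian sd along frequency, in channels.
#' @param width_bins Gaussian sd along lag, in bins.
#' @param amplitude peak height of the excitatory bump.
#' @param suppression_amplitude peak of the suppressive side-lobe
#'   (<= 0; 0 disables it). The side-lobe is centered
#'   `2 * width_bins` earlier in lag at the same frequency.
#' @param beta0 intercept (log expected count per bin).
#' @param alpha,history_lags optional history weights.
#' @param family model family for downstream simulation.
#' @return An [strf_coefficients()] object.
#' @export
make_bump_strf <- function(map, lags, center_freq_hz = 1000,
                           center_lag_s = 0.15, width_channels = 1.5,
                           width_bins = 1, amplitude = 2,
                           suppression_amplitude = -0.8,
                           beta0 = log(0.2), alpha = numeric(0),
                           history_lags = seq_len(length(alpha)),
                           family = "poisson") {
  freqs <- channel_freqs(map)
  if (center_freq_hz < min(freqs) || center_freq_hz > max(freqs))
    rlang::abort("bump center frequency outside the map range")
  if (center_lag_s < 0 || center_lag_s > lags$span_s)
    rlang::abort("bump center lag outside the lag span")
  if (suppression_amplitude > 0)
    rlang::abort("suppression_amplitude must be <= 0")
  n_f <- length(freqs); n_t <- lags$n_lags
  f0 <- which.min(abs(freqs - center_freq_hz))
  t0 <- min(n_t, floor(center_lag_s / lags$lag_step_s) + 1)
  fi <- matrix(seq_len(n_f), n_f, n_t)
  ti <- matrix(seq_len(n_t), n_f, n_t, byrow = TRUE)
  bump <- amplitude *
    exp(-((fi - f0)^2 / (2 * width_channels^2) +
          (ti - t0)^2 / (2 * width_bins^2)))
  if (suppression_amplitude < 0) {
    ts <- t0 - round(2 * width_bins)
    if (ts >= 1)
      bump <- bump + suppression_amplitude *
        exp(-((fi - f0)^2 / (2 * width_channels^2) +
              (ti - ts)^2 / (2 * width_bins^2)))
  }
  bump[abs(bump) < 0.01 * abs(amplitude)] <- 0
  strf_coefficients(beta0, bump, alpha, family, history_lags)
}

# shared stimulus drive: s(t) = sum_f sum_tau beta[f,tau+1] x_f(t-tau)
.stim_drive <- function(beta, schedule) {
  n_bins <- ncol(schedule)
  n_t <- ncol(beta)
  drive <- numeric(n_bins)
  on <- which(schedule == 1L, arr.ind = TRUE)
  if (nrow(on) > 0) for (i in seq_len(nrow(on))) {
    f <- on[i, 1]; t0 <- on[i, 2]
    idx <- t0:min(n_bins, t0 + n_t - 1)
    drive[idx] <- drive[idx] + beta[f, seq_along(idx)]
  }
  drive
}

#' Simulate spike counts from the Poisson encoding model
#'
#' Sequentially generates per-bin counts from the conditional intensity
#' `lambda(t) = exp(beta0 + sum_f sum_tau beta_f(tau) x_f(t - tau) +
#' sum_h alpha_h r(t - h))`, where the history terms use the counts
#' already generated (strictly causal). Rates are per bin; a linear
#' predictor above `cap` signals a self-exciting blow-up and raises an
#' error.
#'
#' @param truth an [strf_coefficients()] with `family = "poisson"`;
#'   `beta` row count must match the schedule.
#' @param schedule a [draw_chord_schedule()] result.
#' @param seed integer RNG seed.
#' @param cap maximum allowed linear predictor (default 10).
#' @return A [response_series()] of counts, length `n_bins`.
#' @export
simulate_counts <- function(truth, schedule, seed = 1L, cap = 10) {
  if (truth$family != "poisson")
    rlang::abort("simulate_counts needs a poisson-family truth")
  if (nrow(truth$beta) != nrow(schedule))
    rlang::abort("beta rows must match schedule channels")
  n_bins <- ncol(schedule)
  drive <- truth$beta0 + .stim_drive(truth$beta, schedule)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- truth$alpha; hl <- truth$history_lags
  if (length(a) > 0 && any(hl < 1))
    rlang::abort("poisson history lags must start at h = 1")
  r <- numeric(n_bins)
  if (length(a) == 0) {
    if (any(drive > cap)) rlang::abort("linear predictor exceeds cap")
    r <- stats::rpois(n_bins, exp(drive))
  } else {
    for (t in seq_len(n_bins)) {
      eta <- drive[t]
      for (k in seq_along(a)) {
        h <- hl[k]
        if (t - h >= 1) eta <- eta + a[k] * r[t - h]
      }
      if (eta > cap)
        rlang::abort("linear predictor exceeds cap: unstable history weights")
      r[t] <- stats::rpois(1, exp(eta))
    }
  }
  response_series(r, attr(schedule, "bin_width_s"), "counts")
}

#' Simulate log high-gamma power from the log-Gaussian encoding model
#'
#' `log_gamma(t) = beta0 + sum_f sum_tau beta_f(tau) x_f(t - tau) +
#' sum_h alpha_h r(t - h) + N(0, noise_sigma^2)`, with i.i.d. Gaussian
#' noise. When `alpha` includes a lag-0 term the same-bin count is used.
#'
#' @param truth an [strf_coefficients()] with `family = "log_gaussian"`.
#' @param schedule a [draw_chord_schedule()] result.
#' @param counts a [response_series()] of simultaneously recorded spike
#'   counts; required when `alpha` is non-empty.
#' @param noise_sigma Gaussian noise sd (>= 0).
#' @param seed integer RNG seed.
#' @return A [response_series()] with `kind = "log_power"`.
#' @export
simulate_log_gamma <- function(truth, schedule, counts = NULL,
                               noise_sigma = 0.5, seed = 1L) {
  if (truth$family != "log_gaussian")
    rlang::abort("simulate_log_gamma needs a log_gaussian-family truth")
  if (noise_sigma < 0) rlang::abort("noise_sigma must be >= 0")
  n_bins <- ncol(schedule)
  eta <- truth$beta0 + .stim_drive(truth$beta, schedule)
  if (length(truth$alpha) > 0) {
    if (is.null(counts)) rlang::abort("nonzero alpha requires counts")
    r <- as.numeric(counts)
    for (k in seq_along(truth$alpha)) {
      h <- truth$history_lags[k]
      shifted <- c(rep(0, h), r)[seq_len(n_bins)]
      eta <- eta + truth$alpha[k] * shifted
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- eta + stats::rnorm(n_bins, 0, noise_sigma)
  response_series(y, attr(schedule, "bin_width_s"), "log_power")
}

#' Simulate a full synthetic recording
#'
#' Convenience wrapper bundling a schedule, a Poisson spike-count series
#' and a log high-gamma series generated from the same ground truth, for
#' end-to-end pipeline tests. The log-Gaussian series reuses the Poisson
#' truth's STRF and couples to the simulated counts through
#' `gamma_alpha` (range `h = 0..`).
#'
#' @param truth a poisson-family [strf_coefficients()].
#' @param schedule a [draw_chord_schedule()] result.
#' @param gamma_alpha history weights tying log power to the counts
#'   (lag 0 first); default a weak same-bin coupling.
#' @param noise_sigma log-power noise sd.
#' @param seed integer seed (counts use `seed`, noise `seed + 1`).
#' @return A list of class `simulated_recording` with `schedule`,
#'   `counts`, `log_gamma`, `truth`, `seed`.
#' @export
simulate_recording <- function(truth, schedule, gamma_alpha = c(0.5, 0.25),
                               noise_sigma = 0.5, seed = 1L) {
  counts <- simulate_counts(truth, schedule, seed = seed)
  gtruth <- strf_coefficients(truth$beta0, truth$beta, gamma_alpha,
                              family = "log_gaussian",
                              history_lags = seq_along(gamma_alpha) - 1L)
  lg <- simulate_log_gamma(gtruth, schedule, counts,
                           noise_sigma = noise_sigma, seed = seed + 1L)
  structure(list(schedule = schedule, counts = counts, log_gamma = lg,
                 truth = truth, seed = as.integer(seed)),
            class = "simulated_recording")
}
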