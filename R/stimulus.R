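#' ERB parameter set for human auditory filters
#'
#' Bundles the constants of the equivalent-rectangular-bandwidth (ERB)
#' approximation to human cochlear filter bandwidths: the ear quality
#' factor, the minimum bandwidth, the filter order, and the multiplicative
#' scaling applied to the ERB to obtain the gammatone bandwidth. Defaults
#' follow the Glasberg & Moore recommendations (`q_ear = 9.26447`,
#' `bw_min = 24.7` Hz) with first-order filters and a 1.019 ERB multiplier.
#'
#' @param q_ear dimensionless quality factor (> 0).
#' @param bw_min minimum bandwidth in Hz (> 0).
#' @param order_n integer filter order (>= 1).
#' @param bw_scale dimensionless multiplier applied to the ERB (> 0).
#' @return A list of class `erb_params`.
#' @export
#' @examples
#' erb_params()
erb_params <- function(q_ear = 9.26447, bw_min = 24.7, order_n = 1L,
                       bw_scale = 1.019) {
  stopifnot(q_ear > 0, bw_min > 0, order_n >= 1, bw_scale > 0)
  structure(list(q_ear = q_ear, bw_min = bw_min,
                 order_n = as.integer(order_n), bw_scale = bw_scale),
            class = "erb_params")
}

#' Equivalent rectangular bandwidth at a center frequency
#'
#' Computes `ERB(fc) = ((fc / q_ear)^n + bw_min^n)^(1/n)`, the perceptual
#' bandwidth of the human auditory filter centered at `fc`. Strictly
#' increasing in `fc` for any order `n >= 1`.
#'
#' @param fc_hz center frequency in Hz (vectorized, >= 0).
#' @param params an [erb_params()] object.
#' @return ERB in Hz, same length as `fc_hz`.
#' @export
#' @examples
#' compute_erb(0)     # reduces to bw_min
#' compute_erb(1000)  # 1000/9.26447 + 24.7 at first order
compute_erb <- function(fc_hz, params = erb_params()) {
  if (any(fc_hz < 0)) rlang::abort("center frequency must be non-negative")
  n <- params$order_n
  ((fc_hz / params$q_ear)^n + params$bw_min^n)^(1 / n)
}

#' ERB-scaled cochleotopic map of gammatone center frequencies
#'
#' Places `n_channels` center frequencies between `f_low_hz` and
#' `f_high_hz` so that they tile the human cochlea uniformly:
#' `Fc(i) = -Q b + (F_high + Q b) * exp(i * (log(F_low + Q b) -
#' log(F_high + Q b)) / N)` with `Q = q_ear`, `b = bw_min`, `i = 1..N`.
#' The spacing is exponential with an additive ERB offset; frequencies are
#' strictly decreasing in the index, with `Fc(N) = f_low_hz` exactly and
#' the (hypothetical) index 0 equal to `f_high_hz`.
#'
#' @param n_channels number of filterbank channels (>= 1); default 50.
#' @param f_low_hz lowest center frequency, Hz.
#' @param f_high_hz highest frequency of the bank (its upper edge), Hz.
#' @param params an [erb_params()] object.
#' @return A tibble of class `cochleotopic_map` with columns `index`
#'   (1..N, descending frequency), `center_freq_hz`, `erb_hz`, and `bw_hz`
#'   (`bw_scale * erb_hz`), plus the generating parameters as attributes.
#' @export
#' @examples
#' m <- make_cochleotopic_map()
#' head(m)
make_cochleotopic_map <- function(n_channels = 50L, f_low_hz = 100,
                                  f_high_hz = 12207,
                                  params = erb_params()) {
  if (f_low_hz <= 0 || f_low_hz >= f_high_hz)
    rlang::abort("need 0 < f_low_hz < f_high_hz")
  stopifnot(n_channels >= 1)
  qb <- params$q_ear * params$bw_min
  idx <- seq_len(n_channels)
  fc <- -qb + (f_high_hz + qb) *
    exp(idx * (log(f_low_hz + qb) - log(f_high_hz + qb)) / n_channels)
  erb <- compute_erb(fc, params)
  out <- tibble::tibble(index = idx, center_freq_hz = fc, erb_hz = erb,
                        bw_hz = params$bw_scale * erb)
  attr(out, "f_low_hz") <- f_low_hz
  attr(out, "f_high_hz") <- f_high_hz
  attr(out, "erb_params") <- params
  class(out) <- c("cochleotopic_map", class(out))
  out
}

#' Center frequencies of a map in ascending order
#'
#' The map itself is indexed from high to low frequency (apex-to-base
#' cochlear convention); STRF grids in this package store frequency
#' ascending (row 1 = lowest center frequency). This adapter makes the
#' mapping explicit.
#'
#' @param map a [make_cochleotopic_map()] result.
#' @return Numeric vector of center frequencies, lowest first.
#' @export
channel_freqs <- function(map) {
  sort(map$center_freq_hz)
}

#' Gammatone kernel
#'
#' Samples the gammatone impulse response
#' `g(t) = a * t^(n-1) * cos(2 pi fc t + phi) * exp(-2 pi bw t)` at
#' `sample_rate_hz` for `duration_s` seconds. The decaying-exponential
#' convention is used: the envelope has time constant `1 / (2 pi bw)`.
#' The bandwidth is taken from the map (`bw_scale * ERB` at `fc_hz`).
#'
#' @param fc_hz center frequency, Hz; must be below the Nyquist rate.
#' @param map a [make_cochleotopic_map()] result supplying the ERB
#'   parameters (order, bandwidth scaling).
#' @param sample_rate_hz audio sampling rate, Hz.
#' @param duration_s kernel length, seconds.
#' @param phase_rad carrier phase, radians.
#' @param gain amplitude scale `a`.
#' @return A list of class `gammatone_kernel` with fields `waveform`,
#'   `fc_hz`, `bw_hz`, `order_n`, `phase_rad`, `gain`, `sample_rate_hz`,
#'   `duration_s`.
#' @export
#' @examples
#' k <- make_gammatone_kernel(1000, make_cochleotopic_map(),
#'                            sample_rate_hz = 24414, duration_s = 0.05)
#' plot(k$waveform, type = "l")
make_gammatone_kernel <- function(fc_hz, map, sample_rate_hz,
                                  duration_s = 0.05, phase_rad = 0,
                                  gain = 1) {
  if (fc_hz >= sample_rate_hz / 2)
    rlang::abort("center frequency must be below Nyquist")
  stopifnot(duration_s > 0)
  params <- attr(map, "erb_params")
  n <- params$order_n
  bw <- params$bw_scale * compute_erb(fc_hz, params)
  len <- round(duration_s * sample_rate_hz)
  t <- seq(0, length.out = len, by = 1 / sample_rate_hz)
  env <- if (n == 1) rep(1, len) else t^(n - 1)  # t^0 := 1 at t = 0
  w <- gain * env * cos(2 * pi * fc_hz * t + phase_rad) *
    exp(-2 * pi * bw * t)
  structure(list(waveform = w, fc_hz = fc_hz, bw_hz = bw, order_n = n,
                 phase_rad = phase_rad, gain = gain,
                 sample_rate_hz = sample_rate_hz, duration_s = duration_s),
            class = "gammatone_kernel")
}

#' Bernoulli random-chord onset schedule
#'
#' Draws the binary stimulus-state matrix `x_f(t)`: independently for each
#' channel and each time bin, a gammatone blip onset occurs with
#' probability `p_onset`. With the defaults (50 channels, p = 0.02, 50 ms
#' bins) the expected aggregate onset rate is 20 blips per second.
#'
#' @param n_channels number of frequency channels; rows of the grid,
#'   ordered low to high center frequency.
#' @param n_bins number of time bins.
#' @param p_onset per-channel per-bin onset probability in \[0, 1\].
#' @param bin_width_s bin width in seconds (default 0.05).
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#' @return An integer 0/1 matrix of class `chord_schedule`
#'   (`n_channels x n_bins`) with attributes `bin_width_s`, `p_onset`,
#'   `seed`.
#' @export
#' @examples
#' s <- draw_chord_schedule(50, 6000, seed = 1)
#' mean(s) # close to 0.02
draw_chord_schedule <- function(n_channels = 50L, n_bins = 6000L,
                                p_onset = 0.02, bin_width_s = 0.05,
                                seed = 1L) {
  stopifnot(p_onset >= 0, p_onset <= 1, n_bins >= 1, n_channels >= 1,
            bin_width_s > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- matrix(stats::rbinom(n_channels * n_bins, 1L, p_onset),
              nrow = n_channels, ncol = n_bins)
  structure(x, bin_width_s = bin_width_s, p_onset = p_onset,
            seed = as.integer(seed),
            class = c("chord_schedule", "matrix", "array"))
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Schedule as a tidy event list
#'
#' @param schedule a [draw_chord_schedule()] result.
#' @param map optional [make_cochleotopic_map()] result used to attach
#'   center frequencies (matched to schedule rows in ascending order).
#' @return A tibble with one row per onset: `onset_time_s`,
#'   `channel_index` (1-based, low-to-high frequency), and
#'   `center_freq_hz` (NA when no map is given).
#' @export
schedule_events <- function(schedule, map = NULL) {
  on <- which(schedule == 1L, arr.ind = TRUE)
  bw <- attr(schedule, "bin_width_s")
  fr <- if (is.null(map)) rep(NA_real_, nrow(schedule)) else channel_freqs(map)
  out <- tibble::tibble(onset_time_s = (on[, 2] - 1) * bw,
                        channel_index = as.integer(on[, 1]),
                        center_freq_hz = fr[on[, 1]])
  dplyr::arrange(out, .data$onset_time_s, .data$channel_index)
}

#' Render the acoustic stimulus for a chord schedule
#'
#' For every onset in the schedule a Gaussian-noise-excited gammatone blip
#' (unit-variance white noise convolved with that channel's kernel, scaled
#' by `gain`) is added to the waveform at the onset sample; channels are
#' summed. Blips that would run past the end of the schedule are
#' truncated; the audio length is exactly `n_bins * bin_width_s` seconds.
#' Each blip's noise is seeded from `noise_seed` plus the blip's index in
#' time-then-channel order, so renders are reproducible.
#'
#' @param schedule a [draw_chord_schedule()] result; its row count must
#'   match the map's channel count.
#' @param map a [make_cochleotopic_map()] result.
#' @param sample_rate_hz audio sampling rate; must be at least twice the
#'   highest center frequency.
#' @param noise_seed integer seed for the per-blip excitation noise.
#' @param blip_duration_s gammatone kernel length per blip, seconds.
#' @param gain per-blip amplitude scale.
#' @return A list of class `audio_stimulus` with fields `samples`,
#'   `sample_rate_hz`, `noise_seed`, `gain`.
#' @export
render_audio <- function(schedule, map, sample_rate_hz = 24414,
                         noise_seed = 1L, blip_duration_s = 0.05,
                         gain = 1) {
  if (nrow(schedule) != nrow(map))
    rlang::abort("schedule channel count must match map channel count")
  freqs <- channel_freqs(map)
  if (sample_rate_hz < 2 * max(freqs))
    rlang::abort("sample rate below 2x the highest center frequency")
  bw <- attr(schedule, "bin_width_s")
  n_bins <- ncol(schedule)
  n_samp <- round(n_bins * bw * sample_rate_hz)
  kernels <- lapply(freqs, make_gammatone_kernel, map = map,
                    sample_rate_hz = sample_rate_hz,
                    duration_s = blip_duration_s)
  y <- numeric(n_samp)
  ev <- which(t(schedule) == 1L, arr.ind = TRUE)  # time-major ordering
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (nrow(ev) > 0) for (i in seq_len(nrow(ev))) {
    bin <- ev[i, 1]; ch <- ev[i, 2]
    k <- kernels[[ch]]$waveform
    set.seed(as.integer(noise_seed) + i)
    noise <- stats::rnorm(length(k))
    blip <- .conv_full(noise, k) * gain
    start <- round((bin - 1) * bw * sample_rate_hz) + 1
    stop_ <- min(start + length(blip) - 1, n_samp)
    if (start <= n_samp)
      y[start:stop_] <- y[start:stop_] + blip[seq_len(stop_ - start + 1)]
  }
  structure(list(samples = y, sample_rate_hz = sample_rate_hz,
                 noise_seed = as.integer(noise_seed), gain = gain),
            class = "audio_stimulus")
}

# full linear convolution via FFT (stats::convolve open convention)
.conv_full <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}
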