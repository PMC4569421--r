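#' Extract log high-gamma band power from a raw trace
#'
#' Pipeline: resample the trace to `work_rate_hz` (default 400 Hz), apply
#' a zero-phase FIR bandpass over `band` (windowed-sinc Hamming design,
#' run forward and reverse), form the analytic signal by Hilbert
#' transform, square its magnitude to obtain instantaneous band power,
#' low-pass (anti-alias) and decimate to `output_rate_hz`, and take the
#' natural log. The log is floored at `1e-12` times the median power so
#' silent stretches stay finite.
#'
#' A unit-amplitude sinusoid inside the band yields log power near
#' `log(1) = 0` away from the edges; tones outside the band are attenuated
#' by the filter's stopband (>= 40 dB by design).
#'
#' @param trace a [raw_trace()].
#' @param band passband `(low, high)` in Hz; must lie inside
#'   `(0, work_rate_hz / 2)`.
#' @param output_rate_hz output sampling rate (default 40 Hz; must divide
#'   `work_rate_hz`).
#' @param work_rate_hz intermediate analysis rate (default 400 Hz).
#' @param fir_order FIR filter order (default 128 taps + 1; Hamming
#'   window, about 53 dB stopband, transition well under 20 Hz at 400 Hz).
#' @return A list of class `high_gamma_series` with `log_power`,
#'   `output_rate_hz`, `band_hz`.
#' @export
extract_high_gamma <- function(trace, band = c(70, 150),
                               output_rate_hz = 40, work_rate_hz = 400,
                               fir_order = 128L) {
  stopifnot(inherits(trace, "raw_trace"))
  if (band[1] <= 0 || band[2] >= work_rate_hz / 2 || band[1] >= band[2])
    rlang::abort("band must lie inside (0, work_rate_hz/2)")
  if (band[2] >= trace$sample_rate_hz / 2)
    rlang::abort("band exceeds the trace Nyquist rate")
  x <- trace$samples
  fs <- trace$sample_rate_hz
  if (length(x) < 3 * (fir_order + 1) * max(1, fs / work_rate_hz))
    rlang::abort("trace shorter than 3x the filter length")
  if (fs != work_rate_hz) {
    rat <- .rational_approx(work_rate_hz / fs)
    x <- signal::resample(x, rat[1], rat[2])
  }
  h <- signal::fir1(fir_order, band / (work_rate_hz / 2), type = "pass")
  xb <- signal::filtfilt(h, x)
  power <- Mod(.analytic(xb))^2
  q <- round(work_rate_hz / output_rate_hz)
  if (abs(work_rate_hz / output_rate_hz - q) > 1e-9)
    rlang::abort("output_rate_hz must divide work_rate_hz")
  if (q > 1) {
    # anti-alias: zero-phase FIR low-pass at 80% of the output Nyquist
    hl <- signal::fir1(fir_order, 0.8 * (output_rate_hz / 2) /
                         (work_rate_hz / 2))
    power <- signal::filtfilt(hl, power)
    power <- power[seq(1, length(power), by = q)]
  }
  n_out <- floor(length(trace$samples) / fs * output_rate_hz)
  power <- power[seq_len(min(n_out, length(power)))]
  floor_eps <- 1e-12 * max(stats::median(power), .Machine$double.xmin)
  structure(list(log_power = log(pmax(power, floor_eps)),
                 output_rate_hz = output_rate_hz, band_hz = band),
            class = "high_gamma_series")
}

# small continued-fraction rational approximation p/q ~= r
.rational_approx <- function(r, tol = 1e-9, max_den = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < tol) break
    if (abs(x - a) < 1e-15) break
    x <- 1 / (x - a)
  }
  c(as.integer(p1), as.integer(q1))
}

# analytic signal via FFT (positive frequencies doubled)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Bin spike times into counts
#'
#' Half-open bins `[k w, (k+1) w)`: a spike exactly on an edge belongs to
#' the later bin. Counts over all bins sum to the number of spikes inside
#' `[0, duration_s)`.
#'
#' @param times_s sorted non-negative spike times, seconds.
#' @param bin_width_s bin width (> 0), seconds.
#' @param duration_s total duration; must cover the largest spike time.
#' @return A [response_series()] of counts with
#'   `ceiling(duration_s / bin_width_s)` bins.
#' @export
bin_spikes <- function(times_s, bin_width_s = 0.025, duration_s) {
  if (bin_width_s <= 0) rlang::abort("bin width must be positive")
  if (is.unsorted(times_s)) rlang::abort("spike times must be sorted")
  if (length(times_s) > 0 && (min(times_s) < 0 || max(times_s) > duration_s))
    rlang::abort("spike times must lie in [0, duration_s]")
  n_bins <- ceiling(duration_s / bin_width_s)
  idx <- floor(times_s / bin_width_s) + 1L
  idx <- idx[idx <= n_bins]       # a spike exactly at duration_s is dropped
  counts <- tabulate(idx, nbins = n_bins)
  response_series(counts, bin_width_s, "counts")
}

#' Remove large-amplitude transients from a raw trace
#'
#' Iteratively z-scores the trace against the statistics of the samples
#' not yet marked, marking any sample whose |z| exceeds `z_thresh`, until
#' no new sample is marked. Marked samples are replaced by linear
#' interpolation from the surviving samples, and the repaired stretches
#' are smoothed with a normalized Hamming window.
#'
#' @param trace a [raw_trace()].
#' @param z_thresh z-score threshold (> 0, default 10).
#' @param hamming_len length of the smoothing window (odd, default 11).
#' @return A repaired [raw_trace()]; identical to the input if nothing is
#'   marked.
#' @export
remove_transients <- function(trace, z_thresh = 10, hamming_len = 11L) {
  stopifnot(inherits(trace, "raw_trace"), z_thresh > 0)
  x <- trace$samples
  keep <- rep(TRUE, length(x))
  repeat {
    mu <- mean(x[keep]); s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) break
    z <- abs(x - mu) / s
    newly <- keep & z > z_thresh
    if (!any(newly)) break
    keep[newly] <- FALSE
    if (!any(keep)) rlang::abort("all samples marked as transients")
  }
  if (all(keep)) return(trace)
  bad <- which(!keep)
  x2 <- x
  x2[bad] <- stats::approx(which(keep), x[keep], xout = bad,
                           rule = 2)$y
  # Hamming smoothing confined to the repaired neighbourhoods
  hw <- hamming_len %/% 2L
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, hamming_len - 1) /
                           (hamming_len - 1))
  w <- w / sum(w)
  sm <- stats::filter(c(rep(x2[1], hw), x2, rep(x2[length(x2)], hw)),
                      w, sides = 2)
  sm <- as.numeric(sm)[(hw + 1):(hw + length(x2))]
  touch <- unique(pmin(pmax(rep(bad, each = 2 * hw + 1) +
                              rep(-hw:hw, length(bad)), 1), length(x2)))
  x2[touch] <- sm[touch]
  raw_trace(x2, trace$sample_rate_hz)
}
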