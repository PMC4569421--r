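# Shared fixtures, built in code at test time.

# a cochleotopic-map-shaped tibble with prescribed center frequencies
toy_map <- function(freqs, params = erb_params()) {
  out <- tibble::tibble(index = seq_along(freqs),
                        center_freq_hz = sort(freqs, decreasing = TRUE),
                        erb_hz = compute_erb(sort(freqs, decreasing = TRUE),
                                             params),
                        bw_hz = params$bw_scale *
                          compute_erb(sort(freqs, decreasing = TRUE), params))
  attr(out, "f_low_hz") <- min(freqs)
  attr(out, "f_high_hz") <- max(freqs)
  attr(out, "erb_params") <- params
  class(out) <- c("cochleotopic_map", class(out))
  out
}

# wrap an arbitrary numeric matrix (first column all ones) as a design
toy_design <- function(X, n_freqs, n_lags, n_history = 0L,
                       history_lags = integer(0), bin_width_s = 0.05) {
  stopifnot(ncol(X) == 1 + n_freqs * n_lags + n_history)
  catalog <- c("intercept",
               paste0("stim(f=", rep(seq_len(n_freqs), each = n_lags),
                      ",tau=", rep(0:(n_lags - 1), n_freqs), ")"),
               if (n_history > 0) paste0("history(h=", history_lags, ")"))
  structure(list(X = methods::as(X, "CsparseMatrix"), catalog = catalog,
                 n_freqs = n_freqs, n_lags = n_lags,
                 n_history = as.integer(n_history),
                 history_lags = as.integer(history_lags),
                 n_obs = nrow(X), bin_width_s = bin_width_s),
            class = "strf_design")
}

# small end-to-end simulation used across estimation/selection tests
small_sim <- function(seed = 1, n_channels = 10, n_bins = 800,
                      n_lags = 6, p_onset = 0.05, amplitude = 1.5,
                      beta0 = log(0.5), alpha = numeric(0)) {
  map <- make_cochleotopic_map(n_channels, 200, 8000)
  lags <- lag_grid(n_lags)
  s <- draw_chord_schedule(n_channels, n_bins, p_onset, seed = seed)
  truth <- make_bump_strf(map, lags, center_freq_hz = 1000,
                          center_lag_s = 0.1, amplitude = amplitude,
                          suppression_amplitude = 0, beta0 = beta0,
                          alpha = alpha)
  counts <- simulate_counts(truth, s, seed = seed + 100)
  list(map = map, lags = lags, schedule = s, truth = truth,
       counts = counts)
}

# brute-force lagged design oracle: explicit triple loop over (f, tau, t)
brute_force_stim_block <- function(schedule, n_lags) {
  n_f <- nrow(schedule); n <- ncol(schedule)
  out <- matrix(0, n, n_f * n_lags)
  for (f in seq_len(n_f)) for (tau in 0:(n_lags - 1)) for (t in seq_len(n)) {
    if (t - tau >= 1)
      out[t, (f - 1) * n_lags + tau + 1] <- schedule[f, t - tau]
  }
  out
}
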