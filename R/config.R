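#' Run configuration
#'
#' A single JSON-serializable document holding every tunable parameter of
#' the pipeline, with the package defaults: the cochleotopic map (50
#' channels, 100-12207 Hz), the Bernoulli schedule (p = 0.02, 50 ms bins,
#' 6000 bins = 5 minutes), the lag grid (40 lags of 50 ms = 2 s), the
#' history block (H = 15), the penalty (group, 4 x 4 patches), the solver,
#' the permutation selection (200 reps), and the signals settings
#' (70-150 Hz band, 40 Hz output). Unknown fields in `...` override the
#' defaults by name.
#'
#' @param ... named overrides of nested defaults, e.g.
#'   `schedule = list(p_onset = 0.01)`.
#' @return A nested list of class `run_config`.
#' @export
strf_config <- function(...) {
  cfg <- list(
    map = list(n_channels = 50L, f_low_hz = 100, f_high_hz = 12207,
               q_ear = 9.26447, bw_min = 24.7, order_n = 1L,
               bw_scale = 1.019),
    schedule = list(n_bins = 6000L, p_onset = 0.02, bin_width_s = 0.05,
                    seed = 1L),
    lags = list(n_lags = 40L, lag_step_s = 0.05),
    history = list(n_history = 15L, include_current_count = FALSE),
    penalty = list(kind = "group", patch = c(4L, 4L),
                   penalize_history = TRUE, lambda = "auto"),
    solver = list(max_iter = 5000L, tol = 1e-8, acceleration = "fista"),
    selection = list(n_reps = 200L, seed = 2L),
    signals = list(band_hz = c(70, 150), output_rate_hz = 40,
                   work_rate_hz = 400),
    audio = list(sample_rate_hz = 24414, blip_duration_s = 0.05,
                 noise_seed = 3L),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read and write run configurations as JSON
#'
#' Round-trips through the file without loss of values.
#'
#' @param config a [strf_config()] object.
#' @param path JSON file path.
#' @return Writer: `path` invisibly; reader: a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(strf_config, raw)
  cfg
}
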