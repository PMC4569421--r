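#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted encoding GLM
#'
#' One row per model coefficient: the intercept, each `stim(f, tau)` cell
#' with its frequency (Hz, when a map is supplied) and lag (s), and each
#' history weight.
#'
#' @param x an `strf_fit`.
#' @param map optional [make_cochleotopic_map()] to resolve channel
#'   frequencies.
#' @param lag_step_s lag step used to convert lag indices to seconds.
#' @param ... unused.
#' @return A tibble with columns `term`, `type`
#'   (intercept/stim/history), `channel`, `freq_hz`, `lag_s`, `estimate`.
#' @export
tidy.strf_fit <- function(x, map = NULL, lag_step_s = 0.05, ...) {
  co <- x$coefficients
  n_f <- nrow(co$beta); n_t <- ncol(co$beta)
  freqs <- if (is.null(map)) rep(NA_real_, n_f) else channel_freqs(map)
  stim <- tibble::tibble(
    term = paste0("stim(f=", rep(seq_len(n_f), each = n_t),
                  ",tau=", rep(0:(n_t - 1), n_f), ")"),
    type = "stim",
    channel = rep(seq_len(n_f), each = n_t),
    freq_hz = rep(freqs, each = n_t),
    lag_s = rep(0:(n_t - 1), n_f) * lag_step_s,
    estimate = vectorize_strf(co$beta))
  hist <- if (length(co$alpha))
    tibble::tibble(term = paste0("history(h=", co$history_lags, ")"),
                   type = "history", channel = NA_integer_,
                   freq_hz = NA_real_,
                   lag_s = co$history_lags * lag_step_s,
                   estimate = co$alpha)
  else NULL
  dplyr::bind_rows(
    tibble::tibble(term = "intercept", type = "intercept",
                   channel = NA_integer_, freq_hz = NA_real_,
                   lag_s = NA_real_, estimate = co$beta0),
    stim, hist)
}

#' One-row summary of a fitted encoding GLM
#'
#' @param x an `strf_fit`.
#' @param ... unused.
#' @return A tibble with `family`, `penalty`, `lambda`, `df`, `deviance`,
#'   `n_iter`, `converged`.
#' @export
glance.strf_fit <- function(x, ...) {
  tibble::tibble(family = x$family, penalty = x$penalty$kind,
                 lambda = x$penalty$lambda, df = x$df,
                 deviance = x$deviance, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Plot an STRF grid
#'
#' Heatmap of the coefficient grid with lag on the x axis and (log-scaled)
#' center frequency on the y axis, diverging palette centered at zero.
#'
#' @param grid an `F x T` matrix, `strf_fit`, or [strf_coefficients()].
#' @param map optional cochleotopic map for the frequency axis.
#' @param lag_step_s lag step in seconds.
#' @return A ggplot object.
#' @export
plot_strf <- function(grid, map = NULL, lag_step_s = 0.05) {
  if (inherits(grid, "strf_fit")) grid <- grid$coefficients$beta
  if (inherits(grid, "strf_coefficients")) grid <- grid$beta
  n_f <- nrow(grid); n_t <- ncol(grid)
  freqs <- if (is.null(map)) seq_len(n_f) else channel_freqs(map)
  d <- tidyr::expand_grid(channel = seq_len(n_f), lag = seq_len(n_t))
  d$freq <- freqs[d$channel]
  d$lag_s <- (d$lag - 1) * lag_step_s
  d$value <- grid[cbind(d$channel, d$lag)]
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_s, .data$freq,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    (if (is.null(map)) ggplot2::scale_y_continuous()
     else ggplot2::scale_y_log10()) +
    ggplot2::labs(x = "lag (s)",
                  y = if (is.null(map)) "channel" else "frequency (Hz)",
                  fill = "coef") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strf
#' @param object an `strf_fit`.
#' @param ... passed to [plot_strf()].
#' @export
autoplot.strf_fit <- function(object, ...) plot_strf(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of the permutation null of the all-zeroing penalty weight
#'
#' @param object a [permutation_lambda_null()] result.
#' @param ... unused.
#' @return A ggplot object with the selected (median) weight marked.
#' @export
autoplot.permutation_null <- function(object, ...) {
  d <- tibble::tibble(min_lambda = object$min_lambdas)
  ggplot2::ggplot(d, ggplot2::aes(.data$min_lambda)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$selected_lambda,
                        colour = "red") +
    ggplot2::labs(x = expression(minimum ~ lambda), y = "permutations") +
    ggplot2::theme_minimal()
}

#' @export
print.strf_fit <- function(x, ...) {
  cat("<strf_fit>", x$family, "family,", x$penalty$kind, "penalty",
      sprintf("(lambda = %.4g)", x$penalty$lambda), "\n")
  cat("  df =", x$df, " deviance =", format(x$deviance, digits = 6),
      " iterations =", x$n_iter,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null>", x$n_reps, "permutations,",
      x$penalty_kind, "penalty\n")
  cat("  selected lambda (median):", format(x$selected_lambda, digits = 6),
      "\n")
  invisible(x)
}
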