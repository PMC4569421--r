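#' Lag grid for the STRF
#'
#' The STRF spans `n_lags` delays at `lag_step_s` resolution; the default
#' 40 lags of 50 ms give a 2-second impulse response. Lag `tau = 0` is the
#' same-bin (instantaneous) influence.
#'
#' @param n_lags number of lags `T` (>= 1).
#' @param lag_step_s lag step in seconds; one bin of the common grid.
#' @return A list of class `lag_grid` with `n_lags`, `lag_step_s`, and
#'   the total `span_s`.
#' @export
lag_grid <- function(n_lags = 40L, lag_step_s = 0.05) {
  stopifnot(n_lags >= 1, lag_step_s > 0)
  structure(list(n_lags = as.integer(n_lags), lag_step_s = lag_step_s,
                 span_s = n_lags * lag_step_s), class = "lag_grid")
}

#' Response series container
#'
#' A per-bin response aligned to the stimulus grid: non-negative integer
#' spike counts (`kind = "counts"`) or real-valued log high-gamma power
#' (`kind = "log_power"`).
#'
#' @param values numeric vector; integer-valued and >= 0 when
#'   `kind = "counts"`.
#' @param bin_width_s bin width, seconds.
#' @param kind `"counts"` or `"log_power"`.
#' @return Numeric vector of class `response_series` with attributes
#'   `bin_width_s` and `kind`.
#' @export
response_series <- function(values, bin_width_s = 0.05,
                            kind = c("counts", "log_power")) {
  kind <- match.arg(kind)
  if (kind == "counts" &&
      (any(values < 0) || any(values != round(values))))
    rlang::abort("counts must be non-negative integers")
  structure(as.numeric(values), bin_width_s = bin_width_s, kind = kind,
            class = "response_series")
}

#' Lagged stimulus design matrix with spike-history covariates
#'
#' Builds the sparse design matrix of the encoding GLM. Columns are, in
#' order: an all-ones intercept; one column per (frequency, lag) pair
#' `stim(f, tau)` whose row `t` holds `x_f(t - tau)` (zero-padded where
#' `t - tau < 1`), lag varying fastest within frequency; and, when
#' `n_history > 0`, one column per history term `history(h)` holding the
#' lagged response `r(t - h)`. The history range is `h = 1..H` for the
#' Poisson spike-count model and `h = 0..H-1` when
#' `include_current_count = TRUE` (the log high-gamma model, which also
#' conditions on the same-bin count).
#'
#' @param schedule a [draw_chord_schedule()] result (`F x n_bins`); rows
#'   ordered low-to-high center frequency.
#' @param lags a [lag_grid()] result.
#' @param response a [response_series()] of length `n_bins`; required
#'   when `n_history > 0`.
#' @param n_history number of history covariates `H` (default 0).
#' @param include_current_count if `TRUE` the history range starts at
#'   `h = 0` (same-bin count), else at `h = 1`.
#' @return A list of class `strf_design` with fields `X` (a
#'   `dgCMatrix`), `catalog` (column labels), `n_freqs`, `n_lags`,
#'   `n_history`, `history_lags`, `n_obs`, `bin_width_s`.
#' @export
#' @examples
#' s <- draw_chord_schedule(8, 200, seed = 2)
#' d <- build_design(s, lag_grid(5))
#' dim(d$X)  # 200 x (1 + 8*5)
build_design <- function(schedule, lags, response = NULL, n_history = 0L,
                         include_current_count = FALSE) {
  n_f <- nrow(schedule); n_bins <- ncol(schedule)
  n_t <- lags$n_lags
  n_history <- as.integer(n_history)
  if (n_history > 0) {
    if (is.null(response)) rlang::abort("history covariates need a response")
    if (length(response) != n_bins)
      rlang::abort("response length must match schedule bins")
  }
  # stimulus block via onset triplets: onset (f, t0) puts a 1 in rows
  # t0 + tau, column stim(f, tau)
  on <- which(schedule == 1L, arr.ind = TRUE)
  ii <- integer(0); jj <- integer(0)
  if (nrow(on) > 0) {
    taus <- 0:(n_t - 1)
    f <- rep(on[, 1], each = n_t)
    t0 <- rep(on[, 2], each = n_t)
    tau <- rep(taus, nrow(on))
    row <- t0 + tau
    keep <- row <= n_bins
    ii <- row[keep]
    jj <- 1L + (f[keep] - 1L) * n_t + tau[keep] + 1L  # after intercept
  }
  hist_lags <- integer(0)
  if (n_history > 0) {
    hist_lags <- if (include_current_count) 0:(n_history - 1L)
                 else 1:n_history
  }
  n_cols <- 1L + n_f * n_t + n_history
  # intercept
  ii <- c(seq_len(n_bins), ii)
  jj <- c(rep(1L, n_bins), jj)
  vv <- rep(1, length(ii))
  # history columns
  if (n_history > 0) {
    r <- as.numeric(response)
    for (k in seq_along(hist_lags)) {
      h <- hist_lags[k]
      rows <- (h + 1L):n_bins
      vals <- r[rows - h]
      nz <- vals != 0
      ii <- c(ii, rows[nz])
      jj <- c(jj, rep(1L + n_f * n_t + k, sum(nz)))
      vv <- c(vv, vals[nz])
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_bins, n_cols))
  catalog <- c("intercept",
               paste0("stim(f=", rep(seq_len(n_f), each = n_t),
                      ",tau=", rep(0:(n_t - 1), n_f), ")"),
               if (n_history > 0) paste0("history(h=", hist_lags, ")"))
  structure(list(X = X, catalog = catalog, n_freqs = n_f, n_lags = n_t,
                 n_history = n_history, history_lags = hist_lags,
                 n_obs = n_bins,
                 bin_width_s = attr(schedule, "bin_width_s")),
            class = "strf_design")
}

#' Group map for the grouped (L1/L2) penalty
#'
#' Tiles the `F x T` STRF grid with non-overlapping `patch` patches
#' (default 4 x 4), row-major; partial patches at the grid edges form
#' their own groups. With the default 50 x 40 grid this yields 130
#' stimulus groups. When `with_history = TRUE` all spike-history
#' covariates share one additional group.
#'
#' @param n_freqs grid rows `F`.
#' @param n_lags grid columns `T`.
#' @param patch integer pair (rows, cols) of the patch shape.
#' @param with_history add a single extra group for the history block.
#' @return A list of class `group_map` with fields `group_id` (an
#'   `F x T` integer matrix, ids 1..n_stim_groups), `history_group_id`
#'   (or `NA`), `patch`, `n_groups`.
#' @export
#' @examples
#' g <- build_group_map(50, 40)
#' g$n_groups  # 130
build_group_map <- function(n_freqs, n_lags, patch = c(4L, 4L),
                            with_history = FALSE) {
  stopifnot(patch[1] >= 1, patch[2] >= 1)
  fr <- ceiling(seq_len(n_freqs) / patch[1])
  lg <- ceiling(seq_len(n_lags) / patch[2])
  n_col_patches <- max(lg)
  gid <- outer(fr, lg, function(a, b) (a - 1L) * n_col_patches + b)
  storage.mode(gid) <- "integer"
  n_stim <- max(gid)
  structure(list(group_id = gid,
                 history_group_id = if (with_history) n_stim + 1L
                                    else NA_integer_,
                 patch = as.integer(patch),
                 n_groups = n_stim + as.integer(with_history)),
            class = "group_map")
}

#' Flatten an STRF grid to the design-matrix coefficient ordering
#'
#' `vectorize_strf()` maps an `F x T` grid to the vector ordering of the
#' `stim(f, tau)` columns (lag fastest within frequency);
#' `grid_strf()` inverts it. Round-tripping is exact.
#'
#' @param grid an `F x T` numeric matrix (frequency ascending by row).
#' @return A numeric vector of length `F * T`.
#' @export
vectorize_strf <- function(grid) {
  as.numeric(t(grid))
}

#' @rdname vectorize_strf
#' @param v numeric vector of length `n_freqs * n_lags`.
#' @param n_freqs,n_lags grid dimensions.
#' @export
grid_strf <- function(v, n_freqs, n_lags) {
  if (length(v) != n_freqs * n_lags)
    rlang::abort("length(v) must equal n_freqs * n_lags")
  matrix(v, nrow = n_freqs, ncol = n_lags, byrow = TRUE)
}

# per-column group assignment for a full design (0 = unpenalized/intercept,
# used internally by the solver and lambda_max)
.column_groups <- function(design, groups = NULL, penalty_kind = "l1",
                           penalize_history = TRUE) {
  p <- ncol(design$X)
  n_stim <- design$n_freqs * design$n_lags
  g <- integer(p)             # 0 = unpenalized
  if (penalty_kind == "group") {
    if (is.null(groups)) rlang::abort("group penalty requires a group map")
    g[1 + seq_len(n_stim)] <- vectorize_strf(groups$group_id)
    if (design$n_history > 0) {
      hid <- groups$history_group_id
      if (is.na(hid)) hid <- max(groups$group_id) + 1L
      g[1 + n_stim + seq_len(design$n_history)] <-
        if (penalize_history) hid else 0L
    }
  } else {
    # l1 / none: every penalized column its own group
    g[1 + seq_len(n_stim)] <- seq_len(n_stim)
    if (design$n_history > 0)
      g[1 + n_stim + seq_len(design$n_history)] <-
        if (penalize_history) n_stim + seq_len(design$n_history) else 0L
  }
  g
}
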