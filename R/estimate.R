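#' Spike-triggered average STRF
#'
#' The classical reverse-correlation estimator
#' `STRF_f(tau) = E[r(t) x_f(t - tau)]`, estimated by the sample mean over
#' all bins (out-of-range products treated as zero). With a Bernoulli
#' chord stimulus no whitening is required.
#'
#' @param schedule a [draw_chord_schedule()] result.
#' @param response a [response_series()] of the same length.
#' @param lags a [lag_grid()] result.
#' @param center if `TRUE`, mean-center the response first (off by
#'   default).
#' @return An `F x T` numeric matrix (frequency ascending by row).
#' @export
sta <- function(schedule, response, lags, center = FALSE) {
  r <- as.numeric(response)
  if (length(r) == 0) rlang::abort("empty response")
  if (length(r) != ncol(schedule))
    rlang::abort("response length must match schedule bins")
  if (center) r <- r - mean(r)
  n <- length(r); n_f <- nrow(schedule); n_t <- lags$n_lags
  g <- matrix(0, n_f, n_t)
  x <- schedule
  for (tau in 0:(n_t - 1)) {
    g[, tau + 1] <- (x[, seq_len(n - tau), drop = FALSE] %*%
                       r[(1 + tau):n]) / n
  }
  g
}

#' Penalty specification for the sparse GLM
#'
#' @param kind `"none"`, `"l1"` (elementwise lasso), or `"group"`
#'   (grouped L1/L2 norm over [build_group_map()] patches).
#' @param lambda non-negative penalty weight.
#' @param group_map a [build_group_map()] result; required when
#'   `kind = "group"`.
#' @param penalize_history should history covariates be penalized (as
#'   their own single group under `kind = "group"`)? Default `TRUE`.
#' @return A list of class `penalty_spec`. The intercept is never
#'   penalized.
#' @export
penalty_spec <- function(kind = c("none", "l1", "group"), lambda = 0,
                         group_map = NULL, penalize_history = TRUE) {
  kind <- match.arg(kind)
  if (lambda < 0) rlang::abort("lambda must be >= 0")
  if (kind == "group" && is.null(group_map))
    rlang::abort("group penalty requires a group_map")
  structure(list(kind = kind, lambda = lambda, group_map = group_map,
                 penalize_history = penalize_history),
            class = "penalty_spec")
}

#' Solver options for the proximal gradient method
#'
#' @param max_iter iteration cap (default 5000).
#' @param tol relative objective-change convergence tolerance
#'   (default 1e-8).
#' @param acceleration `"fista"` (default) or `"ista"`. Both use
#'   backtracking on the smooth part; the ISTA path is monotone in the
#'   penalized objective, and the FISTA path restarts its momentum
#'   whenever the objective would increase, so it is monotone as well.
#' @return A list of class `solver_options`. The solver is deterministic.
#' @export
solver_options <- function(max_iter = 5000L, tol = 1e-8,
                           acceleration = c("fista", "ista")) {
  acceleration <- match.arg(acceleration)
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 acceleration = acceleration), class = "solver_options")
}

#' Negative log-likelihood and gradient of the encoding GLM
#'
#' Poisson: `sum(exp(eta)) - sum(r * eta)` (the `log r!` constant is
#' omitted; it is restored in [strf_deviance()] through the saturated
#' model). Gaussian (log high-gamma): `0.5 * sum((y - eta)^2)`.
#'
#' @param family `"poisson"` or `"log_gaussian"`.
#' @param design an [build_design()] result.
#' @param response a [response_series()]; integer counts required for
#'   the Poisson family.
#' @param coefficients full coefficient vector in design-column order
#'   (intercept first).
#' @return List with `value` and `gradient` (length `ncol(X)`).
#' @export
negloglik <- function(family, design, response, coefficients) {
  r <- as.numeric(response)
  X <- design$X
  if (length(coefficients) != ncol(X))
    rlang::abort("coefficient length must match design columns")
  eta <- as.numeric(X %*% coefficients)
  if (family == "poisson") {
    if (any(r < 0) || any(r != round(r)))
      rlang::abort("poisson family needs non-negative integer counts")
    mu <- exp(eta)
    list(value = sum(mu) - sum(r * eta),
         gradient = as.numeric(Matrix::crossprod(X, mu - r)))
  } else {
    res <- r - eta
    list(value = 0.5 * sum(res^2),
         gradient = as.numeric(Matrix::crossprod(X, -res)))
  }
}

#' Soft-thresholding (L1 proximal operator)
#'
#' `sign(v) * max(|v| - t, 0)` elementwise; positions listed in
#' `unpenalized` (e.g. the intercept) pass through unchanged.
#'
#' @param v numeric vector.
#' @param t threshold (>= 0).
#' @param unpenalized integer indices exempt from shrinkage.
#' @return Thresholded vector.
#' @export
prox_l1 <- function(v, t, unpenalized = NULL) {
  stopifnot(t >= 0)
  out <- sign(v) * pmax(abs(v) - t, 0)
  if (length(unpenalized)) out[unpenalized] <- v[unpenalized]
  out
}

#' Group soft-thresholding (grouped L1/L2 proximal operator)
#'
#' Per group `g`: `v_g * max(1 - t / ||v_g||_2, 0)`; a group whose norm is
#' at most `t` is zeroed entirely. Elements with group id 0 pass through
#' unchanged.
#'
#' @param v numeric vector.
#' @param t threshold (>= 0).
#' @param groups integer vector of group ids per element (0 =
#'   unpenalized).
#' @return Thresholded vector.
#' @export
prox_group <- function(v, t, groups) {
  stopifnot(t >= 0, length(groups) == length(v))
  out <- v
  pen <- groups > 0
  if (any(pen)) {
    gg <- groups[pen]
    ss <- rowsum(v[pen]^2, gg)
    nm <- sqrt(ss[, 1])
    scale <- pmax(1 - t / pmax(nm, .Machine$double.xmin), 0)
    scale[nm == 0] <- 0
    names(scale) <- rownames(ss)
    out[pen] <- v[pen] * scale[as.character(gg)]
  }
  out
}

# penalty value for a coefficient vector given per-column groups
.penalty_value <- function(b, lambda, groups) {
  if (lambda == 0) return(0)
  pen <- groups > 0
  if (!any(pen)) return(0)
  ss <- rowsum(b[pen]^2, groups[pen])
  lambda * sum(sqrt(ss[, 1]))
}

#' Fit a penalized encoding GLM by proximal gradient
#'
#' Minimizes `-l(beta) + lambda * P(beta)` where `l` is the Poisson or
#' Gaussian log-likelihood and `P` is none, the L1 norm, or the grouped
#' L1/L2 norm over the supplied group map (history covariates forming one
#' additional group). The intercept is never penalized. The solver is
#' ISTA/FISTA with backtracking line search on the smooth part; FISTA
#' momentum is restarted whenever it would increase the objective, so the
#' recorded objective trace is non-increasing for both modes. A run that
#' hits `max_iter` is returned with `converged = FALSE` rather than
#' raising.
#'
#' @param design an [build_design()] result.
#' @param response a [response_series()] of length `design$n_obs`.
#' @param family `"poisson"` or `"log_gaussian"`.
#' @param penalty a [penalty_spec()].
#' @param options a [solver_options()].
#' @return A list of class `strf_fit`: `coefficients` (an
#'   [strf_coefficients()]), `b` (full vector), `family`, `penalty`,
#'   `df` (nonzero penalized coefficients + 1 for the intercept),
#'   `deviance`, `n_iter`, `converged`, `objective_trace`, `design_dims`,
#'   `catalog`.
#' @export
fit_penalized_glm <- function(design, response, family = "poisson",
                              penalty = penalty_spec("none"),
                              options = solver_options()) {
  r <- as.numeric(response)
  if (length(r) != design$n_obs)
    rlang::abort("response length must match design rows")
  X <- design$X
  p <- ncol(X)
  groups <- .column_groups(design, penalty$group_map, penalty$kind,
                           penalty$penalize_history)
  if (penalty$kind == "none") groups <- integer(p)  # nothing penalized
  lambda <- penalty$lambda
  fam <- family

  f_of <- function(b) negloglik(fam, design, response, b)
  # intercept-only start
  b <- numeric(p)
  b[1] <- if (fam == "poisson") log(max(mean(r), 1e-8)) else mean(r)
  st <- f_of(b)
  obj <- st$value + .penalty_value(b, lambda, groups)
  L <- 1
  tk <- 1
  y <- b
  b_prev <- b
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  use_fista <- options$acceleration == "fista"

  for (it in seq_len(options$max_iter)) {
    n_iter <- it
    fy <- f_of(y)
    if (!is.finite(fy$value) || !all(is.finite(fy$gradient))) {
      # momentum overshot into a non-finite region: restart at b
      y <- b; tk <- 1
      fy <- f_of(y)
    }
    repeat {
      z <- .prox_step(y - fy$gradient / L, lambda / L, groups)
      fz <- f_of(z)$value
      dz <- z - y
      q <- fy$value + sum(fy$gradient * dz) + 0.5 * L * sum(dz^2)
      if (is.finite(fz) && fz <= q + 1e-12 * abs(q)) break
      L <- 2 * L
      if (L > 1e18) rlang::abort("backtracking failed: step size underflow")
    }
    obj_z <- fz + .penalty_value(z, lambda, groups)
    if (use_fista && obj_z > obj) {
      # restart momentum and redo a plain ISTA step from b
      y <- b; tk <- 1
      fy <- f_of(y)
      repeat {
        z <- .prox_step(y - fy$gradient / L, lambda / L, groups)
        fz <- f_of(z)$value
        dz <- z - y
        q <- fy$value + sum(fy$gradient * dz) + 0.5 * L * sum(dz^2)
        if (is.finite(fz) && fz <= q + 1e-12 * abs(q)) break
        L <- 2 * L
      }
      obj_z <- fz + .penalty_value(z, lambda, groups)
    }
    # majorization at the current iterate guarantees obj_z <= obj here
    trace <- c(trace, obj_z)
    done <- abs(obj - obj_z) <= options$tol * max(1, abs(obj))
    b_prev <- b
    b <- z
    obj <- obj_z
    if (use_fista) {
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- b + ((tk - 1) / tk1) * (b - b_prev)
      tk <- tk1
    } else {
      y <- b
    }
    if (done) { converged <- TRUE; break }
  }

  n_stim <- design$n_freqs * design$n_lags
  beta <- grid_strf(b[1 + seq_len(n_stim)], design$n_freqs, design$n_lags)
  alpha <- if (design$n_history > 0) b[1 + n_stim + seq_len(design$n_history)]
           else numeric(0)
  co <- strf_coefficients(b[1], beta, alpha,
                          family = if (fam == "poisson") "poisson"
                                   else "log_gaussian",
                          history_lags = design$history_lags)
  df <- sum(b[-1] != 0 & groups[-1] > 0) + sum(b[-1] != 0 & groups[-1] == 0) + 1L
  fit <- structure(list(coefficients = co, b = b, family = fam,
                        penalty = penalty, df = as.integer(df),
                        n_iter = n_iter, converged = converged,
                        objective_trace = trace,
                        design_dims = c(n_freqs = design$n_freqs,
                                        n_lags = design$n_lags,
                                        n_history = design$n_history),
                        catalog = design$catalog),
                   class = "strf_fit")
  fit$deviance <- strf_deviance(fit, design, response)
  fit
}

.prox_step <- function(v, t, groups) {
  if (t == 0 || !any(groups > 0)) return(v)
  prox_group(v, t, groups)
}

#' Model deviance of a fitted encoding GLM
#'
#' `2 * (saturated log-likelihood - model log-likelihood)`. For the
#' Poisson family the saturated model sets each bin's rate to its
#' observed count (`D = 2 * sum(r log(r / mu) - (r - mu))`, zero-count
#' terms contributing `mu`); for the Gaussian family the deviance is the
#' residual sum of squares.
#'
#' @param fit an [fit_penalized_glm()] or [fit_glm_ml()] result.
#' @param design the design the fit was computed on.
#' @param response the observed [response_series()].
#' @return A single non-negative number.
#' @export
strf_deviance <- function(fit, design, response) {
  r <- as.numeric(response)
  eta <- as.numeric(design$X %*% fit$b)
  if (fit$family == "poisson") {
    mu <- exp(eta)
    pos <- r > 0
    2 * (sum(r[pos] * log(r[pos] / mu[pos])) - sum(r - mu))
  } else {
    sum((r - eta)^2)
  }
}

#' Predicted response of a fitted encoding GLM
#'
#' Poisson: per-bin expected count `exp(eta)` (the conditional intensity
#' times the bin width); Gaussian: the linear predictor.
#'
#' @param object an `strf_fit`.
#' @param design an [build_design()] result with the same column catalog.
#' @param ... unused.
#' @return Numeric vector of per-bin predictions.
#' @export
predict.strf_fit <- function(object, design, ...) {
  if (!identical(design$catalog, object$catalog))
    rlang::abort("design column catalog does not match the fit")
  eta <- as.numeric(design$X %*% object$b)
  if (object$family == "poisson") exp(eta) else eta
}

#' Zero-phase low-pass smoothing of a count series
#'
#' Second-order Butterworth low-pass (default 6 Hz cutoff) applied
#' forward and backward, as used to display recorded spike counts next to
#' model predictions.
#'
#' @param counts a [response_series()] or numeric vector.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param rate_hz sampling rate of the series; defaults to
#'   `1 / bin_width_s` when `counts` is a [response_series()].
#' @return Numeric smoothed series.
#' @export
smooth_counts <- function(counts, cutoff_hz = 6, rate_hz = NULL) {
  if (is.null(rate_hz)) {
    bw <- attr(counts, "bin_width_s")
    if (is.null(bw)) rlang::abort("rate_hz needed for a bare vector")
    rate_hz <- 1 / bw
  }
  if (cutoff_hz >= rate_hz / 2)
    rlang::abort("cutoff must be below the Nyquist rate")
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  # edge-replicate padding keeps the zero-phase filter from ringing at
  # the series ends (a constant series passes through unchanged)
  x <- as.numeric(counts)
  pad <- min(length(x), max(30, ceiling(rate_hz / cutoff_hz) * 8))
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + length(x))]
}

#' First-order (KKT) optimality residual of a penalized fit
#'
#' For the L1 penalty the subgradient conditions require
#' `|g_j| <= lambda` for zero coefficients and `g_j = -lambda sign(b_j)`
#' for active ones, where `g` is the gradient of the log-likelihood part;
#' the grouped analogue bounds `||g_g||_2`. Returns the largest violation
#' scaled by `max(1, lambda)`.
#'
#' @param fit an `strf_fit`.
#' @param design,response the fitted problem.
#' @return Non-negative scalar; near zero at an exact solution.
#' @export
kkt_residual <- function(fit, design, response) {
  g <- negloglik(fit$family, design, response, fit$b)$gradient
  pen <- fit$penalty
  groups <- .column_groups(design, pen$group_map, pen$kind,
                           pen$penalize_history)
  if (pen$kind == "none") groups <- integer(length(g))
  lam <- pen$lambda
  viol <- abs(g[groups == 0])   # unpenalized: gradient must vanish
  pens <- which(groups > 0)
  if (length(pens)) {
    gg <- groups[pens]
    gn <- sqrt(rowsum(g[pens]^2, gg)[, 1])
    bn <- sqrt(rowsum(fit$b[pens]^2, gg)[, 1])
    active <- bn > 0
    viol <- c(viol,
              pmax(gn[!active] - lam, 0),     # inactive: ||g_g|| <= lambda
              abs(gn[active] - lam))          # active: ||g_g|| = lambda
  }
  max(viol) / max(1, lam)
}

#' Unpenalized maximum-likelihood fit (classical GLM)
#'
#' Fits the encoding model without any penalty using iteratively
#' reweighted least squares ([stats::glm.fit()]) for the Poisson family
#' and ordinary least squares for the Gaussian family. Used for the
#' nested-model spike-history tests, where classical chi-square / F null
#' distributions require unshrunk estimates. The design is densified, so
#' this is intended for moderate problem sizes.
#'
#' @param design an [build_design()] result.
#' @param response a [response_series()].
#' @param family `"poisson"` or `"log_gaussian"`.
#' @return An `strf_fit`-classed list (penalty `"none"`, `lambda = 0`).
#' @export
fit_glm_ml <- function(design, response, family = "poisson") {
  r <- as.numeric(response)
  Xd <- as.matrix(design$X)
  if (family == "poisson") {
    g <- suppressWarnings(stats::glm.fit(Xd, r, family = stats::poisson()))
    b <- g$coefficients
  } else {
    b <- stats::lm.fit(Xd, r)$coefficients
  }
  b[is.na(b)] <- 0
  n_stim <- design$n_freqs * design$n_lags
  beta <- grid_strf(b[1 + seq_len(n_stim)], design$n_freqs, design$n_lags)
  alpha <- if (design$n_history > 0) b[1 + n_stim + seq_len(design$n_history)]
           else numeric(0)
  co <- strf_coefficients(b[1], beta, alpha,
                          family = if (family == "poisson") "poisson"
                                   else "log_gaussian",
                          history_lags = design$history_lags)
  fit <- structure(list(coefficients = co, b = as.numeric(b),
                        family = family,
                        penalty = penalty_spec("none", 0),
                        df = ncol(Xd), n_iter = NA_integer_,
                        converged = TRUE, objective_trace = numeric(0),
                        design_dims = c(n_freqs = design$n_freqs,
                                        n_lags = design$n_lags,
                                        n_history = design$n_history),
                        catalog = design$catalog),
                   class = "strf_fit")
  fit$deviance <- strf_deviance(fit, design, response)
  fit
}
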