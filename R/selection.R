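#' Smallest penalty weight that zeroes all free covariates
#'
#' Closed-form from the subgradient (KKT) conditions at the null model:
#' fit the unpenalized columns alone (for the default intercept-only case
#' this is `log(mean(r))` / `mean(y)`), take the gradient `g` of the
#' negative log-likelihood at that point restricted to the penalized
#' columns, and return `max_j |g_j|` for the L1 penalty or
#' `max_g ||g_g||_2` for the grouped penalty. Solving at any
#' `lambda >= lambda_max` returns the all-zero penalized solution
#' (df = 1, intercept only); just below it at least one covariate enters.
#'
#' @param design an [build_design()] result.
#' @param response a [response_series()].
#' @param family `"poisson"` or `"log_gaussian"`.
#' @param penalty_kind `"l1"` or `"group"`.
#' @param groups a [build_group_map()] result (required for
#'   `penalty_kind = "group"`).
#' @param penalize_history as in [penalty_spec()].
#' @return A single non-negative number; 0 for a zero-variance response.
#' @export
lambda_max <- function(design, response, family = "poisson",
                       penalty_kind = c("l1", "group"), groups = NULL,
                       penalize_history = TRUE) {
  penalty_kind <- match.arg(penalty_kind)
  r <- as.numeric(response)
  gvec <- .column_groups(design, groups, penalty_kind, penalize_history)
  free <- which(gvec == 0)
  b <- numeric(ncol(design$X))
  if (identical(free, 1L)) {
    b[1] <- if (family == "poisson") log(max(mean(r), 1e-12)) else mean(r)
  } else {
    # unpenalized block beyond the intercept: small ML fit on it
    sub <- list(X = design$X[, free, drop = FALSE])
    Xd <- as.matrix(sub$X)
    bf <- if (family == "poisson")
      suppressWarnings(stats::glm.fit(Xd, r,
                                      family = stats::poisson()))$coefficients
    else stats::lm.fit(Xd, r)$coefficients
    bf[is.na(bf)] <- 0
    b[free] <- bf
  }
  g <- negloglik(family, design, response, b)$gradient
  pens <- which(gvec > 0)
  if (!length(pens)) return(0)
  gn <- sqrt(rowsum(g[pens]^2, gvec[pens])[, 1])
  if (penalty_kind == "l1") max(abs(g[pens])) else max(gn)
}

#' Permutation null distribution of the all-zeroing penalty weight
#'
#' Discovery-based selection of the regularizer: the response is randomly
#' permuted `n_reps` times, destroying any stimulus-response association;
#' for each permutation the smallest penalty weight that zeroes all free
#' covariates ([lambda_max()]) is recorded. The median of this null
#' distribution is the selected weight `lambda*` — the value at which a
#' chance-only STRF would be entirely removed — and fitting the
#' unpermuted data at `lambda*` is the recommended final fit.
#'
#' @inheritParams lambda_max
#' @param n_reps number of permutations (default 200, >= 2).
#' @param seed integer RNG seed for the permutation draws.
#' @return A list of class `permutation_null` with `min_lambdas`
#'   (length `n_reps`), `selected_lambda` (their median; for even
#'   `n_reps` the mean of the central pair), `n_reps`, `seed`,
#'   `penalty_kind`, `family`.
#' @export
permutation_lambda_null <- function(design, response, family = "poisson",
                                    penalty_kind = c("l1", "group"),
                                    groups = NULL, penalize_history = TRUE,
                                    n_reps = 200L, seed = 1L) {
  penalty_kind <- match.arg(penalty_kind)
  if (n_reps < 2) rlang::abort("n_reps must be at least 2")
  r <- as.numeric(response)
  bw <- attr(response, "bin_width_s") %||% 0.05
  kind <- attr(response, "kind") %||% "counts"
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- replicate(n_reps, sample.int(length(r)), simplify = FALSE)
  mins <- vapply(perms, function(p) {
    lambda_max(design, response_series(r[p], bw, kind), family,
               penalty_kind, groups, penalize_history)
  }, numeric(1))
  structure(list(min_lambdas = mins,
                 selected_lambda = stats::median(mins),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 penalty_kind = penalty_kind, family = family),
            class = "permutation_null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nested-model test for the spike-history contribution
#'
#' Compares an encoding model with spike-history covariates against the
#' reduced model without them, both fitted by unpenalized maximum
#' likelihood ([fit_glm_ml()]). For the Poisson spike-count model the
#' statistic is the deviance difference
#' `Delta D = D_reduced - D_full`, referred to a chi-square distribution
#' with as many degrees of freedom as history covariates. For the
#' Gaussian log high-gamma model an F statistic
#' `((SSE_r - SSE_f) / df1) / (SSE_f / df2)` with
#' `df2 = n_obs - n_covariates(full)` is used. A negative difference
#' (reduced fitting better, possible only numerically) is floored at zero
#' with a warning.
#'
#' @param full,reduced `strf_fit`s of the full (with history) and
#'   reduced (without) models. The reduced model's covariates must be a
#'   subset of the full's.
#' @param full_design,reduced_design the corresponding designs.
#' @param response the shared observed [response_series()].
#' @param test_kind `"chi2"` (deviance difference) or `"f"`.
#' @return A one-row tibble of class `nested_test`: `statistic`,
#'   `test_kind`, `df1`, `df2` (NA for chi2), `p_raw`, `p_adjusted`
#'   (equal to `p_raw` until [fdr_adjust()] is applied across tests).
#' @export
history_test <- function(full, reduced, full_design, reduced_design,
                         response, test_kind = c("chi2", "f")) {
  test_kind <- match.arg(test_kind)
  if (!all(reduced$catalog %in% full$catalog))
    rlang::abort("reduced model covariates must be a subset of the full model")
  df1 <- length(setdiff(full$catalog, reduced$catalog))
  if (df1 == 0) {
    stat <- 0; p <- 1; df2 <- NA_real_
  } else if (test_kind == "chi2") {
    d_full <- strf_deviance(full, full_design, response)
    d_red <- strf_deviance(reduced, reduced_design, response)
    stat <- d_red - d_full
    if (stat < 0) {
      rlang::warn("reduced model fit better than full; statistic floored at 0")
      stat <- 0
    }
    p <- stats::pchisq(stat, df = df1, lower.tail = FALSE)
    df2 <- NA_real_
  } else {
    r <- as.numeric(response)
    sse_f <- sum((r - as.numeric(full_design$X %*% full$b))^2)
    sse_r <- sum((r - as.numeric(reduced_design$X %*% reduced$b))^2)
    df2 <- length(r) - length(full$catalog)
    stat <- ((sse_r - sse_f) / df1) / (sse_f / df2)
    if (stat < 0) {
      rlang::warn("reduced model fit better than full; statistic floored at 0")
      stat <- 0
    }
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  }
  out <- tibble::tibble(statistic = stat, test_kind = test_kind,
                        df1 = df1, df2 = df2, p_raw = p, p_adjusted = p)
  class(out) <- c("nested_test", class(out))
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), as applied across
#' recording sites before declaring a spike-history contribution
#' significant.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
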