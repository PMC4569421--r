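test_that("STA matches the cross-moment definition", {
  s <- draw_chord_schedule(6, 200, 0.1, seed = 3)
  lags <- lag_grid(4)
  r0 <- response_series(rep(0, 200))
  expect_true(all(sta(s, r0, lags) == 0))
  # response equal to a lagged copy of one channel peaks at (f0, tau0)
  f0 <- 4; tau0 <- 2
  r <- response_series(c(rep(0, tau0), s[f0, 1:(200 - tau0)]))
  g <- sta(s, r, lags)
  expect_equal(which(g == max(g), arr.ind = TRUE)[1, ],
               c(row = f0, col = tau0 + 1))
  # brute-force expectation oracle on the same data
  oracle <- matrix(0, 6, 4)
  rr <- as.numeric(r)
  for (f in 1:6) for (tau in 0:3) {
    acc <- 0
    for (t in 1:200) if (t - tau >= 1) acc <- acc + rr[t] * s[f, t - tau]
    oracle[f, tau + 1] <- acc / 200
  }
  expect_equal(g, oracle)
})

test_that("STA of an independent response is within sampling noise", {
  n <- 5000; p <- 0.1; q <- 0.3
  s <- draw_chord_schedule(10, n, p, seed = 6)
  set.seed(7)
  r <- response_series(rbinom(n, 1, q))
  g <- sta(s, r, lag_grid(10), center = TRUE)
  se <- sqrt(p * q * (1 - p * q) / n)
  expect_gte(mean(abs(g) < 5 * se), 0.99)
})

test_that("negative log-likelihood values and gradients are correct", {
  s <- draw_chord_schedule(4, 60, 0.1, seed = 2)
  d <- build_design(s, lag_grid(3))
  r0 <- response_series(rep(0, 60))
  nl <- negloglik("poisson", d, r0, rep(0, ncol(d$X)))
  expect_equal(nl$value, 60)   # n_obs * exp(0), log r! convention omitted
  # gaussian with eta = y is exactly zero
  y <- response_series(rnorm(60), kind = "log_power")
  b <- c(mean(y), rep(0, ncol(d$X) - 1))
  expect_equal(negloglik("log_gaussian", d,
                         response_series(rep(b[1], 60), kind = "log_power"),
                         b)$value, 0)
  # central-difference oracle for both families
  set.seed(8)
  r <- response_series(rpois(60, 1))
  for (fam in c("poisson", "log_gaussian")) {
    resp <- if (fam == "poisson") r else y
    bb <- rnorm(ncol(d$X), sd = 0.1)
    an <- negloglik(fam, d, resp, bb)
    eps <- 1e-6
    num <- vapply(seq_along(bb), function(j) {
      bp <- bb; bp[j] <- bp[j] + eps
      bm <- bb; bm[j] <- bm[j] - eps
      (negloglik(fam, d, resp, bp)$value -
         negloglik(fam, d, resp, bm)$value) / (2 * eps)
    }, numeric(1))
    expect_equal(an$gradient, num, tolerance = 1e-5)
  }
  expect_error(negloglik("poisson", d,
                         response_series(rnorm(60), kind = "log_power"),
                         rep(0, ncol(d$X))), "integer")
})

test_that("proximal operators implement soft and group thresholding", {
  expect_equal(prox_l1(3, 1), 2)
  expect_equal(prox_l1(-0.5, 1), 0)
  v <- rnorm(10)
  expect_equal(prox_l1(v, 0), v)
  expect_equal(prox_l1(c(5, -3), 2, unpenalized = 1), c(5, -1))
  # group (3, 4): norm exactly 5
  expect_equal(prox_group(c(3, 4), 5, c(1L, 1L)), c(0, 0))
  expect_equal(prox_group(c(3, 4), 2.5, c(1L, 1L)), c(1.5, 2.0))
  expect_equal(prox_group(v, 0, rep(1L, 10)), v)
  # group id 0 passes through
  expect_equal(prox_group(c(7, 3, 4), 5, c(0L, 1L, 1L)), c(7, 0, 0))
})

test_that("unpenalized proximal fit matches the IRLS oracle", {
  sim <- small_sim(seed = 21, n_channels = 8, n_bins = 500, n_lags = 4)
  d <- build_design(sim$schedule, sim$lags, sim$counts, n_history = 2)
  opts <- solver_options(max_iter = 60000, tol = 1e-13)
  for (fam in c("poisson", "log_gaussian")) {
    resp <- if (fam == "poisson") sim$counts
            else response_series(log1p(as.numeric(sim$counts)) +
                                   rnorm(500, sd = 0.2), kind = "log_power")
    fit <- fit_penalized_glm(d, resp, fam, penalty_spec("none"), opts)
    expect_true(fit$converged)
    Xd <- as.matrix(d$X)
    oracle <- if (fam == "poisson")
      suppressWarnings(glm.fit(Xd, as.numeric(resp),
                               family = poisson()))$coefficients
    else lm.fit(Xd, as.numeric(resp))$coefficients
    expect_lt(max(abs(fit$b - oracle)) / max(1, max(abs(oracle))), 1e-4)
  }
})

test_that("lambda at or above lambda_max yields the intercept-only model", {
  sim <- small_sim(seed = 22)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  for (kind in c("l1", "group")) {
    lm_ <- lambda_max(d, sim$counts, "poisson", kind,
                      if (kind == "group") gm)
    fit <- fit_penalized_glm(d, sim$counts, "poisson",
                             penalty_spec(kind, lm_ * 1.001,
                                          if (kind == "group") gm))
    expect_equal(fit$df, 1L)
    expect_true(all(fit$b[-1] == 0))
    expect_equal(fit$b[1], log(mean(sim$counts)), tolerance = 1e-6)
    fit_lo <- fit_penalized_glm(d, sim$counts, "poisson",
                                penalty_spec(kind, lm_ * 0.9,
                                             if (kind == "group") gm))
    expect_gt(fit_lo$df, 1L)
  }
})

test_that("gaussian L1 on an orthonormal design equals soft-thresholded OLS", {
  set.seed(30)
  n <- 120; p <- 12
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  X <- cbind(1, Q)
  d <- toy_design(X, n_freqs = p, n_lags = 1)
  beta_true <- c(0.5, rnorm(p))
  y <- response_series(as.numeric(X %*% beta_true) + rnorm(n, sd = 0.3),
                       kind = "log_power")
  lam <- 0.8
  fit <- fit_penalized_glm(d, y, "log_gaussian", penalty_spec("l1", lam),
                           solver_options(20000, 1e-12))
  yy <- as.numeric(y)
  ls <- as.numeric(crossprod(Q, yy - mean(yy)))
  closed <- sign(ls) * pmax(abs(ls) - lam, 0)
  expect_equal(fit$b[-1], closed, tolerance = 1e-5)
})

test_that("ISTA objective is monotone and solutions satisfy KKT", {
  sim <- small_sim(seed = 23)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  lmax <- lambda_max(d, sim$counts, "poisson", "group", gm)
  fit_i <- fit_penalized_glm(d, sim$counts, "poisson",
                             penalty_spec("group", 0.4 * lmax, gm),
                             solver_options(acceleration = "ista"))
  expect_true(all(diff(fit_i$objective_trace) <= 1e-9))
  fit_f <- fit_penalized_glm(d, sim$counts, "poisson",
                             penalty_spec("group", 0.4 * lmax, gm),
                             solver_options(tol = 1e-10))
  expect_lt(kkt_residual(fit_f, d, sim$counts), 1e-4)
  l1max <- lambda_max(d, sim$counts, "poisson", "l1")
  fit_l1 <- fit_penalized_glm(d, sim$counts, "poisson",
                              penalty_spec("l1", 0.4 * l1max),
                              solver_options(max_iter = 20000, tol = 1e-12))
  expect_lt(kkt_residual(fit_l1, d, sim$counts), 1e-4)
})

test_that("degrees of freedom decline monotonically along the lambda path", {
  sim <- small_sim(seed = 24)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  for (kind in c("l1", "group")) {
    lmax <- lambda_max(d, sim$counts, "poisson", kind,
                       if (kind == "group") gm)
    path <- exp(seq(log(lmax * 1.05), log(lmax * 0.01), length.out = 20))
    dfs <- vapply(path, function(l) {
      fit_penalized_glm(d, sim$counts, "poisson",
                        penalty_spec(kind, l,
                                     if (kind == "group") gm))$df
    }, integer(1))
    expect_true(all(diff(dfs) >= 0))  # path runs from large to small lambda
  }
})

test_that("group penalty produces all-or-none groups; L1 does not", {
  sim <- small_sim(seed = 25, amplitude = 2)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  lmax <- lambda_max(d, sim$counts, "poisson", "group", gm)
  fit_g <- fit_penalized_glm(d, sim$counts, "poisson",
                             penalty_spec("group", 0.3 * lmax, gm))
  gv <- vectorize_strf(gm$group_id)
  bg <- fit_g$b[-1]
  frac_nz <- tapply(bg != 0, gv, mean)
  expect_true(all(frac_nz %in% c(0, 1)))
  expect_true(any(frac_nz == 0) && any(frac_nz == 1))
  l1max <- lambda_max(d, sim$counts, "poisson", "l1")
  fit_1 <- fit_penalized_glm(d, sim$counts, "poisson",
                             penalty_spec("l1", 0.3 * l1max))
  frac1 <- tapply(fit_1$b[-1] != 0, gv, mean)
  expect_true(any(frac1 > 0 & frac1 < 1))
})

test_that("deviance follows the saturated-model definition", {
  s <- draw_chord_schedule(2, 3, p_onset = 0, seed = 1)
  d <- build_design(s, lag_grid(1))
  r <- response_series(c(1, 2, 3))
  ml <- fit_glm_ml(d, r, "poisson")   # intercept only: stim cols all zero
  rbar <- 2
  hand <- 2 * sum(c(1, 2, 3) * log(c(1, 2, 3) / rbar) - (c(1, 2, 3) - rbar))
  expect_equal(strf_deviance(ml, d, r), hand, tolerance = 1e-8)
  # saturated poisson fit has zero deviance
  sat <- ml; sat$b <- c(0, rep(0, ncol(d$X) - 1))
  sat_d <- d
  sat_d$X[, 1] <- log(c(1, 2, 3))  # eta = log r via the "intercept" column
  sat$b[1] <- 1
  expect_equal(strf_deviance(sat, sat_d, r), 0)
  # gaussian deviance is the residual sum of squares; perfect fit -> 0
  y <- response_series(c(0.5, 0.5, 0.5), kind = "log_power")
  mg <- fit_glm_ml(d, y, "log_gaussian")
  expect_equal(strf_deviance(mg, d, y), 0, tolerance = 1e-12)
})

test_that("prediction and count smoothing behave as documented", {
  s <- draw_chord_schedule(3, 40, p_onset = 0, seed = 1)
  d <- build_design(s, lag_grid(2))
  r <- response_series(rpois(40, 2))
  fit <- fit_penalized_glm(d, r, "poisson",
                           penalty_spec("l1", 1e6))  # intercept only
  pred <- predict(fit, d)
  expect_equal(pred, rep(mean(r), 40), tolerance = 1e-6)
  expect_equal(smooth_counts(response_series(rep(3, 100))),
               rep(3, 100), tolerance = 1e-6)
  d2 <- build_design(s, lag_grid(3))
  expect_error(predict(fit, d2), "catalog")
  expect_error(smooth_counts(rep(1, 10)), "rate_hz")
})
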