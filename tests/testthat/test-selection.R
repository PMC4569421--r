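test_that("closed-form lambda_max matches hand KKT and a path-search oracle", {
  # gaussian, single stimulus column x, y = x: lambda_max = |x'(y - ybar)|
  s <- draw_chord_schedule(1, 100, 0.2, seed = 9)
  d <- build_design(s, lag_grid(1))
  x <- as.numeric(s[1, ])
  y <- response_series(x, kind = "log_power")
  expect_equal(lambda_max(d, y, "log_gaussian", "l1"),
               abs(sum(x * (x - mean(x)))))
  # response carrying no signal, exactly mean-centered: lambda_max = 0
  y0 <- response_series(rep(2, 100), kind = "log_power")
  expect_equal(lambda_max(d, y0, "log_gaussian", "l1"), 0)

  # equivalence with a 31-point log-spaced path search on random instances
  for (seed in 1:10) {
    sim <- small_sim(seed = seed + 40, n_channels = 5, n_bins = 300,
                     n_lags = 3)
    d_ <- build_design(sim$schedule, sim$lags)
    kind <- if (seed %% 2 == 0) "l1" else "group"
    gm <- if (kind == "group") build_group_map(5, 3, c(2, 2))
    lm_closed <- lambda_max(d_, sim$counts, "poisson", kind, gm)
    path <- exp(seq(log(lm_closed * 3), log(lm_closed / 3),
                    length.out = 31))
    dfs <- vapply(path, function(l) {
      fit_penalized_glm(d_, sim$counts, "poisson",
                        penalty_spec(kind, l, gm))$df
    }, integer(1))
    lm_path <- path[max(which(dfs == 1L))]  # smallest all-zeroing grid point
    step <- path[1] / path[2]
    expect_lt(lm_path / lm_closed, step^1.01)
    expect_gt(lm_path / lm_closed, 1 / step^1.01)
  }
})

test_that("lambda_max brackets the support boundary", {
  sim <- small_sim(seed = 51)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  for (kind in c("l1", "group")) {
    lm_ <- lambda_max(d, sim$counts, "poisson", kind,
                      if (kind == "group") gm)
    hi <- fit_penalized_glm(d, sim$counts, "poisson",
                            penalty_spec(kind, lm_ * (1 + 1e-3),
                                         if (kind == "group") gm))
    lo <- fit_penalized_glm(d, sim$counts, "poisson",
                            penalty_spec(kind, lm_ * 0.9,
                                         if (kind == "group") gm))
    expect_true(all(hi$b[-1] == 0))
    expect_gt(sum(lo$b[-1] != 0), 0)
  }
})

test_that("permutation null selects the median all-zeroing weight", {
  sim <- small_sim(seed = 52)
  d <- build_design(sim$schedule, sim$lags)
  gm <- build_group_map(10, 6, c(4, 4))
  pn <- permutation_lambda_null(d, sim$counts, "poisson", "group", gm,
                                n_reps = 50, seed = 5)
  expect_length(pn$min_lambdas, 50)
  expect_equal(pn$selected_lambda, median(pn$min_lambdas))
  # reproducible given the seed
  pn2 <- permutation_lambda_null(d, sim$counts, "poisson", "group", gm,
                                 n_reps = 50, seed = 5)
  expect_identical(pn$min_lambdas, pn2$min_lambdas)
  # a constant response is permutation-invariant
  cst <- response_series(rep(1, length(sim$counts)))
  pc <- permutation_lambda_null(d, cst, "poisson", "group", gm,
                                n_reps = 10, seed = 1)
  expect_equal(max(pc$min_lambdas) - min(pc$min_lambdas), 0)
  expect_equal(pc$selected_lambda, pc$min_lambdas[1])
  expect_error(permutation_lambda_null(d, cst, n_reps = 1), "n_reps")
  # two seeds agree to within 10% at n_reps = 200
  pa <- permutation_lambda_null(d, sim$counts, "poisson", "group", gm,
                                n_reps = 200, seed = 11)
  pb <- permutation_lambda_null(d, sim$counts, "poisson", "group", gm,
                                n_reps = 200, seed = 12)
  expect_lt(abs(pa$selected_lambda - pb$selected_lambda) /
              pa$selected_lambda, 0.1)
})

test_that("nested history tests compute the right statistics and tails", {
  sim <- small_sim(seed = 53, alpha = c(-0.8, -0.4))
  fd <- build_design(sim$schedule, sim$lags, sim$counts, n_history = 2)
  rd <- build_design(sim$schedule, sim$lags)
  full <- fit_glm_ml(fd, sim$counts, "poisson")
  red <- fit_glm_ml(rd, sim$counts, "poisson")
  tt <- history_test(full, red, fd, rd, sim$counts, "chi2")
  expect_equal(tt$df1, 2)
  expect_equal(tt$statistic,
               strf_deviance(red, rd, sim$counts) -
                 strf_deviance(full, fd, sim$counts))
  expect_equal(tt$p_raw,
               pchisq(tt$statistic, 2, lower.tail = FALSE))
  # identical models give a null result
  t0 <- history_test(full, full, fd, fd, sim$counts, "chi2")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_raw, 1)
  # F test on the gaussian family
  y <- response_series(as.numeric(sim$counts) + rnorm(800, sd = 0.5),
                       kind = "log_power")
  fdg <- build_design(sim$schedule, sim$lags, y, n_history = 2,
                      include_current_count = TRUE)
  fullg <- fit_glm_ml(fdg, y, "log_gaussian")
  redg <- fit_glm_ml(rd, y, "log_gaussian")
  tf <- history_test(fullg, redg, fdg, rd, y, "f")
  sse_f <- sum((as.numeric(y) - as.numeric(fdg$X %*% fullg$b))^2)
  sse_r <- sum((as.numeric(y) - as.numeric(rd$X %*% redg$b))^2)
  df2 <- 800 - length(fullg$catalog)
  expect_equal(tf$statistic, ((sse_r - sse_f) / 2) / (sse_f / df2))
  expect_equal(tf$df2, df2)
  expect_equal(tf$p_raw, pf(tf$statistic, 2, df2, lower.tail = FALSE))
  expect_error(history_test(red, full, rd, fd, sim$counts, "chi2"),
               "subset")
})

test_that("history test has power against a true history dependence", {
  map <- make_cochleotopic_map(10, 200, 8000)
  lags <- lag_grid(10)
  # positive (self-exciting) history at a low baseline rate keeps the
  # process stable while giving the test real signal
  truth <- make_bump_strf(map, lags, center_freq_hz = 1000,
                          center_lag_s = 0.2, amplitude = 0.8,
                          beta0 = log(0.15), alpha = c(0.35, 0.18),
                          history_lags = 1:2)
  rej <- vapply(1:15, function(i) {
    s <- draw_chord_schedule(10, 6000, 0.02, seed = i + 300)
    r <- simulate_counts(truth, s, seed = i + 700)
    fd <- build_design(s, lags, r, n_history = 15)
    rd <- build_design(s, lags)
    tt <- history_test(fit_glm_ml(fd, r), fit_glm_ml(rd, r), fd, rd, r,
                       "chi2")
    tt$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Benjamini-Hochberg adjustment matches hand computation", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  # m = 4 ladder: adjusted p = max over steps of p_(i) * m / i, monotone
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.5, 0.9)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})
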