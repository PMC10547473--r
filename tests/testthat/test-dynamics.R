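test_that("trace_cv matches the hand-computed sd/mean", {
  # constant trace: CV = 0
  tt <- seq(0, 600, 6)
  flat <- cell_trace(tt, rep(2, length(tt)))
  expect_equal(trace_cv(flat, 0), 0)
  # window values (1,3,1,3): sample sd sqrt(4/3) over mean 2
  tr <- cell_trace(seq(120, 138, 6), c(1, 3, 1, 3))
  cv <- trace_cv(tr, 0, window = c(2, 6), stride = 1, min_points = 4)
  expect_equal(cv, sqrt(4 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(cv, 3), 0.577)
  # nonpositive window mean flagged, not an error
  neg <- cell_trace(tt, rep(-1, length(tt)))
  out <- trace_cv(neg, 0)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "nonpositive")
  expect_error(trace_cv(cell_trace(seq(0, 30, 6), rep(1, 6)), 0), "points")
})

test_that("striding reduces the CV of alternating point-to-point noise", {
  # pure alternating +/- noise at full rate: stride 2 samples only one phase
  tt <- seq(0, 600, 6)
  v <- 2 + 0.5 * rep(c(1, -1), length.out = length(tt))
  tr <- cell_trace(tt, v)
  cv2 <- trace_cv(tr, 0, stride = 2)
  cv1 <- trace_cv(tr, 0, stride = 1)
  expect_lt(cv2, cv1)
  expect_equal(cv2, 0)
})

test_that("CV is scale-invariant but not shift-invariant", {
  set.seed(13)
  tt <- seq(0, 600, 6)
  tr <- cell_trace(tt, 2 + cumsum(rnorm(length(tt), 0, 0.05)))
  cv <- trace_cv(tr, 0)
  sc <- tr; sc$value <- 4 * tr$value
  expect_equal(trace_cv(sc, 0), cv)
  sh <- tr; sh$value <- tr$value + 5
  expect_false(isTRUE(all.equal(trace_cv(sh, 0), cv)))
})

test_that("cohort_cv summarizes groups and orders planted noise scales", {
  mk <- function(noise, cond, seed) {
    cfg <- sim_config(n_cells = 60, duration = 420, condition = cond,
                      latent_params = list(baseline_aa = 0.05, baseline_gf = 1,
                                           noise_sd = noise),
                      reporter_params = list(r = reporter_spec(noise_sd = 0.02)),
                      missing_rate = 0, seed = seed)
    as.data.frame(simulate_trajectories(cfg)$traces)
  }
  lo <- mk(0.05, "low", 1); lo$cell_id <- paste0("lo_", lo$cell_id)
  hi <- mk(0.15, "high", 2); hi$cell_id <- paste0("hi_", hi$cell_id)
  set <- trajectory_set(rbind(lo, hi))
  cc <- cohort_cv(set, t_perturb = 0)
  s <- cc$summary
  expect_lt(s$median_cv[s$group == "low"], s$median_cv[s$group == "high"])
  expect_true(all(s$n == 60))
  # identical constant traces: median CV = 0, IQR = 0
  flat <- set_from_traces(lapply(1:5, function(i)
    cell_trace(seq(0, 420, 6), rep(2, 71), cell_id = paste0("c", i),
               condition = "flat")))
  sf <- cohort_cv(flat, 0)$summary
  expect_equal(sf$median_cv, 0)
  expect_equal(sf$iqr_hi - sf$iqr_lo, 0)
})

test_that("cross-correlation finds exact lags and respects tie rules", {
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = 0.9), 120))
  cc0 <- cross_correlate_pair(x, x, max_lag = 10)
  expect_identical(cc0$best_lag, 0L)
  expect_equal(cc0$best_cor, 1)
  # delayed copy: optimal lag equals the shift, correlation 1 on overlap
  y <- c(rep(x[1], 2), head(x, -2))
  cc2 <- cross_correlate_pair(x, y, max_lag = 10)
  expect_identical(cc2$best_lag, 2L)
  expect_gt(cc2$best_cor, 0.999)
  # symmetry: corr(x, y at k) = corr(y, x at -k)
  z <- as.numeric(arima.sim(list(ar = 0.8), 120))
  ca <- cross_correlate_pair(x, z, 8)
  cb <- cross_correlate_pair(z, x, 8)
  expect_equal(ca$cor, rev(cb$cor))
  # detrending removes a shared linear drift that otherwise dominates
  set.seed(22)
  drift <- 0.05 * seq_len(120)
  a <- rnorm(120) + drift; b <- rnorm(120) + drift
  raw <- cross_correlate_pair(a, b, 5)
  det <- cross_correlate_pair(a, b, 5, detrend = TRUE)
  expect_gt(raw$best_cor, 0.5)        # drift-induced spurious coupling
  expect_lt(det$best_cor, 0.3)        # gone after detrending
  # zero-variance overlap undefined and excluded
  const <- rep(1, 120)
  ccc <- cross_correlate_pair(x, const, 5)
  expect_true(all(is.na(ccc$cor)))
  expect_true(is.na(ccc$best_lag))
})

test_that("independent white noise stays below the scrambled-null tail", {
  set.seed(77)
  x <- rnorm(80); y <- rnorm(80)
  cc <- cross_correlate_pair(x, y, 10)
  # empirical null: correlations of freshly simulated independent pairs
  null_best <- replicate(200, {
    a <- rnorm(80); b <- rnorm(80)
    cross_correlate_pair(a, b, 10)$best_cor
  })
  expect_lt(cc$best_cor, quantile(null_best, 0.99))
})

test_that("coupling analysis recovers planted lags and rejects unmatched ids", {
  cp <- simulate_coupled_reporters(starved_config(150, seed = 7), 2)
  s <- coupled_sets(cp)
  ca <- coupling_analysis(s$A, s$B, max_lag = 20, n_null = 200, seed = 11)
  expect_identical(ca$median_lag, 2L)
  # real-pair correlations exceed the scrambled null
  expect_gt(median(ca$cells$cor_at_median, na.rm = TRUE),
            median(ca$null, na.rm = TRUE))
  # single-cell input: median = that cell's lag
  one <- simulate_coupled_reporters(starved_config(1, seed = 3), 3)
  so <- coupled_sets(one)
  ca1 <- coupling_analysis(so$A, so$B, max_lag = 10, n_null = 0, seed = 1)
  expect_equal(as.numeric(ca1$median_lag), ca1$cells$best_lag[1])
  # unmatched ids rejected with the id list
  sb2 <- s$B[s$B$cell_id != "cell_0001", ]
  expect_error(coupling_analysis(s$A, trajectory_set(sb2), 10),
               "cell_0001")
})

test_that("scrambled null is seeded, centered, and never self-pairs", {
  mk <- function(seed) {
    cfg <- starved_config(40, duration = 480, noise_sd = 0.05, seed = seed)
    trajectory_set(simulate_trajectories(cfg)$traces)
  }
  sa <- mk(31); sb <- mk(32)
  n1 <- scrambled_null(sa, sb, n_pairs = 300, seed = 5)
  n2 <- scrambled_null(sa, sb, n_pairs = 300, seed = 5)
  expect_identical(n1, n2)
  # independent cells: null mean within 2 standard errors of 0
  se <- sd(n1, na.rm = TRUE) / sqrt(sum(is.finite(n1)))
  expect_lt(abs(mean(n1, na.rm = TRUE)), 2.5 * se + 0.02)
  expect_warning(scrambled_null(sa, sb, n_pairs = 40 * 39 + 1, seed = 1),
                 "replacement")
  expect_error(scrambled_null(trajectory_set(sa[sa$cell_id == "cell_0001", ]),
                              trajectory_set(sa[sa$cell_id == "cell_0001", ]),
                              10), ">= 2")
})

test_that("shared latent: real pairs exceed a null centered on the shared component", {
  # same latent mean, independent fluctuations: the null captures only the
  # population-shared component, real pairs add the cell-specific coupling
  cp <- simulate_coupled_reporters(starved_config(60, seed = 41,
                                                  noise_sd = 0.1), 0)
  s <- coupled_sets(cp)
  ca <- coupling_analysis(s$A, s$B, max_lag = 5, n_null = 500, seed = 2)
  expect_gt(median(ca$cells$cor_at_median, na.rm = TRUE),
            quantile(ca$null, 0.75, na.rm = TRUE))
})
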