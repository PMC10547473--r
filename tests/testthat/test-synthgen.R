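test_that("trajectory generation is seed-deterministic and validates input", {
  cfg <- sim_config(n_cells = 4, duration = 120, seed = 11,
                    missing_rate = 0.05)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a$traces$value, b$traces$value)
  expect_identical(a$traces$missing, b$traces$missing)
  expect_identical(a$truth$latent, b$truth$latent)

  expect_error(sim_config(n_cells = 0, duration = 100), "n_cells")
  expect_error(sim_config(n_cells = 2, duration = -5), "duration")
  expect_error(sim_config(n_cells = 2, duration = 100, sample_interval = 0),
               "sample_interval")
  expect_error(treatment_schedule(10, "aa", 1.5), "doses")
  expect_error(treatment_schedule(c(10, 10), c("aa", "aa"), c(0, 1)),
               "increasing")
})

test_that("noise-free step dose gives a deterministic monotone step", {
  cfg <- sim_config(
    n_cells = 3, duration = 300,
    treatment_schedule = treatment_schedule(60, "aa", 1),
    latent_params = list(noise_sd = 0, baseline_aa = 0, baseline_gf = 1),
    reporter_params = list(TFEB_TR = reporter_spec(noise_sd = 0)),
    missing_rate = 0, seed = 1)
  sim <- simulate_trajectories(cfg)
  for (tr in split_traces(sim$traces)) {
    expect_false(any(tr$missing))
    expect_true(all(diff(tr$value) >= 0))         # monotone step
    expect_length(unique(round(tr$value, 12)), 2L)  # exactly two levels
  }
  # all cells identical in the noise-free limit
  vals <- vapply(split_traces(sim$traces), function(tr) tr$value,
                 numeric(length(sim$truth$time)))
  expect_true(all(vals == vals[, 1L]))
})

test_that("mean post-step reporter level increases strictly with dose", {
  # oracle: group means computed directly from the generated table
  means <- vapply(c(0, 0.25, 0.5, 1), function(d) {
    cfg <- sim_config(n_cells = 200, duration = 300,
                      treatment_schedule = treatment_schedule(60, "aa", d),
                      latent_params = list(baseline_gf = 1),
                      seed = 1)
    s <- simulate_trajectories(cfg)$traces
    mean(s$value[s$time_min > 120 & !s$missing])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("trace count and missing fraction match the configuration", {
  cfg <- sim_config(n_cells = 60, duration = 600, missing_rate = 0.05,
                    reporter_params = list(a = reporter_spec(),
                                           b = reporter_spec()),
                    seed = 4)
  sim <- simulate_trajectories(cfg)
  traces <- split_traces(sim$traces)
  expect_length(traces, 60L * 2L)
  # observed missing fraction within 4 binomial sd of the rate (gap
  # capping removes a negligible fraction of long runs)
  n <- nrow(sim$traces)
  p_hat <- mean(sim$traces$missing)
  expect_lt(abs(p_hat - 0.05), 4 * sqrt(0.05 * 0.95 / n) + 0.002)
  # no missing run exceeds max_gap
  runs <- vapply(traces, function(tr) mtordyn:::max_run(tr$missing), 1L)
  expect_true(all(runs <= cfg$max_gap))
})

test_that("coupled reporters: zero-lag zero-noise channels are identical", {
  cfg <- sim_config(n_cells = 5, duration = 300,
                    latent_params = list(baseline_aa = 0.1, baseline_gf = 1),
                    reporter_params = list(r = reporter_spec(noise_sd = 0)),
                    missing_rate = 0, seed = 2)
  cp <- simulate_coupled_reporters(cfg, 0)
  s <- coupled_sets(cp)
  for (id in unique(s$A$cell_id)) {
    a <- s$A$value[s$A$cell_id == id]
    b <- s$B$value[s$B$cell_id == id]
    expect_equal(cor(a, b), 1)
  }
  expect_error(simulate_coupled_reporters(cfg, 1000), "lag_steps")
})

test_that("coupled reporters: noise-free planted lag is exact downstream", {
  cfg <- sim_config(n_cells = 10, duration = 600,
                    latent_params = list(baseline_aa = 0.05, baseline_gf = 1),
                    reporter_params = list(r = reporter_spec(noise_sd = 0)),
                    missing_rate = 0, seed = 6)
  cp <- simulate_coupled_reporters(cfg, 2)
  s <- coupled_sets(cp)
  ca <- coupling_analysis(s$A, s$B, max_lag = 10, n_null = 50, seed = 1)
  expect_true(all(ca$cells$best_lag == 2))
  expect_identical(ca$median_lag, 2L)
})

test_that("stain table respects target_r2 bounds and rejects bad input", {
  cfg <- sim_config(n_cells = 300, duration = 10, seed = 8)
  expect_error(simulate_stain_table(cfg, 16, -0.1), "target_r2")
  expect_error(simulate_stain_table(cfg, 16, 1.1), "target_r2")
  expect_error(simulate_stain_table(cfg, 1, 0.5), "n_conditions")
  st <- simulate_stain_table(cfg, 16, 0.6)
  expect_s3_class(st$table, "stain_table")
  expect_equal(nrow(st$table), 300L)
  expect_true(all(c("p4EBP1", "t4EBP1", "pS6_235_236", "pS6_240_244", "tS6",
                    "pS6K_389", "pULK1_757", "TFEB_CN", "pAKT_473", "tAKT",
                    "pGSK3B_9", "tGSK3B", "pACC_79", "pRb_249_252", "tTFEB",
                    "OPP") %in% names(st$table)))
  expect_true(all(st$table$OPP > 0))
  expect_equal(st$truth$target_r2, 0.6)
  # determinism
  st2 <- simulate_stain_table(cfg, 16, 0.6)
  expect_identical(st$table$OPP, st2$table$OPP)
})

test_that("image generator places cells, reports truth, rejects overfull fields", {
  im <- simulate_images(6, nucleus_radius = 8, intensities = c(100, 50),
                        noise_sd = 0, seed = 1)
  expect_equal(max(im$truth$labels), 6L)
  # ground-truth C/N measured on truth masks is exact in the noise-free case
  masks <- make_compartment_masks(im$truth$labels, erode_px = 2, ring_px = 5)
  meas <- measure_cells(im$reporter, masks)
  expect_equal(meas$cn, rep(0.5, 6))
  # uniform reporter intensity gives C/N = 1
  uni <- matrix(7, nrow(im$reporter), ncol(im$reporter))
  expect_equal(measure_cells(uni, masks)$cn, rep(1, 6))
  expect_error(simulate_images(50, field = c(60, 60)), "cannot place")
  expect_error(simulate_images(3, nucleus_radius = 2), "radius")
})
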