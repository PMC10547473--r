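test_that("normalize_stains builds phospho/total ratios with stated policy", {
  tab <- data.frame(cell_id = "c1", glucose = 1, glutamine = 1, insulin = 1,
                    aa = 1, p4EBP1 = 2, t4EBP1 = 4, pS6_235_236 = 3,
                    pS6_240_244 = 6, tS6 = 3, pAKT_473 = 1, tAKT = 2,
                    pGSK3B_9 = 5, tGSK3B = 10)
  out <- normalize_stains(tab)
  expect_equal(out$p4EBP1_norm, 0.5)
  expect_equal(out$pS6_235_236_norm, 1)
  expect_equal(out$pS6_240_244_norm, 2)
  # zero total: ratio missing, cell retained
  tab2 <- tab; tab2$t4EBP1 <- 0
  out2 <- normalize_stains(tab2)
  expect_true(is.na(out2$p4EBP1_norm))
  expect_equal(out2$pAKT_473_norm, 0.5)
  # scaling a total by k scales its ratio by 1/k exactly
  tab3 <- tab; tab3$tS6 <- tab$tS6 * 7
  out3 <- normalize_stains(tab3)
  expect_equal(out3$pS6_235_236_norm, out$pS6_235_236_norm / 7)
  # missing matching total column rejected naming the pair
  expect_error(normalize_stains(tab[, setdiff(names(tab), "tAKT")]),
               "pAKT_473 / tAKT")
})

test_that("PLSR with one predictor equals squared Pearson correlation", {
  set.seed(6)
  x <- matrix(rnorm(400), ncol = 1)
  y <- 2 * x[, 1] + rnorm(400, 0, 1)
  rep <- plsr_variance_explained(x, y, "single-cell", seed = 1,
                                 log_transform = FALSE)
  expect_equal(rep$r2_insample, 100 * cor(x[, 1], y)^2, tolerance = 1e-8)
  expect_identical(rep$dF, 1L)
})

test_that("PLSR handles the exact-linear and independent extremes", {
  set.seed(16)
  X <- matrix(rnorm(2000), ncol = 4)
  y <- X %*% c(1, -2, 0.5, 3)
  rep <- plsr_variance_explained(X, as.numeric(y), "single-cell", seed = 1,
                                 log_transform = FALSE)
  expect_gt(rep$r2_cv, 99.5)
  expect_equal(rep$r2_insample, 100, tolerance = 1e-6)
  # independent output: cross-validated R2 <= 2%
  y0 <- rnorm(5000)
  X0 <- matrix(rnorm(5000 * 5), ncol = 5)
  rep0 <- plsr_variance_explained(X0, y0, "single-cell", seed = 2,
                                  log_transform = FALSE)
  expect_lt(rep0$r2_cv, 2)
})

test_that("individually weak predictors can be jointly strong", {
  # distributed loadings: each predictor explains ~1/5 of the signal
  set.seed(26)
  n <- 3000
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- paste0("s", 1:4)
  y <- rowSums(X) + rnorm(n, 0, 1)  # total R2 = 4/5
  joint <- plsr_variance_explained(X, y, "single-cell", seed = 3,
                                   log_transform = FALSE)$r2_cv
  singles <- vapply(1:4, function(j)
    plsr_variance_explained(X[, j, drop = FALSE], y, "single-cell", seed = 3,
                            log_transform = FALSE)$r2_cv, numeric(1))
  expect_gt(joint, max(singles) + 10)
})

test_that("population-average collapse is invariant to cell order", {
  cfg <- sim_config(n_cells = 800, duration = 10, seed = 18)
  st <- simulate_stain_table(cfg, 16, 0.6)$table
  X <- st[, stain_predictor_columns(st)]
  cond <- interaction(st$glucose, st$glutamine, st$insulin, st$aa, drop = TRUE)
  r1 <- plsr_variance_explained(X, st$OPP, "population-average",
                                conditions = cond, seed = 4)
  perm <- sample(nrow(st))
  r2 <- plsr_variance_explained(X[perm, ], st$OPP[perm], "population-average",
                                conditions = cond[perm], seed = 4)
  expect_equal(r1$r2_cv, r2$r2_cv, tolerance = 1e-9)
  expect_identical(r1$n, 16L)
  expect_identical(r1$n_folds, 16L)  # leave-one-condition-out
})

test_that("subset_screen reports every subset at every level", {
  cfg <- sim_config(n_cells = 1600, duration = 10, seed = 19)
  st <- simulate_stain_table(cfg, 16, 0.6)$table
  sc <- subset_screen(st, seed = 2)
  expect_setequal(sc$subset, c("all_stains", "norm_mtorc1"))
  expect_setequal(sc$level, c("population-average", "single-cell"))
  expect_equal(nrow(sc), 4L)
  # nestedness: the full stain set beats a single stain on the same data
  one <- plsr_variance_explained(st[, "pULK1_757", drop = FALSE], st$OPP,
                                 "single-cell", seed = 2)
  all_sc <- sc[sc$subset == "all_stains" & sc$level == "single-cell", ]
  expect_gte(all_sc$r2_insample, one$r2_insample)
  expect_gt(all_sc$r2_cv, one$r2_cv)
  expect_error(subset_screen(st, subsets = list(bad = "nope")), "unknown")
})

test_that("recovered R2 tracks target_r2 within 5 points (10 seeds)", {
  for (s in 1:10) {
    cfg <- sim_config(n_cells = 5000, duration = 10, seed = s)
    st <- simulate_stain_table(cfg, 16, 0.6)
    X <- st$table[, stain_predictor_columns(st$table)]
    rep <- plsr_variance_explained(X, st$table$OPP, "single-cell",
                                   seed = 100 + s)
    expect_lt(abs(rep$r2_cv - 60), 5)
  }
})

test_that("theil_sen matches the explicit median-of-pairwise-slopes oracle", {
  # exact line
  x <- 1:10
  fit <- theil_sen(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  # two points: slope = dy/dx exactly
  f2 <- theil_sen(c(1, 3), c(5, 9))
  expect_equal(f2$slope, 2)
  # 9 collinear points + one gross outlier: slope still 2; verify against
  # the explicit enumeration of all 45 pairwise slopes
  x9 <- 1:10
  y9 <- 2 * x9; y9[10] <- 500
  fit9 <- theil_sen(x9, y9)
  slopes <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    slopes <- c(slopes, (y9[j] - y9[i]) / (x9[j] - x9[i]))
  }
  expect_length(slopes, 45L)
  expect_equal(fit9$slope, median(slopes))
  expect_equal(fit9$slope, 2)
  expect_error(theil_sen(rep(1, 5), 1:5), "distinct")
})

test_that("theil_sen resists up to ~29% outlier contamination (property)", {
  set.seed(33)
  for (i in 1:10) {
    n <- 40
    x <- sort(runif(n, 0, 10))
    y <- 3 * x - 2
    k <- 11  # 27.5% contamination
    idx <- sample(n, k)
    y[idx] <- y[idx] + runif(k, 50, 100)
    fit <- theil_sen(x, y)
    expect_lt(abs(fit$slope - 3), 0.35)
  }
})

test_that("welch_test matches the reference implementation", {
  expect_error(welch_test(1, 1:3), "n >= 2")
  expect_error(welch_test(rep(1, 4), rep(2, 4)), "zero variance")
  # identical samples: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)
  # oracle: stats::t.test with var.equal = FALSE
  set.seed(44)
  for (i in 1:10) {
    a <- rnorm(30, 0, 1); b <- rnorm(25, 0.5, 2)
    w <- welch_test(a, b)
    ref <- t.test(a, b, var.equal = FALSE)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$parameter, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p.value, ref$p.value, tolerance = 1e-12)
  }
  # well-separated samples: p < 1e-6
  set.seed(45)
  a <- rnorm(50); b <- rnorm(50, 10)
  expect_lt(welch_test(a, b)$p.value, 1e-6)
  # antisymmetry
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p.value, w2$p.value)
})
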