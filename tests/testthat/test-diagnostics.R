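test_that("weighted VIF is 1 for orthogonal predictors and Inf for duplicates", {
  # orthogonal, mean-zero predictors via orthogonal polynomials
  Z <- cbind(1, poly(1:60, 4))
  colnames(Z) <- c("(Intercept)", "T", "T2", "P", "P2")
  v <- weighted_vif(Z)
  expect_equal(unname(v$vif[1, ]), rep(1, 4), tolerance = 1e-8)

  dup <- Z
  dup[, "T2"] <- dup[, "T"]
  expect_true(is.infinite(weighted_vif(dup)$vif_max))
})

test_that("uniform-weight VIF matches the standard regression routine", {
  skip_if_not_installed("car")
  sim <- noisy_cell(seed = 37, M = 120)
  X <- build_design(sim$cell$T, sim$cell$P)
  ours <- weighted_vif(X)$vif[1, ]
  df <- data.frame(y = sim$cell$N, T = X[, 2], T2 = X[, 3],
                   P = X[, 4], P2 = X[, 5])
  ref <- car::vif(lm(y ~ T + T2 + P + P2, data = df))
  expect_equal(unname(ours), unname(ref[c("T", "T2", "P", "P2")]),
               tolerance = 1e-8)
})

test_that("per-month kernel-weighted VIFs are finite on realistic designs", {
  sim <- noisy_cell(seed = 41, M = 96)
  X <- build_design(sim$cell$T, sim$cell$P)
  v <- weighted_vif(X, kernel_spec(12, 12))
  expect_equal(dim(v$vif), c(96L, 4L))
  expect_true(all(is.finite(v$vif)))
  expect_gte(min(v$vif), 1)
})

test_that("Durbin-Watson reproduces hand calculations and symmetries", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  set.seed(1)
  for (i in 1:10) {
    e <- rnorm(50)
    expect_equal(durbin_watson(e), durbin_watson(rev(e)), tolerance = 1e-12)
    expect_true(durbin_watson(e) >= 0 && durbin_watson(e) <= 4)
  }
  expect_warning(dw <- durbin_watson(rep(0, 10)), "all-zero")
  expect_true(is.na(dw))
  expect_error(durbin_watson(c(1, 2)), "at least 3")
})

test_that("Cochrane-Orcutt leaves an already-white fit unchanged", {
  cell <- exact_cell(M = 72)     # zero residuals, rho estimate 0
  expect_warning(co <- cochrane_orcutt(cell, kernel_spec(6, 6)),
                 "all-zero residual")   # DW undefined on exact data
  expect_equal(co$iterations, 1L)
  expect_true(co$converged)
  expect_false(co$fit$corrected)
  expect_equal(co$fit$beta_t, fit_lwlr(cell, kernel_spec(6, 6))$beta_t)

  # white-noise residuals with a generous tolerance: no transform either
  sim <- noisy_cell(seed = 43, M = 120)
  co2 <- cochrane_orcutt(sim$cell, kernel_spec(12, 12), tol = 0.2)
  expect_equal(co2$iterations, 1L)
  expect_false(co2$fit$corrected)
})

test_that("Cochrane-Orcutt estimates AR(1) residual correlation sensibly", {
  rhos <- vapply(1:8, function(s) {
    sim <- make_cell(synthetic_truth(rho_eps = 0.6, sigma_eps = 0.02,
                                     seed = 200 + s), M = 240)
    co <- cochrane_orcutt(sim$cell, kernel_spec(12, 12))
    expect_true(co$converged)
    expect_equal(co$fit$t_index, 2:240)
    # corrected fit re-expressed against the original data
    X <- build_design(sim$cell$T, sim$cell$P)[-1, ]
    expect_equal(co$fit$fitted, rowSums(X * co$fit$beta_t), tolerance = 1e-12)
    co$rho
  }, numeric(1))
  # sanity band only; the precise consistency check runs in the
  # acceptance suite with 50 seeds
  expect_gt(mean(rhos), 0.4)
  expect_lt(mean(rhos), 0.75)
})

test_that("Delta-P is small for normal samples and larger for uniform ones", {
  set.seed(7)
  dp_norm <- replicate(20, delta_p(rnorm(5000)))
  expect_lt(max(dp_norm), 0.05)

  set.seed(11)
  wins <- replicate(50, {
    delta_p(runif(240, -3, 3)) > delta_p(rnorm(240))
  })
  expect_gte(mean(wins), 0.9)
})

test_that("Delta-P is invariant under affine transformation of residuals", {
  set.seed(13)
  e <- rnorm(240, 5, 0.01)
  expect_equal(delta_p(e), delta_p(-2.5 * e + 7), tolerance = 1e-12)
  expect_error(delta_p(rep(1, 100)), "zero variance")
  expect_error(delta_p(rnorm(10)), "at least 30")
})

test_that("tau calibration is reproducible and shrinks with series length", {
  a <- calibrate_tau(n_datasets = 150, series_length = 240, seed = 5)
  b <- calibrate_tau(n_datasets = 150, series_length = 240, seed = 5)
  expect_identical(a$mean_dp, b$mean_dp)
  expect_equal(a$tau, round(a$mean_dp, 2))

  long <- calibrate_tau(n_datasets = 100, series_length = 2000, seed = 5)
  expect_lt(long$mean_dp, a$mean_dp)   # KDE consistency
  expect_error(calibrate_tau(n_datasets = 50), ">= 100")
})

test_that("the normality decision uses a strict threshold", {
  expect_true(normality_test(0.03, 0.04))
  expect_false(normality_test(0.05, 0.04))
  expect_false(normality_test(0.04, 0.04))   # boundary: strict inequality
  expect_error(normality_test(NA_real_, 0.04), "finite")
})
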