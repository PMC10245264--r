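test_that("global fit recovers exact coefficients and flags degeneracy", {
  beta <- c(0.1, 0.02, 1e-4, 0.001, -1e-6)
  cell <- exact_cell(M = 60, beta = beta)
  gl <- fit_global(cell)
  expect_equal(unname(gl$beta), beta, tolerance = 1e-8)
  expect_equal(gl$Rg2, 1, tolerance = 1e-8)
  expect_equal(gl$fitted + gl$residuals, cell$N)

  # constant NDVI: intercept carries everything, R^2 undefined
  flat <- cell_series(rep(0.4, 48), cell$T[1:48], cell$P[1:48])
  gf <- fit_global(flat)
  expect_equal(unname(gf$beta[1]), 0.4, tolerance = 1e-8)
  expect_equal(unname(gf$beta[2:5]), rep(0, 4), tolerance = 1e-8)
  expect_true(gf$degenerate)
  expect_true(is.na(gf$Rg2))
})

test_that("global fit matches an independent normal-equations solve", {
  sim <- noisy_cell(seed = 11, M = 120)
  gl <- fit_global(sim$cell)
  X <- build_design(sim$cell$T, sim$cell$P)
  beta_ne <- drop(solve(crossprod(X), crossprod(X, sim$cell$N)))
  expect_equal(unname(gl$beta), unname(beta_ne), tolerance = 1e-8)
})

test_that("local fit matches weighted least squares and is weight-scale free", {
  sim <- noisy_cell(seed = 3, M = 96)
  cell <- sim$cell
  X <- build_design(cell$T, cell$P)
  spec <- kernel_spec(6, 12)
  for (t in c(1L, 20L, 48L, 96L)) {
    loc <- fit_local(t, cell, spec)
    # oracle: R's weighted LS with the weights scaled by an arbitrary factor
    w <- kernel_weights(t, cell$M, spec) * 7.3
    ora <- lm.wfit(X, cell$N, w)$coefficients
    expect_equal(unname(loc$beta), unname(ora), tolerance = 1e-8)
    expect_false(loc$singular)
  }
})

test_that("local fit minimises the weighted objective (generic optimiser)", {
  set.seed(42)
  t_idx <- 12L
  M <- 24L
  Tv <- 10 + 8 * cos(2 * pi * (1:M - 7) / 12) + rnorm(M)
  Pv <- pmax(0, 70 + 50 * cos(2 * pi * (1:M - 7) / 12) + rnorm(M, 0, 15))
  N <- 0.25 + 0.012 * Tv + 2e-4 * Tv^2 + 8e-4 * Pv - 1.5e-6 * Pv^2 +
    rnorm(M, 0, 0.02)
  cell <- cell_series(N, Tv, Pv)
  spec <- kernel_spec(6, 6)
  loc <- fit_local(t_idx, cell, spec)

  X <- build_design(Tv, Pv)
  w <- kernel_weights(t_idx, M, spec)
  scl <- apply(abs(X), 2, max)            # precondition for the optimiser
  Xs <- sweep(X, 2, scl, "/")
  obj <- function(b) sum(w * (N - drop(Xs %*% b))^2)
  o <- optim(loc$beta * scl * 0, obj, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 5000))
  expect_equal(unname(loc$beta), unname(o$par / scl), tolerance = 1e-6)
})

test_that("huge bandwidths collapse the local fit onto global OLS", {
  sim <- noisy_cell(seed = 5, M = 120)
  gl <- fit_global(sim$cell)
  fit <- fit_lwlr(sim$cell, kernel_spec(1e6, 1e6))
  expect_lt(max(abs(sweep(fit$beta_t, 2, gl$beta))), 1e-6)
})

test_that("zero-noise constant-coefficient data are recovered exactly", {
  beta <- c(0.25, 0.012, 2e-4, 8e-4, -1.5e-6)
  cell <- exact_cell(M = 72, beta = beta)
  for (spec in list(kernel_spec(2, 3), kernel_spec(9, 9))) {
    fit <- fit_lwlr(cell, spec)
    expect_lt(max(abs(sweep(fit$beta_t, 2, beta))), 1e-8)
    expect_equal(fit$Rl2, 1, tolerance = 1e-8)
    expect_equal(fit$Rlg, 1, tolerance = 1e-8)
  }
})

test_that("fitted identity and Rlg consistency hold on noisy fits", {
  sim <- noisy_cell(seed = 7, M = 120)
  fit <- fit_lwlr(sim$cell, kernel_spec(6, 12))
  X <- build_design(sim$cell$T, sim$cell$P)
  expect_lt(max(abs(fit$fitted - rowSums(X * fit$beta_t))), 1e-12)
  expect_equal(fit$fitted + fit$residuals, sim$cell$N)

  # Rlg recomputed independently from the stored series
  N <- sim$cell$N
  Rl2 <- sum((fit$fitted - mean(N))^2) / sum((N - mean(N))^2)
  Rg2 <- {
    gl <- fit_global(sim$cell)
    sum((gl$fitted - mean(N))^2) / sum((N - mean(N))^2)
  }
  expect_equal(fit$Rlg, Rl2 / Rg2, tolerance = 1e-12)
})

test_that("a strongly time-varying coefficient makes the local model win", {
  tr <- synthetic_truth(beta1 = sin_coef(0.012, 0.008, 60),
                        sigma_eps = 0.01, seed = 9)
  sim <- make_cell(tr, M = 240)
  fit <- fit_lwlr(sim$cell, kernel_spec(9, 9))
  expect_gt(fit$Rlg, 1)
})

test_that("boundary flags mark months within max bandwidth of the ends", {
  sim <- noisy_cell(seed = 2, M = 60)
  fit <- fit_lwlr(sim$cell, kernel_spec(6, 12))
  expect_equal(which(fit$boundary_flag), c(1:12, 49:60))
})
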