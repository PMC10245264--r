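test_that("PNC series reproduce hand arithmetic and the additive identity", {
  # constant truth (0.1, 0.02, 0, 0.001, 0), T[1] = 10, P[1] = 50:
  # f = 0.2, g = 0.05, b0 = 0.1, fitted = 0.35
  cell <- exact_cell(M = 48, beta = c(0.1, 0.02, 0, 0.001, 0))
  fit <- fit_lwlr(cell, kernel_spec(6, 6))
  ser <- pnc_series(fit, cell)
  expect_equal(ser$f_hat[1], 0.2, tolerance = 1e-8)
  expect_equal(ser$g_hat[1], 0.05, tolerance = 1e-8)
  expect_equal(ser$b0_hat[1], 0.1, tolerance = 1e-8)
  expect_equal(ser$fitted[1], 0.35, tolerance = 1e-8)

  # identity on a noisy fit, plus its mean version through apnc()
  sim <- noisy_cell(seed = 3, M = 120)
  fit <- fit_lwlr(sim$cell, kernel_spec(6, 12))
  ser <- pnc_series(fit, sim$cell)
  expect_lt(max(abs(ser$f_hat + ser$g_hat + ser$b0_hat - fit$fitted)), 1e-12)
  ap <- apnc(ser)
  expect_equal(ap$f_bar + ap$g_bar + ap$b0_bar, mean(fit$fitted),
               tolerance = 1e-12)
})

test_that("APNC dominance and sign summaries follow the printed rules", {
  fab <- structure(list(f_hat = rep(0.2, 48), g_hat = rep(0.1, 48),
                        b0_hat = rep(0.3, 48)),
                   class = "contribution_series")
  ap <- apnc(fab)
  expect_equal(c(ap$f_bar, ap$g_bar, ap$b0_bar), c(0.2, 0.1, 0.3))
  expect_equal(ap$dominant, "tie")          # climate sum equals b0 exactly

  fab$f_hat <- rep(-0.15, 48)               # climate APNC negative
  ap <- apnc(fab)
  expect_equal(ap$climate, -0.05)
  expect_false(ap$climate_positive)
  expect_equal(ap$dominant, "anthropogenic")
})

test_that("STL components reconstruct the input and isolate known signals", {
  t <- 1:120
  x <- 0.3 + 0.002 * t + 0.1 * sin(2 * pi * t / 12)
  d <- stl_decompose(x)
  expect_lt(max(abs(d$trend + d$seasonal + d$remainder - x)), 1e-10)

  # pure sinusoid: trend stays near zero away from the boundaries
  s <- sin(2 * pi * t / 12)
  tr <- stl_trend(s)
  expect_lt(max(abs(tr[13:108])), 0.05)

  # linear ramp: trend recovers the ramp away from the boundaries
  ramp <- 1 + 0.01 * t
  tr <- stl_trend(ramp)
  expect_lt(max(abs(tr[13:108] - ramp[13:108])) / diff(range(ramp)), 0.01)

  expect_error(stl_decompose(1:20), "two periods")
})

test_that("cubic mean trend nests polynomials exactly", {
  expect_equal(cubic_mean_trend(3 + 0.5 * (1:40))$mean_derivative, 0.5,
               tolerance = 1e-10)
  expect_equal(cubic_mean_trend(rep(2, 20))$mean_derivative, 0,
               tolerance = 1e-10)
  # y = t^3 on 24 months: mean derivative = mean(3 t^2) = 612.5
  cf <- cubic_mean_trend((1:24)^3)
  expect_equal(cf$mean_derivative, 612.5, tolerance = 1e-6)

  # cross-check against a numerical derivative of the fitted cubic
  y <- 0.2 + 1e-4 * (1:60) - 3e-6 * (1:60)^2
  cf <- cubic_mean_trend(y)
  eps <- 1e-3
  poly_at <- function(t) {
    cr <- cf$coefficients
    cr[["c0"]] + cr[["c1"]] * t + cr[["c2"]] * t^2 + cr[["c3"]] * t^3
  }
  num <- mean((poly_at(1:60 + eps) - poly_at(1:60 - eps)) / (2 * eps))
  expect_equal(cf$mean_derivative, num, tolerance = 1e-6)
  expect_error(cubic_mean_trend(1:5), "at least 8")
})

test_that("changing trends vanish on trendless truth and recover real slopes", {
  # null: constant coefficients, trendless climate
  vals <- t(vapply(1:12, function(s) {
    sim <- make_cell(synthetic_truth(seed = 500 + s), M = 240)
    fit <- fit_lwlr(sim$cell, kernel_spec(24, 24))
    unlist(compute_alphas(pnc_series(fit, sim$cell), fit))
  }, numeric(4)))
  for (j in 1:4) {
    se <- sd(vals[, j]) / sqrt(nrow(vals))
    expect_lt(abs(mean(vals[, j])), 3 * se + 1e-12)
  }

  # recovery: rising anthropogenic term with slope 2.5e-4 NDVI/month
  a0 <- vapply(1:15, function(s) {
    tr <- synthetic_truth(beta0 = linear_coef(0.20, 2.5e-4), seed = 600 + s)
    sim <- make_cell(tr, M = 240)
    fit <- fit_lwlr(sim$cell, kernel_spec(24, 24))
    compute_alphas(pnc_series(fit, sim$cell), fit)$alpha0
  }, numeric(1))
  expect_lt(abs(mean(a0) - 2.5e-4) / 2.5e-4, 0.25)

  # sign convention: a growing climate contribution gives alpha > 0
  tr <- synthetic_truth(
    temp = climate_params(8, 12, slope = 0.006, rho = 0.3, sigma = 0.8),
    precip = climate_params(70, 55, slope = 0.15, rho = 0.3, sigma = 25,
                            floor = 0),
    seed = 77)
  sim <- make_cell(tr, M = 240)
  fit <- fit_lwlr(sim$cell, kernel_spec(24, 24))
  ser <- pnc_series(fit, sim$cell)
  al <- compute_alphas(ser, fit)
  expect_gt(al$alpha, 0)
  expect_gt(lwlrattrib:::ols_slope(ser$fg_trend), 0)
})

test_that("ingredient structure reduces to coefficient x climate slopes", {
  # constant coefficients, trending seasonal climate, no noise: the
  # trajectories are exactly constant, so the coefficient-derivative terms
  # vanish and the approximation is exactly beta1 * slope(T) + beta3 * slope(P)
  tr <- synthetic_truth(
    temp = climate_params(8, 6, slope = 0.01, rho = 0, sigma = 0),
    precip = climate_params(70, 30, slope = 0.2, rho = 0, sigma = 0,
                            floor = 0),
    sigma_eps = 0, seed = 1)
  sim <- make_cell(tr, M = 48)
  fit <- fit_lwlr(sim$cell, kernel_spec(6, 6))
  ing <- ingredient_structure(fit, sim$cell)
  expect_equal(ing$means[["T_dbeta1"]], 0, tolerance = 1e-8)
  expect_equal(ing$means[["P_dbeta3"]], 0, tolerance = 1e-8)
  sT <- lwlrattrib:::ols_slope(sim$cell$T)
  sP <- lwlrattrib:::ols_slope(sim$cell$P)
  expect_equal(ing$alpha_approx, 0.012 * sT + 8e-4 * sP, tolerance = 1e-8)

  # temperature-only generating model labels temperature as the driver
  tr <- synthetic_truth(beta3 = const_coef(0), beta4 = const_coef(0),
                        temp = climate_params(8, 6, slope = 0.01,
                                              rho = 0, sigma = 0),
                        precip = climate_params(70, 20, rho = 0, sigma = 0,
                                                floor = 0),
                        sigma_eps = 0, seed = 2)
  sim <- make_cell(tr, M = 48)
  fit <- fit_lwlr(sim$cell, kernel_spec(6, 6))
  expect_equal(ingredient_structure(fit, sim$cell)$dominant_factor,
               "temperature")
})

test_that("ingredient approximation tracks finite differences of the trend", {
  # low noise, trending climate, slowly varying beta1, small quadratics
  tr <- synthetic_truth(
    beta1 = linear_coef(0.010, 2e-5), beta2 = const_coef(2e-5),
    beta3 = const_coef(8e-4), beta4 = const_coef(-2e-7),
    temp = climate_params(8, 12, slope = 0.006, rho = 0, sigma = 0.1),
    precip = climate_params(70, 55, slope = 0.15, rho = 0, sigma = 3,
                            floor = 0),
    sigma_eps = 0.002, seed = 7)
  sim <- make_cell(tr, M = 240)
  fit <- fit_lwlr(sim$cell, kernel_spec(12, 12))
  ser <- pnc_series(fit, sim$cell)
  ing <- ingredient_structure(fit, sim$cell)
  num <- mean(diff(ser$fg_trend))      # oracle: finite differences of FG trend
  expect_lt(abs(ing$alpha_approx - num) / abs(num), 0.2)
})

test_that("relative roles follow the printed ratio arithmetic", {
  r <- relative_roles(3e-6, 1e-6)
  expect_equal(c(r$Ra, r$Rc), c(0.75, 0.25))
  r <- relative_roles(2e-6, 2e-6)
  expect_equal(c(r$Ra, r$Rc), c(0.5, 0.5))
  r <- relative_roles(-1e-6, 2e-6)
  expect_equal(c(r$Ra, r$Rc), c(-1, 2))
  expect_match(r$note, "degraded owing to anthropogenic")

  # Ra + Rc = 1 whenever defined
  set.seed(3)
  for (i in 1:20) {
    a0 <- rnorm(1, 0, 1e-4); a <- rnorm(1, 0, 1e-4)
    r <- relative_roles(a0, a)
    if (r$defined) expect_equal(r$Ra + r$Rc, 1, tolerance = 1e-12)
  }
  r <- relative_roles(1e-13, -1e-13)
  expect_false(r$defined)
  expect_true(is.na(r$Ra))

  expect_equal(relative_roles(1e-5, 1e-5)$driver_class, "both-promote")
  expect_equal(relative_roles(-1e-5, -1e-5)$driver_class, "both-degrade")
  expect_equal(relative_roles(1e-5, -1e-5)$driver_class,
               "anthropogenic-promotes-climate-degrades")
  expect_equal(relative_roles(1e-7, 1e-7)$driver_class, "insignificant")
  expect_equal(relative_roles(1e-7, 1e-5)$driver_class, "climate-promotes")
})

test_that("the anthropogenic share and its bins follow the printed formula", {
  expect_equal(apnc_share(0.2, 0.1, 0.3)$R_ac, 0.5)
  expect_equal(apnc_share(0.2, 0.1, 0.3)$bin, "<=0.50")
  expect_equal(apnc_share(0.05, 0.05, 0.3)$R_ac, 0.75)
  expect_equal(apnc_share(0.05, 0.05, 0.3)$bin, "0.51-0.75")
  s <- apnc_share(-0.05, -0.05, 0.3)     # negative climate APNC
  expect_equal(s$R_ac, 1.5)
  expect_equal(s$bin, ">1")
  expect_false(apnc_share(0.1, -0.1, 0)$defined)
})

test_that("monthly slope classification applies the greening thresholds", {
  t <- 1:240
  season <- 0.08 * sin(2 * pi * t / 12)
  for (case in list(list(s = 3e-5, cls = "promoted"),
                    list(s = 0, cls = "non-significant"),
                    list(s = 3e-4, cls = "strongly-promoted"),
                    list(s = -3e-5, cls = "degraded"))) {
    out <- monthly_slope_class(0.3 + case$s * t + season)
    expect_equal(out$class, case$cls)
    expect_equal(out$slope, case$s, tolerance = 5e-6)
  }
})
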