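#' Coefficient functions for synthetic ground truth
#'
#' Constructors for the time-varying coefficient functions used by the data
#' generator: constant, linear, cubic and sinusoidal shapes.  Each stores its
#' parameters so truth values and analytic derivatives can be recovered for
#' recovery testing.
#'
#' @param value,intercept,slope,c0,c1,c2,c3,mean,amplitude,period,phase
#'   shape parameters; `period` in months, `phase` in months.
#' @return An object of class `coef_fun`.
#' @name coef-funs
NULL

#' @rdname coef-funs
#' @export
const_coef <- function(value) {
  structure(list(type = "constant", value = value), class = "coef_fun")
}

#' @rdname coef-funs
#' @export
linear_coef <- function(intercept, slope) {
  structure(list(type = "linear", intercept = intercept, slope = slope),
            class = "coef_fun")
}

#' @rdname coef-funs
#' @export
cubic_coef <- function(c0, c1 = 0, c2 = 0, c3 = 0) {
  structure(list(type = "cubic", c0 = c0, c1 = c1, c2 = c2, c3 = c3),
            class = "coef_fun")
}

#' @rdname coef-funs
#' @export
sin_coef <- function(mean, amplitude, period, phase = 0) {
  structure(list(type = "sinusoidal", mean = mean, amplitude = amplitude,
                 period = period, phase = phase),
            class = "coef_fun")
}

#' Evaluate a coefficient function (or its derivative) at months `t`
#'
#' @param cf a [coef-funs] object.
#' @param t month indices.
#' @return Numeric vector.
#' @export
eval_coef <- function(cf, t) {
  stopifnot(inherits(cf, "coef_fun"))
  switch(cf$type,
    constant   = rep(cf$value, length(t)),
    linear     = cf$intercept + cf$slope * t,
    cubic      = cf$c0 + cf$c1 * t + cf$c2 * t^2 + cf$c3 * t^3,
    sinusoidal = cf$mean + cf$amplitude *
      sin(2 * pi * (t - cf$phase) / cf$period)
  )
}

#' @rdname eval_coef
#' @export
eval_coef_deriv <- function(cf, t) {
  stopifnot(inherits(cf, "coef_fun"))
  switch(cf$type,
    constant   = rep(0, length(t)),
    linear     = rep(cf$slope, length(t)),
    cubic      = cf$c1 + 2 * cf$c2 * t + 3 * cf$c3 * t^2,
    sinusoidal = cf$amplitude * (2 * pi / cf$period) *
      cos(2 * pi * (t - cf$phase) / cf$period)
  )
}

#' Climate series parameters
#'
#' Parameters of a seasonal + trend + AR(1)-noise monthly climate series:
#' `mean + amplitude * cos(2 pi (t - phase) / 12) + slope * t + e(t)` with
#' `e(t) = rho e(t-1) + innovation`, innovation sd `sigma`.  Setting
#' `floor = 0` truncates at zero (used for precipitation).
#'
#' @param mean long-term mean.
#' @param amplitude seasonal amplitude.
#' @param slope linear trend per month.
#' @param phase month of the seasonal peak.
#' @param rho AR(1) coefficient of the noise, `|rho| < 1`.
#' @param sigma innovation standard deviation.
#' @param floor lower truncation bound, or `NULL`.
#' @return A `climate_params` list.
#' @export
climate_params <- function(mean, amplitude = 0, slope = 0, phase = 7,
                           rho = 0, sigma = 0, floor = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(mean = mean, amplitude = amplitude, slope = slope,
                 phase = phase, rho = rho, sigma = sigma, floor = floor),
            class = "climate_params")
}

# stationary AR(1) noise; returns zeros when sigma = 0
ar1_noise <- function(M, rho, sigma) {
  if (sigma == 0) return(numeric(M))
  e <- numeric(M)
  e[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - rho^2))
  if (M > 1) {
    innov <- stats::rnorm(M - 1, 0, sigma)
    for (t in 2:M) e[t] <- rho * e[t - 1] + innov[t - 1]
  }
  e
}

climate_series <- function(M, p) {
  t <- seq_len(M)
  x <- p$mean + p$amplitude * cos(2 * pi * (t - p$phase) / 12) +
    p$slope * t + ar1_noise(M, p$rho, p$sigma)
  if (!is.null(p$floor)) x <- pmax(p$floor, x)
  x
}

#' Generate synthetic monthly climate series
#'
#' @param M number of months (>= 36).
#' @param temp,precip [climate_params()] for temperature and precipitation;
#'   precipitation is floored at zero by default.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return List with numeric vectors `T` and `P` of length `M`.
#' @export
make_climate <- function(M,
                         temp = climate_params(8, 12, rho = 0.3, sigma = 0.8),
                         precip = climate_params(70, 55, rho = 0.3,
                                                 sigma = 25, floor = 0),
                         seed = NULL) {
  if (M < 36L) stop("M must be >= 36", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  list(T = climate_series(M, temp), P = climate_series(M, precip))
}

#' Synthetic ground truth for one cell
#'
#' Collects everything needed to generate a cell and to score recovery
#' afterwards: the five coefficient functions, the climate parameters, the
#' NDVI noise model (innovation sd `sigma_eps`, optional AR(1) `rho_eps`),
#' the response lag in months, and the seed.
#'
#' @param beta0,beta1,beta2,beta3,beta4 [coef-funs] objects.  Default
#'   magnitudes keep NDVI in a realistic `[0, 1]`-like range.
#' @param temp,precip [climate_params()].
#' @param sigma_eps NDVI noise innovation sd (NDVI units).
#' @param rho_eps AR(1) coefficient of the NDVI noise.
#' @param lag months by which NDVI lags the climate inputs (>= 0).
#' @param seed RNG seed.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(beta0 = const_coef(0.25),
                            beta1 = const_coef(0.012),
                            beta2 = const_coef(2e-4),
                            beta3 = const_coef(8e-4),
                            beta4 = const_coef(-1.5e-6),
                            temp = climate_params(8, 12, rho = 0.3,
                                                  sigma = 0.8),
                            precip = climate_params(70, 55, rho = 0.3,
                                                    sigma = 25, floor = 0),
                            sigma_eps = 0.02, rho_eps = 0, lag = 0L,
                            seed = 1L) {
  if (lag < 0L) stop("lag must be >= 0", call. = FALSE)
  structure(
    list(betas = list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                      beta3 = beta3, beta4 = beta4),
         temp = temp, precip = precip,
         sigma_eps = sigma_eps, rho_eps = rho_eps,
         lag = as.integer(lag), seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

# true coefficient trajectories as an M x 5 matrix at months t
truth_beta_matrix <- function(truth, t) {
  m <- vapply(truth$betas, eval_coef, numeric(length(t)), t = t)
  colnames(m) <- c("(Intercept)", "T", "T2", "P", "P2")
  m
}

#' Generate NDVI from climate series and a ground truth
#'
#' `N(t) = beta0(t) + beta1(t) T(t - lag) + beta2(t) T^2(t - lag)
#'  + beta3(t) P(t - lag) + beta4(t) P^2(t - lag) + eps(t)`.
#' The first `lag` months, for which no lagged climate exists, are trimmed
#' from all returned series, so the output pairs `N(t)` with the
#' *contemporaneous* climate the fitting model sees.
#'
#' @param T,P climate series (e.g. from [make_climate()]).
#' @param truth a [synthetic_truth()]; its `seed` is *not* applied here --
#'   use [make_cell()] for fully reproducible generation.
#' @return List with trimmed `N`, `T`, `P`, the true `beta` matrix aligned
#'   to the trimmed months, and the noise-free `N_true`.
#' @export
make_ndvi <- function(T, P, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  M <- length(T)
  lag <- truth$lag
  if (lag >= M) stop("lag must be smaller than the series length",
                     call. = FALSE)
  t <- seq_len(M)
  keep <- t > lag
  tk <- t[keep]
  B <- truth_beta_matrix(truth, tk)
  Tl <- T[tk - lag]; Pl <- P[tk - lag]
  signal <- B[, 1] + B[, 2] * Tl + B[, 3] * Tl^2 + B[, 4] * Pl + B[, 5] * Pl^2
  eps <- ar1_noise(length(tk), truth$rho_eps, truth$sigma_eps)
  list(N = signal + eps, T = T[keep], P = P[keep], beta = B, N_true = signal)
}

#' Generate one fully specified synthetic cell
#'
#' Seeds the RNG from `truth$seed`, draws the climate, builds NDVI, and
#' returns the cell together with its aligned ground truth.  Regeneration
#' from the same truth object is bit-identical.
#'
#' @param truth a [synthetic_truth()].
#' @param M number of months before lag trimming.
#' @param cell_id,lon,lat cell metadata.
#' @return List of class `synthetic_cell`: `cell` (a [cell_series()]),
#'   `truth`, `beta_true` (matrix aligned to the cell's months),
#'   `N_true` (noise-free NDVI), and `lagged_T`, `lagged_P` (the climate
#'   actually driving NDVI, equal to `cell$T`, `cell$P` when `lag = 0`).
#' @export
make_cell <- function(truth, M = 240L, cell_id = "synthetic-1",
                      lon = 100, lat = 35) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  clim <- make_climate(M, truth$temp, truth$precip, seed = NULL)
  sim <- make_ndvi(clim$T, clim$P, truth)
  keep <- seq_len(M) > truth$lag
  cell <- cell_series(sim$N, sim$T, sim$P, cell_id = cell_id,
                      lon = lon, lat = lat)
  structure(
    list(cell = cell, truth = truth, beta_true = sim$beta,
         N_true = sim$N_true,
         lagged_T = clim$T[which(keep) - truth$lag],
         lagged_P = clim$P[which(keep) - truth$lag]),
    class = "synthetic_cell"
  )
}

scenario_names <- c("climate-dominant", "anthropogenic-dominant",
                    "degrading", "lagged", "no-vegetation")

# Study-condition parameterisations for each named scenario.
scenario_truth <- function(scenario, seed) {
  base_temp <- climate_params(8, 12, slope = 0, rho = 0.3, sigma = 0.8)
  base_precip <- climate_params(70, 55, slope = 0, rho = 0.3, sigma = 25,
                                floor = 0)
  switch(scenario,
    "climate-dominant" = synthetic_truth(
      beta0 = const_coef(0.25),
      temp = climate_params(8, 12, slope = 0.006, rho = 0.3, sigma = 0.8),
      precip = climate_params(70, 55, slope = 0.15, rho = 0.3, sigma = 25,
                              floor = 0),
      seed = seed),
    "anthropogenic-dominant" = synthetic_truth(
      beta0 = linear_coef(0.20, 2.5e-4),
      temp = base_temp, precip = base_precip, seed = seed),
    "degrading" = synthetic_truth(
      beta0 = linear_coef(0.32, -2.5e-4),
      temp = base_temp, precip = base_precip, seed = seed),
    "lagged" = synthetic_truth(
      temp = base_temp, precip = base_precip, lag = 2L, seed = seed),
    "no-vegetation" = synthetic_truth(
      beta0 = const_coef(0.05), beta1 = const_coef(3e-3),
      beta2 = const_coef(0), beta3 = const_coef(2e-4),
      beta4 = const_coef(0),
      temp = base_temp, precip = base_precip,
      sigma_eps = 0.01, seed = seed),
    stop("unknown scenario '", scenario, "'; available: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  )
}

#' Generate a synthetic grid of cells
#'
#' Draws `n_cells` cells on a synthetic lat/lon lattice, each from a named
#' scenario.  `scenario = "mixed"` cycles through all five scenarios.
#' Per-cell seeds are derived deterministically from `seed`.
#'
#' @param n_cells number of cells.
#' @param scenario one of `"climate-dominant"`, `"anthropogenic-dominant"`,
#'   `"degrading"`, `"lagged"`, `"no-vegetation"`, or `"mixed"`.
#' @param M months per cell.
#' @param seed base RNG seed.
#' @return An object of class `synthetic_grid`: lists `cells` and `sims`
#'   (the full `synthetic_cell` objects) plus the per-cell `scenario`
#'   labels.
#' @export
make_grid <- function(n_cells, scenario = "mixed", M = 240L, seed = 1L) {
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  scen <- if (identical(scenario, "mixed")) {
    rep_len(scenario_names, n_cells)
  } else {
    if (!scenario %in% scenario_names) {
      stop("unknown scenario '", scenario, "'; available: mixed, ",
           paste(scenario_names, collapse = ", "), call. = FALSE)
    }
    rep(scenario, n_cells)
  }
  nx <- ceiling(sqrt(n_cells))
  sims <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    truth <- scenario_truth(scen[i], seed = seed + i)
    sims[[i]] <- make_cell(
      truth, M = M, cell_id = sprintf("cell-%03d", i),
      lon = 90 + 0.25 * ((i - 1) %% nx),
      lat = 30 + 0.25 * ((i - 1) %/% nx))
  }
  structure(
    list(cells = lapply(sims, `[[`, "cell"), sims = sims, scenario = scen,
         seed = as.integer(seed)),
    class = "synthetic_grid"
  )
}

#' @export
print.synthetic_grid <- function(x, ...) {
  cat("<synthetic_grid> ", length(x$cells), " cells (seed ", x$seed, ")\n",
      sep = "")
  print(table(x$scenario))
  invisible(x)
}

#' Score coefficient and trend recovery against the generating truth
#'
#' @param sim a [make_cell()] result.
#' @param fit an [fit_lwlr()] fit of `sim$cell`.
#' @return List with `rmse` (per-coefficient RMSE over interior,
#'   non-boundary months), `cor_beta1` (trajectory correlation for the
#'   temperature coefficient over interior months; `NA` when the truth is
#'   constant), `alpha0_true`, `alpha1_true`, `alpha3_true` (analytic mean
#'   derivatives of the generating coefficient functions),
#'   `alpha0_sign_match` and `apnc_error` (fitted minus true
#'   `(f_bar, g_bar, b0_bar)`).
#' @export
recovery_report <- function(sim, fit) {
  stopifnot(inherits(sim, "synthetic_cell"), inherits(fit, "lwlr_fit"))
  idx <- fit$t_index
  interior <- !fit$boundary_flag
  Bt <- sim$beta_true[idx, , drop = FALSE]
  rmse <- sqrt(colMeans((fit$beta_t[interior, , drop = FALSE] -
                           Bt[interior, , drop = FALSE])^2))
  b1_true <- Bt[interior, "T"]
  cor_beta1 <- if (stats::sd(b1_true) > 0 &&
                   stats::sd(fit$beta_t[interior, "T"]) > 0) {
    stats::cor(fit$beta_t[interior, "T"], b1_true)
  } else {
    NA_real_
  }
  tt <- idx + sim$truth$lag  # generator months corresponding to cell months
  a0_true <- mean(eval_coef_deriv(sim$truth$betas$beta0, tt))
  a1_true <- mean(eval_coef_deriv(sim$truth$betas$beta1, tt))
  a3_true <- mean(eval_coef_deriv(sim$truth$betas$beta3, tt))
  series <- pnc_series(fit, sim$cell)
  ap <- apnc(series)
  Tl <- sim$lagged_T[idx]; Pl <- sim$lagged_P[idx]
  f_true <- mean(Bt[, "T"] * Tl + Bt[, "T2"] * Tl^2)
  g_true <- mean(Bt[, "P"] * Pl + Bt[, "P2"] * Pl^2)
  b0_true <- mean(Bt[, "(Intercept)"])
  alphas <- compute_alphas(series, fit)
  list(rmse = rmse, cor_beta1 = cor_beta1,
       alpha0_true = a0_true, alpha1_true = a1_true, alpha3_true = a3_true,
       alpha0_sign_match = sign(alphas$alpha0) == sign(a0_true) ||
         (abs(a0_true) < 1e-12 && abs(alphas$alpha0) < 1e-5),
       apnc_error = c(f = ap$f_bar - f_true, g = ap$g_bar - g_true,
                      b0 = ap$b0_bar - b0_true))
}
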