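#' Predicted nonlinear contribution (PNC) series
#'
#' Splits the fitted NDVI into its three additive sources:
#' temperature `f_hat(t) = beta1(t) T(t) + beta2(t) T^2(t)`, precipitation
#' `g_hat(t) = beta3(t) P(t) + beta4(t) P^2(t)`, and the time-varying
#' intercept `b0_hat(t)`, interpreted as the anthropogenic (non-climatic)
#' contribution.  The climate sum `fg = f_hat + g_hat` is STL-detrended
#' (period 12) to give `fg_trend`, the deseasonalised climate-contribution
#' trend used by the changing-trend statistics.
#'
#' @param fit an [fit_lwlr()] (possibly Cochrane-Orcutt corrected) fit.
#' @param cell the [cell_series()] the fit came from.
#' @return An object of class `contribution_series` with fields `t_index`,
#'   `f_hat`, `g_hat`, `b0_hat`, `fg`, `fg_trend` and `fitted`.  The identity
#'   `f_hat + g_hat + b0_hat == fitted` holds exactly.
#' @export
pnc_series <- function(fit, cell) {
  stopifnot(inherits(fit, "lwlr_fit"))
  assert_cell(cell)
  idx <- fit$t_index
  if (max(idx) > cell$M) stop("fit and cell are misaligned", call. = FALSE)
  Tv <- cell$T[idx]; Pv <- cell$P[idx]
  b <- fit$beta_t
  f_hat <- b[, "T"] * Tv + b[, "T2"] * Tv^2
  g_hat <- b[, "P"] * Pv + b[, "P2"] * Pv^2
  b0_hat <- b[, "(Intercept)"]
  fg <- f_hat + g_hat
  structure(
    list(t_index = idx, f_hat = f_hat, g_hat = g_hat, b0_hat = b0_hat,
         fg = fg, fg_trend = stl_trend(fg), fitted = fit$fitted,
         cell_id = cell$cell_id),
    class = "contribution_series"
  )
}

#' Average predicted nonlinear contributions (APNC)
#'
#' Time averages of the three contribution series, plus the dominance and
#' sign summaries: climate dominates when `f_bar + g_bar > b0_bar`, a
#' positive climate APNC means the climate environment favoured vegetation
#' growth over the period, and a negative anthropogenic APNC means human
#' activity depressed it.
#'
#' @param series a [pnc_series()] result.
#' @return List with `f_bar`, `g_bar`, `b0_bar`, `climate` (`f_bar + g_bar`),
#'   `dominant` (`"climate"`, `"anthropogenic"` or `"tie"`),
#'   `climate_positive` and `anthropogenic_positive`.
#' @export
apnc <- function(series) {
  stopifnot(inherits(series, "contribution_series"))
  f_bar <- mean(series$f_hat)
  g_bar <- mean(series$g_hat)
  b0_bar <- mean(series$b0_hat)
  climate <- f_bar + g_bar
  dominant <- if (isTRUE(all.equal(climate, b0_bar))) {
    "tie"
  } else if (climate > b0_bar) "climate" else "anthropogenic"
  list(f_bar = f_bar, g_bar = g_bar, b0_bar = b0_bar, climate = climate,
       dominant = dominant,
       climate_positive = climate > 0,
       anthropogenic_positive = b0_bar > 0)
}

#' Seasonal-trend decomposition (STL) helpers
#'
#' Thin wrappers over [stats::stl()] used throughout the attribution layer:
#' period 12, seasonal window 13, robust fitting.  The three components sum
#' to the input exactly.
#'
#' @param x numeric monthly series, at least two full periods long.
#' @param period seasonal period in months.
#' @param s_window loess window for seasonal extraction.
#' @param robust use robust loess iterations.
#' @return `stl_decompose()`: list with `trend`, `seasonal`, `remainder`;
#'   `stl_trend()`: the trend component only.
#' @export
stl_decompose <- function(x, period = 12L, s_window = 13, robust = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 2L * period) {
    stop("series must cover at least two periods (", 2L * period,
         " months)", call. = FALSE)
  }
  fit <- stats::stl(stats::ts(x, frequency = period),
                    s.window = s_window, robust = robust)
  comp <- fit$time.series
  trend <- as.numeric(comp[, "trend"])
  seasonal <- as.numeric(comp[, "seasonal"])
  list(trend = trend, seasonal = seasonal, remainder = x - trend - seasonal)
}

#' @rdname stl_decompose
#' @export
stl_trend <- function(x, period = 12L, s_window = 13, robust = TRUE) {
  stl_decompose(x, period, s_window, robust)$trend
}

#' Cubic fit and its average derivative (mean changing trend)
#'
#' Fits `y = c0 + c1 t + c2 t^2 + c3 t^3` by OLS (internally on a rescaled
#' time axis for conditioning; coefficients are reported in raw per-month
#' units) and returns the average of the first derivative over the observed
#' months, `(1/M) sum_t (3 c3 t^2 + 2 c2 t + c1)`.  This "mean changing
#' trend" is the slope summary used for all alpha statistics.
#'
#' @param y numeric series, length >= 8.
#' @param t time index of each observation (months).
#' @return An object of class `cubic_fit` with `coefficients` (`c0..c3`, raw
#'   units), `fitted`, `residuals`, `mean_derivative` and `t`.
#' @examples
#' cubic_mean_trend(3 + 0.5 * (1:40))$mean_derivative   # 0.5
#' @export
cubic_mean_trend <- function(y, t = seq_along(y)) {
  y <- as.numeric(y)
  if (length(y) < 8L) stop("need at least 8 points for a cubic fit",
                           call. = FALSE)
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  sc <- max(abs(t))
  s <- t / sc
  S <- cbind(1, s, s^2, s^3)
  sol <- ls_solve(S, y)
  cs <- sol$coefficients
  cr <- cs / sc^(0:3)
  names(cr) <- c("c0", "c1", "c2", "c3")
  fitted <- drop(S %*% cs)
  structure(
    list(coefficients = cr, fitted = fitted, residuals = y - fitted,
         mean_derivative = mean(3 * cr[["c3"]] * t^2 + 2 * cr[["c2"]] * t +
                                  cr[["c1"]]),
         t = t),
    class = "cubic_fit"
  )
}

# first derivative of a cubic_fit evaluated at its own time points
cubic_derivative <- function(fit, t = fit$t) {
  cr <- fit$coefficients
  3 * cr[["c3"]] * t^2 + 2 * cr[["c2"]] * t + cr[["c1"]]
}

#' Average changing trends of the contribution series
#'
#' The four alpha statistics, each the mean first derivative of a cubic fit:
#' `alpha` from the STL trend of the climate contribution `fg_trend`,
#' `alpha0` from the anthropogenic series `b0_hat` (fitted directly, no STL),
#' `alpha1` and `alpha3` from the coefficient trajectories `beta1(t)` and
#' `beta3(t)`.  Positive `alpha` means the climate contribution to NDVI grew
#' over the record; positive `alpha0` the same for human activity.
#'
#' @param series a [pnc_series()] result.
#' @param fit the matching [fit_lwlr()] object.
#' @param method `"cubic"` (mean derivative of the cubic fit, the default)
#'   or `"numeric"` (mean first difference of the series itself).
#' @return List with `alpha`, `alpha0`, `alpha1`, `alpha3`
#'   (units: NDVI/month for the first two; coefficient units/month for
#'   the last two).
#' @export
compute_alphas <- function(series, fit, method = c("cubic", "numeric")) {
  stopifnot(inherits(series, "contribution_series"), inherits(fit, "lwlr_fit"))
  method <- match.arg(method)
  idx <- fit$t_index
  if (method == "numeric") {
    return(list(alpha = mean(diff(series$fg_trend)),
                alpha0 = mean(diff(series$b0_hat)),
                alpha1 = mean(diff(fit$beta_t[, "T"])),
                alpha3 = mean(diff(fit$beta_t[, "P"]))))
  }
  list(alpha = cubic_mean_trend(series$fg_trend, idx)$mean_derivative,
       alpha0 = cubic_mean_trend(series$b0_hat, idx)$mean_derivative,
       alpha1 = cubic_mean_trend(fit$beta_t[, "T"], idx)$mean_derivative,
       alpha3 = cubic_mean_trend(fit$beta_t[, "P"], idx)$mean_derivative)
}

#' Ingredient structure of the climate trend alpha
#'
#' First-order decomposition of the climate contribution's changing trend,
#' neglecting the (small) quadratic terms:
#' `d(fg)/dt ~ T dbeta1/dt + beta1 dT/dt + P dbeta3/dt + beta3 dP/dt`.
#' Coefficient derivatives come from the cubic fits of the trajectories;
#' climate derivatives are the OLS linear slopes of `T` and `P` by default.
#' The per-month terms are averaged and the temperature vs precipitation
#' share decides the dominant factor label: `"temperature"` when the
#' temperature terms carry at least 60% of the absolute mean contribution,
#' `"precipitation"` at most 40%, `"combination"` between.
#'
#' @param fit an [fit_lwlr()] object.
#' @param cell the matching [cell_series()].
#' @param climate_deriv `"ols"` (linear slope of `T`, `P`; default) or
#'   `"diff"` (per-month first differences).
#' @return List with per-month `terms` (matrix with columns `T_dbeta1`,
#'   `beta1_dT`, `P_dbeta3`, `beta3_dP`), their `means`, `alpha_approx`
#'   (mean of the four terms' sum), `share_temperature` and
#'   `dominant_factor`.
#' @export
ingredient_structure <- function(fit, cell, climate_deriv = c("ols", "diff")) {
  stopifnot(inherits(fit, "lwlr_fit"))
  assert_cell(cell)
  climate_deriv <- match.arg(climate_deriv)
  idx <- fit$t_index
  Tv <- cell$T[idx]; Pv <- cell$P[idx]
  b1 <- fit$beta_t[, "T"]; b3 <- fit$beta_t[, "P"]
  db1 <- cubic_derivative(cubic_mean_trend(b1, idx))
  db3 <- cubic_derivative(cubic_mean_trend(b3, idx))
  if (climate_deriv == "ols") {
    dT <- ols_slope(Tv, idx)
    dP <- ols_slope(Pv, idx)
  } else {
    dT <- c(diff(Tv)[1], diff(Tv))
    dP <- c(diff(Pv)[1], diff(Pv))
  }
  terms <- cbind(T_dbeta1 = Tv * db1, beta1_dT = b1 * dT,
                 P_dbeta3 = Pv * db3, beta3_dP = b3 * dP)
  means <- colMeans(terms)
  a_T <- abs(means[["T_dbeta1"]] + means[["beta1_dT"]])
  a_P <- abs(means[["P_dbeta3"]] + means[["beta3_dP"]])
  share <- if (a_T + a_P > 0) a_T / (a_T + a_P) else NA_real_
  dominant <- if (is.na(share)) {
    "none"
  } else if (share >= 0.6) {
    "temperature"
  } else if (share <= 0.4) "precipitation" else "combination"
  list(terms = terms, means = means, alpha_approx = sum(means),
       share_temperature = share, dominant_factor = dominant)
}

ols_slope <- function(y, t = seq_along(y)) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Relative contribution ratios of human activity and climate
#'
#' `Ra = alpha0 / (alpha0 + alpha)` and `Rc = 1 - Ra` apportion the NDVI
#' changing trend between anthropogenic activity and climate.  Negative `Ra`
#' means vegetation growth is degraded by anthropogenic activity while the
#' overall trend is carried by climate (or vice versa); the ratio is flagged
#' undefined when `|alpha0 + alpha|` is below tolerance.  The driver class
#' crosses the signs of the two trends, calling either insignificant when
#' its magnitude is below `insig_threshold`.
#'
#' @param alpha0 anthropogenic changing trend (NDVI/month).
#' @param alpha climate changing trend (NDVI/month).
#' @param insig_threshold magnitude below which a trend is treated as
#'   insignificant (default 5e-6 NDVI/month).
#' @param tol denominator tolerance for the ratio.
#' @return List with `Ra`, `Rc`, `defined`, `driver_class` and `note`
#'   (non-`NA` when `Ra < 0`).
#' @export
relative_roles <- function(alpha0, alpha, insig_threshold = 5e-6,
                           tol = 1e-12) {
  if (!is.finite(alpha0) || !is.finite(alpha)) {
    stop("alpha0 and alpha must be finite", call. = FALSE)
  }
  denom <- alpha0 + alpha
  defined <- abs(denom) >= tol
  Ra <- if (defined) alpha0 / denom else NA_real_
  Rc <- if (defined) 1 - Ra else NA_real_
  sgn <- function(a) {
    if (a > insig_threshold) 1L else if (a < -insig_threshold) -1L else 0L
  }
  s0 <- sgn(alpha0); sc <- sgn(alpha)
  driver_class <- if (s0 == 0L && sc == 0L) {
    "insignificant"
  } else if (s0 > 0L && sc > 0L) {
    "both-promote"
  } else if (s0 < 0L && sc < 0L) {
    "both-degrade"
  } else if (s0 > 0L && sc < 0L) {
    "anthropogenic-promotes-climate-degrades"
  } else if (s0 < 0L && sc > 0L) {
    "climate-promotes-anthropogenic-degrades"
  } else if (s0 == 0L) {
    if (sc > 0L) "climate-promotes" else "climate-degrades"
  } else {
    if (s0 > 0L) "anthropogenic-promotes" else "anthropogenic-degrades"
  }
  note <- if (defined && Ra < 0) {
    "vegetation growth is degraded owing to anthropogenic activity"
  } else {
    NA_character_
  }
  list(Ra = Ra, Rc = Rc, defined = defined, driver_class = driver_class,
       note = note)
}

#' Anthropogenic share of the average contributions
#'
#' `R_ac = b0_bar / (f_bar + g_bar + b0_bar)`: the fraction of the average
#' fitted NDVI attributable to human activity.  Values above 1 occur when
#' the climate APNC is negative.
#'
#' @param f_bar,g_bar,b0_bar APNC values from [apnc()].
#' @param tol denominator tolerance.
#' @return List with `R_ac`, `bin`
#'   (one of `"<=0.50"`, `"0.51-0.75"`, `"0.76-1.00"`, `">1"`) and
#'   `defined`.
#' @export
apnc_share <- function(f_bar, g_bar, b0_bar, tol = 1e-12) {
  denom <- f_bar + g_bar + b0_bar
  if (!is.finite(denom) || abs(denom) < tol) {
    return(list(R_ac = NA_real_, bin = NA_character_, defined = FALSE))
  }
  R_ac <- b0_bar / denom
  bin <- if (R_ac <= 0.5) {
    "<=0.50"
  } else if (R_ac <= 0.75) {
    "0.51-0.75"
  } else if (R_ac <= 1) "0.76-1.00" else ">1"
  list(R_ac = R_ac, bin = bin, defined = TRUE)
}

#' Monthly NDVI trend slope and greening class
#'
#' STL-detrends the NDVI series, estimates the OLS slope of the trend
#' component against the month index, and classifies the cell:
#' `"degraded"` below `-2e-5`/month, `"non-significant"` within
#' `[-2e-5, 2e-5]`, `"promoted"` above `2e-5`, upgraded to
#' `"strongly-promoted"` above `2e-4`/month.
#'
#' @param N monthly NDVI series, at least 24 months.
#' @param thresholds length-2 vector: the significance threshold and the
#'   strong-greening threshold (NDVI/month).
#' @return List with `slope` (NDVI/month), `class` and `trend` (the STL
#'   trend series).
#' @export
monthly_slope_class <- function(N, thresholds = c(2e-5, 2e-4)) {
  trend <- stl_trend(N)
  slope <- ols_slope(trend)
  cls <- if (slope < -thresholds[1]) {
    "degraded"
  } else if (slope <= thresholds[1]) {
    "non-significant"
  } else if (slope > thresholds[2]) "strongly-promoted" else "promoted"
  list(slope = slope, class = cls, trend = trend)
}
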