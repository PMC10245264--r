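#' Weighted variance inflation factors
#'
#' Collinearity check for the quadratic climate design.  For each focal month
#' `t` (and its kernel weights) and each predictor among `T`, `T^2`, `P`,
#' `P^2`, the predictor is regressed on the remaining predictors plus an
#' intercept by weighted least squares; `VIF_i(t) = 1 / (1 - R_i^2(t))` with
#' the weighted coefficient of determination.  With `spec = NULL` weights are
#' uniform and a single set of (ordinary) VIFs is returned.
#'
#' @param design an `M x 5` design from [build_design()].
#' @param spec optional [kernel_spec()]; when supplied, VIFs are computed for
#'   every focal month with that kernel.
#' @return List with `vif` (matrix, one row per focal month, columns
#'   `T`, `T2`, `P`, `P2`) and `vif_max`.  Perfectly collinear predictors
#'   yield `Inf`.
#' @details The conventional reading is that VIF above ~4 signals collinearity
#'   worth attention; [run_cell()] logs a warning flag at that level.
#' @export
weighted_vif <- function(design, spec = NULL) {
  X <- as.matrix(design)
  if (ncol(X) != 5L) stop("expected a 5-column design from build_design()",
                          call. = FALSE)
  M <- nrow(X)
  preds <- 2:5
  vif_for_w <- function(w) {
    vapply(preds, function(i) {
      y <- X[, i]
      Z <- X[, -i, drop = FALSE]  # remaining predictors + intercept
      sw <- sqrt(w)
      sol <- ls_solve(Z * sw, y * sw)
      e <- y - drop(Z %*% sol$coefficients)
      wm <- sum(w * y) / sum(w)
      sst <- sum(w * (y - wm)^2)
      if (sst < .Machine$double.eps * M) return(Inf)
      r2 <- 1 - sum(w * e^2) / sst
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  if (is.null(spec)) {
    vif <- matrix(vif_for_w(rep(1, M)), nrow = 1)
  } else {
    spec <- as_kernel_spec(spec)
    vif <- t(vapply(seq_len(M),
                    function(t) vif_for_w(kernel_weights(t, M, spec)),
                    numeric(4)))
  }
  colnames(vif) <- colnames(X)[preds]
  list(vif = vif, vif_max = max(vif))
}

#' Durbin-Watson statistic of a residual series
#'
#' `DW = sum_{t>=2} (e_t - e_{t-1})^2 / sum_t e_t^2`.  Values near 2 indicate
#' no lag-1 autocorrelation; the pipeline treats `[1.70, 2.30]` as the
#' acceptable band, outside of which the Cochrane-Orcutt correction is
#' applied.
#'
#' @param residuals numeric residual series, length >= 3.
#' @return The DW statistic in `[0, 4]`; `NA` (with a warning) for an
#'   all-zero series.
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 3L) stop("need at least 3 residuals", call. = FALSE)
  denom <- sum(e^2)
  if (denom < .Machine$double.eps * length(e)) {
    warning("Durbin-Watson undefined for an all-zero residual series",
            call. = FALSE)
    return(NA_real_)
  }
  sum(diff(e)^2) / denom
}

# lag-1 sample autocorrelation (mean removed)
acf_lag1 <- function(e) {
  e <- e - mean(e)
  denom <- sum(e^2)
  if (denom < .Machine$double.eps * length(e)) return(0)
  sum(e[-1] * e[-length(e)]) / denom
}

#' Cochrane-Orcutt correction of a locally weighted fit
#'
#' Removes (or reduces) AR(1) autocorrelation in the LWLR residuals by
#' iterative quasi-differencing: estimate `rho` as the lag-1 autocorrelation
#' of the residuals, transform `N*(t) = N(t) - rho N(t-1)` and every design
#' column likewise (the intercept column becomes `1 - rho`, so coefficients
#' stay on the original scale), refit, and repeat until `rho` stabilises.
#' The first month is dropped by the differencing, so the corrected
#' trajectories cover months `2..M`.
#'
#' @param cell a [cell_series()].
#' @param spec a [kernel_spec()].
#' @param max_iter maximum number of refits.
#' @param tol convergence tolerance on `|delta rho|`; an initial `|rho|`
#'   below `tol` returns the uncorrected fit unchanged.
#' @return List with `fit` (an `lwlr_fit`, `corrected = TRUE` and
#'   `t_index = 2:M` when a correction was applied; fitted values and
#'   residuals are re-expressed against the original, untransformed data,
#'   and the whitened residuals of the quasi-differenced regression are
#'   kept in `fit$residuals_white` for diagnostics), `rho` (final AR(1)
#'   estimate), `iterations` (number of fits performed, counting the
#'   initial one), `converged`, `dw_before`, `dw_after` (Durbin-Watson of
#'   the whitened residuals).
#' @export
cochrane_orcutt <- function(cell, spec, max_iter = 20L, tol = 1e-3) {
  assert_cell(cell)
  spec <- as_kernel_spec(spec)
  fit0 <- fit_lwlr(cell, spec)
  rho <- acf_lag1(fit0$residuals)
  dw0 <- durbin_watson(fit0$residuals)
  if (abs(rho) >= 1) stop("initial |rho| >= 1; series is non-stationary",
                          call. = FALSE)
  if (abs(rho) < tol) {
    return(list(fit = fit0, rho = rho, iterations = 1L, converged = TRUE,
                dw_before = dw0, dw_after = dw0))
  }
  X <- build_design(cell$T, cell$P)
  M <- cell$M
  iterations <- 1L
  converged <- FALSE
  beta <- NULL
  for (i in seq_len(max_iter)) {
    Ns <- cell$N[-1] - rho * cell$N[-M]
    Xs <- X[-1, , drop = FALSE] - rho * X[-M, , drop = FALSE]
    out <- lwlr_coefs(Xs, Ns, spec)
    beta <- out$beta
    iterations <- iterations + 1L
    # residuals of the original-scale equation under the current trajectories
    e <- cell$N[-1] - rowSums(X[-1, , drop = FALSE] * beta)
    rho_new <- acf_lag1(e)
    if (abs(rho_new - rho) < tol) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  if (!converged) {
    warning("Cochrane-Orcutt did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  fitted <- rowSums(X[-1, , drop = FALSE] * beta)
  res <- cell$N[-1] - fitted
  # residuals of the transformed (quasi-differenced) regression: these are
  # the innovations the correction whitens, and what DW/normality assess
  res_white <- Ns - rowSums(Xs * beta)
  hmax <- max(spec$h1, spec$h2)
  pos <- seq_len(M - 1L)   # position within the transformed series
  fit <- new_lwlr_fit(
    beta_t = beta, fitted = fitted, residuals = res,
    Rl2 = r2_explained(cell$N[-1], fitted), Rg2 = fit0$Rg2,
    kernel = spec, t_index = 2:M,
    boundary_flag = pos <= hmax | pos > (M - 1L) - hmax,
    singular = out$singular, cell_id = cell$cell_id,
    corrected = TRUE, rho = rho
  )
  fit$residuals_white <- res_white
  list(fit = fit, rho = rho, iterations = iterations, converged = converged,
       dw_before = dw0, dw_after = durbin_watson(res_white))
}

#' Maximum density discrepancy from normality (Delta-P)
#'
#' Compares the Gaussian kernel density estimate of the standardised
#' residuals with the standard normal density on a common 512-point grid over
#' `[-5, 5]` and returns the maximum absolute pointwise difference.
#' Residuals are standardised by their sample mean and standard deviation
#' first, which together with the scale-equivariant Silverman bandwidth makes
#' Delta-P invariant under affine transformations of the residuals -- a single
#' threshold `tau` therefore applies across cells with very different
#' residual scales.
#'
#' @param residuals numeric series, length >= 30.
#' @param n_grid number of evaluation points.
#' @return Delta-P (scalar, >= 0).
#' @details The KDE bandwidth is Silverman's normal-reference rule
#'   `1.06 * sd * n^(-1/5)` ([stats::bw.nrd]).
#' @seealso [calibrate_tau()] for the Monte-Carlo threshold,
#'   [normality_test()] for the pass/fail rule.
#' @export
delta_p <- function(residuals, n_grid = 512L) {
  e <- as.numeric(residuals)
  if (length(e) < 30L) stop("need at least 30 residuals", call. = FALSE)
  s <- stats::sd(e)
  if (!is.finite(s) || s < .Machine$double.eps) {
    stop("residuals have (near-)zero variance; Delta-P undefined",
         call. = FALSE)
  }
  z <- (e - mean(e)) / s
  d <- stats::density(z, bw = stats::bw.nrd(z), n = n_grid, from = -5, to = 5)
  max(abs(d$y - stats::dnorm(d$x)))
}

#' Monte-Carlo calibration of the normality threshold tau
#'
#' Draws `n_datasets` independent standard-normal series of length
#' `series_length`, computes [delta_p()] for each, and sets
#' `tau = round(mean(Delta-P), 2)`.
#'
#' @param n_datasets number of Monte-Carlo datasets (>= 100).
#' @param series_length length of each series; the default matches a
#'   20-year monthly record.
#' @param seed RNG seed (integer).
#' @return An object of class `tau_calibration` with `n_datasets`,
#'   `series_length`, `mean_dp`, `sd_dp`, `tau` and `seed`.
#' @examples
#' \donttest{
#' calibrate_tau(n_datasets = 200, seed = 1)
#' }
#' @export
calibrate_tau <- function(n_datasets = 10000L, series_length = 240L, seed = 1L) {
  if (n_datasets < 100L) stop("n_datasets must be >= 100", call. = FALSE)
  set.seed(seed)
  dp <- vapply(seq_len(n_datasets),
               function(i) delta_p(stats::rnorm(series_length)),
               numeric(1))
  structure(
    list(n_datasets = as.integer(n_datasets),
         series_length = as.integer(series_length),
         mean_dp = mean(dp), sd_dp = stats::sd(dp),
         tau = round(mean(dp), 2), seed = as.integer(seed)),
    class = "tau_calibration"
  )
}

#' @export
print.tau_calibration <- function(x, ...) {
  cat(sprintf(paste0("<tau_calibration> %d datasets of length %d: ",
                     "mean Delta-P = %.4f (sd %.4f) -> tau = %.2f\n"),
              x$n_datasets, x$series_length, x$mean_dp, x$sd_dp, x$tau))
  invisible(x)
}

#' Residual normality decision
#'
#' Pass if and only if `dp < tau` (strict inequality).
#'
#' @param dp a [delta_p()] value.
#' @param tau threshold, typically from [calibrate_tau()]; 0.04 for
#'   240-month series.
#' @return Logical.
#' @export
normality_test <- function(dp, tau = 0.04) {
  if (!is.finite(dp) || !is.finite(tau) || dp < 0 || tau < 0) {
    stop("dp and tau must be finite and non-negative", call. = FALSE)
  }
  dp < tau
}
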