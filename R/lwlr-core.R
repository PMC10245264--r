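#' Quadratic climate design matrix
#'
#' Builds the regression design shared by the global and locally weighted
#' models: an intercept plus linear and quadratic terms in temperature and
#' precipitation, `[1, T, T^2, P, P^2]`.  The quadratic terms let each climate
#' variable act through a concave or convex response (too little and too much
#' water/heat both depress greenness).
#'
#' @param T temperature series.
#' @param P precipitation series, same length.
#' @return An `M x 5` numeric matrix with columns
#'   `(Intercept)`, `T`, `T2`, `P`, `P2`.
#' @examples
#' build_design(T = c(2, 0), P = c(3, 0))
#' @export
build_design <- function(T, P) {
  T <- as.numeric(T); P <- as.numeric(P)
  if (length(T) != length(P)) {
    stop("T and P must have equal length", call. = FALSE)
  }
  if (!all(is.finite(T)) || !all(is.finite(P))) {
    stop("design inputs must be finite", call. = FALSE)
  }
  X <- cbind(1, T, T^2, P, P^2)
  colnames(X) <- c("(Intercept)", "T", "T2", "P", "P2")
  X
}

#' Asymmetric dual-bandwidth Gaussian kernel
#'
#' Specification of the temporal weighting kernel.  Months before the focal
#' month decay with bandwidth `h1`, the focal month and later months with
#' `h2`; the ratio `Rh = h2 / h1` summarises the lead-lag asymmetry between
#' the vegetation index and the climate drivers.
#'
#' @param h1 bandwidth (months) applied to time points before the focal month.
#' @param h2 bandwidth (months) applied to the focal month and later points.
#' @return An object of class `kernel_spec` with fields `h1`, `h2`, `Rh`.
#' @details Bandwidths below 1 month are rejected: the local regression has 5
#'   unknowns and needs a few effectively weighted months of support even at
#'   the series ends.
#' @export
kernel_spec <- function(h1, h2 = h1) {
  h1 <- as.numeric(h1); h2 <- as.numeric(h2)
  if (length(h1) != 1L || length(h2) != 1L || !is.finite(h1) || !is.finite(h2)) {
    stop("h1 and h2 must be single finite numbers", call. = FALSE)
  }
  if (h1 < 1 || h2 < 1) {
    stop("bandwidths must be >= 1 month (got h1 = ", h1, ", h2 = ", h2, ")",
         call. = FALSE)
  }
  structure(list(h1 = h1, h2 = h2, Rh = h2 / h1), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> h1 = %g, h2 = %g months (Rh = %.3f)\n",
              x$h1, x$h2, x$Rh))
  invisible(x)
}

as_kernel_spec <- function(spec) {
  if (inherits(spec, "kernel_spec")) return(spec)
  if (is.numeric(spec) && length(spec) == 2L) return(kernel_spec(spec[1], spec[2]))
  stop("expected a 'kernel_spec' (see kernel_spec()) or a numeric pair (h1, h2)",
       call. = FALSE)
}

#' Kernel weights around a focal month
#'
#' Weight of every month `j = 1..M` relative to focal month `t`:
#' `exp(-((j - t) / h1)^2 / 2)` for `j < t` and
#' `exp(-((j - t) / h2)^2 / 2)` for `j >= t`.  The focal month always has
#' weight 1 and weights decay monotonically with temporal distance on each
#' side.
#'
#' @param t focal month index, `1 <= t <= M`.
#' @param M series length.
#' @param spec a [kernel_spec()].
#' @return Numeric weight vector of length `M`, values in `(0, 1]`.
#' @examples
#' w <- kernel_weights(6, 12, kernel_spec(2, 8))
#' w[6]            # focal month: 1
#' w[2]            # 4 months back, h1 = 2: exp(-2)
#' w[10]           # 4 months ahead, h2 = 8: exp(-0.125)
#' @export
kernel_weights <- function(t, M, spec) {
  spec <- as_kernel_spec(spec)
  if (length(t) != 1L || t < 1L || t > M || t != round(t)) {
    stop("focal month t must be an integer in 1..M", call. = FALSE)
  }
  d <- seq_len(M) - t
  h <- ifelse(d < 0, spec$h1, spec$h2)
  exp(-0.5 * (d / h)^2)
}

# Least-squares solve with a pseudo-inverse fallback for (numerically)
# singular systems.  Returns coefficients plus a singularity flag.
ls_solve <- function(A, b, tol = 1e-10) {
  fit <- .lm.fit(A, b)
  if (fit$rank == ncol(A)) {
    co <- fit$coefficients
    return(list(coefficients = co, singular = FALSE))
  }
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1]
  co <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  list(coefficients = drop(co), singular = TRUE)
}

# R^2 in the "explained variance" form: sum(fitted - mean(y))^2 over
# sum(y - mean(y))^2.  For plain OLS with an intercept this equals
# 1 - SSE/SST; for a locally weighted fit it may exceed 1.
r2_explained <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps * length(y)) {
    return(NA_real_)
  }
  sum((fitted - mean(y))^2) / sst
}

#' Global (constant-coefficient) quadratic regression
#'
#' Ordinary least squares fit of NDVI on the quadratic climate design with
#' time-constant coefficients.  This is the benchmark the locally weighted
#' model is compared against through the ratio `Rlg = Rl2 / Rg2`.
#'
#' @param cell a [cell_series()].
#' @return An object of class `global_fit`: coefficients `beta`, `fitted`,
#'   `residuals`, the determination coefficient `Rg2` (`NA` and flagged
#'   `degenerate` when NDVI has zero variance), and `rank_deficient`.
#' @export
fit_global <- function(cell) {
  assert_cell(cell)
  X <- build_design(cell$T, cell$P)
  sol <- ls_solve(X, cell$N)
  if (sol$singular) {
    warning("rank-deficient global design; coefficients from pseudo-inverse",
            call. = FALSE)
  }
  beta <- stats::setNames(sol$coefficients, colnames(X))
  fitted <- drop(X %*% beta)
  res <- cell$N - fitted
  Rg2 <- r2_explained(cell$N, fitted)
  structure(
    list(beta = beta, fitted = fitted, residuals = res, Rg2 = Rg2,
         degenerate = is.na(Rg2), rank_deficient = sol$singular),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>  Rg2 =", format(x$Rg2, digits = 4), "\n")
  print(signif(x$beta, 4))
  invisible(x)
}

# Core LWLR engine: one weighted solve per focal index of y on X.
# `zero_self` supports leave-one-out prediction.  Shared by fit_lwlr(),
# the bandwidth CV and the Cochrane-Orcutt refits.
lwlr_coefs <- function(X, y, spec, focal = seq_len(nrow(X)), zero_self = FALSE) {
  M <- nrow(X)
  p <- ncol(X)
  beta <- matrix(NA_real_, length(focal), p, dimnames = list(NULL, colnames(X)))
  singular <- logical(length(focal))
  for (k in seq_along(focal)) {
    t <- focal[k]
    w <- kernel_weights(t, M, spec)
    if (zero_self) w[t] <- 0
    sw <- sqrt(w)
    sol <- ls_solve(X * sw, y * sw)
    beta[k, ] <- sol$coefficients
    singular[k] <- sol$singular
  }
  list(beta = beta, singular = singular)
}

#' Local coefficient estimate at one focal month
#'
#' Solves the kernel-weighted least-squares problem centred at month `t`,
#' giving the time-varying coefficient vector
#' `(beta0(t), beta1(t), ..., beta4(t))`.
#'
#' @param t focal month index.
#' @param cell a [cell_series()].
#' @param spec a [kernel_spec()].
#' @return List with `beta` (named length-5 vector) and `singular` (flag set
#'   when the weighted moment matrix was solved by pseudo-inverse).
#' @export
fit_local <- function(t, cell, spec) {
  assert_cell(cell)
  X <- build_design(cell$T, cell$P)
  out <- lwlr_coefs(X, cell$N, spec, focal = t)
  list(beta = stats::setNames(out$beta[1, ], colnames(X)),
       singular = out$singular[1])
}

#' Locally weighted regression fit with time-varying coefficients
#'
#' Estimates the full coefficient trajectories `beta0(t)..beta4(t)` by
#' repeating the kernel-weighted least-squares solve at every month, then
#' forms fitted values, residuals and the local determination coefficient
#' `Rl2` together with its ratio to the global fit, `Rlg = Rl2 / Rg2`.
#' `Rlg > 1` means the time-varying model explains more NDVI variance than
#' the constant-coefficient benchmark.
#'
#' @param cell a [cell_series()].
#' @param spec a [kernel_spec()].
#' @return An object of class `lwlr_fit` with fields `beta_t` (`M x 5`
#'   trajectory matrix), `fitted`, `residuals`, `Rl2`, `Rg2`, `Rlg`,
#'   `kernel`, `t_index` (months the trajectories refer to),
#'   `boundary_flag` (`TRUE` within `max(h1, h2)` months of either series
#'   end, where the one-sided kernel support makes estimates less stable)
#'   and `singular` (per-month pseudo-inverse flags).
#'
#' @details `Rl2` uses the explained-variance form
#'   `sum((fitted - mean(N))^2) / sum((N - mean(N))^2)`.  Because a locally
#'   weighted fit is not an orthogonal projection, `Rl2` can exceed 1 for
#'   aggressive (small) bandwidths; values are reported as computed.
#' @seealso [select_bandwidths()] for choosing `(h1, h2)`,
#'   [pnc_series()] for the attribution layer.
#' @export
fit_lwlr <- function(cell, spec) {
  assert_cell(cell)
  spec <- as_kernel_spec(spec)
  X <- build_design(cell$T, cell$P)
  out <- lwlr_coefs(X, cell$N, spec)
  fitted <- rowSums(X * out$beta)
  res <- cell$N - fitted
  gl <- fit_global(cell)
  Rl2 <- r2_explained(cell$N, fitted)
  hmax <- max(spec$h1, spec$h2)
  tt <- seq_len(cell$M)
  new_lwlr_fit(
    beta_t = out$beta, fitted = fitted, residuals = res,
    Rl2 = Rl2, Rg2 = gl$Rg2,
    kernel = spec, t_index = tt,
    boundary_flag = tt <= hmax | tt > cell$M - hmax,
    singular = out$singular, cell_id = cell$cell_id
  )
}

new_lwlr_fit <- function(beta_t, fitted, residuals, Rl2, Rg2, kernel, t_index,
                         boundary_flag, singular, cell_id,
                         corrected = FALSE, rho = NA_real_) {
  structure(
    list(beta_t = beta_t, fitted = fitted, residuals = residuals,
         Rl2 = Rl2, Rg2 = Rg2,
         Rlg = if (is.na(Rl2) || is.na(Rg2)) NA_real_ else Rl2 / Rg2,
         kernel = kernel, t_index = t_index, boundary_flag = boundary_flag,
         singular = singular, cell_id = cell_id,
         corrected = corrected, rho = rho),
    class = "lwlr_fit"
  )
}

#' @export
print.lwlr_fit <- function(x, ...) {
  cat("<lwlr_fit> ", x$cell_id,
      if (x$corrected) "  (Cochrane-Orcutt corrected)", "\n", sep = "")
  cat(sprintf("  kernel h1 = %g, h2 = %g (Rh = %.3f)\n",
              x$kernel$h1, x$kernel$h2, x$kernel$Rh))
  cat(sprintf("  Rl2 = %.4f, Rg2 = %.4f, Rlg = %.4f\n", x$Rl2, x$Rg2, x$Rlg))
  cat(sprintf("  months: %d (%d boundary, %d singular)\n",
              length(x$t_index), sum(x$boundary_flag), sum(x$singular)))
  invisible(x)
}
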