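#' Default candidate bandwidth grid
#'
#' Cartesian product of `h1, h2 in {1, 2, 3, 4, 6, 9, 12, 18, 24, 36, 48}`
#' months.  The set spans sub-seasonal to multi-year smoothing on a roughly
#' geometric ladder; 121 candidates keep an exhaustive leave-one-out search
#' affordable for series of a few hundred months.
#'
#' @param h1,h2 candidate values for the left and right bandwidths.
#' @return A data frame with columns `h1`, `h2`.
#' @export
default_bandwidth_grid <- function(h1 = c(1, 2, 3, 4, 6, 9, 12, 18, 24, 36, 48),
                                   h2 = h1) {
  expand.grid(h1 = as.numeric(h1), h2 = as.numeric(h2), KEEP.OUT.ATTRS = FALSE)
}

#' Leave-one-out prediction at a focal month
#'
#' Re-estimates the local coefficients at month `t` with the weight of month
#' `t` itself set to zero, then predicts NDVI there from its own design row.
#' This is the building block of the bandwidth cross-validation score.
#'
#' @param t focal month index.
#' @param cell a [cell_series()].
#' @param spec a [kernel_spec()].
#' @return The held-out prediction (scalar).
#' @export
loo_predict <- function(t, cell, spec) {
  assert_cell(cell)
  X <- build_design(cell$T, cell$P)
  out <- lwlr_coefs(X, cell$N, spec, focal = t, zero_self = TRUE)
  drop(X[t, ] %*% out$beta[1, ])
}

#' Leave-one-out cross-validation score for one bandwidth pair
#'
#' Sum over all months of the squared held-out prediction error,
#' `sum_t (N(t) - Nhat_{-t}(t))^2`.  Boundary months are included in the sum.
#'
#' @param cell a [cell_series()].
#' @param spec a [kernel_spec()].
#' @return Scalar CV score (sum of squared errors).
#' @export
cv_score <- function(cell, spec) {
  assert_cell(cell)
  spec <- as_kernel_spec(spec)
  X <- build_design(cell$T, cell$P)
  N <- cell$N
  M <- cell$M
  err2 <- numeric(M)
  for (t in seq_len(M)) {
    w <- kernel_weights(t, M, spec)
    w[t] <- 0
    sw <- sqrt(w)
    sol <- ls_solve(X * sw, N * sw)
    pred <- drop(X[t, ] %*% sol$coefficients)
    if (!is.finite(pred)) {
      stop("non-finite leave-one-out prediction at t = ", t,
           " (h1 = ", spec$h1, ", h2 = ", spec$h2, ")", call. = FALSE)
    }
    err2[t] <- (N[t] - pred)^2
  }
  sum(err2)
}

#' Select the dual bandwidths by exhaustive leave-one-out cross-validation
#'
#' Evaluates [cv_score()] for every candidate `(h1, h2)` pair and returns the
#' minimiser.  Ties (within machine tolerance) are broken by preferring the
#' smaller `h1 + h2`, then the ratio `h2/h1` closest to 1, then lexicographic
#' order on `(h1, h2)`.
#'
#' @param cell a [cell_series()].
#' @param grid data frame of candidates with columns `h1`, `h2`
#'   (default [default_bandwidth_grid()]).
#' @return An object of class `cv_result`: the scored `grid` (with `score`
#'   and `rmse` columns), the selected `best` [kernel_spec()], `score_best`
#'   and `rmse_best`.
#' @export
select_bandwidths <- function(cell, grid = default_bandwidth_grid()) {
  assert_cell(cell)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L || !all(c("h1", "h2") %in% names(grid))) {
    stop("grid must be a non-empty data frame with columns h1, h2",
         call. = FALSE)
  }
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(cv_score(cell, kernel_spec(grid$h1[i], grid$h2[i])),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("all candidate bandwidths produced non-finite CV scores",
         call. = FALSE)
  }
  smin <- min(scores[is.finite(scores)])
  # candidates tied with the minimum (relative tolerance), then tie-break
  tied <- which(is.finite(scores) & scores <= smin * (1 + 1e-12))
  ord <- order(grid$h1[tied] + grid$h2[tied],
               abs(grid$h2[tied] / grid$h1[tied] - 1),
               grid$h1[tied], grid$h2[tied])
  best_i <- tied[ord[1]]
  grid$score <- scores
  grid$rmse <- sqrt(scores / cell$M)
  structure(
    list(grid = grid,
         best = kernel_spec(grid$h1[best_i], grid$h2[best_i]),
         score_best = scores[best_i],
         rmse_best = grid$rmse[best_i],
         cell_id = cell$cell_id),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$cell_id, ": ", nrow(x$grid), " candidates\n", sep = "")
  cat(sprintf("  best h1 = %g, h2 = %g (Rh = %.3f), CV = %.6g (RMSE %.4g)\n",
              x$best$h1, x$best$h2, x$best$Rh, x$score_best, x$rmse_best))
  invisible(x)
}
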