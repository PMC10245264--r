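#' Monthly NDVI/climate series for one grid cell
#'
#' Bundles the three aligned monthly series the attribution model works on:
#' a vegetation index (NDVI, unitless), air temperature (degrees C) and
#' precipitation (mm/month).  The month index `t` runs `1..M` from the first
#' month present; all downstream trend quantities are per-month rates on that
#' index.
#'
#' @param N numeric vector, NDVI series.
#' @param T numeric vector, temperature series (degrees C), same length as `N`.
#' @param P numeric vector, precipitation series (mm/month), same length as `N`.
#' @param cell_id identifier for the cell.
#' @param lon,lat cell centre coordinates in decimal degrees (optional).
#' @param start_month calendar month (1-12) of the first observation; carried
#'   as metadata only.
#'
#' @return An object of class `cell_series`: a list with elements `cell_id`,
#'   `lon`, `lat`, `start_month`, `N`, `T`, `P` and the series length `M`.
#'
#' @details Series must be complete (no missing values) and at least 12 months
#'   long; at least 36 months (three seasonal cycles) are recommended for a
#'   stable local fit and are required by the STL-based attribution layer.
#'
#' @examples
#' tt <- 1:48
#' cell <- cell_series(N = 0.3 + 0.1 * sin(2 * pi * tt / 12),
#'                     T = 10 + 12 * cos(2 * pi * (tt - 7) / 12),
#'                     P = pmax(0, 80 + 60 * cos(2 * pi * (tt - 7) / 12)))
#' cell
#' @export
cell_series <- function(N, T, P, cell_id = "cell-1", lon = NA_real_,
                        lat = NA_real_, start_month = 1L) {
  N <- as.numeric(N); T <- as.numeric(T); P <- as.numeric(P)
  M <- length(N)
  if (length(T) != M || length(P) != M) {
    stop("N, T and P must have identical length; got ",
         M, ", ", length(T), ", ", length(P), call. = FALSE)
  }
  if (M < 12L) {
    stop("series too short (M = ", M, "); at least 12 months are required",
         call. = FALSE)
  }
  if (anyNA(N) || anyNA(T) || anyNA(P) ||
      !all(is.finite(N)) || !all(is.finite(T)) || !all(is.finite(P))) {
    stop("series contain missing or non-finite values", call. = FALSE)
  }
  structure(
    list(cell_id = cell_id, lon = as.numeric(lon), lat = as.numeric(lat),
         start_month = as.integer(start_month), N = N, T = T, P = P, M = M),
    class = "cell_series"
  )
}

#' @export
print.cell_series <- function(x, ...) {
  cat("<cell_series> ", x$cell_id, "  (", x$M, " months)\n", sep = "")
  if (is.finite(x$lon) && is.finite(x$lat)) {
    cat("  location: ", format(x$lon), "E ", format(x$lat), "N\n", sep = "")
  }
  cat(sprintf("  NDVI   mean %.3f  range [%.3f, %.3f]\n",
              mean(x$N), min(x$N), max(x$N)))
  cat(sprintf("  temp   mean %.1f C   precip mean %.1f mm/month\n",
              mean(x$T), mean(x$P)))
  invisible(x)
}

is_cell_series <- function(x) inherits(x, "cell_series")

assert_cell <- function(cell) {
  if (!is_cell_series(cell)) {
    stop("expected a 'cell_series' object; see cell_series()", call. = FALSE)
  }
  invisible(cell)
}
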