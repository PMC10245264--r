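#' Pipeline run configuration
#'
#' Assembles (and validates) the settings of the per-cell attribution
#' workflow.  Values mirror the method's operating defaults: a 0.15 mean-NDVI
#' vegetation mask, the full bandwidth grid, the Durbin-Watson band
#' `[1.70, 2.30]` that triggers the Cochrane-Orcutt correction, the
#' calibrated normality threshold `tau = 0.04`, a `5e-6` NDVI/month
#' significance floor for the changing trends, and the `2e-5` / `2e-4`
#' NDVI/month greening-slope thresholds.
#'
#' @param mask_threshold mean-NDVI cutoff; cells at or below it are masked.
#' @param cv_grid candidate bandwidth data frame (columns `h1`, `h2`).
#' @param tau normality threshold; see [calibrate_tau()].
#' @param dw_band acceptable Durbin-Watson interval.
#' @param co_max_iter,co_tol Cochrane-Orcutt iteration controls.
#' @param alpha_threshold trend-significance floor (NDVI/month).
#' @param slope_thresholds greening-slope class thresholds (NDVI/month).
#' @param vif_warn VIF level above which a collinearity flag is raised.
#' @param seed RNG seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(mask_threshold = 0.15,
                       cv_grid = default_bandwidth_grid(),
                       tau = 0.04,
                       dw_band = c(1.70, 2.30),
                       co_max_iter = 20L, co_tol = 1e-3,
                       alpha_threshold = 5e-6,
                       slope_thresholds = c(2e-5, 2e-4),
                       vif_warn = 4,
                       seed = 1L) {
  stopifnot(mask_threshold > 0, mask_threshold < 1,
            all(slope_thresholds > 0), alpha_threshold > 0,
            length(dw_band) == 2L, dw_band[1] < dw_band[2])
  structure(
    list(mask_threshold = mask_threshold, cv_grid = as.data.frame(cv_grid),
         tau = tau, dw_band = dw_band,
         co_max_iter = as.integer(co_max_iter), co_tol = co_tol,
         alpha_threshold = alpha_threshold,
         slope_thresholds = slope_thresholds, vif_warn = vif_warn,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' The round trip through the file is lossless.
#'
#' @param path YAML file path.
#' @param config a [run_config()].
#' @return `read_config()`: a `run_config`; `write_config()`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (key in intersect(names(raw), names(cfg))) {
    val <- raw[[key]]
    if (key == "cv_grid") val <- as.data.frame(val)
    cfg[[key]] <- val
  }
  cfg$co_max_iter <- as.integer(cfg$co_max_iter)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$cv_grid <- as.list(config$cv_grid)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Vegetation mask
#'
#' Partitions cells by mean NDVI: a cell whose average NDVI over the study
#' period is less than or equal to `threshold` is classified as having no
#' vegetation and excluded.
#'
#' @param cells list of [cell_series()] objects.
#' @param threshold mean-NDVI cutoff (inclusive).
#' @return List with `kept` and `excluded` (both lists of cells) and the
#'   logical vector `masked`.
#' @export
mask_cells <- function(cells, threshold = 0.15) {
  stopifnot(threshold > 0, threshold < 1)
  masked <- vapply(cells, function(c) mean(c$N) <= threshold, logical(1))
  list(kept = cells[!masked], excluded = cells[masked], masked = masked)
}

#' Run the full attribution workflow on one cell
#'
#' Stages: select bandwidths by leave-one-out CV; weighted VIF with the
#' selected kernel; LWLR fit; Durbin-Watson check and, when the statistic
#' falls outside `config$dw_band`, the Cochrane-Orcutt correction; the
#' Delta-P normality test on the final residuals; and the attribution layer
#' (PNC/APNC, changing trends, relative roles, ingredient structure,
#' greening class).  Any stage failure is caught and reported in the
#' outcome; a batch never aborts because of one cell.
#'
#' @param cell a [cell_series()].
#' @param config a [run_config()].
#' @return An object of class `cell_outcome`.  For `status = "fitted"` it
#'   carries `fit`, `cv`, `diagnostics` (a list with `vif_max`,
#'   `vif_flag`, `dw`, `dw_in_band`, `rho`, `co_iterations`,
#'   `co_converged`, `delta_p`, `tau`, `normal_pass`), `attribution`
#'   (APNC values, `R_ac` + bin, all four alphas, `Ra`, `Rc`,
#'   `driver_class`, `dominant_factor`, `slope`, `slope_class`) and stage
#'   `timings`; for `status = "failed"`, the failing `stage` and `error`.
#' @export
run_cell <- function(cell, config = run_config()) {
  assert_cell(cell)
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  stage <- "start"
  outcome <- tryCatch({
    tick <- function(name, expr) {
      stage <<- name
      t0 <- proc.time()[["elapsed"]]
      val <- force(expr)
      timings[name] <<- proc.time()[["elapsed"]] - t0
      val
    }
    cv <- tick("select_bandwidths", select_bandwidths(cell, config$cv_grid))
    vif <- tick("weighted_vif",
                weighted_vif(build_design(cell$T, cell$P), cv$best))
    fit <- tick("fit_lwlr", fit_lwlr(cell, cv$best))
    dw0 <- tick("durbin_watson", durbin_watson(fit$residuals))
    co <- NULL
    dw <- dw0
    if (is.finite(dw0) &&
        (dw0 < config$dw_band[1] || dw0 > config$dw_band[2])) {
      co <- tick("cochrane_orcutt",
                 cochrane_orcutt(cell, cv$best,
                                 max_iter = config$co_max_iter,
                                 tol = config$co_tol))
      fit <- co$fit
      dw <- co$dw_after
    }
    diag_res <- if (!is.null(fit$residuals_white)) {
      fit$residuals_white   # whitened residuals after Cochrane-Orcutt
    } else {
      fit$residuals
    }
    dp <- tick("delta_p", tryCatch(delta_p(diag_res),
                                   error = function(e) NA_real_))
    normal_pass <- if (is.na(dp)) NA else normality_test(dp, config$tau)
    att <- tick("attribution", {
      series <- pnc_series(fit, cell)
      ap <- apnc(series)
      al <- compute_alphas(series, fit)
      ing <- ingredient_structure(fit, cell)
      roles <- relative_roles(al$alpha0, al$alpha,
                              insig_threshold = config$alpha_threshold)
      share <- apnc_share(ap$f_bar, ap$g_bar, ap$b0_bar)
      slope <- monthly_slope_class(cell$N, config$slope_thresholds)
      list(f_bar = ap$f_bar, g_bar = ap$g_bar, b0_bar = ap$b0_bar,
           apnc_dominant = ap$dominant,
           R_ac = share$R_ac, R_ac_bin = share$bin,
           alpha = al$alpha, alpha0 = al$alpha0,
           alpha1 = al$alpha1, alpha3 = al$alpha3,
           Ra = roles$Ra, Rc = roles$Rc, roles_defined = roles$defined,
           driver_class = roles$driver_class,
           dominant_factor = ing$dominant_factor,
           slope = slope$slope, slope_class = slope$class)
    })
    diagnostics <- list(
      vif_max = vif$vif_max, vif_flag = vif$vif_max > config$vif_warn,
      dw = dw0, dw_in_band = is.finite(dw0) &&
        dw0 >= config$dw_band[1] && dw0 <= config$dw_band[2],
      dw_final = dw,
      rho = if (is.null(co)) acf_lag1(fit$residuals) else co$rho,
      co_applied = !is.null(co),
      co_iterations = if (is.null(co)) 0L else co$iterations,
      co_converged = if (is.null(co)) NA else co$converged,
      delta_p = dp, tau = config$tau, normal_pass = normal_pass)
    structure(
      list(cell_id = cell$cell_id, lon = cell$lon, lat = cell$lat,
           status = "fitted", cv = cv, fit = fit,
           diagnostics = diagnostics, attribution = att,
           boundary_fraction = mean(fit$boundary_flag), timings = timings),
      class = "cell_outcome")
  }, error = function(e) {
    structure(
      list(cell_id = cell$cell_id, lon = cell$lon, lat = cell$lat,
           status = "failed", stage = stage, error = conditionMessage(e),
           timings = timings),
      class = "cell_outcome")
  })
  outcome
}

#' @export
print.cell_outcome <- function(x, ...) {
  cat("<cell_outcome> ", x$cell_id, ": ", x$status, "\n", sep = "")
  if (x$status == "failed") {
    cat("  stage '", x$stage, "': ", x$error, "\n", sep = "")
  } else if (x$status == "fitted") {
    cat(sprintf("  h = (%g, %g), Rlg = %.3f, DW = %.2f, Delta-P = %.3f\n",
                x$fit$kernel$h1, x$fit$kernel$h2, x$fit$Rlg,
                x$diagnostics$dw, x$diagnostics$delta_p))
    cat(sprintf("  APNC f = %.3f, g = %.3f, b0 = %.3f;  Ra = %.2f (%s)\n",
                x$attribution$f_bar, x$attribution$g_bar,
                x$attribution$b0_bar, x$attribution$Ra,
                x$attribution$driver_class))
  }
  invisible(x)
}

masked_outcome <- function(cell) {
  structure(
    list(cell_id = cell$cell_id, lon = cell$lon, lat = cell$lat,
         status = "masked"),
    class = "cell_outcome")
}

#' Run the attribution pipeline over a grid of cells
#'
#' Masks no-vegetation cells, runs [run_cell()] on the rest, and assembles
#' the per-cell results table plus a run summary with the masked fraction,
#' the `Rlg` level bins (`1.00-1.10`, `1.11-1.20`, ..., `>1.50`), the
#' Delta-P pass fraction, `Ra` and `R_ac` bin fractions, and the sign
#' classes of the changing trends.
#'
#' @param input list of [cell_series()], a [make_grid()] result, or the path
#'   of a long-format CSV (see [read_long_csv()]).
#' @param config a [run_config()].
#' @return An object of class `grid_result`: `outcomes` (list of
#'   [run_cell()] outcomes), `table` (one row per cell, see
#'   [outcome_table()]), `summary` (list) and `config`.
#' @export
run_grid <- function(input, config = run_config()) {
  cells <- if (is.character(input)) {
    read_long_csv(input)
  } else if (inherits(input, "synthetic_grid")) {
    input$cells
  } else {
    input
  }
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id in input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mask <- mask_cells(cells, config$mask_threshold)
  outcomes <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    outcomes[[i]] <- if (mask$masked[i]) {
      masked_outcome(cells[[i]])
    } else {
      run_cell(cells[[i]], config)
    }
  }
  tab <- outcome_table(outcomes)
  structure(
    list(outcomes = outcomes, table = tab,
         summary = summarise_outcomes(tab, config), config = config),
    class = "grid_result"
  )
}

#' Flatten cell outcomes into a results table
#'
#' @param outcomes list of [run_cell()] outcomes.
#' @return A data frame with one row per cell: identifiers and coordinates,
#'   status, selected bandwidths and `Rh`, fit statistics (`Rg2`, `Rl2`,
#'   `Rlg`), diagnostics, the attribution quantities and the boundary-month
#'   fraction.
#' @export
outcome_table <- function(outcomes) {
  row_for <- function(o) {
    base <- data.frame(
      cell_id = o$cell_id, lon = o$lon, lat = o$lat, status = o$status,
      h1 = NA_real_, h2 = NA_real_, Rh = NA_real_,
      Rg2 = NA_real_, Rl2 = NA_real_, Rlg = NA_real_,
      vif_max = NA_real_, dw = NA_real_, rho = NA_real_,
      co_applied = NA, delta_p = NA_real_, normal_pass = NA,
      f_bar = NA_real_, g_bar = NA_real_, b0_bar = NA_real_,
      R_ac = NA_real_, R_ac_bin = NA_character_,
      alpha = NA_real_, alpha0 = NA_real_,
      alpha1 = NA_real_, alpha3 = NA_real_,
      Ra = NA_real_, Rc = NA_real_,
      driver_class = NA_character_, dominant_factor = NA_character_,
      slope = NA_real_, slope_class = NA_character_,
      boundary_fraction = NA_real_,
      stage_failed = NA_character_, error = NA_character_,
      stringsAsFactors = FALSE)
    if (o$status == "fitted") {
      a <- o$attribution; d <- o$diagnostics
      base[c("h1", "h2", "Rh")] <-
        list(o$fit$kernel$h1, o$fit$kernel$h2, o$fit$kernel$Rh)
      base[c("Rg2", "Rl2", "Rlg")] <- list(o$fit$Rg2, o$fit$Rl2, o$fit$Rlg)
      base[c("vif_max", "dw", "rho", "co_applied", "delta_p",
             "normal_pass")] <-
        list(d$vif_max, d$dw, d$rho, d$co_applied, d$delta_p, d$normal_pass)
      base[c("f_bar", "g_bar", "b0_bar", "R_ac", "R_ac_bin",
             "alpha", "alpha0", "alpha1", "alpha3", "Ra", "Rc",
             "driver_class", "dominant_factor", "slope", "slope_class")] <-
        list(a$f_bar, a$g_bar, a$b0_bar, a$R_ac, a$R_ac_bin,
             a$alpha, a$alpha0, a$alpha1, a$alpha3, a$Ra, a$Rc,
             a$driver_class, a$dominant_factor, a$slope, a$slope_class)
      base$boundary_fraction <- o$boundary_fraction
    } else if (o$status == "failed") {
      base$stage_failed <- o$stage
      base$error <- o$error
    }
    base
  }
  do.call(rbind, lapply(outcomes, row_for))
}

rlg_bins <- c(1.00, 1.10, 1.20, 1.30, 1.40, 1.50, Inf)
rlg_bin_labels <- c("1.00-1.10", "1.11-1.20", "1.21-1.30", "1.31-1.40",
                    "1.41-1.50", ">1.50")

summarise_outcomes <- function(tab, config) {
  n <- nrow(tab)
  fitted <- tab[tab$status == "fitted", , drop = FALSE]
  bin_frac <- function(x, breaks, labels) {
    x <- x[is.finite(x)]
    if (!length(x)) return(stats::setNames(rep(NA_real_, length(labels)),
                                           labels))
    counts <- table(cut(x, breaks = breaks, labels = labels,
                        include.lowest = TRUE, right = TRUE))
    as.numeric(counts) / length(x) |> stats::setNames(labels)
  }
  sign_frac <- function(x, thr) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(negative = NA, insignificant = NA,
                             positive = NA))
    c(negative = mean(x < -thr),
      insignificant = mean(abs(x) <= thr),
      positive = mean(x > thr))
  }
  list(
    n_cells = n,
    n_masked = sum(tab$status == "masked"),
    n_fitted = nrow(fitted),
    n_failed = sum(tab$status == "failed"),
    masked_fraction = mean(tab$status == "masked"),
    rlg_bin_counts = if (nrow(fitted)) {
      table(cut(pmax(fitted$Rlg, 1), breaks = rlg_bins,
                labels = rlg_bin_labels, include.lowest = TRUE))
    } else {
      NULL
    },
    normal_pass_fraction = if (nrow(fitted)) {
      mean(fitted$normal_pass, na.rm = TRUE)
    } else {
      NA_real_
    },
    mean_Ra = if (nrow(fitted)) mean(fitted$Ra, na.rm = TRUE) else NA_real_,
    mean_Rc = if (nrow(fitted)) mean(fitted$Rc, na.rm = TRUE) else NA_real_,
    R_ac_bin_fractions = if (nrow(fitted)) {
      prop.table(table(factor(fitted$R_ac_bin,
                              c("<=0.50", "0.51-0.75", "0.76-1.00", ">1"))))
    } else {
      NULL
    },
    alpha_sign_fractions = sign_frac(fitted$alpha, config$alpha_threshold),
    alpha0_sign_fractions = sign_frac(fitted$alpha0, config$alpha_threshold)
  )
}

#' @export
print.grid_result <- function(x, ...) {
  s <- x$summary
  cat("<grid_result> ", s$n_cells, " cells: ", s$n_fitted, " fitted, ",
      s$n_masked, " masked, ", s$n_failed, " failed\n", sep = "")
  if (!is.null(s$rlg_bin_counts)) {
    cat("  Rlg bins:\n"); print(s$rlg_bin_counts)
  }
  cat(sprintf("  mean Ra = %.3f, mean Rc = %.3f, Delta-P pass = %.2f\n",
              s$mean_Ra, s$mean_Rc, s$normal_pass_fraction))
  invisible(x)
}

#' Read a long-format grid CSV
#'
#' Expected columns: `cell_id`, `lon`, `lat`, `date` (`YYYY-MM`), `ndvi`,
#' `temp`, `precip`.  Each cell must cover a complete, gap-free monthly
#' range; cells with missing months, malformed dates or missing values are
#' rejected individually (with a warning naming the reason) without
#' affecting other cells.
#'
#' @param path CSV file path.
#' @return List of [cell_series()] objects, ordered by first appearance.
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lon", "lat", "date", "ndvi", "temp", "precip")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("input is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells <- list()
  for (id in unique(df$cell_id)) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    parsed <- regmatches(sub$date,
                         regexec("^(\\d{4})-(\\d{2})$", sub$date))
    ok <- lengths(parsed) == 3L
    if (!all(ok)) {
      warning("cell '", id, "' rejected: malformed date(s) e.g. '",
              sub$date[!ok][1], "'", call. = FALSE)
      next
    }
    yr <- as.integer(vapply(parsed, `[`, character(1), 2))
    mo <- as.integer(vapply(parsed, `[`, character(1), 3))
    if (any(mo < 1L | mo > 12L)) {
      warning("cell '", id, "' rejected: month outside 1-12", call. = FALSE)
      next
    }
    key <- yr * 12L + mo
    sub <- sub[order(key), , drop = FALSE]
    key <- sort(key)
    if (anyDuplicated(key) || !identical(key, seq(key[1], key[length(key)]))) {
      warning("cell '", id, "' rejected: missing or duplicated months",
              call. = FALSE)
      next
    }
    cell <- tryCatch(
      cell_series(sub$ndvi, sub$temp, sub$precip, cell_id = id,
                  lon = sub$lon[1], lat = sub$lat[1],
                  start_month = mo[1]),
      error = function(e) {
        warning("cell '", id, "' rejected: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(cell)) cells[[length(cells) + 1L]] <- cell
  }
  cells
}

#' Write a grid of cells as a long-format CSV
#'
#' Inverse of [read_long_csv()]; the round trip preserves series values to
#' full double precision.
#'
#' @param cells list of [cell_series()] (or a [make_grid()] result).
#' @param path output CSV path.
#' @param start `"YYYY-MM"` date assigned to month 1.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(cells, path, start = "2000-01") {
  if (inherits(cells, "synthetic_grid")) cells <- cells$cells
  p <- as.integer(strsplit(start, "-")[[1]])
  rows <- lapply(cells, function(c) {
    key <- (p[1] * 12L + p[2] - 1L) + seq_len(c$M) - 1L
    data.frame(cell_id = c$cell_id, lon = c$lon, lat = c$lat,
               date = sprintf("%04d-%02d", key %/% 12L, key %% 12L + 1L),
               ndvi = c$N, temp = c$T, precip = c$P,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write pipeline outputs
#'
#' Writes the per-cell results table as `results.csv` and the run summary
#' as `summary.json` under `dir`.
#'
#' @param result a [run_grid()] result.
#' @param dir output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "grid_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(result$table, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  s <- result$summary
  s$rlg_bin_counts <- as.list(s$rlg_bin_counts)
  s$R_ac_bin_fractions <- as.list(s$R_ac_bin_fractions)
  s$alpha_sign_fractions <- as.list(s$alpha_sign_fractions)
  s$alpha0_sign_fractions <- as.list(s$alpha0_sign_fractions)
  jsonlite::write_json(s, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
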