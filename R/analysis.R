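#' Round half away from zero
#'
#' Report-boundary rounding used for printed tables (R's `round()` rounds
#' half to even, which does not reproduce values such as 8.57 -> 8.6).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.tc_peak_column <- function(peak) {
  col <- switch(peak,
                E = "E_area", Z = "Z_area",
                adduct1 = "adduct1_area", adduct2 = "adduct2_area",
                stop(sprintf("unknown peak '%s' (use E, Z, adduct1, adduct2)",
                             peak), call. = FALSE))
  col
}

#' Conversion of a peak relative to its 0-min reference area
#'
#' The experimental reference is a thiol-free control incubation, so the
#' ratio `A(t_end)/A0` measures the net disappearance of the parent
#' chalcone, and `100 * (1 - ratio)` is its percent reduction.
#'
#' @param tc A `timecourse`.
#' @param peak Peak name (`"E"`, `"Z"`, `"adduct1"`, `"adduct2"`).
#' @param t_end Endpoint in minutes; must be on the sampling grid (default:
#'   last timepoint).
#' @param area0 Reference 0-min area (> 0); defaults to the `area0_E`
#'   metadata recorded by [simulate_scenario()] when `peak = "E"`.
#' @return An object of class `conversion_result` with fields
#'   `ratio_Aend_A0`, `percent_reduction`, `timepoint_used`. Values are kept
#'   at full precision; round only at report time.
#' @export
conversion <- function(tc, peak = "E", t_end = max(tc$time_min),
                       area0 = NULL) {
  col <- .tc_peak_column(peak)
  if (is.null(area0) && peak == "E") area0 <- tc_meta(tc)$area0_E
  if (is.null(area0) || !is.numeric(area0) || is.na(area0)) {
    stop("area0 (thiol-free control reference area) is required",
         call. = FALSE)
  }
  if (area0 == 0) stop("area0 must be non-zero", call. = FALSE)
  i <- which(tc$time_min == t_end)
  if (length(i) != 1L) {
    stop(sprintf("t_end = %g is not on the sampling grid", t_end),
         call. = FALSE)
  }
  ratio <- tc[[col]][i] / area0
  structure(
    list(ratio_Aend_A0 = ratio,
         percent_reduction = 100 * (1 - ratio),
         timepoint_used = t_end),
    class = "conversion_result"
  )
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("A(%g)/A0 = %.4g; reduction %.1f%%\n",
              x$timepoint_used, x$ratio_Aend_A0,
              round_half_up(x$percent_reduction, 1)))
  invisible(x)
}

#' Diastereomer area ratio at a timepoint
#'
#' Ratio of the adduct-2 peak (later retention, less polar diastereomer
#' pair) to the adduct-1 peak. The ratio is invariant under a common
#' rescaling of both areas, so it can be compared across detectors.
#'
#' @param tc A `timecourse`.
#' @param t Timepoint in minutes (must be on the grid).
#' @param floor Detection floor in area units; if the adduct-1 area is at or
#'   below the floor the ratio is undefined and `NA` is returned (flagged,
#'   not an error), mirroring "not detectable" table entries.
#' @return The ratio (scalar), or `NA` if undefined.
#' @export
diastereomer_ratio <- function(tc, t = max(tc$time_min), floor = 0) {
  i <- which(tc$time_min == t)
  if (length(i) != 1L) {
    stop(sprintf("t = %g is not on the sampling grid", t), call. = FALSE)
  }
  a1 <- tc$adduct1_area[i]
  a2 <- tc$adduct2_area[i]
  if (a1 <= floor) return(NA_real_)
  a2 / a1
}

#' Diastereomer ratio time series
#'
#' @param tc A `timecourse`.
#' @param floor Detection floor (see [diastereomer_ratio()]).
#' @return Data.frame `time_min`, `ratio_2_1` (`NA` where undefined).
#' @export
diastereomer_ratio_series <- function(tc, floor = 0) {
  data.frame(
    time_min = tc$time_min,
    ratio_2_1 = vapply(tc$time_min,
                       function(t) diastereomer_ratio(tc, t, floor),
                       numeric(1))
  )
}

#' Pseudo-first-order rate fit of a decaying peak
#'
#' With the thiol in 10:1 excess, the disappearance of the parent chalcone
#' is approximately first order; the observed rate constant is estimated by
#' ordinary least squares of `ln(area)` against time, anchored by the
#' thiol-free control point `(0, ln(area0))`.
#'
#' @param tc A `timecourse`.
#' @param peak Peak to fit (default the (E)-chalcone).
#' @param area0 0-min reference area; defaults to metadata as in
#'   [conversion()].
#' @return Object of class `rate_fit`: `k_obs` (1/min, = -slope),
#'   `intercept` (log-area), `r_squared`, `half_life` (min, `ln 2 / k_obs`
#'   for positive `k_obs`), `n_points`.
#' @export
pseudo_first_order_fit <- function(tc, peak = "E", area0 = NULL) {
  col <- .tc_peak_column(peak)
  if (is.null(area0) && peak == "E") area0 <- tc_meta(tc)$area0_E
  if (is.null(area0) || is.na(area0) || area0 <= 0) {
    stop("positive area0 is required for the log-linear anchor",
         call. = FALSE)
  }
  t <- c(0, tc$time_min[tc$time_min > 0])
  a <- c(area0, tc[[col]][tc$time_min > 0])
  usable <- a > 0
  if (any(!usable)) {
    warning(sprintf("%d non-positive area(s) excluded from the log fit",
                    sum(!usable)), call. = FALSE)
  }
  t <- t[usable]; a <- a[usable]
  if (length(a) < 3L) {
    stop("fewer than 3 usable (positive-area) points; cannot fit",
         call. = FALSE)
  }
  fit <- stats::lm(log(a) ~ t)
  k <- -unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(a) - mean(log(a)))^2)
  # a constant series (zero total variance) is fitted exactly by a flat line
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(k_obs = k, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         half_life = if (k > 0) log(2) / k else NA_real_,
         n_points = length(a)),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("k_obs = %.4g 1/min (t1/2 = %.4g min), r^2 = %.4f, n = %d\n",
              x$k_obs, x$half_life, x$r_squared, x$n_points))
  invisible(x)
}

#' Nonlinear exponential cross-check fit
#'
#' Direct least-squares fit of `A0 * exp(-k t)` on the linear area scale,
#' provided as a cross-check on [pseudo_first_order_fit()] (which weights
#' residuals on the log scale).
#'
#' @inheritParams pseudo_first_order_fit
#' @return List with `k_obs` and `A0_hat`.
#' @export
exponential_fit <- function(tc, peak = "E", area0 = NULL) {
  col <- .tc_peak_column(peak)
  if (is.null(area0) && peak == "E") area0 <- tc_meta(tc)$area0_E
  start_k <- pseudo_first_order_fit(tc, peak, area0)$k_obs
  df <- data.frame(t = c(0, tc$time_min[tc$time_min > 0]),
                   a = c(area0, tc[[col]][tc$time_min > 0]))
  fit <- stats::nls(a ~ A0 * exp(-k * t), data = df,
                    start = list(A0 = area0, k = max(start_k, 1e-6)),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  co <- stats::coef(fit)
  list(k_obs = unname(co["k"]), A0_hat = unname(co["A0"]))
}

#' Equilibrium-plateau test
#'
#' Classifies whether a peak has reached its equilibrium plateau: a line is
#' fitted to the last `window` points and the flag is true when the absolute
#' fitted change per 100 min, relative to the window mean, is below `tol`.
#'
#' @param tc A `timecourse`.
#' @param peak Peak name.
#' @param window Number of trailing points (>= 3).
#' @param tol Relative slope threshold (default 0.05 = 5% change per 100 min
#'   relative to the window mean).
#' @return `TRUE` if the series has plateaued.
#' @export
plateau_test <- function(tc, peak = "E", window = 4, tol = 0.05) {
  col <- .tc_peak_column(peak)
  if (window < 3) stop("window must be >= 3 points", call. = FALSE)
  if (window > nrow(tc)) {
    stop(sprintf("window (%d) exceeds series length (%d)", window, nrow(tc)),
         call. = FALSE)
  }
  idx <- seq(nrow(tc) - window + 1, nrow(tc))
  t <- tc$time_min[idx]
  a <- tc[[col]][idx]
  m <- mean(a)
  if (m == 0) return(TRUE)  # flat zero tail
  slope <- unname(stats::coef(stats::lm(a ~ t))[2])
  abs(slope) * 100 / abs(m) < tol
}

#' Summary table across incubations
#'
#' One row per time course, mirroring the layout of endpoint peak-area
#' tables: 315-min (E) conversion ratio, (Z) area, both adduct areas and
#' the diastereomer ratio. Areas at or below the detection floor are
#' reported as not detectable.
#'
#' @param tcs A list of `timecourse` objects (or a single one).
#' @param floor Detection floor in area units (default 5); adduct peaks at
#'   or below it become `NA` and the ratio is undefined.
#' @param area0 Optional vector of reference areas (recycled); defaults to
#'   each series' `area0_E` metadata.
#' @param round If `TRUE` (default), apply report rounding: ratios to 2
#'   decimals, areas to 1.
#' @return Data.frame with columns `scenario`, `compound`, `thiol`,
#'   `pH_aqueous`, `ratio_end_0`, `area_Z`, `area_adduct1`, `area_adduct2`,
#'   `ratio_2_1`. Rows with unanalyzable input carry `NA` markers.
#' @export
summary_table <- function(tcs, floor = 5, area0 = NULL, round = TRUE) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  area0 <- if (is.null(area0)) rep(NA_real_, length(tcs)) else
    rep_len(area0, length(tcs))
  rows <- lapply(seq_along(tcs), function(i) {
    tc <- tcs[[i]]
    m <- tc_meta(tc)
    a0 <- if (!is.na(area0[i])) area0[i] else m$area0_E
    t_end <- max(tc$time_min)
    j <- which(tc$time_min == t_end)
    ratio <- tryCatch(conversion(tc, "E", t_end, a0)$ratio_Aend_A0,
                      error = function(e) NA_real_)
    nd <- function(x) if (x <= floor) NA_real_ else x
    a1 <- nd(tc$adduct1_area[j]); a2 <- nd(tc$adduct2_area[j])
    data.frame(
      scenario = m$scenario %||% NA_character_,
      compound = m$compound %||% NA_character_,
      thiol = m$thiol %||% NA_character_,
      pH_aqueous = m$pH_aqueous %||% NA_real_,
      ratio_end_0 = ratio,
      area_Z = tc$Z_area[j],
      area_adduct1 = a1,
      area_adduct2 = a2,
      ratio_2_1 = if (is.na(a1) || is.na(a2)) NA_real_ else a2 / a1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (round) {
    out$ratio_end_0 <- round_half_up(out$ratio_end_0, 2)
    out$ratio_2_1 <- round_half_up(out$ratio_2_1, 2)
    for (cn in c("area_Z", "area_adduct1", "area_adduct2")) {
      out[[cn]] <- round_half_up(out[[cn]], 1)
    }
  }
  out
}

#' Write a summary table CSV with ND markers
#'
#' @param st Data.frame from [summary_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(st, path) {
  out <- st
  for (cn in c("area_adduct1", "area_adduct2", "ratio_2_1")) {
    out[[cn]] <- ifelse(is.na(st[[cn]]), "ND", format(st[[cn]], digits = 10))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
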