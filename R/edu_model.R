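#' Cell-cycle parameters from cumulative labeling
#'
#' @param tc_h Total cell-cycle length in hours.
#' @param ts_h S-phase length in hours (0 < Ts < Tc).
#' @param gf Growth fraction (fraction of cycling cells; the labeling-index
#'   plateau), in (0, 1].
#' @param slope,intercept,r2 Optional linear-fit diagnostics
#'   (slope in 1/h).
#' @return A `CellCycleParams` list; `plateau_onset_h` is Tc - Ts.
#' @export
cell_cycle_params <- function(tc_h, ts_h, gf, slope = NA_real_,
                              intercept = NA_real_, r2 = NA_real_) {
  if (!(ts_h > 0 && ts_h < tc_h)) stop("invalid params: need 0 < Ts < Tc")
  if (!(gf > 0 && gf <= 1)) stop("invalid params: need 0 < GF <= 1")
  structure(list(
    tc_h = tc_h, ts_h = ts_h, gf = gf,
    plateau_onset_h = tc_h - ts_h,
    slope = slope, intercept = intercept, r2 = r2
  ), class = "CellCycleParams")
}

as_cell_cycle_params <- function(p) {
  if (inherits(p, "CellCycleParams")) return(p)
  cell_cycle_params(p$tc_h, p$ts_h, p$gf)
}

#' @export
print.CellCycleParams <- function(x, ...) {
  cat(sprintf("Tc = %.2f h, Ts = %.2f h, GF = %.3f (plateau onset %.2f h)\n",
              x$tc_h, x$ts_h, x$gf, x$plateau_onset_h))
  if (!is.na(x$r2)) cat(sprintf("linear fit: slope %.5f /h, intercept %.4f, r2 %.4f\n",
                                x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Predicted labeling index under the linear-rise-to-plateau model
#'
#' @param params A `CellCycleParams`.
#' @param t Time(s) in hours (>= 0).
#' @return `min(GF * (t + Ts) / Tc, GF)`.
#' @export
predict_labeling <- function(params, t) {
  p <- as_cell_cycle_params(params)
  if (any(t < 0)) stop("t must be >= 0")
  pmin(p$gf * (t + p$ts_h) / p$tc_h, p$gf)
}

#' Estimate cell-cycle parameters from a cumulative-labeling curve
#'
#' Implements the classical cumulative-labeling regression: the labeling
#' index rises linearly with exposure time until every cycling cell is
#' labeled, then plateaus at the growth fraction GF. The plateau is detected
#' by scanning per-time mean labeling indices from the latest time backwards,
#' keeping times within `plateau_tol` of the curve maximum; GF is the mean of
#' the plateau observations. A least-squares line is fitted to the strictly
#' pre-plateau observations (individual replicate points, not time means);
#' then Ts = intercept / slope (the x-intercept of the line is -Ts),
#' Tc - Ts = (GF - intercept) / slope, and Tc = GF / slope.
#'
#' @param curve data.frame with `time_h` and `labeling_index` (optionally
#'   `replicate`), as from [gen_labeling_curve()].
#' @param plateau_tol Tolerance band below the maximum within which a time
#'   point counts as plateau (default 0.02).
#' @return A [cell_cycle_params()] with fit diagnostics.
#' @export
fit_cumulative_labeling <- function(curve, plateau_tol = 0.02) {
  if (!all(c("time_h", "labeling_index") %in% names(curve))) {
    stop("curve must have columns time_h and labeling_index")
  }
  if (any(curve$time_h < 0)) stop("times must be >= 0")
  if (any(curve$labeling_index < 0 | curve$labeling_index > 1)) {
    stop("labeling indices must be in [0, 1]")
  }
  tm <- tapply(curve$labeling_index, curve$time_h, mean)
  times <- as.numeric(names(tm))
  if (length(times) < 2) stop("GF unresolvable: no plateau detected")
  mx <- max(tm)
  # the plateau is the terminal flat segment: anchored at the earliest time
  # attaining the curve maximum (and everything later), extended backwards
  # through times within plateau_tol of the maximum
  t_max <- times[which.max(tm)]
  if (t_max == min(times)) stop("GF unresolvable: no plateau detected")
  plateau_start <- t_max
  for (k in rev(which(times < t_max))) {
    if (tm[k] >= mx - plateau_tol) plateau_start <- times[k] else break
  }
  on_plateau <- curve$time_h >= plateau_start
  gf <- mean(curve$labeling_index[on_plateau])
  pre <- curve[!on_plateau, , drop = FALSE]
  if (nrow(pre) < 3) stop("need >= 3 pre-plateau observations")
  fit <- stats::lm(labeling_index ~ time_h, data = pre)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("fit failure: non-positive slope")
  r2 <- summary(fit)$r.squared
  cell_cycle_params(
    tc_h = gf / slope,
    ts_h = intercept / slope,
    gf = gf,
    slope = slope, intercept = intercept, r2 = r2
  )
}
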