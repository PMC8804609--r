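# Family- and dataset-level gating statistics: conductance-voltage curves
# and their pH/zinc shifts, the voltage dependence of activation kinetics,
# and the threshold-versus-reversal regression describing pH-dependent
# gating.

#' Conductance-voltage curve of a family
#'
#' Applies [conductance_point()] to the fitted steady-state current of every
#' usable step. Steps closer than `exclude_mV` to the reversal potential are
#' excluded (the chord conductance is ill-conditioned there); small negative
#' conductances arising from noise are clamped to zero.
#'
#' @param family an `hv_family`.
#' @param vrev an `hv_reversal` (or a voltage in mV) for the driving force.
#' @param fits optional list of per-trace [fit_activation()] results;
#'   computed if missing, with failing (sub-threshold) traces dropped.
#' @param exclude_mV half-width of the exclusion window around V_rev.
#' @return an `hv_gv`: data frame `points` (`V_mV`, `g_nS`), `g_max_nS`,
#'   `V_rev_mV`, `conditions`.
#' @export
build_gv <- function(family, vrev, fits = NULL, exclude_mV = 5) {
  stopifnot(inherits(family, "hv_family"))
  vrev_mV <- if (inherits(vrev, "hv_reversal")) vrev$V_rev_mV else as.numeric(vrev)
  if (is.null(fits)) {
    fits <- lapply(family$traces, function(tr)
      tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL))
  }
  fits <- Filter(Negate(is.null), fits)
  v <- vapply(fits, `[[`, numeric(1), "V_mV")
  iss <- vapply(fits, `[[`, numeric(1), "I_ss_pA")
  keep <- abs(v - vrev_mV) >= exclude_mV
  v <- v[keep]; iss <- iss[keep]
  if (length(v) < 3L)
    stop("fewer than 3 usable conductance points in this family")
  o <- order(v)
  g <- pmax(conductance_point(iss[o], v[o], vrev_mV), 0)
  structure(list(points = data.frame(V_mV = v[o], g_nS = g),
                 g_max_nS = max(g), V_rev_mV = vrev_mV,
                 conditions = family$conditions),
            class = "hv_gv")
}

#' @export
print.hv_gv <- function(x, ...) {
  cat(sprintf("g-V curve: %d points, g_max = %.3f nS (V_rev %+.1f mV)\n",
              nrow(x$points), x$g_max_nS, x$V_rev_mV))
  invisible(x)
}

#' @export
plot.hv_gv <- function(x, ...) {
  graphics::plot(x$points$V_mV, x$points$g_nS / x$g_max_nS, type = "b",
                 xlab = "V (mV)", ylab = "g / g_max", ...)
  invisible(x)
}

# half-maximum voltage of a normalized conductance curve by linear
# interpolation at the first upward crossing of 0.5
gv_half_mV <- function(gv) {
  v <- gv$points$V_mV
  gn <- gv$points$g_nS / gv$g_max_nS
  if (min(gn) > 0.5 || max(gn) < 0.5)
    stop("curve does not span its half-maximum; cannot locate V_half")
  i <- which(gn >= 0.5)[1L]
  if (i == 1L) return(v[1L])
  v[i - 1L] + (v[i] - v[i - 1L]) * (0.5 - gn[i - 1L]) / (gn[i] - gn[i - 1L])
}

#' Voltage shift between two conductance-voltage curves
#'
#' Difference of the half-maximum voltages of the two normalized curves;
#' positive values mean curve `b` lies rightward (more positive) of curve
#' `a`. Antisymmetric by construction.
#'
#' @param curve_a,curve_b `hv_gv` objects, each spanning its half-maximum.
#' @return shift in mV.
#' @export
gv_shift <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "hv_gv"), inherits(curve_b, "hv_gv"))
  gv_half_mV(curve_b) - gv_half_mV(curve_a)
}

#' Voltage dependence of the activation time constant
#'
#' Ordinary least squares of ln(tau) on V over the maximal contiguous run
#' where tau decreases with depolarization (the physiologically meaningful
#' limb; near threshold the estimates flatten and are excluded). Reports the
#' log-slope (e-fold per mV) and its reciprocal magnitude (mV per e-fold).
#'
#' @param fits a data frame with columns `V_mV` and `tau_s`, or a list of
#'   [fit_activation()] results.
#' @param min_points minimum length of the decreasing run (default 3).
#' @param noise_tol fractional increase of tau between neighbouring points
#'   tolerated inside a decreasing run (default 0.05). Fitted time constants
#'   carry estimation noise; terminating the run at every noisy uptick would
#'   preferentially keep exaggerated decreases and bias the slope steep. A
#'   run must still decrease overall.
#' @param min_snr when `fits` is a list of [fit_activation()] results,
#'   drop fits whose steady-state amplitude is below `min_snr` times the
#'   baseline noise SD (default 10): a time constant is only interpretable
#'   when the current rises well clear of the noise, and near-threshold
#'   traces otherwise contaminate the kinetics plot.
#' @return an `hv_tau_fit`: `efold_per_mV`, `mV_per_efold`, `fit_range_mV`,
#'   `n_points`.
#' @export
fit_tau_voltage <- function(fits, min_points = 3L, noise_tol = 0.05,
                            min_snr = 10) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) > 0L && !is.null(fits[[1]]$noise_sd_pA)) {
      fits <- Filter(function(f)
        abs(f$I_ss_pA) >= min_snr * max(f$noise_sd_pA, 1e-12) ||
          f$noise_sd_pA == 0, fits)
    }
    fits <- data.frame(V_mV = vapply(fits, `[[`, numeric(1), "V_mV"),
                       tau_s = vapply(fits, `[[`, numeric(1), "tau_s"))
  }
  stopifnot(is.data.frame(fits), all(c("V_mV", "tau_s") %in% names(fits)))
  fits <- fits[order(fits$V_mV), ]
  v <- fits$V_mV; tau <- fits$tau_s
  if (length(v) < min_points) stop("need at least min_points tau estimates")
  dec <- diff(tau) < utils::head(tau, -1) * noise_tol
  runs <- rle(dec)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  # candidate runs must decrease overall (a flat stretch does not qualify)
  cand <- cand[vapply(cand, function(k)
    tau[ends[k] + 1L] < tau[starts[k]], logical(1))]
  if (length(cand) == 0L)
    stop("no decreasing region of tau versus voltage")
  best <- cand[which.max(runs$lengths[cand])]
  idx <- seq(starts[best], ends[best] + 1L)  # run of diffs -> +1 points
  if (length(idx) < min_points)
    stop("no decreasing run of at least min_points tau estimates")
  fit <- stats::lm(log(tau[idx]) ~ v[idx])
  slope <- unname(stats::coef(fit)[2L])
  df <- stats::df.residual(fit)
  structure(list(efold_per_mV = slope, mV_per_efold = 1 / abs(slope),
                 fit_range_mV = range(v[idx]), n_points = length(idx),
                 residual_sd = if (df > 0)
                   sqrt(sum(stats::residuals(fit)^2) / df) else NA_real_),
            class = "hv_tau_fit")
}

#' @export
print.hv_tau_fit <- function(x, ...) {
  cat(sprintf("tau_act voltage dependence: %.3f e-fold/mV (%.2f mV per e-fold), %d points over %+g..%+g mV\n",
              x$efold_per_mV, x$mV_per_efold, x$n_points,
              x$fit_range_mV[1], x$fit_range_mV[2]))
  invisible(x)
}

#' Threshold-versus-reversal regression of pH-dependent gating
#'
#' Fits V_thres = slope * V_rev + offset by ordinary least squares over
#' determinations pooled across cells, restricted to a voltage window
#' (default -70..+70 mV) applied to both coordinates before fitting. The
#' slope summarises how tightly gating follows the proton gradient (1 would
#' be perfectly Nernstian) and the offset locates activation relative to the
#' reversal potential: a negative offset means the channel opens negative to
#' V_rev and conducts protons inward.
#'
#' @param pairs a data frame with columns `V_rev_mV` and `V_thres_mV` (one
#'   row per determination).
#' @param range voltage window applied to both coordinates, default
#'   `c(-70, 70)` mV.
#' @return an `hv_gating_fit` with fields `slope`, `offset_mV`,
#'   `n_determinations`, `voltage_range_mV`, `residual_sd_mV` and the
#'   underlying `lm` fit. `coef()`, `print()`, `summary()` and `predict()`
#'   methods are available.
#' @export
threshold_reversal_regression <- function(pairs, range = c(-70, 70)) {
  stopifnot(is.data.frame(pairs),
            all(c("V_rev_mV", "V_thres_mV") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("V_rev_mV", "V_thres_mV")]) &
    pairs$V_rev_mV >= range[1] & pairs$V_rev_mV <= range[2] &
    pairs$V_thres_mV >= range[1] & pairs$V_thres_mV <= range[2]
  dat <- pairs[ok, ]
  if (nrow(dat) < 2L)
    stop("fewer than 2 determinations inside the voltage window")
  fit <- stats::lm(V_thres_mV ~ V_rev_mV, data = dat)
  cf <- stats::coef(fit)
  df <- stats::df.residual(fit)
  structure(list(slope = unname(cf[2L]), offset_mV = unname(cf[1L]),
                 n_determinations = nrow(dat), voltage_range_mV = range,
                 residual_sd_mV = if (df > 0)
                   sqrt(sum(stats::residuals(fit)^2) / df) else NA_real_,
                 lm = fit, data = dat),
            class = "hv_gating_fit")
}

#' @export
print.hv_gating_fit <- function(x, ...) {
  cat(sprintf("pH-dependent gating: V_thres = %.3f V_rev %+.2f mV (n = %d, window %+g..%+g mV, residual SD %.2f mV)\n",
              x$slope, x$offset_mV, x$n_determinations,
              x$voltage_range_mV[1], x$voltage_range_mV[2],
              x$residual_sd_mV))
  invisible(x)
}

#' @export
coef.hv_gating_fit <- function(object, ...) {
  c(slope = object$slope, offset_mV = object$offset_mV)
}

#' @export
summary.hv_gating_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat(sprintf("Threshold-versus-reversal regression (%d determinations)\n",
              object$n_determinations))
  print(s$coefficients)
  cat(sprintf("Predicted gating shift: %.1f mV per pH unit at 293.15 K\n",
              shift_per_ph_unit(object)))
  invisible(s)
}

#' @export
predict.hv_gating_fit <- function(object, V_rev_mV, ...) {
  object$slope * V_rev_mV + object$offset_mV
}

#' @export
plot.hv_gating_fit <- function(x, ...) {
  graphics::plot(x$data$V_rev_mV, x$data$V_thres_mV,
                 xlab = "V_rev (mV)", ylab = "V_thres (mV)", ...)
  graphics::abline(x$offset_mV, x$slope)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Predicted gating shift per unit of pH gradient
#'
#' The regression slope times the Nernst slope (RT ln10/F in mV): the
#' displacement of the conductance-voltage relationship expected for one
#' unit change of the transmembrane pH gradient. A slope of 1 would give
#' exactly the Nernst slope (58.17 mV at 293.15 K).
#'
#' @param regression an `hv_gating_fit`, or a bare dimensionless slope.
#' @param temperature_K temperature for the Nernst slope (default 293.15 K).
#' @return millivolts per unit delta-pH.
#' @examples
#' shift_per_ph_unit(0.77)  # ~44.8 mV per pH unit
#' @export
shift_per_ph_unit <- function(regression, temperature_K = 293.15) {
  slope <- if (inherits(regression, "hv_gating_fit")) regression$slope
           else as.numeric(regression)
  slope * nernst_slope_mV(thermo_context(temperature_K))
}

#' Zinc dose analysis of simulated or recorded families
#'
#' For families recorded at increasing zinc concentrations (the zinc-free
#' family serving as reference), reports the rightward g-V shift relative to
#' the reference and the mean slowing factor of the activation time constant
#' at matched voltages.
#'
#' @param families a named or unnamed list of `hv_family` objects; the zinc
#'   concentration of each is taken from its conditions.
#' @param vrev_mV reversal potential used for the conductance curves;
#'   defaults to the proton Nernst potential of each family's conditions
#'   (external zinc leaves the pH gradient unchanged).
#' @return an `hv_zinc_report` data frame with columns `zinc_uM`,
#'   `gv_shift_mV`, `tau_factor`, sorted by ascending concentration; the
#'   zinc-free row has shift 0 and factor 1 by definition.
#' @export
zinc_dose_analysis <- function(families, vrev_mV = NULL) {
  stopifnot(is.list(families), length(families) >= 1L)
  zn <- vapply(families, function(f) f$conditions$zinc_uM, numeric(1))
  if (!any(zn == 0)) stop("a zinc-free reference family is required")
  o <- order(zn)
  families <- families[o]; zn <- zn[o]
  per <- lapply(families, function(f) {
    fits <- lapply(f$traces, function(tr)
      tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL))
    vr <- if (is.null(vrev_mV))
      nernst(f$conditions$pH_o, f$conditions$pH_i_pipette,
             thermo_context(f$conditions$temperature_K))
    else vrev_mV
    gv <- build_gv(f, vr, fits = fits)
    ok <- !vapply(fits, is.null, logical(1))
    list(gv = gv,
         tau = data.frame(V_mV = vapply(fits[ok], `[[`, numeric(1), "V_mV"),
                          tau_s = vapply(fits[ok], `[[`, numeric(1), "tau_s")))
  })
  ref <- per[[1L]]
  rows <- lapply(seq_along(per), function(i) {
    shift <- if (i == 1L) 0 else gv_shift(ref$gv, per[[i]]$gv)
    if (i == 1L) fac <- 1
    else {
      m <- merge(ref$tau, per[[i]]$tau, by = "V_mV", suffixes = c("_ref", "_zn"))
      if (nrow(m) == 0L) stop("no matched voltages between reference and zinc family")
      fac <- mean(m$tau_s_zn / m$tau_s_ref)
    }
    data.frame(zinc_uM = zn[i], gv_shift_mV = shift, tau_factor = fac)
  })
  structure(do.call(rbind, rows), class = c("hv_zinc_report", "data.frame"))
}

#' @export
print.hv_zinc_report <- function(x, ...) {
  cat("Zinc dose analysis (reference = zinc-free family)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
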