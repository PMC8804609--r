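# Per-trace and per-family analysis primitives: rising-exponential
# activation fits, tail-current measurement, first-tail threshold detection
# and the two reversal-potential methods (zero current, tail current).

trace_segment <- function(trace, label) {
  seg <- trace$segments[trace$segments$label == label, ]
  if (nrow(seg) == 0L) stop(sprintf("trace has no '%s' segment", label))
  idx <- which(trace$time_s >= seg$start_s & trace$time_s < seg$end_s)
  list(idx = idx, time_s = trace$time_s[idx],
       current_pA = trace$current_pA[idx], mV = seg$mV,
       start_s = seg$start_s, end_s = seg$end_s)
}

pre_pulse_stats <- function(trace) {
  pre <- trace_segment(trace, "pre")
  if (length(pre$idx) < 4L) stop("pre-pulse baseline window too short")
  list(baseline_pA = stats::median(pre$current_pA),
       noise_sd_pA = stats::sd(pre$current_pA))
}

#' Fit a rising exponential to an activating current
#'
#' Fits I(t) = A (1 - exp(-(t - t0)/tau)) + I_offset to the test segment of
#' a trace by bounded nonlinear least squares, with t0 fixed at the start of
#' the fit window. The sigmoidal onset of the current (channels assembled
#' from more than one gating subunit) is handled by the delay policy: by
#' default, samples before the current has covered half of its plateau
#' excursion are excluded, after which the remaining late phase is well
#' described by a single exponential whose time constant matches the gating
#' relaxation to about 12% for dimeric kinetics (a 10% exclusion leaves a
#' 30% bias, which is why the default is the half-rise point).
#'
#' `I_ss_pA` is the fitted current extrapolated to infinite time minus the
#' current at the onset of the test pulse (where the channel contribution is
#' still negligible): the steady-state channel current, free of constant
#' contributions such as ohmic leak, and invariant to additive baseline.
#'
#' @param trace an `hv_trace` (or any list with `time_s`, `current_pA` and a
#'   `segments` table containing a `test` segment).
#' @param delay_policy `"plateau_fraction"` (default; exclude the rise below
#'   `delay_fraction` of the plateau excursion) or `"none"`.
#' @param delay_fraction fraction of the plateau excursion defining the
#'   excluded onset (default 0.5).
#' @param min_points minimum samples after the delay (default 10).
#' @param max_iter iteration cap of the Levenberg-Marquardt optimiser.
#' @return an `hv_activation_fit`: `I_ss_pA`, `tau_s`, `delay_s`,
#'   `I_offset_pA`, `rmse_pA`, `window`, `V_mV`, `tau_at_bound`.
#' @export
fit_activation <- function(trace, delay_policy = c("plateau_fraction", "none"),
                           delay_fraction = 0.5, min_points = 10L,
                           max_iter = 100L) {
  delay_policy <- match.arg(delay_policy)
  test <- trace_segment(trace, "test")
  t <- test$time_s - test$start_s
  y <- test$current_pA
  if (length(y) < min_points) stop("test segment too short to fit")

  n_tail <- max(5L, ceiling(0.1 * length(y)))
  plateau <- mean(y[seq(length(y) - n_tail + 1L, length(y))])
  start_lvl <- stats::median(y[seq_len(min(5L, length(y)))])
  ampl <- plateau - start_lvl
  noise <- tryCatch(pre_pulse_stats(trace)$noise_sd_pA, error = function(e) stats::sd(y) / 10)
  if (!is.finite(ampl) || abs(ampl) <= max(3 * noise, 1e-12))
    stop("fit failed: no activating component above the noise in this trace")

  delay_s <- 0
  if (delay_policy == "plateau_fraction") {
    crossed <- which(abs(y - start_lvl) >= delay_fraction * abs(ampl))
    if (length(crossed) == 0L) stop("fit failed: current never leaves baseline")
    delay_s <- t[crossed[1L]]
  }
  keep <- t >= delay_s
  if (sum(keep) < min_points)
    stop("fit failed: fewer than min_points samples after the onset delay")
  tw <- t[keep] - delay_s
  yw <- y[keep]

  # initial guesses from the log-linearised late phase of (plateau - I)
  z <- (plateau - yw) / ampl
  usable <- which(z > 0.02 & z < 0.9)
  tau0 <- if (length(usable) >= 3L) {
    sl <- stats::coef(stats::lm(log(z[usable]) ~ tw[usable]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else max(tw) / 3
  } else max(tw) / 3
  tau_lo <- diff(tw[1:2])
  tau_hi <- 50 * max(tw)
  tau0 <- min(max(tau0, tau_lo * 2), tau_hi / 2)

  dat <- data.frame(tw = tw, yw = yw)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yw ~ A * (1 - exp(-tw / tau)) + C, data = dat,
      start = list(A = ampl, tau = tau0, C = start_lvl),
      lower = c(A = -Inf, tau = tau_lo, C = -Inf),
      upper = c(A = Inf, tau = tau_hi, C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) stop("fit failed: ", conditionMessage(e))
  )
  cf <- stats::coef(fit)
  tau_at_bound <- cf[["tau"]] <= tau_lo * 1.0001 || cf[["tau"]] >= tau_hi * 0.9999
  if (tau_at_bound)
    warning("activation fit: tau hit its bound; result flagged")
  # steady-state channel current: fitted asymptote minus the pulse-onset
  # level (channel still closed there); reduces to A when no delay is cut
  iss <- if (delay_s > 0) {
    n_entry <- max(1L, floor(0.15 * sum(t < delay_s)))
    unname(cf[["A"]] + cf[["C"]]) - mean(y[seq_len(min(n_entry, length(y)))])
  } else unname(cf[["A"]])
  structure(list(I_ss_pA = iss, tau_s = unname(cf[["tau"]]),
                 delay_s = delay_s, I_offset_pA = unname(cf[["C"]]),
                 rmse_pA = sqrt(mean(stats::resid(fit)^2)),
                 noise_sd_pA = noise,
                 window = c(start_s = test$start_s + delay_s, end_s = test$end_s),
                 V_mV = test$mV, tau_at_bound = tau_at_bound),
            class = "hv_activation_fit")
}

#' @export
print.hv_activation_fit <- function(x, ...) {
  cat(sprintf("Activation fit at %+g mV: I_ss = %.2f pA, tau = %.4g s (delay %.3g s, rmse %.2f pA)\n",
              x$V_mV, x$I_ss_pA, x$tau_s, x$delay_s, x$rmse_pA))
  invisible(x)
}

#' Measure the tail current of a trace
#'
#' Returns the signed peak of the baseline-subtracted current in the first
#' 20% of the tail (repolarization) segment. The baseline is the median
#' current of the pre-pulse holding window, so at a tail potential equal to
#' the holding potential the ohmic leak cancels exactly; the noise standard
#' deviation comes from the same quiescent window. Before peak picking the
#' window is lightly smoothed (5-sample running mean, short against any
#' realistic deactivation time constant) so that the reported peak reflects
#' the deterministic tail rather than the largest single noise excursion.
#'
#' @param trace an `hv_trace` containing a tail segment.
#' @param peak_fraction fraction of the tail segment searched for the peak
#'   (default 0.2).
#' @param smooth_samples width of the running mean applied before peak
#'   picking (default 5; no smoothing when the window is shorter).
#' @return an `hv_tail`: `step_mV`, `tail_mV`, `tail_peak_pA`, `noise_sd_pA`.
#' @export
measure_tail <- function(trace, peak_fraction = 0.2, smooth_samples = 5L) {
  tail_seg <- trace_segment(trace, "tail")
  if (length(tail_seg$idx) < 2L) stop("missing or empty tail segment")
  bs <- pre_pulse_stats(trace)
  n_win <- max(1L, ceiling(peak_fraction * length(tail_seg$idx)))
  win <- tail_seg$current_pA[seq_len(n_win)] - bs$baseline_pA
  if (length(win) >= smooth_samples && smooth_samples > 1L) {
    sm <- stats::filter(win, rep(1 / smooth_samples, smooth_samples), sides = 2)
    win <- as.numeric(sm[!is.na(sm)])
  }
  peak <- win[which.max(abs(win))]
  structure(list(step_mV = trace$test_mV, tail_mV = tail_seg$mV,
                 tail_peak_pA = peak, noise_sd_pA = bs$noise_sd_pA),
            class = "hv_tail")
}

#' Detect the threshold potential from first tail currents
#'
#' The threshold is the most negative step potential at which a tail
#' current is observed on repolarization. "Observed" is operationalised as
#' |tail peak| exceeding the larger of (i) `k_sigma` times the pre-pulse
#' noise SD and (ii) `rel_fraction` of the family's maximal tail amplitude,
#' with the additional persistence requirement that every more positive
#' step also exceeds the criterion (a single noisy excursion does not
#' count). The relative component makes the detection limit a fixed
#' fraction of full activation independent of the tail driving force, so
#' families recorded under different pH gradients are judged at the same
#' effective open probability: with the default 0.01 a tail counts as
#' "observed" once it reaches 1% of the family's maximal tail amplitude,
#' i.e. once the open probability at the end of the pulse reaches about 1%
#' of saturation -- the same limit that defines the threshold potential in
#' the simulator's gating law (`p_detect`).
#'
#' @param family an `hv_family` of ascending steps.
#' @param k_sigma detection multiple of the noise SD (default 3).
#' @param rel_fraction relative detection limit as a fraction of the
#'   largest tail amplitude in the family (default 0.01; set to 0 to
#'   disable the relative component).
#' @param family_id optional identifier copied into the result.
#' @return an `hv_threshold`: `V_thres_mV` (NA when no step qualifies),
#'   `status` (`"ok"`, `"no-threshold"` or `"saturated"` when every step
#'   qualifies), `criterion`, and the per-step tail table.
#' @export
detect_threshold <- function(family, k_sigma = 3, rel_fraction = 0.01,
                             family_id = NA_character_) {
  stopifnot(inherits(family, "hv_family"))
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  tails <- lapply(family$traces, measure_tail)
  v <- vapply(tails, `[[`, numeric(1), "step_mV")
  if (any(diff(v) <= 0)) stop("family steps must be ordered ascending")
  peak <- vapply(tails, `[[`, numeric(1), "tail_peak_pA")
  sd_ <- vapply(tails, `[[`, numeric(1), "noise_sd_pA")
  exceeds <- abs(peak) > pmax(k_sigma * sd_, rel_fraction * max(abs(peak)))
  # first index from which all successors exceed the criterion
  ok_from <- rev(cumprod(rev(exceeds))) == 1
  tab <- data.frame(step_mV = v, tail_peak_pA = peak, noise_sd_pA = sd_,
                    exceeds = exceeds)
  crit <- sprintf("|tail peak| > max(%g * sd(noise), %g * max tail), persistent",
                  k_sigma, rel_fraction)
  if (!any(ok_from)) {
    res <- list(V_thres_mV = NA_real_, status = "no-threshold",
                criterion = crit, family_id = family_id, tails = tab)
  } else {
    i <- which(ok_from)[1L]
    status <- if (i == 1L) "saturated" else "ok"
    if (status == "saturated")
      warning("all steps exceed the tail criterion; threshold is at or below the lowest step")
    res <- list(V_thres_mV = v[i], status = status, criterion = crit,
                family_id = family_id, tails = tab)
  }
  structure(res, class = "hv_threshold")
}

#' @export
print.hv_threshold <- function(x, ...) {
  if (is.na(x$V_thres_mV)) cat("Threshold: none detected\n")
  else cat(sprintf("Threshold: %+g mV (%s; %s)\n", x$V_thres_mV, x$status,
                   x$criterion))
  invisible(x)
}

new_reversal <- function(V_rev_mV, method, bracket_mV, conditions, n_points) {
  structure(list(V_rev_mV = V_rev_mV, method = method,
                 bracket_mV = bracket_mV, conditions = conditions,
                 n_points = n_points),
            class = "hv_reversal")
}

#' @export
print.hv_reversal <- function(x, ...) {
  cat(sprintf("V_rev = %+.2f mV (%s method, bracket %+g..%+g mV)\n",
              x$V_rev_mV, x$method, x$bracket_mV[1], x$bracket_mV[2]))
  invisible(x)
}

#' Reversal potential by the zero-current method
#'
#' When the channel activates negative to its reversal potential, the fitted
#' steady-state currents change sign across the family and the reversal
#' potential is read directly as the zero crossing, linearly interpolated
#' between the bracketing steps.
#'
#' @param family an `hv_family` of ascending steps.
#' @param fits optional list of [fit_activation()] results (one per trace);
#'   computed if missing, with failing traces (e.g. sub-threshold steps)
#'   dropped.
#' @return an `hv_reversal` with `method = "zero_current"`.
#' @export
vrev_zero_current <- function(family, fits = NULL) {
  stopifnot(inherits(family, "hv_family"))
  if (is.null(fits)) {
    fits <- lapply(family$traces, function(tr)
      tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL))
  }
  keep <- !vapply(fits, is.null, logical(1))
  v <- vapply(fits[keep], `[[`, numeric(1), "V_mV")
  iss <- vapply(fits[keep], `[[`, numeric(1), "I_ss_pA")
  o <- order(v); v <- v[o]; iss <- iss[o]
  if (length(v) < 2L)
    stop("fewer than two usable steady-state fits in the family")
  exact <- which(iss == 0)
  if (length(exact) > 0L) {
    vz <- v[exact[1L]]
    return(new_reversal(vz, "zero_current", c(vz, vz), family$conditions,
                        length(v)))
  }
  # last negative fitted steady-state current, then the next positive one
  neg <- which(iss < 0)
  if (length(neg) == 0L || max(neg) == length(v))
    stop("no sign change of I_ss across the family; use vrev_tail() on a tail family")
  i <- max(neg)
  pos_after <- which(iss > 0 & seq_along(v) > i)
  if (length(pos_after) == 0L)
    stop("no sign change of I_ss across the family; use vrev_tail() on a tail family")
  j <- pos_after[1L]
  vz <- v[i] + (v[j] - v[i]) * (-iss[i]) / (iss[j] - iss[i])
  new_reversal(vz, "zero_current", c(v[i], v[j]), family$conditions, length(v))
}

#' Reversal potential by the tail-current method
#'
#' Used when the channel opens only positive to its reversal potential: a
#' fixed activating prepulse opens the channel, the repolarization potential
#' is varied, and the sign change of the early tail current across tail
#' potentials is interpolated linearly.
#'
#' @param tail_family an `hv_family` built by [simulate_tail_family()] (or
#'   an equivalent recording with varying tail potentials).
#' @return an `hv_reversal` with `method = "tail"`.
#' @export
vrev_tail <- function(tail_family) {
  stopifnot(inherits(tail_family, "hv_family"))
  tails <- lapply(tail_family$traces, measure_tail)
  v <- vapply(tails, `[[`, numeric(1), "tail_mV")
  peak <- vapply(tails, `[[`, numeric(1), "tail_peak_pA")
  o <- order(v); v <- v[o]; peak <- peak[o]
  if (length(v) < 2L) stop("tail family must contain at least two tail potentials")
  exact <- which(peak == 0)
  if (length(exact) > 0L) {
    vz <- v[exact[1L]]
    return(new_reversal(vz, "tail", c(vz, vz), tail_family$conditions, length(v)))
  }
  neg <- which(peak < 0)
  if (length(neg) == 0L || max(neg) == length(v))
    stop("no sign change of tail currents across tail potentials")
  i <- max(neg)
  pos_after <- which(peak > 0 & seq_along(v) > i)
  if (length(pos_after) == 0L)
    stop("no sign change of tail currents across tail potentials")
  j <- pos_after[1L]
  vz <- v[i] + (v[j] - v[i]) * (-peak[i]) / (peak[j] - peak[i])
  new_reversal(vz, "tail", c(v[i], v[j]), tail_family$conditions, length(v))
}

#' Chord conductance at one voltage
#'
#' g = I_ss / (V - V_rev), in nS when current is in pA and voltages in mV.
#'
#' @param I_ss_pA fitted steady-state current (pA).
#' @param V_mV step potential (mV).
#' @param V_rev_mV reversal potential (mV); must differ from `V_mV`.
#' @return conductance in nS.
#' @export
conductance_point <- function(I_ss_pA, V_mV, V_rev_mV) {
  if (any(abs(V_mV - V_rev_mV) < 1e-9))
    stop("conductance undefined at V = V_rev")
  I_ss_pA / (V_mV - V_rev_mV)
}
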