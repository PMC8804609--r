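# Whole-cell proton-current simulator. Gating follows a Hodgkin-Huxley n^N
# scheme whose position on the voltage axis is set by the threshold law
# V_thres = thr_slope * E_H + thr_offset (+ zinc shift). Within a constant-
# voltage segment the gate relaxes analytically; proton-depletion feedback
# on intracellular pH is integrated on the sample grid with sub-stepping.

#' Threshold potential of the gating law
#'
#' V_thres = thr_slope * E_H(conditions) + thr_offset_mV + zinc shift, the
#' voltage at which the steady-state open probability equals the law's
#' `p_detect`.
#'
#' @param conditions an [solution_conditions()] object.
#' @param law an [gating_law()] object.
#' @return threshold potential in mV.
#' @export
v_thres_mV <- function(conditions, law) {
  eh <- nernst(conditions$pH_o, conditions$pH_i_pipette,
               thermo_context(conditions$temperature_K))
  law$thr_slope * eh + law$thr_offset_mV + zinc_shift_mV(conditions$zinc_uM, law)
}

#' Zinc modulation of gating
#'
#' `zinc_shift_mV()` is the rightward displacement of the activation curve,
#' `zinc_slow_factor()` the multiplicative slowing of activation kinetics,
#' both smooth, monotone functions of the zinc concentration:
#' shift = zn_shift_mV_per_decade * log10(1 + zinc/Kd) and
#' factor = zn_slow_factor_per_decade ^ log10(1 + zinc/Kd).
#'
#' @param zinc_uM external zinc concentration (micromolar).
#' @param law an [gating_law()].
#' @return mV (shift) or a dimensionless factor >= 1 (slowing).
#' @export
zinc_shift_mV <- function(zinc_uM, law) {
  stopifnot(all(zinc_uM >= 0))
  law$zn_shift_mV_per_decade * log10(1 + zinc_uM / law$zn_Kd_uM)
}

#' @rdname zinc_shift_mV
#' @export
zinc_slow_factor <- function(zinc_uM, law) {
  stopifnot(all(zinc_uM >= 0))
  law$zn_slow_factor_per_decade ^ log10(1 + zinc_uM / law$zn_Kd_uM)
}

# Per-gate half-activation voltage. Placed so that open probability
# n_inf(V_thres)^N equals p_detect: n_inf(V_thres) = p_detect^(1/N).
v_half_mV <- function(conditions, law) {
  q <- law$p_detect ^ (1 / law$n_subunits)
  v_thres_mV(conditions, law) + law$steepness_k_mV * log((1 - q) / q)
}

#' Steady-state open probability
#'
#' Open probability n_inf(V)^N with n_inf(V) = 1/(1 + exp(-(V - V_half)/k)).
#' V_half is positioned so that the open probability at the law's threshold
#' potential equals `p_detect`; the curve therefore translates rigidly with
#' pH and zinc.
#'
#' @param V_mV membrane potential(s), mV.
#' @param conditions an [solution_conditions()].
#' @param law an [gating_law()].
#' @return open probability in \[0, 1\], vectorised over `V_mV`.
#' @examples
#' law <- eth_v1_law()
#' cond <- solution_conditions(6.5, 5.5)
#' steady_state_open_prob(v_thres_mV(cond, law), cond, law)  # = p_detect
#' @export
steady_state_open_prob <- function(V_mV, conditions, law) {
  if (any(!is.finite(V_mV))) stop("V_mV must be finite")
  vh <- v_half_mV(conditions, law)
  ninf <- stats::plogis((V_mV - vh) / law$steepness_k_mV)
  ninf ^ law$n_subunits
}

#' Voltage-dependent activation time constant
#'
#' tau_act(V) = tau_ref_s * exp(-(V - V_thres)/efold_act_mV) * zinc slowing:
#' anchored at the threshold potential and accelerating e-fold for every
#' `efold_act_mV` of depolarization.
#'
#' @inheritParams steady_state_open_prob
#' @return time constant(s) in seconds.
#' @export
tau_act_model <- function(V_mV, conditions, law) {
  if (any(!is.finite(V_mV))) stop("V_mV must be finite")
  vt <- v_thres_mV(conditions, law)
  law$tau_ref_s * exp(-(V_mV - vt) / law$efold_act_mV) *
    zinc_slow_factor(conditions$zinc_uM, law)
}

#' Voltage-dependent deactivation time constant
#'
#' tau_deact(V) = tau_deact_ref_s * exp((V + 80)/efold_deact_mV): anchored
#' at the -80 mV reference tail potential and slowing at more positive
#' potentials (tails are large and relatively slow).
#'
#' @inheritParams steady_state_open_prob
#' @export
tau_deact_model <- function(V_mV, conditions, law) {
  if (any(!is.finite(V_mV))) stop("V_mV must be finite")
  law$tau_deact_ref_s * exp((V_mV + 80) / law$efold_deact_mV)
}

# Relaxation time constant used during a segment: activation law when the
# gate is opening (n_inf above the entry value), deactivation law otherwise.
segment_tau <- function(V_mV, n0, conditions, law) {
  vh <- v_half_mV(conditions, law)
  ninf <- stats::plogis((V_mV - vh) / law$steepness_k_mV)
  if (ninf >= n0) tau_act_model(V_mV, conditions, law)
  else tau_deact_model(V_mV, conditions, law)
}

# Buffering capacity of a monoprotic buffer, mol/L per pH unit:
# beta(pH) = ln(10) * C * Ka * [H+] / (Ka + [H+])^2.
buffer_capacity_M_per_pH <- function(pH, buffer_total_mM, buffer_pKa) {
  C <- buffer_total_mM / 1000
  Ka <- 10^(-buffer_pKa)
  H <- 10^(-pH)
  log(10) * C * Ka * H / (Ka + H)^2
}

# Deterministic per-trace seed derived from a family seed and step index.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 97 * i) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a single voltage-step trace
#'
#' Integrates the gating variable from its holding-potential steady state
#' through a pre-pulse baseline, the depolarizing test segment and the
#' repolarizing tail. The proton current is
#' I_H(t) = g_max n(t)^N (V - V_rev(t)) with V_rev(t) the instantaneous
#' proton Nernst potential; the total recorded current adds an ohmic leak
#' (reversing at 0 mV) and Gaussian noise. When the cell has depletion
#' enabled, intracellular pH obeys
#' dpH_i/dt = I_H / (F volume beta(pH_i)) + (pH_pip - pH_i)/tau_exchange,
#' with beta the monoprotic buffer capacity, so sustained outward current
#' alkalinises the cytosol and drags V_rev with it.
#'
#' @param test_mV test potential (mV).
#' @param duration_s test-pulse duration (s).
#' @param cell an [cell_model()].
#' @param conditions an [solution_conditions()].
#' @param law an [gating_law()].
#' @param seed integer seed for the noise stream.
#' @param holding_mV,tail_mV,tail_duration_s,sample_rate_Hz,pre_s protocol
#'   segment parameters (see [step_protocol()]).
#' @param pH_i_start initial cytosolic pH; defaults to the pipette pH.
#' @return an `hv_trace`: fields `time_s`, `current_pA`, `command_mV`,
#'   `segments` (data frame with `label`, `start_s`, `end_s`, `mV`),
#'   `conditions`, `pH_i_trajectory` (simulator ground truth), `seed`.
#' @export
simulate_step <- function(test_mV, duration_s, cell, conditions, law,
                          seed = 42L, holding_mV = -80, tail_mV = -80,
                          tail_duration_s = 1, sample_rate_Hz = 500,
                          pre_s = 0.3, pH_i_start = NULL) {
  if (!is.finite(test_mV)) stop("test_mV must be finite")
  if (duration_s <= 0) stop("duration_s must be > 0")
  stopifnot(inherits(cell, "hv_cell"), inherits(conditions, "hv_conditions"),
            inherits(law, "hv_gating_law"))
  dt <- 1 / sample_rate_Hz
  seg <- data.frame(
    label = c("pre", "test", "tail"),
    start_s = c(0, pre_s, pre_s + duration_s),
    end_s = c(pre_s, pre_s + duration_s, pre_s + duration_s + tail_duration_s),
    mV = c(holding_mV, test_mV, tail_mV),
    stringsAsFactors = FALSE
  )
  n_samp <- as.integer(round(seg$end_s[3] * sample_rate_Hz))
  time_s <- (seq_len(n_samp) - 1L) * dt
  seg_idx <- findInterval(time_s, seg$start_s, rightmost.closed = FALSE)
  command <- seg$mV[seg_idx]

  nernst_k <- nernst_slope_mV(thermo_context(conditions$temperature_K))
  pH_pip <- conditions$pH_i_pipette
  gmax <- g_max_nS(cell)
  N <- law$n_subunits
  vh <- v_half_mV(conditions, law)
  k <- law$steepness_k_mV

  # gate state: analytic relaxation within each constant-voltage segment
  n <- numeric(n_samp)
  n0 <- stats::plogis((holding_mV - vh) / k)^1  # per-gate variable
  for (s in seq_len(3)) {
    idx <- which(seg_idx == s)
    if (length(idx) == 0L) next
    V <- seg$mV[s]
    ninf <- stats::plogis((V - vh) / k)
    tau <- segment_tau(V, n0, conditions, law)
    tloc <- time_s[idx] - seg$start_s[s]
    n[idx] <- ninf + (n0 - ninf) * exp(-tloc / tau)
    n0 <- ninf + (n0 - ninf) * exp(-(seg$end_s[s] - seg$start_s[s]) / tau)
  }

  # intracellular pH trajectory and proton current
  pH0 <- if (is.null(pH_i_start)) pH_pip else pH_i_start
  if (cell$depletion_enabled) {
    pH <- numeric(n_samp)
    F_C <- thermo_context(conditions$temperature_K)$F_C_per_mol
    vol <- cell$volume_pL
    tau_ex <- cell$pipette_exchange_tau_s
    p <- pH0
    for (i in seq_len(n_samp)) {
      pH[i] <- p
      vrev <- nernst_k * (p - conditions$pH_o)
      IH <- gmax * n[i]^N * (command[i] - vrev)
      beta <- buffer_capacity_M_per_pH(p, conditions$buffer_total_mM,
                                       conditions$buffer_pKa)
      rate <- IH / (F_C * vol * beta) +
        (if (is.finite(tau_ex) && tau_ex > 0) (pH_pip - p) / tau_ex else 0)
      m <- max(1L, ceiling(abs(rate) * dt / 1e-3))
      if (m == 1L) {
        p <- p + rate * dt
      } else {
        h <- dt / m
        for (j in seq_len(m)) {
          vrev <- nernst_k * (p - conditions$pH_o)
          IH <- gmax * n[i]^N * (command[i] - vrev)
          beta <- buffer_capacity_M_per_pH(p, conditions$buffer_total_mM,
                                           conditions$buffer_pKa)
          rate <- IH / (F_C * vol * beta) +
            (if (is.finite(tau_ex) && tau_ex > 0) (pH_pip - p) / tau_ex else 0)
          p <- p + rate * h
        }
      }
      if (tau_ex == 0) p <- pH_pip  # instant exchange clamps pH_i
      if (!is.finite(p) || p <= 0 || p >= 14)
        stop(sprintf(
          "integration instability: pH_i left (0, 14) during %s segment at %+g mV",
          seg$label[seg_idx[i]], seg$mV[seg_idx[i]]))
    }
    vrev_t <- nernst_k * (pH - conditions$pH_o)
  } else {
    pH <- rep(pH0, n_samp)
    vrev_t <- nernst_k * (pH0 - conditions$pH_o)
  }

  I_H <- gmax * n^N * (command - vrev_t)
  noise <- if (cell$noise_sd_pA > 0)
    with_seed(seed, stats::rnorm(n_samp, 0, cell$noise_sd_pA))
  else numeric(n_samp)
  current <- I_H + cell$leak_nS * command + noise

  structure(list(time_s = time_s, current_pA = current, command_mV = command,
                 segments = seg, conditions = conditions,
                 pH_i_trajectory = pH, seed = seed,
                 test_mV = test_mV, tail_mV = tail_mV,
                 holding_mV = holding_mV, sample_rate_Hz = sample_rate_Hz,
                 pH_i_end = pH[n_samp], n_end = n0),
            class = "hv_trace")
}

#' Simulate a family of depolarizing steps
#'
#' One trace per protocol step, sharing conditions, cell and gating law.
#' Between pulses the cytosolic pH relaxes toward the pipette pH for
#' `inter_pulse_s` seconds of exchange, emulating the resting interval of a
#' pulse-family acquisition; the gate returns to its holding steady state.
#' Fully deterministic for a given seed.
#'
#' @param protocol an [step_protocol()].
#' @param cell an [cell_model()].
#' @param conditions an [solution_conditions()].
#' @param law an [gating_law()]; retained in the family as ground truth for
#'   parameter-recovery work.
#' @param seed integer; per-trace noise seeds are derived from it.
#' @return an `hv_family`: list with `protocol`, `traces`, `conditions`,
#'   `cell`, `law`, `seed`.
#' @export
simulate_family <- function(protocol, cell, conditions, law, seed = 42L) {
  stopifnot(inherits(protocol, "hv_protocol"))
  traces <- vector("list", nrow(protocol$steps))
  pH_start <- conditions$pH_i_pipette
  tau_ex <- cell$pipette_exchange_tau_s
  for (i in seq_len(nrow(protocol$steps))) {
    tr <- simulate_step(
      test_mV = protocol$steps$test_mV[i],
      duration_s = protocol$steps$duration_s[i],
      cell = cell, conditions = conditions, law = law,
      seed = derive_seed(seed, i),
      holding_mV = protocol$holding_mV, tail_mV = protocol$tail_mV,
      tail_duration_s = protocol$tail_duration_s,
      sample_rate_Hz = protocol$sample_rate_Hz, pre_s = protocol$pre_s,
      pH_i_start = pH_start
    )
    traces[[i]] <- tr
    pH_start <- if (!cell$depletion_enabled) conditions$pH_i_pipette
    else if (is.finite(tau_ex) && tau_ex > 0)
      conditions$pH_i_pipette +
        (tr$pH_i_end - conditions$pH_i_pipette) * exp(-protocol$inter_pulse_s / tau_ex)
    else if (tau_ex == 0) conditions$pH_i_pipette
    else tr$pH_i_end  # sealed cell: depletion carries over fully
  }
  structure(list(protocol = protocol, traces = traces, conditions = conditions,
                 cell = cell, law = law, seed = seed, kind = "step"),
            class = "hv_family")
}

#' Simulate a tail family for the tail-current reversal method
#'
#' A fixed activating prepulse opens the channel; the repolarization
#' potential is then varied across traces. The sign change of the early
#' tail current across tail potentials brackets the reversal potential.
#'
#' @param prepulse_mV,prepulse_s activating prepulse voltage and duration.
#' @param tail_mV_values tail potentials, strictly increasing.
#' @param tail_duration_s,holding_mV,sample_rate_Hz,pre_s,inter_pulse_s as
#'   in [step_protocol()].
#' @inheritParams simulate_family
#' @return an `hv_family` with `kind = "tail"` (one trace per tail
#'   potential; `steps` record the varying tail potential).
#' @export
simulate_tail_family <- function(prepulse_mV, prepulse_s, tail_mV_values,
                                 cell, conditions, law, seed = 42L,
                                 tail_duration_s = 1, holding_mV = -40,
                                 sample_rate_Hz = 500, pre_s = 0.3,
                                 inter_pulse_s = 15) {
  if (any(diff(tail_mV_values) <= 0))
    stop("tail_mV_values must be strictly increasing")
  traces <- vector("list", length(tail_mV_values))
  pH_start <- conditions$pH_i_pipette
  tau_ex <- cell$pipette_exchange_tau_s
  for (i in seq_along(tail_mV_values)) {
    tr <- simulate_step(
      test_mV = prepulse_mV, duration_s = prepulse_s,
      cell = cell, conditions = conditions, law = law,
      seed = derive_seed(seed, i),
      holding_mV = holding_mV, tail_mV = tail_mV_values[i],
      tail_duration_s = tail_duration_s, sample_rate_Hz = sample_rate_Hz,
      pre_s = pre_s, pH_i_start = pH_start
    )
    traces[[i]] <- tr
    pH_start <- if (!cell$depletion_enabled) conditions$pH_i_pipette
    else if (is.finite(tau_ex) && tau_ex > 0)
      conditions$pH_i_pipette +
        (tr$pH_i_end - conditions$pH_i_pipette) * exp(-inter_pulse_s / tau_ex)
    else if (tau_ex == 0) conditions$pH_i_pipette
    else tr$pH_i_end
  }
  proto <- step_protocol(holding_mV = holding_mV,
                         steps = data.frame(test_mV = tail_mV_values,
                                            duration_s = prepulse_s),
                         tail_mV = tail_mV_values[1],
                         tail_duration_s = tail_duration_s,
                         sample_rate_Hz = sample_rate_Hz, pre_s = pre_s,
                         inter_pulse_s = inter_pulse_s)
  structure(list(protocol = proto, traces = traces, conditions = conditions,
                 cell = cell, law = law, seed = seed, kind = "tail",
                 prepulse_mV = prepulse_mV),
            class = "hv_family")
}

#' Build a pulse-length ladder protocol
#'
#' Activation near threshold is slow, so pulses there must be long to reach
#' steady state, while strongly depolarized pulses activate quickly and are
#' kept short to limit proton depletion. Each step lasts
#' `tau_multiple * tau_act(V)`, clamped to `[min_s, max_s]`.
#'
#' @param v_range numeric vector of test potentials (strictly increasing),
#'   or `c(from, to)` expanded in `by_mV` increments. Must span the law's
#'   threshold potential.
#' @param law an [gating_law()].
#' @param conditions an [solution_conditions()].
#' @param by_mV step increment when `v_range` has length 2 (default 10 mV).
#' @param tau_multiple pulse duration as a multiple of tau_act (default 5).
#' @param min_s,max_s duration clamp (defaults 0.25 and 12 s).
#' @param ... further arguments to [step_protocol()].
#' @return an [step_protocol()].
#' @export
make_protocol_ladder <- function(v_range, law, conditions, by_mV = 10,
                                 tau_multiple = 5, min_s = 0.25, max_s = 12,
                                 ...) {
  if (length(v_range) == 0L) stop("empty voltage range")
  volts <- if (length(v_range) == 2L) seq(v_range[1], v_range[2], by = by_mV)
           else sort(unique(v_range))
  if (length(volts) < 2L) stop("voltage range must contain at least two steps")
  vt <- v_thres_mV(conditions, law)
  if (min(volts) > vt || max(volts) < vt)
    warning("voltage range does not span the law's threshold potential")
  dur <- pmin(pmax(tau_multiple * tau_act_model(volts, conditions, law),
                   min_s), max_s)
  step_protocol(steps = data.frame(test_mV = volts, duration_s = dur), ...)
}

#' @export
print.hv_trace <- function(x, ...) {
  cat(sprintf("Trace: %+g mV step (%.3g s), %d samples at %g Hz, seed %d\n",
              x$test_mV,
              x$segments$end_s[2] - x$segments$start_s[2],
              length(x$time_s), x$sample_rate_Hz, x$seed))
  print(x$conditions)
  invisible(x)
}

#' @export
print.hv_family <- function(x, ...) {
  cat(sprintf("%s family: %d traces, seed %d\n",
              if (identical(x$kind, "tail")) "Tail" else "Step",
              length(x$traces), x$seed))
  print(x$conditions); print(x$cell)
  invisible(x)
}

#' Plot a simulated current family
#'
#' @param x an `hv_family`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hv_family <- function(x, ...) {
  tmat <- sapply(x$traces, `[[`, "current_pA")
  graphics::matplot(x$traces[[1]]$time_s, tmat, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "current (pA)", ...)
  invisible(x)
}
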