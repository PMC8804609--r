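# Domain objects for whole-cell proton-current simulation: recording
# solutions, the model cell, the gating law (ground truth of the simulator),
# and voltage-step protocols.

#' Recording solution conditions
#'
#' Describes the pH gradient, temperature and zinc content of a whole-cell
#' recording. `pH_i_pipette` is the nominal intracellular pH imposed by the
#' pipette solution; the simulator lets the cytosolic pH drift away from it
#' when proton depletion is enabled. Buffering follows a single monoprotic
#' buffer used close to its pKa (as in patch-clamp practice, where ~100 mM
#' buffer near its pKa is used on both sides of the membrane).
#'
#' @param pH_i_pipette,pH_o internal (pipette) and external pH, in (0, 14).
#' @param temperature_K absolute temperature (default 293.15 K).
#' @param zinc_uM external Zn2+ concentration, micromolar, >= 0.
#' @param buffer_total_mM total buffer concentration (mM).
#' @param buffer_pKa buffer pKa; defaults to `pH_i_pipette` (buffer chosen
#'   to match the working pH, which maximises buffering capacity).
#' @param cation_mM,anion_mM main bulk ions (e.g. TMA+ and methanesulfonate),
#'   carried along for GHK calculations.
#' @return an `hv_conditions` object.
#' @examples
#' solution_conditions(pH_i_pipette = 6.5, pH_o = 5.5)
#' @export
solution_conditions <- function(pH_i_pipette = 7.0, pH_o = 7.0,
                                temperature_K = 293.15, zinc_uM = 0,
                                buffer_total_mM = 100,
                                buffer_pKa = pH_i_pipette,
                                cation_mM = 100, anion_mM = 100) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("%s must be a single finite number", nm))
    x
  }
  for (nm in c("pH_i_pipette", "pH_o", "buffer_pKa"))
    if (num1(get(nm), nm) <= 0 || get(nm) >= 14)
      stop(sprintf("%s must lie in (0, 14)", nm))
  if (num1(temperature_K, "temperature_K") <= 0) stop("temperature_K must be > 0")
  if (num1(zinc_uM, "zinc_uM") < 0) stop("zinc_uM must be >= 0")
  if (num1(buffer_total_mM, "buffer_total_mM") < 0) stop("buffer_total_mM must be >= 0")
  structure(list(pH_i_pipette = pH_i_pipette, pH_o = pH_o,
                 temperature_K = temperature_K, zinc_uM = zinc_uM,
                 buffer_total_mM = buffer_total_mM, buffer_pKa = buffer_pKa,
                 cation_mM = cation_mM, anion_mM = anion_mM),
            class = "hv_conditions")
}

#' Model cell for whole-cell simulation
#'
#' Electrical and geometric parameters of the simulated cell. Defaults
#' emulate a small transfected mammalian cell line expressing the channel:
#' 9.62 pF capacitance and 1.07 nS/pF maximal proton conductance density
#' (means of a typical transfected-cell population), ~1 pL of accessible
#' cytosolic volume, and a first-order relaxation of cytosolic pH toward the
#' pipette pH with time constant `pipette_exchange_tau_s` (pipette-cytosol
#' buffer diffusion takes seconds to minutes in whole-cell mode).
#'
#' @param capacitance_pF membrane capacitance (pF).
#' @param g_max_density_nS_per_pF maximal conductance density (nS/pF); the
#'   absolute g_max is `capacitance_pF * g_max_density_nS_per_pF`.
#' @param volume_pL accessible cytosolic volume (pL); must be > 0 when
#'   depletion is enabled.
#' @param leak_nS ohmic seal/leak conductance reversing at 0 mV.
#' @param pipette_exchange_tau_s time constant of pipette <-> cytosol pH
#'   equilibration (s).
#' @param noise_sd_pA standard deviation of additive Gaussian recording
#'   noise (pA).
#' @param depletion_enabled logical; integrate proton-depletion feedback on
#'   intracellular pH.
#' @return an `hv_cell` object. `g_max_nS(cell)` gives the absolute maximal
#'   conductance.
#' @export
cell_model <- function(capacitance_pF = 9.62, g_max_density_nS_per_pF = 1.07,
                       volume_pL = 1, leak_nS = 0.05,
                       pipette_exchange_tau_s = 5, noise_sd_pA = 1,
                       depletion_enabled = TRUE) {
  vals <- c(capacitance_pF = capacitance_pF,
            g_max_density_nS_per_pF = g_max_density_nS_per_pF,
            volume_pL = volume_pL, leak_nS = leak_nS,
            noise_sd_pA = noise_sd_pA)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all cell magnitudes must be finite and >= 0")
  # exchange tau may be Inf (sealed cell, no pipette exchange) or 0 (pH_i
  # clamped to the pipette)
  if (is.na(pipette_exchange_tau_s) || pipette_exchange_tau_s < 0)
    stop("pipette_exchange_tau_s must be >= 0 (Inf disables exchange)")
  if (isTRUE(depletion_enabled) && volume_pL <= 0)
    stop("volume_pL must be > 0 when depletion_enabled")
  structure(list(capacitance_pF = capacitance_pF,
                 g_max_density_nS_per_pF = g_max_density_nS_per_pF,
                 volume_pL = volume_pL, leak_nS = leak_nS,
                 pipette_exchange_tau_s = pipette_exchange_tau_s,
                 noise_sd_pA = noise_sd_pA,
                 depletion_enabled = isTRUE(depletion_enabled)),
            class = "hv_cell")
}

#' @rdname cell_model
#' @param cell an `hv_cell` object.
#' @export
g_max_nS <- function(cell) cell$capacitance_pF * cell$g_max_density_nS_per_pF

#' Phenomenological gating law of a voltage-gated proton channel
#'
#' The ground-truth parameterization used by the simulator and targeted by
#' the parameter-recovery tests. Gating is Hodgkin-Huxley style: each of
#' `n_subunits` gates relaxes toward n_inf(V) = 1/(1 + exp(-(V - V_half)/k))
#' with voltage-dependent time constant, and the open probability is
#' n_inf^N (N = 2 reproduces the sigmoidal current onset attributed to the
#' dimeric architecture of the channel, with a single-exponential late
#' phase). The threshold law positions the whole activation curve:
#' V_thres = thr_slope * E_H + thr_offset_mV (+ zinc shift), and V_half is
#' placed so that the open probability at V_thres equals `p_detect`.
#'
#' Zinc phenomenology (the underlying binding sites are not modelled):
#' V_thres shift = `zn_shift_mV_per_decade * log10(1 + zinc_uM/zn_Kd_uM)` and
#' activation slowing factor
#' `zn_slow_factor_per_decade ^ log10(1 + zinc_uM/zn_Kd_uM)`.
#'
#' @param thr_slope dimensionless slope of V_thres versus V_rev.
#' @param thr_offset_mV threshold offset at V_rev = 0 (mV).
#' @param steepness_k_mV slope factor of the per-gate Boltzmann (mV).
#' @param n_subunits number of gates (default 2, dimer).
#' @param p_detect open probability that defines the detectable threshold
#'   (default 0.01).
#' @param tau_ref_s activation time constant at V_thres (s).
#' @param efold_act_mV voltage change producing an e-fold change of the
#'   activation time constant (mV).
#' @param tau_deact_ref_s deactivation time constant at the reference tail
#'   potential -80 mV (s).
#' @param efold_deact_mV e-fold voltage of the deactivation time constant.
#' @param zn_Kd_uM,zn_shift_mV_per_decade,zn_slow_factor_per_decade zinc
#'   coupling parameters (see Details).
#' @return an `hv_gating_law` object.
#' @seealso [eth_v1_law()], [nph_v1_law()] for published channel fits.
#' @export
gating_law <- function(thr_slope = 0.77, thr_offset_mV = -23,
                       steepness_k_mV = 6, n_subunits = 2L, p_detect = 0.01,
                       tau_ref_s = 2, efold_act_mV = 10,
                       tau_deact_ref_s = 0.3, efold_deact_mV = 20,
                       zn_Kd_uM = 10, zn_shift_mV_per_decade = 30,
                       zn_slow_factor_per_decade = 3) {
  if (steepness_k_mV <= 0) stop("steepness_k_mV must be > 0")
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  if (p_detect <= 0 || p_detect >= 1) stop("p_detect must lie in (0, 1)")
  if (tau_ref_s <= 0 || tau_deact_ref_s <= 0) stop("tau values must be > 0")
  if (efold_act_mV <= 0 || efold_deact_mV <= 0) stop("efold values must be > 0")
  if (zn_Kd_uM <= 0) stop("zn_Kd_uM must be > 0")
  if (zn_slow_factor_per_decade < 1)
    stop("zn_slow_factor_per_decade must be >= 1 (zinc slows activation)")
  structure(list(thr_slope = thr_slope, thr_offset_mV = thr_offset_mV,
                 steepness_k_mV = steepness_k_mV,
                 n_subunits = as.integer(n_subunits), p_detect = p_detect,
                 tau_ref_s = tau_ref_s, efold_act_mV = efold_act_mV,
                 tau_deact_ref_s = tau_deact_ref_s,
                 efold_deact_mV = efold_deact_mV,
                 zn_Kd_uM = zn_Kd_uM,
                 zn_shift_mV_per_decade = zn_shift_mV_per_decade,
                 zn_slow_factor_per_decade = zn_slow_factor_per_decade),
            class = "hv_gating_law")
}

#' Published gating-law presets
#'
#' `eth_v1_law()` configures the gating law with the threshold-versus-
#' reversal regression reported for the stick-insect channel
#' (V_thres = 0.77 V_rev - 23 mV, tau_act e-fold voltage 10 mV);
#' `nph_v1_law()` uses the firebrat-relative channel's line of identical
#' slope and -2.4 mV offset.
#'
#' @param ... overrides passed to [gating_law()].
#' @return an `hv_gating_law`.
#' @export
eth_v1_law <- function(...) {
  args <- list(...)
  do.call(gating_law, utils::modifyList(
    list(thr_slope = 0.77, thr_offset_mV = -23, efold_act_mV = 10), args))
}

#' @rdname eth_v1_law
#' @export
nph_v1_law <- function(...) {
  args <- list(...)
  do.call(gating_law, utils::modifyList(
    list(thr_slope = 0.77, thr_offset_mV = -2.4, efold_act_mV = 10), args))
}

#' Voltage-step protocol
#'
#' A family of depolarizing test pulses from a holding potential, each
#' followed by a repolarizing tail segment. Steps must be strictly ordered
#' by test potential. A short pre-pulse segment at holding precedes each
#' test pulse and provides the quiescent baseline/noise window used by the
#' analysis functions.
#'
#' @param holding_mV holding potential (mV).
#' @param steps data frame with columns `test_mV` and `duration_s`, or a
#'   numeric vector of test potentials combined with `duration_s`.
#' @param duration_s pulse duration(s) used when `steps` is a numeric vector
#'   (recycled).
#' @param tail_mV repolarization potential of the tail segment.
#' @param tail_duration_s tail segment duration (s).
#' @param sample_rate_Hz sampling rate.
#' @param pre_s pre-pulse baseline duration at holding (s).
#' @param inter_pulse_s rest interval between pulses, during which the
#'   pipette re-equilibrates cytosolic pH.
#' @return an `hv_protocol` object.
#' @examples
#' step_protocol(steps = seq(-40, 60, 10), duration_s = 2)
#' @export
step_protocol <- function(holding_mV = -80, steps, duration_s = NULL,
                          tail_mV = -80, tail_duration_s = 1,
                          sample_rate_Hz = 500, pre_s = 0.3,
                          inter_pulse_s = 15) {
  if (is.numeric(steps) && is.null(dim(steps))) {
    if (is.null(duration_s)) stop("duration_s required when steps is a vector")
    steps <- data.frame(test_mV = as.numeric(steps),
                        duration_s = rep_len(as.numeric(duration_s), length(steps)))
  }
  stopifnot(is.data.frame(steps), all(c("test_mV", "duration_s") %in% names(steps)))
  if (nrow(steps) == 0L) stop("protocol must contain at least one step")
  if (any(diff(steps$test_mV) <= 0))
    stop("steps must be strictly ordered by test_mV")
  if (any(steps$duration_s <= 0) || tail_duration_s <= 0)
    stop("durations must be > 0")
  if (sample_rate_Hz <= 0) stop("sample_rate_Hz must be > 0")
  structure(list(holding_mV = holding_mV,
                 steps = steps[, c("test_mV", "duration_s")],
                 tail_mV = tail_mV, tail_duration_s = tail_duration_s,
                 sample_rate_Hz = sample_rate_Hz, pre_s = pre_s,
                 inter_pulse_s = inter_pulse_s),
            class = "hv_protocol")
}

#' @export
print.hv_conditions <- function(x, ...) {
  cat(sprintf("Solution: pH_i %.2f // pH_o %.2f (dpH = %+.2f), %.1f uM Zn2+, %.2f K\n",
              x$pH_i_pipette, x$pH_o, x$pH_o - x$pH_i_pipette,
              x$zinc_uM, x$temperature_K))
  invisible(x)
}

#' @export
print.hv_cell <- function(x, ...) {
  cat(sprintf("Cell: %.2f pF, %.2f nS/pF (g_max %.2f nS), leak %.3f nS, %.1f pL%s\n",
              x$capacitance_pF, x$g_max_density_nS_per_pF, g_max_nS(x),
              x$leak_nS, x$volume_pL,
              if (x$depletion_enabled) ", depletion on" else ", depletion off"))
  invisible(x)
}

#' @export
print.hv_gating_law <- function(x, ...) {
  cat(sprintf("Gating law: V_thres = %.2f V_rev %+.1f mV; k = %.1f mV, N = %d, p_detect = %g\n",
              x$thr_slope, x$thr_offset_mV, x$steepness_k_mV,
              x$n_subunits, x$p_detect))
  cat(sprintf("  tau_act %.2f s at threshold, %.1f mV/e-fold; tau_deact %.2f s at -80 mV\n",
              x$tau_ref_s, x$efold_act_mV, x$tau_deact_ref_s))
  invisible(x)
}

#' @export
print.hv_protocol <- function(x, ...) {
  cat(sprintf("Protocol: hold %g mV, %d steps (%g..%g mV), tail %g mV/%g s, %g Hz\n",
              x$holding_mV, nrow(x$steps), min(x$steps$test_mV),
              max(x$steps$test_mV), x$tail_mV, x$tail_duration_s,
              x$sample_rate_Hz))
  invisible(x)
}
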