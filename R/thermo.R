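# Thermodynamic reference potentials for ion channels: Nernst equilibrium
# potential and the Goldman-Hodgkin-Katz reversal potential for mixtures of
# monovalent ions. Concentrations are treated as activities.

#' Physical constants and temperature context
#'
#' Bundles the gas constant `R`, the Faraday constant `F` (CODATA values) and
#' an absolute temperature. All potentials in the package are derived from
#' this context so that every report can record the temperature used.
#'
#' @param temperature_K absolute temperature in kelvin. The default 293.15 K
#'   (20 degrees C) is the midpoint of a typical 19-23 degrees C recording
#'   range for whole-cell patch clamp at room temperature.
#' @return an object of class `hv_thermo` with fields `temperature_K`,
#'   `R_J_per_mol_K` and `F_C_per_mol`.
#' @examples
#' thermo_context()
#' thermo_context(298.15)
#' @export
thermo_context <- function(temperature_K = 293.15) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K))
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  structure(
    list(temperature_K = temperature_K,
         R_J_per_mol_K = 8.31446261815324,
         F_C_per_mol   = 96485.33212331),
    class = "hv_thermo"
  )
}

as_thermo <- function(x) {
  if (inherits(x, "hv_thermo")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermo_context(x))
  stop("expected an 'hv_thermo' object or a temperature in kelvin")
}

#' Nernst slope per pH unit
#'
#' Returns RT ln(10)/F in millivolts: the change of the proton equilibrium
#' potential per unit of transmembrane pH gradient (58.17 mV at 293.15 K,
#' 59.16 mV at 298.15 K).
#'
#' @param thermo an [thermo_context()] object or a temperature in kelvin.
#' @return millivolts per pH unit.
#' @export
nernst_slope_mV <- function(thermo = thermo_context()) {
  th <- as_thermo(thermo)
  1000 * th$R_J_per_mol_K * th$temperature_K * log(10) / th$F_C_per_mol
}

#' Nernst equilibrium potential for protons
#'
#' Computes E_H = (RT/zF) ln([H+]_out/[H+]_in), expressed in millivolts.
#' In pH terms this is (RT ln10 / zF) (pH_i - pH_o): a one-unit outward-acid
#' gradient (pH_o one unit below pH_i) gives about +58 mV at 20 degrees C.
#'
#' @param pH_o,pH_i external and internal pH.
#' @param thermo an [thermo_context()] or temperature in kelvin.
#' @param z ion charge (+1 for protons); must be non-zero.
#' @return equilibrium potential in mV (vectorised over pH arguments).
#' @examples
#' nernst(5.5, 6.5)          # about +58.2 mV
#' nernst(7.0, 7.0)          # 0 mV
#' @export
nernst <- function(pH_o, pH_i, thermo = thermo_context(), z = 1L) {
  if (!is.numeric(z) || length(z) != 1L || z == 0)
    stop("z must be a non-zero integer charge")
  stopifnot(is.numeric(pH_o), is.numeric(pH_i))
  if (any(!is.finite(pH_o)) || any(!is.finite(pH_i)))
    stop("pH values must be finite")
  if (any(pH_o <= 0 | pH_o >= 14) || any(pH_i <= 0 | pH_i >= 14))
    stop("pH values must lie in (0, 14)")
  nernst_slope_mV(thermo) / z * (pH_i - pH_o)
}

#' Ion species for GHK calculations
#'
#' @param name species label.
#' @param z charge; only +1 and -1 are supported by [ghk_reversal()].
#' @param conc_in,conc_out intra- and extracellular concentration (molar).
#' @param rel_permeability relative permeability (dimensionless, >= 0).
#' @return an `hv_ion` object.
#' @export
ion_species <- function(name, z, conc_in, conc_out, rel_permeability = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!z %in% c(-1L, 1L, -1, 1)) stop("only monovalent species (z = +1 or -1) are supported")
  if (rel_permeability < 0) stop("rel_permeability must be >= 0")
  if (rel_permeability > 0 && (conc_in <= 0 || conc_out <= 0))
    stop("concentrations must be > 0 for permeant species")
  structure(list(name = name, z = as.integer(z), conc_in = conc_in,
                 conc_out = conc_out, rel_permeability = rel_permeability),
            class = "hv_ion")
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' V_rev = (RT/F) ln[(sum P_M [M+]_out + sum P_A [A-]_in) /
#'                   (sum P_M [M+]_in  + sum P_A [A-]_out)], in mV.
#' With a single permeant species this reduces exactly to the Nernst
#' potential, and it is invariant to uniform scaling of all permeabilities.
#'
#' @param species a list of [ion_species()] objects.
#' @param thermo an [thermo_context()] or temperature in kelvin.
#' @return reversal potential in mV.
#' @examples
#' h <- ion_species("H", +1, conc_in = 10^-6.5, conc_out = 10^-5.5,
#'                  rel_permeability = 1)
#' ghk_reversal(list(h))   # equals nernst(5.5, 6.5)
#' @export
ghk_reversal <- function(species, thermo = thermo_context()) {
  th <- as_thermo(thermo)
  if (inherits(species, "hv_ion")) species <- list(species)
  stopifnot(is.list(species), length(species) >= 1L)
  ok <- vapply(species, inherits, logical(1), what = "hv_ion")
  if (!all(ok)) stop("species must be a list of ion_species() objects")
  z <- vapply(species, `[[`, numeric(1), "z")
  p <- vapply(species, `[[`, numeric(1), "rel_permeability")
  if (any(abs(z) != 1)) stop("divalent or multivalent species are not supported")
  if (all(p == 0)) stop("at least one species must have rel_permeability > 0")
  cin  <- vapply(species, `[[`, numeric(1), "conc_in")
  cout <- vapply(species, `[[`, numeric(1), "conc_out")
  cat_i <- z > 0
  num <- sum(p[cat_i] * cout[cat_i]) + sum(p[!cat_i] * cin[!cat_i])
  den <- sum(p[cat_i] * cin[cat_i])  + sum(p[!cat_i] * cout[!cat_i])
  1000 * th$R_J_per_mol_K * th$temperature_K / th$F_C_per_mol * log(num / den)
}

#' Measured-versus-predicted selectivity table
#'
#' Pairs measured reversal potentials with the proton Nernst potential under
#' the same recording conditions. Perfect proton selectivity puts every point
#' on the identity line V_rev = E_H; deviations are typically the signature
#' of imperfect intracellular pH control (proton depletion during sustained
#' outward current alkalinises the cytosol and pulls V_rev off E_H).
#'
#' @param estimates a list of reversal estimates as returned by
#'   [vrev_zero_current()] or [vrev_tail()], each carrying its
#'   [solution_conditions()].
#' @param thermo an [thermo_context()] or temperature in kelvin.
#' @param tol_mV rows whose |measured - predicted| exceeds this tolerance are
#'   flagged as depletion-suspect (default 5 mV).
#' @return an `hv_selectivity` data frame with columns `pH_i`, `pH_o`,
#'   `E_H_mV`, `V_rev_measured_mV`, `deviation_mV`, `suspect`; attributes
#'   `max_abs_deviation_mV` and `temperature_K`.
#' @export
selectivity_table <- function(estimates, thermo = thermo_context(), tol_mV = 5) {
  th <- as_thermo(thermo)
  if (inherits(estimates, "hv_reversal")) estimates <- list(estimates)
  if (length(estimates) == 0L) stop("empty input: no reversal estimates")
  rows <- lapply(estimates, function(e) {
    if (!inherits(e, "hv_reversal"))
      stop("estimates must be hv_reversal objects")
    cond <- e$conditions
    eh <- nernst(cond$pH_o, cond$pH_i_pipette, th)
    data.frame(pH_i = cond$pH_i_pipette, pH_o = cond$pH_o,
               E_H_mV = eh, V_rev_measured_mV = e$V_rev_mV,
               deviation_mV = e$V_rev_mV - eh,
               method = e$method)
  })
  tab <- do.call(rbind, rows)
  tab$suspect <- abs(tab$deviation_mV) > tol_mV
  structure(tab,
            max_abs_deviation_mV = max(abs(tab$deviation_mV)),
            temperature_K = th$temperature_K,
            tol_mV = tol_mV,
            class = c("hv_selectivity", "data.frame"))
}

#' @export
print.hv_thermo <- function(x, ...) {
  cat(sprintf("Thermodynamic context: T = %.2f K (Nernst slope %.2f mV/pH)\n",
              x$temperature_K, nernst_slope_mV(x)))
  invisible(x)
}

#' @export
print.hv_selectivity <- function(x, ...) {
  cat(sprintf("Selectivity table (%d conditions, T = %.2f K)\n",
              nrow(x), attr(x, "temperature_K")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("max |V_rev - E_H| = %.2f mV\n", attr(x, "max_abs_deviation_mV")))
  invisible(x)
}
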