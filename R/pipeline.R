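# End-to-end drivers: per-family analysis, the multi-condition
# determination design for the threshold-versus-reversal regression, the
# pipeline orchestrator and fixture generation.

#' Analyse one current family
#'
#' Runs the per-family stages in the order of a patch-clamp workflow:
#' rising-exponential fits per step, tail-based threshold detection,
#' zero-current reversal estimation, and the conductance-voltage curve.
#' Stages that are not applicable to the family (e.g. no zero crossing)
#' yield NULL components rather than aborting the family.
#'
#' @param family an `hv_family`.
#' @param k_sigma threshold-detection criterion (see [detect_threshold()]).
#' @param family_id identifier carried into the report.
#' @return an `hv_family_report`: `fits`, `threshold`, `vrev`, `gv`,
#'   `tau_fit`, `family_id`, `conditions`.
#' @export
analyze_family <- function(family, k_sigma = 3, family_id = NA_character_) {
  stopifnot(inherits(family, "hv_family"))
  fits <- lapply(family$traces, function(tr)
    tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL))
  thr <- detect_threshold(family, k_sigma = k_sigma, family_id = family_id)
  vrev <- tryCatch(vrev_zero_current(family, fits = fits),
                   error = function(e) NULL)
  gv <- if (!is.null(vrev))
    tryCatch(build_gv(family, vrev, fits = fits), error = function(e) NULL)
  else NULL
  tau_fit <- tryCatch(fit_tau_voltage(fits), error = function(e) NULL)
  structure(list(fits = fits, threshold = thr, vrev = vrev, gv = gv,
                 tau_fit = tau_fit, family_id = family_id,
                 conditions = family$conditions),
            class = "hv_family_report")
}

#' @export
print.hv_family_report <- function(x, ...) {
  cat(sprintf("Family report%s\n",
              if (is.na(x$family_id)) "" else paste0(" [", x$family_id, "]")))
  print(x$threshold)
  if (!is.null(x$vrev)) print(x$vrev) else cat("V_rev: not determined\n")
  if (!is.null(x$tau_fit)) print(x$tau_fit)
  invisible(x)
}

# Voltage list for one determination: a 10-mV ladder spanning from below
# threshold to above reversal, refined to 5-mV increments around the
# expected threshold (where the step potential itself is the measurement)
# and with fine steps bracketing the nominal E_H (+/-2 and +/-6 mV) so the
# zero-current crossing is read over a short, locally linear stretch of the
# I-V relation. `dither_mV` shifts the absolute placement of the
# near-threshold steps; the determination design draws it at random per
# family, mimicking the arbitrary alignment between the experimenter's step
# values and the cell's true threshold.
determination_voltages <- function(conditions, law, by_mV = 10,
                                   dither_mV = 0) {
  vt <- v_thres_mV(conditions, law)
  eh <- nernst(conditions$pH_o, conditions$pH_i_pipette,
               thermo_context(conditions$temperature_K))
  lo <- floor((vt - 25) / by_mV) * by_mV
  hi <- ceiling(max(vt + 45, eh + 15) / by_mV) * by_mV
  thr_fine <- seq(floor((vt - 10) / 2.5) * 2.5, ceiling((vt + 7.5) / 2.5) * 2.5,
                  by = 2.5) + dither_mV
  eh_fine <- round(eh) + c(-6, -2, 2, 6)
  coarse <- seq(lo, hi, by = by_mV)
  coarse <- coarse[vapply(coarse, function(v) all(abs(v - thr_fine) > 2.4),
                          logical(1))]
  sort(unique(c(coarse, thr_fine, eh_fine)))
}

#' Simulate the multi-condition determination design
#'
#' Emulates the experimental design behind a threshold-versus-reversal
#' dataset: determinations spread over a grid of internal and external pH
#' (default pH_i in \{6.5, 7.0\}, pH_o in \{5.5..7.0\}, 16 determinations
#' pooled from 9 simulated cells whose capacitance and conductance density
#' vary around the population means). For each determination a pulse-length
#' ladder family is simulated, the threshold is detected from first tail
#' currents and the reversal potential measured by the zero-current method.
#'
#' @param law an [gating_law()] (ground truth).
#' @param n_cells number of distinct simulated cells (default 9).
#' @param pH_i,pH_o pH grids crossed to form the condition list.
#' @param n_determinations total determinations (conditions recycled).
#' @param seed integer seed; all randomness (cell draws, noise) derives
#'   from it.
#' @param k_sigma threshold criterion.
#' @param thr_jitter_sd_mV SD of the per-cell threshold offset (default
#'   2 mV), emulating cell-to-cell variability of the absolute activation
#'   position around the population gating law; zero-mean, so the pooled
#'   regression still estimates the base law.
#' @param sample_rate_Hz acquisition rate of the simulated families.
#' @return a data frame, one row per determination: `pH_i`, `pH_o`,
#'   `cell_id`, `E_H_mV`, `V_rev_mV`, `V_thres_mV`, `thr_status`,
#'   `V_thres_true_mV`.
#' @export
simulate_determinations <- function(law = eth_v1_law(), n_cells = 9L,
                                    pH_i = c(6.5, 7.0),
                                    pH_o = c(5.5, 6.0, 6.5, 7.0),
                                    n_determinations = 16L, seed = 42L,
                                    k_sigma = 3, thr_jitter_sd_mV = 2,
                                    sample_rate_Hz = 500) {
  grid <- expand.grid(pH_i = pH_i, pH_o = pH_o)
  grid <- grid[rep(seq_len(nrow(grid)),
                   length.out = n_determinations), , drop = FALSE]
  cells <- with_seed(derive_seed(seed, 1L), {
    data.frame(
      cell_id = seq_len(n_cells),
      capacitance_pF = pmax(3, stats::rnorm(n_cells, 9.62, 2.03)),
      g_density = pmax(0.3, stats::rnorm(n_cells, 1.07, 0.44)),
      thr_jitter_mV = stats::rnorm(n_cells, 0, thr_jitter_sd_mV)
    )
  })
  step_dither_mV <- with_seed(derive_seed(seed, 2L),
                              stats::runif(n_determinations, -1.25, 1.25))
  cell_id <- rep(seq_len(n_cells), length.out = n_determinations)
  rows <- vector("list", n_determinations)
  for (d in seq_len(n_determinations)) {
    cond <- solution_conditions(pH_i_pipette = grid$pH_i[d],
                                pH_o = grid$pH_o[d])
    cell <- cell_model(capacitance_pF = cells$capacitance_pF[cell_id[d]],
                       g_max_density_nS_per_pF = cells$g_density[cell_id[d]])
    law_d <- do.call(gating_law, utils::modifyList(
      unclass(law),
      list(thr_offset_mV = law$thr_offset_mV +
             cells$thr_jitter_mV[cell_id[d]])))
    proto <- make_protocol_ladder(
      determination_voltages(cond, law_d, dither_mV = step_dither_mV[d]),
      law_d, cond, sample_rate_Hz = sample_rate_Hz)
    fam <- simulate_family(proto, cell, cond, law_d,
                           seed = derive_seed(seed, 100L + d))
    rep_ <- analyze_family(fam, k_sigma = k_sigma,
                           family_id = sprintf("det_%02d", d))
    eh <- nernst(cond$pH_o, cond$pH_i_pipette,
                 thermo_context(cond$temperature_K))
    vt <- v_thres_mV(cond, law_d)
    # The zero-current reading needs a clear conduction window negative to
    # the reversal potential; when activation opens within ~15 mV of E_H
    # (or positive to it) the crossing cannot be read reliably and the
    # tail-current method is used instead, as in patch-clamp practice.
    vrev <- if (vt < eh - 15) rep_$vrev else NULL
    if (is.null(vrev)) {
      pre_mV <- round(vt + 30)
      tails <- round(eh) + seq(-10, 10, by = 4)
      tf <- simulate_tail_family(
        prepulse_mV = pre_mV,
        prepulse_s = min(max(2.5 * tau_act_model(pre_mV, cond, law_d), 0.25), 12),
        tail_mV_values = tails, cell = cell, conditions = cond, law = law_d,
        seed = derive_seed(seed, 500L + d),
        holding_mV = min(-40, round(vt) - 20),
        sample_rate_Hz = sample_rate_Hz)
      vrev <- tryCatch(vrev_tail(tf), error = function(e) NULL)
    }
    rows[[d]] <- data.frame(
      pH_i = grid$pH_i[d], pH_o = grid$pH_o[d], cell_id = cell_id[d],
      E_H_mV = nernst(cond$pH_o, cond$pH_i_pipette,
                      thermo_context(cond$temperature_K)),
      V_rev_mV = if (is.null(vrev)) NA_real_ else vrev$V_rev_mV,
      vrev_method = if (is.null(vrev)) NA_character_ else vrev$method,
      V_thres_mV = rep_$threshold$V_thres_mV,
      thr_status = rep_$threshold$status,
      V_thres_true_mV = v_thres_mV(cond, law_d)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in acquisition order: simulate (or ingest) the
#' determination families, regress threshold on reversal, fit the voltage
#' dependence of the activation time constant on a symmetric-pH family, and
#' assemble the measured-versus-Nernst selectivity table. Deterministic for
#' a given configuration and seed.
#'
#' @param config an `hv_run_config` (see [default_run_config()]) or a path
#'   to a YAML config file.
#' @param out_dir optional directory for the JSON report and CSV tables.
#' @return an `hv_pipeline_report`: `determinations`, `regression`,
#'   `tau_fit`, `selectivity`, `shift_per_pH_mV`, `provenance`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "hv_run_config"))
  law <- do.call(gating_law, config$law)
  if (config$n_determinations < 1L)
    stop("stage simulate: config requests zero determination families")

  det <- simulate_determinations(
    law = law, n_cells = config$n_cells, pH_i = config$pH_i,
    pH_o = config$pH_o, n_determinations = config$n_determinations,
    seed = config$seed, k_sigma = config$k_sigma)

  reg <- threshold_reversal_regression(det, range = config$voltage_range_mV)

  tf <- config$tau_family
  cond_tau <- solution_conditions(pH_i_pipette = tf$pH_i, pH_o = tf$pH_o)
  cell <- do.call(cell_model, config$cell)
  proto_tau <- make_protocol_ladder(c(tf$v_from, tf$v_to), law, cond_tau,
                                    by_mV = tf$by_mV,
                                    sample_rate_Hz = tf$sample_rate_Hz)
  fam_tau <- simulate_family(proto_tau, cell, cond_tau, law,
                             seed = derive_seed(config$seed, 7000L))
  tau_fit <- fit_tau_voltage(lapply(fam_tau$traces, function(tr)
    tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL)))

  th <- thermo_context(config$temperature_K)
  est <- lapply(which(!is.na(det$V_rev_mV)), function(i)
    new_reversal(det$V_rev_mV[i], "zero_current", c(NA_real_, NA_real_),
                 solution_conditions(pH_i_pipette = det$pH_i[i],
                                     pH_o = det$pH_o[i]),
                 n_points = NA_integer_))
  sel <- selectivity_table(est, th)

  report <- structure(list(
    determinations = det,
    regression = reg,
    tau_fit = tau_fit,
    selectivity = sel,
    shift_per_pH_mV = shift_per_ph_unit(reg, config$temperature_K),
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("hvgate")))
  ), class = "hv_pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(det, file.path(out_dir, "determinations.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sel), file.path(out_dir, "selectivity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(regression = list(slope = reg$slope, offset_mV = reg$offset_mV,
                             n = reg$n_determinations,
                             residual_sd_mV = reg$residual_sd_mV),
           tau_fit = list(mV_per_efold = tau_fit$mV_per_efold,
                          efold_per_mV = tau_fit$efold_per_mV,
                          n_points = tau_fit$n_points),
           shift_per_pH_mV = report$shift_per_pH_mV,
           max_abs_deviation_mV = attr(sel, "max_abs_deviation_mV"),
           provenance = report$provenance),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.hv_pipeline_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  print(x$regression)
  print(x$tau_fit)
  cat(sprintf("Gating shift per pH unit: %.1f mV\n", x$shift_per_pH_mV))
  cat(sprintf("Selectivity: max |V_rev - E_H| = %.2f mV over %d conditions\n",
              attr(x$selectivity, "max_abs_deviation_mV"),
              nrow(x$selectivity)))
  invisible(x)
}

#' Generate the packaged synthetic fixtures
#'
#' Writes canned synthetic data to a directory: three small simulated
#' families (a pH-shift pair, a zinc series and a symmetric-pH family),
#' the synthetic protein and nucleotide FASTA sets with their annotation
#' sidecars, and the aligned S4 block; plus a manifest listing every file
#' with its MD5 checksum. All content is generated in code and labelled
#' synthetic.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @return the manifest data frame, invisibly written as `manifest.json`.
#' @export
generate_fixtures <- function(out_dir, seed = 42L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  law <- eth_v1_law()
  cell <- cell_model()

  fam_dirs <- character(0)
  ph_pair <- list(ph70 = solution_conditions(6.5, 7.0),
                  ph65 = solution_conditions(6.5, 6.5))
  for (nm in names(ph_pair)) {
    cond <- ph_pair[[nm]]
    proto <- make_protocol_ladder(range(determination_voltages(cond, law)),
                                  law, cond, sample_rate_Hz = 250, max_s = 4)
    fam <- simulate_family(proto, cell, cond, law, seed = derive_seed(seed, 11L))
    d <- file.path(out_dir, paste0("family_phshift_", nm))
    write_trace_family(fam, d)
    fam_dirs <- c(fam_dirs, d)
  }
  for (zn in c(0, 10, 100)) {
    cond <- solution_conditions(7.0, 7.0, zinc_uM = zn)
    proto <- make_protocol_ladder(c(-40, 60), law, cond,
                                  sample_rate_Hz = 250, max_s = 4)
    fam <- simulate_family(proto, cell, cond, law, seed = derive_seed(seed, 13L))
    d <- file.path(out_dir, sprintf("family_zinc_%03d", zn))
    write_trace_family(fam, d)
    fam_dirs <- c(fam_dirs, d)
  }
  cond_sym <- solution_conditions(7.0, 7.0)
  proto <- make_protocol_ladder(c(-40, -30, -20, -10, -6, -2, 2, 6, 10, 20, 30),
                                law, cond_sym,
                                sample_rate_Hz = 250, max_s = 4)
  fam <- simulate_family(proto, cell_model(depletion_enabled = FALSE),
                         cond_sym, law, seed = derive_seed(seed, 17L))
  d <- file.path(out_dir, "family_symmetric_ph7")
  write_trace_family(fam, d)
  fam_dirs <- c(fam_dirs, d)

  prots <- synthetic_hv1_proteins()
  write_fasta(prots[c("et", "et_contaminant", "et_sfD")],
              file.path(out_dir, "synthetic_proteins.fasta"))
  write_fasta(prots[c("href", "npref")],
              file.path(out_dir, "synthetic_references.fasta"))
  tx <- synthetic_hv1_transcript()
  write_fasta(tx$sequence, file.path(out_dir, "synthetic_transcript.fasta"))
  s4 <- synthetic_s4_alignment()
  write_fasta(as.list(stats::setNames(as.character(s4), names(s4))),
              file.path(out_dir, "synthetic_s4_alignment.fasta"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Measure the g-V shift between two recording conditions
#'
#' Simulates one cell under two solution conditions (same gating law, same
#' seed-derived noise streams), analyses each family with the standard
#' pipeline (activation fits, zero-current reversal, conductance-voltage
#' curve) and returns the half-maximum voltage shift of condition `b`
#' relative to condition `a` (positive = rightward).
#'
#' @param cond_a,cond_b [solution_conditions()] objects.
#' @param law an [gating_law()].
#' @param cell an [cell_model()]; defaults to the standard cell.
#' @param seed integer seed.
#' @param sample_rate_Hz acquisition rate.
#' @return shift in mV; the two `hv_family_report`s are attached as
#'   attribute `reports`.
#' @export
measure_gv_shift <- function(cond_a, cond_b, law = eth_v1_law(),
                             cell = cell_model(), seed = 42L,
                             sample_rate_Hz = 500) {
  reports <- lapply(list(a = cond_a, b = cond_b), function(cond) {
    proto <- make_protocol_ladder(determination_voltages(cond, law), law,
                                  cond, sample_rate_Hz = sample_rate_Hz)
    fam <- simulate_family(proto, cell, cond, law,
                           seed = derive_seed(seed, 31L))
    analyze_family(fam)
  })
  if (is.null(reports$a$gv) || is.null(reports$b$gv))
    stop("conductance-voltage curve unavailable for one of the conditions")
  structure(gv_shift(reports$a$gv, reports$b$gv), reports = reports)
}
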