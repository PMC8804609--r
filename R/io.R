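# Trace-family file format and configuration round-trips. Traces are plain
# delimited text (one file per trace: time_s, current_pA, command_mV) with a
# JSON metadata sidecar per family holding conditions, cell, law, protocol
# and seed. Diff-able and language neutral; version tagged.

TRACE_FORMAT_VERSION <- "1.0"

cond_to_list <- function(x) unclass(x)
cell_to_list <- function(x) unclass(x)
law_to_list <- function(x) unclass(x)

#' Write a trace family to disk
#'
#' One tab-separated file per trace (`trace_001.tsv`, ... with columns
#' `time_s`, `current_pA`, `command_mV`) plus a `family.json` sidecar with
#' conditions, cell, gating law, protocol, seed and format version.
#'
#' @param family an `hv_family`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trace_family <- function(family, dir) {
  stopifnot(inherits(family, "hv_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(family$traces))
  for (i in seq_along(family$traces)) {
    tr <- family$traces[[i]]
    files[i] <- sprintf("trace_%03d.tsv", i)
    utils::write.table(
      data.frame(time_s = tr$time_s, current_pA = tr$current_pA,
                 command_mV = tr$command_mV),
      file.path(dir, files[i]), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- list(
    format_version = TRACE_FORMAT_VERSION,
    kind = family$kind,
    seed = family$seed,
    conditions = cond_to_list(family$conditions),
    cell = cell_to_list(family$cell),
    law = law_to_list(family$law),
    protocol = list(holding_mV = family$protocol$holding_mV,
                    steps = family$protocol$steps,
                    tail_mV = family$protocol$tail_mV,
                    tail_duration_s = family$protocol$tail_duration_s,
                    sample_rate_Hz = family$protocol$sample_rate_Hz,
                    pre_s = family$protocol$pre_s,
                    inter_pulse_s = family$protocol$inter_pulse_s),
    trace_files = files,
    test_mV = vapply(family$traces, `[[`, numeric(1), "test_mV"),
    tail_mV_per_trace = vapply(family$traces, `[[`, numeric(1), "tail_mV")
  )
  jsonlite::write_json(meta, file.path(dir, "family.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trace family written by [write_trace_family()]
#'
#' Reconstructs the `hv_family`, including segment tables per trace, from
#' the tabular files and the JSON sidecar.
#'
#' @param dir directory containing `family.json` and the trace files.
#' @return an `hv_family`.
#' @export
read_trace_family <- function(dir) {
  meta_path <- file.path(dir, "family.json")
  if (!file.exists(meta_path)) stop("no family.json sidecar in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, TRACE_FORMAT_VERSION))
    warning("trace format version ", meta$format_version,
            " differs from current ", TRACE_FORMAT_VERSION)
  cond <- do.call(solution_conditions, meta$conditions)
  cell <- do.call(cell_model, meta$cell)
  law <- do.call(gating_law, meta$law)
  proto <- step_protocol(holding_mV = meta$protocol$holding_mV,
                         steps = as.data.frame(meta$protocol$steps),
                         tail_mV = meta$protocol$tail_mV,
                         tail_duration_s = meta$protocol$tail_duration_s,
                         sample_rate_Hz = meta$protocol$sample_rate_Hz,
                         pre_s = meta$protocol$pre_s,
                         inter_pulse_s = meta$protocol$inter_pulse_s)
  traces <- lapply(seq_along(meta$trace_files), function(i) {
    tab <- utils::read.delim(file.path(dir, meta$trace_files[i]))
    test_mV <- meta$test_mV[i]
    tail_mV <- meta$tail_mV_per_trace[i]
    dur <- if (identical(meta$kind, "tail")) meta$protocol$steps$duration_s[1]
           else meta$protocol$steps$duration_s[i]
    seg <- data.frame(
      label = c("pre", "test", "tail"),
      start_s = c(0, proto$pre_s, proto$pre_s + dur),
      end_s = c(proto$pre_s, proto$pre_s + dur,
                proto$pre_s + dur + proto$tail_duration_s),
      mV = c(proto$holding_mV, test_mV, tail_mV),
      stringsAsFactors = FALSE)
    structure(list(time_s = tab$time_s, current_pA = tab$current_pA,
                   command_mV = tab$command_mV, segments = seg,
                   conditions = cond, pH_i_trajectory = NULL,
                   seed = NA_integer_, test_mV = test_mV, tail_mV = tail_mV,
                   holding_mV = proto$holding_mV,
                   sample_rate_Hz = proto$sample_rate_Hz),
              class = "hv_trace")
  })
  structure(list(protocol = proto, traces = traces, conditions = cond,
                 cell = cell, law = law, seed = meta$seed,
                 kind = meta$kind),
            class = "hv_family")
}

#' Run configuration round-trip
#'
#' `default_run_config()` returns the full set of simulator and analysis
#' settings used by [run_pipeline()]; `read_run_config()` /
#' `write_run_config()` round-trip it losslessly through YAML. Unknown keys
#' are rejected so that typos never silently fall back to defaults.
#'
#' @param seed integer seed driving every source of randomness.
#' @return a named list of class `hv_run_config`.
#' @export
default_run_config <- function(seed = 42L) {
  structure(list(
    seed = as.integer(seed),
    law = law_to_list(eth_v1_law()),
    cell = cell_to_list(cell_model()),
    pH_i = c(6.5, 7.0),
    pH_o = c(5.5, 6.0, 6.5, 7.0),
    n_cells = 9L,
    n_determinations = 16L,
    temperature_K = 293.15,
    k_sigma = 3,
    voltage_range_mV = c(-70, 70),
    tau_family = list(pH_i = 7.0, pH_o = 7.0,
                      v_from = -25, v_to = 10, by_mV = 5,
                      sample_rate_Hz = 1000)
  ), class = "hv_run_config")
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_run_config()
  unknown <- setdiff(names(raw), names(ref))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(ref), raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$n_determinations <- as.integer(cfg$n_determinations)
  structure(cfg, class = "hv_run_config")
}

#' @rdname default_run_config
#' @param config an `hv_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
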