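# Shared fixtures and small constructors used across the suite. Everything
# is generated in code; expensive simulate-then-analyze runs are cached per
# session so that several tests can share one run.

.hv_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hv_cache)) assign(key, force(expr), envir = .hv_cache)
  get(key, envir = .hv_cache)
}

# The reference simulate -> analyze -> regress round trip at the standard
# 16-determination design (fixed seed shared by the tests that consume it).
determination_run <- function() {
  cached("determinations_seed42", simulate_determinations(seed = 42L))
}

quiet_cell <- function(...) {
  cell_model(noise_sd_pA = 0, depletion_enabled = FALSE, leak_nS = 0, ...)
}

# Construct a bare trace (pre/test/tail segments) from generator functions
# of segment-local time; used to test the analysis primitives against
# currents of known shape without involving the simulator.
constructed_trace <- function(test_fun, tail_fun = function(t) rep(0, length(t)),
                              pre_fun = function(t) rep(0, length(t)),
                              pre_s = 0.3, test_s = 6, tail_s = 1,
                              rate = 200, test_mV = 40, tail_mV = -80,
                              holding_mV = -80) {
  seg <- data.frame(label = c("pre", "test", "tail"),
                    start_s = c(0, pre_s, pre_s + test_s),
                    end_s = c(pre_s, pre_s + test_s, pre_s + test_s + tail_s),
                    mV = c(holding_mV, test_mV, tail_mV),
                    stringsAsFactors = FALSE)
  tm <- seq(0, seg$end_s[3] - 1 / rate, by = 1 / rate)
  idx <- findInterval(tm, seg$start_s)
  cur <- numeric(length(tm))
  cur[idx == 1] <- pre_fun(tm[idx == 1])
  cur[idx == 2] <- test_fun(tm[idx == 2] - pre_s)
  cur[idx == 3] <- tail_fun(tm[idx == 3] - pre_s - test_s)
  structure(list(time_s = tm, current_pA = cur,
                 command_mV = seg$mV[idx], segments = seg,
                 conditions = solution_conditions(), seed = NA_integer_,
                 test_mV = test_mV, tail_mV = tail_mV,
                 holding_mV = holding_mV, sample_rate_Hz = rate),
            class = "hv_trace")
}

# A family of constructed traces with prescribed tail amplitudes (constant
# over the tail segment) and seeded pre-pulse noise of unit SD.
constructed_tail_family <- function(step_mV, tail_peaks_pA, tail_mV = -80,
                                    noise_sd = 1, seed = 7L) {
  traces <- lapply(seq_along(step_mV), function(i) {
    ns <- hvgate:::with_seed(seed + i, stats::rnorm(2000, 0, noise_sd))
    k <- 0L
    draw <- function(m) {
      out <- ns[(k + 1L):(k + m)]; k <<- k + m; out
    }
    constructed_trace(
      pre_fun = function(t) draw(length(t)),
      test_fun = function(t) rep(0, length(t)),
      tail_fun = function(t) tail_peaks_pA[i] + draw(length(t)),
      test_mV = step_mV[i], tail_mV = if (length(tail_mV) > 1) tail_mV[i] else tail_mV,
      test_s = 1, rate = 200)
  })
  structure(list(traces = traces, conditions = solution_conditions(),
                 kind = "step", seed = seed),
            class = "hv_family")
}
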