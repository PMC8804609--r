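law <- eth_v1_law()

test_that("rising-exponential fit recovers a pure exponential to numerical precision", {
  tr <- constructed_trace(function(t) 100 * (1 - exp(-t / 1.5)),
                          test_s = 8, rate = 200)
  fit <- fit_activation(tr, delay_policy = "none")
  expect_equal(fit$I_ss_pA, 100, tolerance = 1e-6)
  expect_equal(fit$tau_s, 1.5, tolerance = 1e-6)
  expect_lt(fit$rmse_pA, 1e-6)
})

test_that("the fit is invariant to additive baseline and time origin", {
  base <- constructed_trace(function(t) 80 * (1 - exp(-t / 0.8)), test_s = 5)
  shifted <- base
  shifted$current_pA <- shifted$current_pA + 37.5
  f1 <- fit_activation(base); f2 <- fit_activation(shifted)
  expect_equal(f1$I_ss_pA, f2$I_ss_pA, tolerance = 1e-8)
  expect_equal(f1$tau_s, f2$tau_s, tolerance = 1e-8)
  # time origin: shift all segment boundaries and timestamps by 2 s
  moved <- base
  moved$time_s <- moved$time_s + 2
  moved$segments$start_s <- moved$segments$start_s + 2
  moved$segments$end_s <- moved$segments$end_s + 2
  f3 <- fit_activation(moved)
  expect_equal(f1$tau_s, f3$tau_s, tolerance = 1e-8)
  expect_equal(f1$I_ss_pA, f3$I_ss_pA, tolerance = 1e-8)
})

test_that("fitted time constants track the gating relaxation of simulated sigmoidal currents", {
  cond <- solution_conditions(6.5, 6.5)
  cell <- quiet_cell()
  for (v in c(-10, 10, 20)) {  # 0 mV is the reversal potential here
    tr <- simulate_step(v, 6 * tau_act_model(v, cond, law), cell, cond, law,
                        seed = 2, sample_rate_Hz = 1000)
    fit <- fit_activation(tr)
    expect_equal(fit$tau_s, tau_act_model(v, cond, law), tolerance = 0.15)
  }
})

test_that("degenerate traces are rejected by the fit", {
  flat <- constructed_trace(function(t) rep(0, length(t)))
  expect_error(fit_activation(flat), "fit failed")
  noisy <- hvgate:::with_seed(3L, constructed_trace(
    function(t) rnorm(length(t)), pre_fun = function(t) rnorm(length(t))))
  expect_error(fit_activation(noisy), "fit failed")
})

test_that("tail measurement reads the injected amplitude and stays at noise level without channel", {
  fam <- constructed_tail_family(step_mV = 20, tail_peaks_pA = -50,
                                 noise_sd = 0.2)
  tm <- measure_tail(fam$traces[[1]])
  expect_equal(tm$tail_peak_pA, -50, tolerance = 0.02)
  # zero-conductance simulated trace: tail peak within noise
  cond <- solution_conditions(7, 7)
  cell <- cell_model(g_max_density_nS_per_pF = 0, depletion_enabled = FALSE)
  tr <- simulate_step(60, 2, cell, cond, law, seed = 8)
  tm2 <- measure_tail(tr)
  expect_lt(abs(tm2$tail_peak_pA), 3 * tm2$noise_sd_pA)
})

test_that("tail amplitudes grow monotonically with step voltage in a simulated family", {
  cond <- solution_conditions(6.5, 6.5)
  proto <- make_protocol_ladder(c(-30, 30), law, cond, max_s = 6)
  fam <- simulate_family(proto, quiet_cell(), cond, law, seed = 4)
  peaks <- abs(vapply(fam$traces, function(tr) measure_tail(tr)$tail_peak_pA,
                      numeric(1)))
  expect_true(all(diff(peaks) >= -1e-9))
})

test_that("threshold detection finds the first persistent tail", {
  fam <- constructed_tail_family(step_mV = c(-10, 0, 10, 20),
                                 tail_peaks_pA = c(0.1, 0.4, 5, 12),
                                 noise_sd = 1, seed = 11)
  thr <- detect_threshold(fam, k_sigma = 3, rel_fraction = 0)
  expect_equal(thr$V_thres_mV, 10)
  expect_equal(thr$status, "ok")
  # all-noise family: no threshold
  fam0 <- constructed_tail_family(step_mV = c(-10, 0, 10),
                                  tail_peaks_pA = c(0, 0, 0), seed = 12)
  thr0 <- detect_threshold(fam0, rel_fraction = 0)
  expect_true(is.na(thr0$V_thres_mV))
  expect_equal(thr0$status, "no-threshold")
  # everything above criterion: saturation warning, lowest step returned
  famS <- constructed_tail_family(step_mV = c(-10, 0, 10),
                                  tail_peaks_pA = c(30, 60, 90), seed = 13)
  expect_warning(thrS <- detect_threshold(famS), "lowest step")
  expect_equal(thrS$V_thres_mV, -10)
  expect_equal(thrS$status, "saturated")
})

test_that("loosening the detection criterion never raises the threshold", {
  cond <- solution_conditions(6.5, 6.5)
  proto <- make_protocol_ladder(c(-50, 30), law, cond, max_s = 8)
  fam <- simulate_family(proto, cell_model(), cond, law, seed = 21)
  ks <- c(6, 4, 3, 2)
  got <- vapply(ks, function(k) detect_threshold(fam, k_sigma = k)$V_thres_mV,
                numeric(1))
  expect_true(all(diff(got) <= 0))
})

test_that("detected threshold lies within one increment of the generator threshold", {
  cond <- solution_conditions(6.5, 6.5)
  vt <- v_thres_mV(cond, law)
  volts <- seq(floor((vt - 25) / 5) * 5, ceiling((vt + 40) / 5) * 5, 5)
  proto <- make_protocol_ladder(volts, law, cond, max_s = 10)
  fam <- simulate_family(proto, cell_model(), cond, law, seed = 33)
  thr <- detect_threshold(fam)
  expect_equal(thr$status, "ok")
  expect_lte(abs(thr$V_thres_mV - vt), 5)
})

test_that("zero-current reversal interpolates fitted steady-state currents", {
  fake_family <- structure(list(conditions = solution_conditions(6.5, 5.5)),
                           class = "hv_family")
  fits <- list(list(V_mV = 40, I_ss_pA = -20),
               list(V_mV = 50, I_ss_pA = -5),
               list(V_mV = 60, I_ss_pA = 10))
  est <- vrev_zero_current(fake_family, fits = fits)
  expect_equal(est$V_rev_mV, 50 + 10 * 5 / 15, tolerance = 1e-12)
  expect_equal(est$bracket_mV, c(50, 60))
  # exact zero at a step
  fits0 <- list(list(V_mV = 40, I_ss_pA = -3), list(V_mV = 50, I_ss_pA = 0),
                list(V_mV = 60, I_ss_pA = 12))
  expect_equal(vrev_zero_current(fake_family, fits = fits0)$V_rev_mV, 50)
  # no sign change: redirect to the tail method
  fitsN <- list(list(V_mV = 40, I_ss_pA = 4), list(V_mV = 50, I_ss_pA = 9))
  expect_error(vrev_zero_current(fake_family, fits = fitsN), "vrev_tail")
})

test_that("measured reversal matches the Nernst prediction when depletion is off", {
  cond <- solution_conditions(6.5, 5.5)
  proto <- make_protocol_ladder(hvgate:::determination_voltages(cond, law),
                                law, cond)
  fam <- simulate_family(proto, cell_model(depletion_enabled = FALSE),
                         cond, law, seed = 14)
  est <- vrev_zero_current(fam)
  expect_equal(est$V_rev_mV, nernst(5.5, 6.5), tolerance = 1 / 58)
})

test_that("tail-current reversal interpolates the tail sign change", {
  fam <- constructed_tail_family(step_mV = c(-10, 0, 10),
                                 tail_peaks_pA = c(-30, -8, 15),
                                 tail_mV = c(-10, 0, 10), noise_sd = 0.01,
                                 seed = 15)
  est <- vrev_tail(fam)
  expect_equal(est$V_rev_mV, 10 * 8 / 23, tolerance = 0.01)
  expect_error(vrev_tail(constructed_tail_family(0, -5, tail_mV = 0)),
               "at least two")
})

test_that("the two reversal methods agree on the same simulated cell", {
  cond <- solution_conditions(7, 7)
  cell <- cell_model(depletion_enabled = FALSE)
  proto <- make_protocol_ladder(hvgate:::determination_voltages(cond, law),
                                law, cond)
  fam <- simulate_family(proto, cell, cond, law, seed = 16)
  zc <- vrev_zero_current(fam)
  tf <- simulate_tail_family(prepulse_mV = 40, prepulse_s = 1.5,
                             tail_mV_values = seq(-10, 10, 2),
                             cell = cell, conditions = cond, law = law,
                             seed = 17)
  tl <- vrev_tail(tf)
  expect_equal(tl$method, "tail")
  expect_lt(abs(zc$V_rev_mV - tl$V_rev_mV), 2)
  expect_lt(abs(tl$V_rev_mV - 0), 1.5)  # symmetric pH: V_rev near 0
})

test_that("chord conductance arithmetic and its guard rails", {
  expect_equal(conductance_point(100, 60, 0), 100 / 60)
  expect_equal(conductance_point(0, 30, 0), 0)
  expect_error(conductance_point(5, 40, 40), "undefined")
})

test_that("normalized conductance reproduces the open-probability curve", {
  cond <- solution_conditions(6.5, 6.5)
  proto <- make_protocol_ladder(c(-30, 30), law, cond, max_s = 8,
                                sample_rate_Hz = 1000)
  fam <- simulate_family(proto, quiet_cell(), cond, law, seed = 18)
  fits <- lapply(fam$traces, function(tr)
    tryCatch(suppressWarnings(fit_activation(tr)), error = function(e) NULL))
  gv <- build_gv(fam, vrev = 0, fits = fits)
  p <- steady_state_open_prob(gv$points$V_mV, cond, law)
  expect_equal(gv$points$g_nS / g_max_nS(quiet_cell()), p, tolerance = 0.02)
})
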