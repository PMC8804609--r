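law <- eth_v1_law()

test_that("steady-state open probability is anchored at the threshold law", {
  cond <- solution_conditions(6.5, 5.5)
  # threshold from the closed-form Nernst potential: 0.77 * 58.17 - 23
  eh <- 1000 * 8.31446261815324 * 293.15 * log(10) / 96485.33212331 * 1.0
  expect_equal(v_thres_mV(cond, law), 0.77 * eh - 23, tolerance = 1e-10)
  expect_equal(steady_state_open_prob(v_thres_mV(cond, law), cond, law),
               law$p_detect, tolerance = 1e-12)
  # saturation limits and monotonicity
  expect_equal(steady_state_open_prob(-1e4, cond, law), 0)
  expect_equal(steady_state_open_prob(1e4, cond, law), 1)
  p <- steady_state_open_prob(seq(-100, 100, 2), cond, law)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  expect_error(steady_state_open_prob(NaN, cond, law), "finite")
})

test_that("activation time constant follows its e-fold law and zinc slows it", {
  cond <- solution_conditions(6.5, 6.5)
  vt <- v_thres_mV(cond, law)
  expect_equal(tau_act_model(vt, cond, law), law$tau_ref_s)
  expect_equal(tau_act_model(vt + 10, cond, law), law$tau_ref_s / exp(1))
  v <- seq(vt - 20, vt + 40, 5)
  expect_true(all(diff(tau_act_model(v, cond, law)) < 0))
  # zinc: tau ratio at matched distance from threshold equals the slow factor
  zn <- solution_conditions(6.5, 6.5, zinc_uM = 100)
  ratio <- tau_act_model(v_thres_mV(zn, law) + 10, zn, law) /
    tau_act_model(vt + 10, cond, law)
  expect_equal(ratio, zinc_slow_factor(100, law), tolerance = 1e-12)
  # zinc monotonicity of both threshold shift and kinetics
  shifts <- zinc_shift_mV(c(0, 10, 100), law)
  slows <- zinc_slow_factor(c(0, 10, 100), law)
  expect_true(all(diff(shifts) > 0) && shifts[1] == 0)
  expect_true(all(diff(slows) > 0) && slows[1] == 1)
})

test_that("a channel-free cell produces only leak and noise", {
  cond <- solution_conditions(7, 7)
  cell <- cell_model(g_max_density_nS_per_pF = 0, leak_nS = 0.2,
                     noise_sd_pA = 1, depletion_enabled = FALSE)
  tr <- simulate_step(60, 2, cell, cond, law, seed = 5)
  test_part <- tr$current_pA[tr$command_mV == 60]
  expect_equal(mean(test_part), 0.2 * 60, tolerance = 0.05)
  expect_equal(sd(test_part), 1, tolerance = 0.1)
})

test_that("noiseless late-time currents reach the steady-state prediction", {
  cond <- solution_conditions(6.5, 6.5)
  cell <- quiet_cell()
  for (v in c(0, 20, 40)) {
    tr <- simulate_step(v, 5 * tau_act_model(v, cond, law) + 2, cell, cond,
                        law, seed = 1)
    late <- utils::tail(tr$current_pA[tr$command_mV == v], 5)
    pred <- g_max_nS(cell) * steady_state_open_prob(v, cond, law) * (v - 0)
    expect_equal(mean(late), pred, tolerance = 0.01)
  }
})

test_that("same seed reproduces a family exactly and traces only appear above threshold", {
  cond <- solution_conditions(6.5, 6.5)
  proto <- make_protocol_ladder(c(-60, 30), law, cond, max_s = 6)
  f1 <- simulate_family(proto, cell_model(), cond, law, seed = 9)
  f2 <- simulate_family(proto, cell_model(), cond, law, seed = 9)
  expect_identical(lapply(f1$traces, `[[`, "current_pA"),
                   lapply(f2$traces, `[[`, "current_pA"))
  f3 <- simulate_family(proto, cell_model(), cond, law, seed = 10)
  expect_false(identical(f1$traces[[1]]$current_pA, f3$traces[[1]]$current_pA))
  # sub-threshold steps carry no detectable current: compare against the
  # open-probability oracle
  vt <- v_thres_mV(cond, law)
  for (tr in f1$traces) {
    p <- steady_state_open_prob(tr$test_mV, cond, law)
    tail_amp <- abs(measure_tail(tr)$tail_peak_pA)
    if (tr$test_mV < vt - 10) {
      expect_lt(p, law$p_detect)
      expect_lt(tail_amp, 3.5)
    }
    if (tr$test_mV > vt + 10) expect_gt(tail_amp, 10)
  }
})

test_that("proton flux is conserved against an independent fine-step integrator", {
  # sealed cell (no pipette exchange): volume * integral(beta dpH) must
  # equal the time integral of I_H / F
  cond <- solution_conditions(7, 7)
  cell <- cell_model(noise_sd_pA = 0, leak_nS = 0,
                     pipette_exchange_tau_s = Inf)
  tr <- simulate_step(60, 10, cell, cond, law, seed = 1, sample_rate_Hz = 500)
  ih <- tr$current_pA           # noise & leak are zero, so this is I_H
  dt <- diff(tr$time_s[1:2])
  rhs <- sum((utils::head(ih, -1) + utils::tail(ih, -1)) / 2) * dt / 96485.33212331  # pmol
  pH <- tr$pH_i_trajectory
  beta_mid <- hvgate:::buffer_capacity_M_per_pH((utils::head(pH, -1) + utils::tail(pH, -1)) / 2,
                                                cond$buffer_total_mM, cond$buffer_pKa)
  lhs <- cell$volume_pL * sum(beta_mid * diff(pH))  # pmol
  expect_gt(utils::tail(pH, 1), 7)   # outward current alkalinises
  expect_equal(lhs, rhs, tolerance = 0.01)

  # full re-integration of the coupled system by an independent integrator
  # at a 10x finer step
  fine_dt <- dt / 10
  k <- law$steepness_k_mV; vh <- hvgate:::v_half_mV(cond, law)
  ninf_h <- stats::plogis((-80 - vh) / k)
  ninf <- stats::plogis((60 - vh) / k)
  tau <- tau_act_model(60, cond, law)
  p <- 7; tcur <- 0
  gmax <- g_max_nS(cell)
  while (tcur < 10) {
    n_t <- ninf + (ninf_h - ninf) * exp(-tcur / tau)
    vrev <- nernst_slope_mV() * (p - 7)
    IH <- gmax * n_t^2 * (60 - vrev)
    beta <- hvgate:::buffer_capacity_M_per_pH(p, cond$buffer_total_mM, cond$buffer_pKa)
    p <- p + IH / (96485.33212331 * cell$volume_pL * beta) * fine_dt
    tcur <- tcur + fine_dt
  }
  # compare final pH_i at the end of the test segment
  pH_end_test <- pH[max(which(tr$command_mV == 60))]
  expect_equal(pH_end_test - 7, p - 7, tolerance = 0.01)
})

test_that("integration aborts with a named segment when pH_i leaves (0, 14)", {
  cond <- solution_conditions(7, 7, buffer_total_mM = 0.001)
  cell <- cell_model(noise_sd_pA = 0, volume_pL = 0.001,
                     pipette_exchange_tau_s = Inf)
  expect_error(simulate_step(80, 10, cell, cond, law, seed = 1),
               "pH_i left \\(0, 14\\) during (test|tail) segment")
})

test_that("pulse-length ladders scale with the activation time constant", {
  cond <- solution_conditions(6.5, 6.5)
  # constant-tau law: all durations equal
  flat <- gating_law(efold_act_mV = 1e9, tau_ref_s = 0.1)
  p1 <- make_protocol_ladder(c(-40, 20), flat, cond, min_s = 0, max_s = 100)
  expect_equal(p1$steps$duration_s, rep(p1$steps$duration_s[1], nrow(p1$steps)),
               tolerance = 1e-6)
  # e-fold of 10 mV: durations fall e-fold per 10 mV above threshold
  p2 <- make_protocol_ladder(c(-30, 30), law, cond, min_s = 0, max_s = 1e4)
  d <- p2$steps$duration_s
  expect_equal(d[1] / d[2], exp(1), tolerance = 1e-9)
  # near threshold at least e^2 longer than 20 mV above
  vt <- v_thres_mV(cond, law)
  p3 <- make_protocol_ladder(c(round(vt), round(vt) + 20), law, cond,
                             by_mV = 20, min_s = 0, max_s = 1e4)
  expect_gte(p3$steps$duration_s[1] / p3$steps$duration_s[2], exp(2) * 0.9)
  expect_error(make_protocol_ladder(numeric(0), law, cond), "empty")
})

test_that("zinc shifts simulated families rightward and shrinks currents at matched voltages", {
  cell <- quiet_cell()
  fams <- lapply(c(0, 10, 100), function(zn) {
    cond <- solution_conditions(7, 7, zinc_uM = zn)
    proto <- step_protocol(holding_mV = -40, steps = seq(-20, 80, 10),
                           duration_s = 3, sample_rate_Hz = 200)
    simulate_family(proto, cell, cond, law, seed = 3)
  })
  at60 <- vapply(fams, function(f) {
    tr <- f$traces[[which(vapply(f$traces, `[[`, numeric(1), "test_mV") == 60)]]
    mean(utils::tail(tr$current_pA[tr$command_mV == 60], 5))
  }, numeric(1))
  expect_true(all(diff(at60) < 0))  # currents shrink with zinc
})
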