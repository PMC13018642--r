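test_that("control law maps confidence to stages with inclusive bounds", {
  g <- control_gains()
  expect_identical(control_law(0.3, g), 0L)
  expect_identical(control_law(0.5, g), 1L)
  expect_identical(control_law(0.75, g), 2L)
  expect_identical(control_law(1.0, g), 2L)
  expect_identical(control_law(c(0, 0.4999, 0.7499), g), c(0L, 0L, 1L))
  expect_error(control_law(1.2, g), "\\[0, 1\\]")
  expect_error(control_law(-0.1, g), "\\[0, 1\\]")
  expect_error(control_gains(theta1 = 0.8, theta2 = 0.5), "theta")
})

test_that("stage modulation scales baselines linearly", {
  g <- control_gains(alpha_g = 0.5, beta_g = 0.5, gamma_g = 0.5,
                     omega_base = 0.7, delta_base = 0.0078, R_base = 60)
  m0 <- modulate_parameters(0, g)
  expect_equal(m0, list(omega_0 = 0.7, delta = 0.0078, R_IN = 60))
  m2 <- modulate_parameters(2, g)
  expect_equal(m2$omega_0, 2 * 0.7)  # 1 + 0.5 * 2
  # non-decreasing in u
  om <- vapply(0:2, function(u) modulate_parameters(u, g)$omega_0,
               numeric(1))
  expect_true(all(diff(om) >= 0))
  expect_error(modulate_parameters(3, g), "u must be")
})

test_that("safety override reduces stages and never raises", {
  g <- control_gains()
  pol <- safety_policy(w_safe = 0.05)
  st <- control_state(pol)
  # nothing binding: proposal passes through
  expect_identical(safety_override(2L, 0, pol, st, 0, g)$u, 2L)
  # at or above the cap: forced to 0 regardless of confidence
  expect_identical(safety_override(2L, 0.05, pol, st, 0, g)$u, 0L)
  expect_identical(safety_override(2L, 0.2, pol, st, 0, g)$u, 0L)
  # within the guard band: stepped down one stage
  expect_identical(safety_override(2L, 0.9 * 0.05, pol, st, 0, g)$u, 1L)
  # interval limit
  st2 <- control_state(pol)
  st2$last_dose_time <- 0
  expect_identical(safety_override(1L, 0, pol, st2, 5, g)$u, 0L)
  # cumulative limit engages the emergency latch
  pol3 <- safety_policy(w_safe = 0.05, max_cumulative_dose = 0.5)
  st3 <- control_state(pol3)
  st3$cumulative_dose <- 0.5
  ov <- safety_override(2L, 0, pol3, st3, 0, g)
  expect_identical(ov$u, 0L)
  expect_true(ov$state$emergency_stop)
  expect_true("emergency_latch_set" %in% ov$state$safety_events$label)
  # failsafe contract: arbitrary adversarial inputs never error
  set.seed(3)
  for (i in 1:50) {
    st4 <- control_state(pol)
    st4$cumulative_dose <- runif(1, 0, 200)
    st4$last_dose_time <- runif(1, -100, 100)
    expect_error(safety_override(sample(0:2, 1), runif(1, 0, 1), pol, st4,
                                 runif(1, 0, 1440), g), NA)
  }
})

test_that("closed loop: silent classifier gives a drug-free run", {
  tr <- generate_trace("correct", base_level = 0)
  run <- run_closed_loop(tr, horizon = 240)
  expect_equal(nrow(run$control$dose_ledger), 0)
  expect_true(all(run$trajectory$states[, "w5"] == 0))
  expect_equal(run$control$cumulative_dose, 0)
})

test_that("closed loop: concentration is clipped at a small w_safe", {
  tr <- generate_trace("correct", base_level = 1)
  pol <- safety_policy(w_safe = 0.01)
  run <- run_closed_loop(tr, policy = pol, horizon = 720)
  expect_lte(max(run$trajectory$states[, "w5"]), pol$w_safe + 1e-10)
  expect_true("w_safe_clip" %in% run$trajectory$events$label)
})

test_that("higher confidence delivers more drug when no safeguard binds", {
  pol <- safety_policy(w_safe = 10)  # far from binding
  r1 <- run_closed_loop(generate_trace("correct", 0.6, horizon = 120),
                        policy = pol, horizon = 120)
  r2 <- run_closed_loop(generate_trace("correct", 0.9, horizon = 120),
                        policy = pol, horizon = 120)
  expect_gt(r2$control$cumulative_dose, r1$control$cumulative_dose)
  expect_equal(nrow(r1$control$dose_ledger), 8)  # every 15 min over 2 h
})

test_that("false negatives delay therapy without any safety violation", {
  pol <- safety_policy()
  tr_fn <- generate_trace("false_negative", base_level = 0.9,
                          horizon = 480)
  run <- run_closed_loop(tr_fn, policy = pol, horizon = 480)
  expect_equal(nrow(run$control$dose_ledger), 0)  # therapy withheld
  expect_lte(max(run$trajectory$states[, "w5"]), pol$w_safe + 1e-10)
})

test_that("feedback never overshoots more than the open loop", {
  tr <- generate_trace("false_positive", base_level = 0.9, horizon = 480)
  pol <- safety_policy()
  closed <- run_closed_loop(tr, policy = pol, horizon = 480)
  open <- run_closed_loop(tr, policy = pol, horizon = 480,
                          enforce_safety = FALSE)
  over_closed <- max(closed$trajectory$states[, "w5"]) - pol$w_safe
  over_open <- max(open$trajectory$states[, "w5"]) - pol$w_safe
  expect_lte(over_closed, max(over_open, 0) + 1e-10)
  expect_gt(over_open, 0)  # the unconstrained run does overshoot
})

test_that("pointwise-larger traces never deliver less (no safeguards binding)", {
  pol <- safety_policy(w_safe = 10)
  set.seed(5)
  for (i in 1:5) {
    pc <- runif(9, 0, 0.9)
    tr_lo <- generate_trace("custom", values = pc, horizon = 120, dt = 15)
    tr_hi <- generate_trace("custom", values = pmin(pc + 0.1, 1),
                            horizon = 120, dt = 15)
    lo <- run_closed_loop(tr_lo, policy = pol, horizon = 120)
    hi <- run_closed_loop(tr_hi, policy = pol, horizon = 120)
    expect_gte(hi$control$cumulative_dose, lo$control$cumulative_dose)
  }
})

test_that("ledger bookkeeping: cumulative dose equals the ledger sum", {
  tr <- generate_trace("correct", 0.8, horizon = 240)
  run <- run_closed_loop(tr, policy = safety_policy(w_safe = 10),
                         horizon = 240)
  expect_equal(run$control$cumulative_dose,
               sum(run$control$dose_ledger$dose))
  expect_true(all(diff(run$control$dose_ledger$time) >= 15))
})
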