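test_that("reverse RHS: decoupled source and conservation limits", {
  # sensor compartment sealed: nothing ever reaches plasma
  p <- reverse_parameters(k21_r = 0)
  traj <- simulate_reverse(p, horizon = 300, opts = fast_opts(),
                           noiseless = TRUE)
  expect_true(all(traj$states[, "v1"] == 0))
  expect_true(all(receiver_output(traj$states[, "v1"], p) == 0))
  # no losses: v1 + v2 conserved
  p2 <- reverse_parameters(k12_r = 0, k1 = 0, k10 = 0)
  tr2 <- simulate_reverse(p2, horizon = 300, opts = fast_opts(),
                          noiseless = TRUE)
  tot <- tr2$states[, "v1"] + tr2$states[, "v2"]
  expect_lt(max(abs(tot - p2$s0)) / p2$s0, 1e-8)
  expect_error(reverse_rhs(0, c(-1, 0, 0, 0), p2), "non-negative")
})

test_that("reverse trace matches the fine-Euler oracle", {
  # the sensor compartment drains at 0.373/min, so first-order Euler needs
  # a very fine step before its own error clears the 1e-6 bar
  p <- reverse_parameters(s0 = 8)
  traj <- simulate_reverse(p, horizon = 120, noiseless = TRUE)
  eu <- simulate_reverse_euler(p, horizon = 120, dt = 1e-5, thin = 1e5)
  keep <- traj$times > 0
  scale <- max(eu$trajectory$states[, "v1"])
  err <- abs(traj$states[keep, "v1"] -
               eu$trajectory$states[keep, "v1"]) / scale
  expect_lt(max(err), 1e-6)
})

test_that("receiver output is the linear capture of plasma signal", {
  p <- reverse_parameters()
  expect_equal(receiver_output(0, p), 0)
  expect_equal(receiver_output(10, p), 0.1e-2 * 10)
  expect_equal(receiver_output(10, p), 0.01)
  p2 <- reverse_parameters(k1 = 2 * p$k1)
  expect_equal(receiver_output(c(1, 5, 10), p2),
               2 * receiver_output(c(1, 5, 10), p))
  expect_error(receiver_output(-1, p), ">= 0")
})

test_that("bioluminescence intensity: kernel, linearity, seeded noise", {
  p <- reverse_parameters()
  expect_equal(bioluminescence_intensity(0, p, noiseless = TRUE), 0)
  I1 <- bioluminescence_intensity(c(1, 2, 4), p, noiseless = TRUE)
  expect_equal(I1[2] / I1[1], 2)
  expect_equal(I1[3] / I1[1], 4)
  expect_equal(I1[1], 0.044 * 40 / (15 + 40))
  set.seed(11); a <- bioluminescence_intensity(rep(1, 50), p)
  set.seed(11); b <- bioluminescence_intensity(rep(1, 50), p)
  expect_identical(a, b)
  expect_gt(sd(a), 0)
  # injectable light kernel
  Ilin <- bioluminescence_intensity(2, p, noiseless = TRUE,
                                    light_fn = function(LU, p) LU)
  expect_equal(Ilin, 2)
})

test_that("threshold decision is boundary-inclusive", {
  expect_identical(threshold_decision(0.7, 0.7), 1L)
  expect_identical(threshold_decision(0, 0.7), 0L)
  expect_identical(threshold_decision(c(0.69, 0.7, 0.71), 0.7),
                   c(0L, 1L, 1L))
  expect_error(threshold_decision(NaN, 0.7), "finite")
  expect_error(threshold_decision(1, 0), "I0")
})

test_that("unit audit: hour-to-minute conversion round-trips exactly", {
  x <- c(10, 150, 10.05, 4.15)
  expect_identical(per_min_to_per_hour(per_hour_to_per_min(x)), x)
  p <- reverse_parameters()
  expect_equal(p$kr, 10 / 60)
  expect_equal(p$kp, 150 / 60)
  expect_equal(p$gamma_r, 10.05 / 60)
  expect_equal(p$gamma_p, 4.15 / 60)
})

test_that("sweep families: ordering of peak intensity", {
  sw <- reverse_sweep("s0", c(2, 8, 32), horizon = 720, opts = fast_opts())
  expect_true(all(diff(sw$peak_I) > 0))
  sw2 <- reverse_sweep("k21_r", c(0.1, 0.373, 0.8), horizon = 720,
                       opts = fast_opts())
  expect_true(all(diff(sw2$peak_I) > 0))
  sw3 <- reverse_sweep("k1", c(0.5e-3, 1e-3, 2e-3), horizon = 720,
                       opts = fast_opts())
  expect_true(all(diff(sw3$peak_I) > 0))
  # a one-value sweep reproduces the plain simulation
  one <- reverse_sweep("s0", 8, horizon = 300, opts = fast_opts())
  ref <- simulate_reverse(reverse_parameters(s0 = 8), horizon = 300,
                          opts = fast_opts(), noiseless = TRUE)
  expect_equal(unname(one$intensity[, 1]), unname(ref$states[, "I"]))
  expect_error(reverse_sweep("nope", 1), "unknown reverse parameter")
})

test_that("minimal detectable s0 is non-increasing in the influx rate", {
  # sweep s0 at two influx rates against a reachable threshold
  min_s0 <- function(k21_r, I0 = 0.005) {
    for (s0 in c(1, 2, 4, 8, 16, 32)) {
      p <- reverse_parameters(s0 = s0, k21_r = k21_r, I0 = I0)
      traj <- simulate_reverse(p, horizon = 720, opts = fast_opts(),
                               noiseless = TRUE)
      if (any(traj$states[, "c_r"] == 1)) return(s0)
    }
    Inf
  }
  m <- vapply(c(0.05, 0.373, 1.0), min_s0, numeric(1))
  expect_true(all(diff(m) <= 0))
  expect_true(is.finite(m[2]))
})

test_that("noiseless intensity is continuous, non-negative and decisions are deterministic", {
  p <- reverse_parameters(I0 = 0.005)
  a <- simulate_reverse(p, horizon = 400, noiseless = TRUE)
  b <- simulate_reverse(p, horizon = 400, noiseless = TRUE)
  expect_identical(a$states, b$states)
  expect_true(all(a$states[, "I"] >= 0))
  # no jumps on the 1-min grid beyond the fastest reporter transient
  expect_lt(max(abs(diff(a$states[, "I"]))),
            0.05 * max(a$states[, "I"]) + 1e-12)
})
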