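test_that("sampling: reproducibility, bounds, range coverage", {
  d <- parameter_distribution(n_samples = 10000, seed = 4)
  a <- sample_parameters(d)
  b <- sample_parameters(d)
  expect_identical(a, b)
  r <- d$ranges
  for (j in seq_len(nrow(r))) {
    x <- a[, r$name[j]]
    expect_gte(min(x), r$low[j])
    expect_lte(max(x), r$high[j])
    if (r$low[j] < r$high[j]) {
      span <- (max(x) - min(x)) / (r$high[j] - r$low[j])
      expect_gte(span, 0.99)
    }
  }
})

test_that("zero-width ranges pin every draw at the default", {
  rng <- data.frame(name = c("k10", "ps"), low = c(2.1e-3, 4.9e-3),
                    default = c(2.1e-3, 4.9e-3), high = c(2.1e-3, 4.9e-3))
  d <- parameter_distribution(rng, n_samples = 20, seed = 1)
  s <- sample_parameters(d)
  expect_true(all(s[, "k10"] == 2.1e-3))
  expect_true(all(s[, "ps"] == 4.9e-3))
  # and the propagated interval has zero width
  mc <- monte_carlo(d, model_runner = function(dr) c(out = dr[["k10"]] +
                                                       dr[["ps"]]))
  expect_equal(mc$summary$p5, mc$summary$p95)
  expect_error(parameter_distribution(
    data.frame(name = "k10", low = 3e-3, default = 2.1e-3, high = 4e-3)),
    "bracket")
})

test_that("monte carlo over SA ranges: ordered intervals, zero failures", {
  d <- parameter_distribution(n_samples = 40, seed = 12)
  mc <- monte_carlo(d, opts = fast_opts())
  expect_equal(mc$failure_rate, 0)
  expect_true(all(mc$summary$p5 <= mc$summary$median))
  expect_true(all(mc$summary$median <= mc$summary$p95))
  expect_lt(mc$summary$p5[mc$summary$output == "peak_w5"],
            mc$summary$p95[mc$summary$output == "peak_w5"])
  # the prediction interval contains the default-parameter output
  ref <- peak_intracellular(simulate_forward(pk_parameters(), 0.7,
                                             opts = fast_opts()))$w5_peak
  row <- mc$summary[mc$summary$output == "peak_w5", ]
  expect_gte(ref, row$p5)
  expect_lte(ref, row$p95)
  # failed runs are counted and excluded, not fatal
  flaky <- function(dr) if (dr[["k10"]] > 2.1e-3) stop("boom") else
    c(out = dr[["k10"]])
  mc2 <- monte_carlo(parameter_distribution(n_samples = 30, seed = 2),
                     model_runner = flaky)
  expect_gt(mc2$n_failed, 0)
  expect_equal(nrow(mc2$outputs) + mc2$n_failed, 30)
})

test_that("widening a range never narrows the prediction interval", {
  mk <- function(lo, hi) parameter_distribution(
    data.frame(name = "ps", low = lo, default = 4.9e-3, high = hi),
    n_samples = 40, seed = 6)
  runner <- function(dr) {
    p <- pk_parameters(ps = dr[["ps"]])
    c(peak_w5 = peak_intracellular(
      simulate_forward(p, 0.7, horizon = 720, opts = fast_opts()))$w5_peak)
  }
  narrow <- monte_carlo(mk(4.4e-3, 5.4e-3), runner)
  wide <- monte_carlo(mk(3.9e-3, 5.9e-3), runner)
  w_n <- narrow$summary$p95 - narrow$summary$p5
  w_w <- wide$summary$p95 - wide$summary$p5
  expect_gte(w_w, w_n)
})

test_that("sensitivity sweeps: baseline reproduction and directions", {
  base <- sensitivity_sweep("ps", 4.9e-3, opts = fast_opts())
  ref <- simulate_forward(pk_parameters(),
                          injected_dose(release_spec())$g_f,
                          opts = fast_opts())
  expect_equal(base$results$peak_w5, peak_intracellular(ref)$w5_peak)
  sw_ps <- sensitivity_sweep("ps", c(3.9e-3, 4.9e-3, 5.9e-3),
                             opts = fast_opts())
  expect_true(all(diff(sw_ps$results$peak_w5) > 0))
  expect_true(sw_ps$monotone_increasing_w5)
  sw_k10 <- sensitivity_sweep("k10", c(1.5e-3, 2.1e-3, 3.0e-3),
                              opts = fast_opts())
  expect_true(all(diff(sw_k10$results$peak_w1) < 0))
  expect_true(sw_k10$monotone_decreasing_w1)
  # release-side sweep reaches the bolus through the dose functional
  sw_om <- sensitivity_sweep("omega0", c(0.5, 0.7, 0.9), opts = fast_opts())
  expect_true(all(diff(sw_om$results$peak_w5) > 0))
  expect_error(sensitivity_sweep("nope", 1), "unknown sweep parameter")
})

test_that("robustness experiment: zero noise reproduces the reference", {
  rb <- robustness_experiment(noise_rel = 0, n_reps = 2, seed = 1,
                              horizon = 480)
  expect_equal(rb$max_rel_dev, 0)
  expect_gt(rb$peak_ref, 0)
})

test_that("peak deviation grows with confidence noise when doses are scarce", {
  # a tight cumulative budget makes the peak sensitive to which stages the
  # noisy trace hits, so the noise level becomes visible in the deviation
  pol <- safety_policy(w_safe = 10, max_cumulative_dose = 1.4)
  dev_at <- function(nr) robustness_experiment(
    noise_rel = nr, n_reps = 15, seed = 2, policy = pol,
    horizon = 720)$max_rel_dev
  devs <- vapply(c(0.05, 0.10, 0.20), dev_at, numeric(1))
  expect_true(all(diff(devs) >= 0))
  expect_gt(devs[3], 0)
})
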