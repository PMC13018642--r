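test_that("forward RHS fixed points and pairwise conservation", {
  p0 <- zero_pk()
  expect_equal(unname(forward_rhs(0, c(1, 2, 3, 4, 5, 6), p0)), rep(0, 6))
  # isolated systemic pair conserves w1 + w3
  p <- pk_parameters(k10 = 0, ps = 0, Fpv_t = 0, k1wi = 0, k2wi = 0,
                     k3wi = 0, k5wi = 0)
  d <- forward_rhs(0, c(0.5, 0.2, 0, 0, 0, 0), p)
  expect_equal(unname(d["w1"] + d["w3"]), 0)
  # empty EES and cell compartments are a fixed point of the uptake chain
  d2 <- forward_rhs(0, c(0, 0, 0, 0, 0, 0), pk_parameters())
  expect_equal(unname(d2["w5"]), 0)
  expect_error(forward_rhs(0, c(-1, 0, 0, 0, 0, 0), pk_parameters()),
               "non-negative")
  expect_error(pk_parameters(k12 = NaN), "finite")
  expect_error(pk_parameters(k10 = -1), ">= 0")
  expect_error(pk_parameters(vp_t = 1.5), "volume fractions")
})

test_that("two-compartment closed form: degenerate limits", {
  # pure elimination
  p <- pk_parameters(k12 = 0, k21 = 0, k10 = 2.1e-3)
  tt <- c(0, 10, 100, 700)
  cf <- two_compartment_closed_form(p, 0.7, tt)
  expect_equal(cf[, "w1"], 0.7 * exp(-2.1e-3 * tt), tolerance = 1e-12)
  # lossless exchange conserves total mass
  p2 <- pk_parameters(k10 = 0)
  cf2 <- two_compartment_closed_form(p2, 0.7, seq(0, 2000, by = 100))
  expect_equal(rowSums(cf2), rep(0.7, 21), tolerance = 1e-10)
  # repeated-eigenvalue limiting form stays finite and correct at t = 0
  p3 <- pk_parameters(k12 = 0, k21 = 0, k10 = 0)
  cf3 <- two_compartment_closed_form(p3, 1, c(0, 5))
  expect_equal(cf3[, "w1"], c(1, 1))
})

test_that("adaptive integrator matches the bi-exponential oracle", {
  p <- pk_parameters(ps = 0, Fpv_t = 0)
  traj <- simulate_forward(p, g_f = 0.7, horizon = 600,
                           opts = solver_options(grid_dt = 6))
  cf <- two_compartment_closed_form(p, 0.7, traj$times)
  keep <- traj$times > 0  # w3(0) = 0 exactly; avoid 0/0
  expect_lt(max(rel_err(traj$states[keep, c("w1", "w3")], cf[keep, ])),
            1e-6)
  # the 60-min spot check of the analytic solution
  t60 <- simulate_forward(p, g_f = 0.7, horizon = 60,
                          opts = solver_options(grid_dt = 60))
  expect_equal(unname(t60$states[2, c("w1", "w3")]),
               unname(two_compartment_closed_form(p, 0.7, 60)[1, ]),
               tolerance = 1e-6)
})

test_that("full-system trajectory: shape, oracle peak, non-negativity", {
  p <- pk_parameters()
  traj <- simulate_forward(p, g_f = 0.7)
  expect_true(all(traj$states >= 0))
  pk <- peak_intracellular(traj)
  # single interior maximum of w5: rises then decays
  w5 <- traj$states[, "w5"]
  i <- which.max(w5)
  expect_gt(i, 1)
  expect_lt(i, length(w5))
  s <- sign(diff(w5))
  expect_equal(sum(diff(s[s != 0]) != 0), 1)  # one sign change: unimodal
  # fine-step explicit-Euler oracle agrees on the peak to 0.1%
  eu <- simulate_forward_euler(p, 0.7, horizon = 1440, dt = 1e-3)
  expect_lt(abs(pk$w5_peak - eu$w5_peak) / eu$w5_peak, 1e-3)
  expect_lt(abs(pk$t_peak - eu$t_peak), 5)
  # zero dose gives the zero trajectory
  z <- simulate_forward(p, g_f = 0, horizon = 100, opts = fast_opts())
  expect_true(all(z$states == 0))
})

test_that("volume-weighted mass is conserved in the loss-free tumor chain", {
  # no elimination, no asymmetric plasma inflow, unit binding
  p <- pk_parameters(k10 = 0, Fpv_t = 0, U_Dox = 1, U_Dox_e = 1)
  y0 <- c(0.3, 0.1, 0.4, 0.05, 0.01, 0)
  traj <- simulate_forward(p, g_f = NA, horizon = 2000, y0 = y0,
                           opts = fast_opts())
  sys_mass <- traj$states[, "w1"] + traj$states[, "w3"]
  tum_mass <- p$vp_t * traj$states[, "w2"] +
    p$ve_t * (traj$states[, "w4"] + traj$states[, "w5"])
  expect_lt(max(abs(sys_mass - sys_mass[1])) / sys_mass[1], 1e-6)
  expect_lt(max(abs(tum_mass - tum_mass[1])) / tum_mass[1], 1e-6)
})

test_that("peak extraction: ties, boundaries, validation", {
  tr <- trajectory(0:5, cbind(w5 = c(0, 1, 3, 3, 2, 0)))
  pk <- peak_intracellular(tr)
  expect_equal(pk$t_peak, 2)  # earliest of the tied maxima
  expect_equal(pk$w5_peak, 3)
  tr0 <- trajectory(0:3, cbind(w5 = rep(0, 4)))
  expect_equal(peak_intracellular(tr0)$t_peak, 0)
  trm <- trajectory(0:3, cbind(w5 = 0:3))
  expect_equal(peak_intracellular(trm)$t_peak, 3)  # monotone: final time
  expect_error(peak_compartment(tr, "nope"), "no such component")
  expect_error(trajectory(c(0, 0, 1), matrix(0, 3, 1)),
               "strictly increasing")
})

test_that("peak w5 responds monotonically to dose and permeability", {
  peaks_gf <- vapply(c(0.5, 0.7, 0.9), function(g)
    peak_intracellular(simulate_forward(pk_parameters(), g,
                                        opts = fast_opts()))$w5_peak,
    numeric(1))
  expect_true(all(diff(peaks_gf) > 0))
  peaks_ps <- vapply(c(3.9e-3, 4.9e-3, 5.9e-3), function(v)
    peak_intracellular(simulate_forward(pk_parameters(ps = v), 0.7,
                                        opts = fast_opts()))$w5_peak,
    numeric(1))
  expect_true(all(diff(peaks_ps) > 0))
})

test_that("higher elimination lowers the post-bolus plasma curve", {
  traj_lo <- simulate_forward(pk_parameters(k10 = 1.5e-3), 0.7,
                              opts = fast_opts())
  traj_hi <- simulate_forward(pk_parameters(k10 = 3.0e-3), 0.7,
                              opts = fast_opts())
  expect_lt(max(traj_hi$states[-1, "w1"]), max(traj_lo$states[-1, "w1"]))
  # time above a fixed plasma threshold shrinks as well
  thr <- 0.1
  expect_lt(sum(traj_hi$states[, "w1"] > thr),
            sum(traj_lo$states[, "w1"] > thr))
})

test_that("no state dips below tolerance across SA-range draws", {
  dist <- parameter_distribution(n_samples = 12, seed = 99)
  draws <- sample_parameters(dist)
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    base <- pk_parameters()
    nm <- intersect(names(d), names(base))
    base[nm] <- as.list(d[nm])
    p <- do.call(pk_parameters, base[setdiff(names(base), "eq15_literal")])
    traj <- simulate_forward(p, g_f = d[["omega0"]], horizon = 720,
                             opts = fast_opts())
    expect_true(all(traj$states >= 0))
  }
})

test_that("literal uptake rendering is exposed and differs", {
  p_lit <- pk_parameters(eq15_literal = TRUE)
  d_std <- forward_rhs(0, c(0, 0, 0, 0.1, 0, 0), pk_parameters())
  d_lit <- forward_rhs(0, c(0, 0, 0, 0.1, 0, 0), p_lit)
  expect_false(isTRUE(all.equal(d_std[["w5"]], d_lit[["w5"]])))
})
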