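#' Forward-path right-hand side
#'
#' Derivatives of the six-state forward system at one instant. The state
#' ordering is `(w1, w3, w2, w4, w5, w_el)`: systemic plasma, peripheral
#' exchange, tumor plasma, tumor EES, tumor intracellular, cumulative
#' eliminated mass. The systemic pair exchanges via `k12`/`k21` and loses
#' mass at `k10`; the tumor chain is driven by systemic plasma through the
#' flow coupling `Fpv_t` and the transvascular term `ps` with the explicit
#' `1/vp_t` and `1/ve_t` volume factors; cellular uptake is linear plus
#' Michaelis-Menten with efflux `k5wi`, scaled by `k3wi`.
#'
#' This pure-R form mirrors the compiled integrator's right-hand side and is
#' used by the test oracles; [simulate_forward()] is the production path.
#'
#' @param t time (min); the system is autonomous, accepted for interface
#'   symmetry.
#' @param state numeric length-6 vector `(w1, w3, w2, w4, w5, w_el)`.
#' @param p a [pk_parameters()] object.
#' @return named numeric vector of derivatives.
#' @export
forward_rhs <- function(t, state, p) {
  stopifnot(inherits(p, "pk_parameters"))
  if (length(state) != 6 || any(!is.finite(state)))
    stop("state must be 6 finite values")
  if (any(state < 0)) stop("state must be non-negative")
  w1 <- state[1]; w3 <- state[2]; w2 <- state[3]
  w4 <- state[4]; w5 <- state[5]
  uptake <- function(x) {
    if (p$eq15_literal)
      p$k3wi * ((p$k1wi * x + p$k2wi * x) / (p$kiwi + x) - p$k5wi * w5)
    else
      p$k3wi * (p$k1wi * x + p$k2wi * x / (p$kiwi + x) - p$k5wi * w5)
  }
  c(w1 = -w1 * (p$k12 + p$k10) + p$k21 * w3,
    w3 = p$k12 * w1 - p$k21 * w3,
    w2 = -(p$ps / p$vp_t) * w2 * p$U_Dox + (p$ps / p$vp_t) * w4 * p$U_Dox_e -
      p$Fpv_t * w2 + p$Fpv_t * w1,
    w4 = (p$ps / p$ve_t) * w2 * p$U_Dox - (p$ps / p$ve_t) * w4 * p$U_Dox_e -
      uptake(w4 * p$U_Dox_e),
    w5 = uptake(w4),
    w_el = p$k10 * w1)
}

.forward_colnames <- c("w1", "w3", "w2", "w4", "w5", "w_el")

#' Solver options
#'
#' Tolerances and reporting grid of the adaptive integrator. The integrator
#' is a Dormand-Prince 5(4) pair whose steps never cross a reporting grid
#' point, so reported states carry no interpolation error. States entering
#' `[-10*atol, 0)` after a step are clipped to zero; larger negativity
#' aborts with diagnostics.
#'
#' @param rtol relative tolerance (default 1e-8).
#' @param atol absolute tolerance (default 1e-10).
#' @param grid_dt reporting grid spacing in minutes (default 1).
#' @return named list.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, grid_dt = 1) {
  stopifnot(rtol > 0, atol > 0, grid_dt > 0)
  list(rtol = rtol, atol = atol, grid_dt = grid_dt)
}

# shared grid builder: 0, dt, 2dt, ..., horizon (horizon always included)
.report_grid <- function(horizon, dt, t0 = 0) {
  g <- seq(t0, horizon, by = dt)
  if (g[length(g)] < horizon) g <- c(g, horizon)
  g
}

#' Simulate the forward path
#'
#' Integrates the six-state forward system from `w1(0) = g_f` (all other
#' compartments zero) to `horizon` minutes, reporting on a uniform grid.
#'
#' @param p a [pk_parameters()].
#' @param g_f initial systemic plasma bolus (mg/mL), e.g. `injected_dose()$g_f`.
#' @param horizon simulation horizon (min), default 24 h.
#' @param opts a [solver_options()] list.
#' @param y0 optional full initial state (length 6) overriding the bolus
#'   convention; used by the closed-loop runner for piecewise integration.
#' @param w_safe optional hard cap applied to `w5` after every accepted
#'   step (safety projection); `Inf` disables it.
#' @return a [trajectory()] with columns `w1, w3, w2, w4, w5, w_el`.
#' @export
simulate_forward <- function(p, g_f, horizon = 1440,
                             opts = solver_options(), y0 = NULL,
                             w_safe = Inf) {
  stopifnot(inherits(p, "pk_parameters"), horizon > 0)
  if (is.null(y0)) {
    if (!is.finite(g_f) || g_f < 0) stop("g_f must be finite and >= 0")
    y0 <- c(g_f, 0, 0, 0, 0, 0)
  }
  grid <- .report_grid(horizon, opts$grid_dt)
  res <- .sim_ode_cpp(1L, as.numeric(y0), .forward_par_vec(p), grid,
                      opts$rtol, opts$atol, wsafe = w_safe, wsafe_idx = 4L,
                      max_steps = 2e7)
  states <- res$states
  colnames(states) <- .forward_colnames
  ev <- if (res$n_clip > 0)
    data.frame(time = res$first_clip_time, label = "w_safe_clip",
               stringsAsFactors = FALSE)
  else data.frame(time = numeric(), label = character(),
                  stringsAsFactors = FALSE)
  trajectory(grid, states, ev)
}

#' Fine-step explicit-Euler oracle for the forward system
#'
#' Fixed-step Euler integration used as an independent check on the
#' adaptive solver. Tracks the running maximum of `w5` at full step
#' resolution and thins the recorded states.
#'
#' @inheritParams simulate_forward
#' @param dt Euler step (min), default 1e-3.
#' @param thin record every `thin`-th step (default: every minute).
#' @return list: `trajectory` (thinned), `t_peak`, `w5_peak`.
#' @export
simulate_forward_euler <- function(p, g_f, horizon = 1440, dt = 1e-3,
                                   thin = round(1 / dt)) {
  stopifnot(inherits(p, "pk_parameters"), horizon > 0, dt > 0)
  n <- round(horizon / dt)
  res <- .sim_euler_cpp(1L, c(g_f, 0, 0, 0, 0, 0), .forward_par_vec(p),
                        0, dt, n, as.integer(thin), track_idx = 4L)
  states <- res$states
  colnames(states) <- .forward_colnames
  list(trajectory = trajectory(res$times, states),
       t_peak = res$t_peak, w5_peak = res$peak)
}

#' Closed-form solution of the systemic two-compartment pair
#'
#' With the tumor couplings disabled (`ps = 0`, `Fpv_t = 0`) the systemic
#' pair `(w1, w3)` is a 2x2 linear system solved exactly by
#' eigen-decomposition:
#' `d/dt w1 = -(k12 + k10) w1 + k21 w3`, `d/dt w3 = k12 w1 - k21 w3`.
#' The bi-exponential solution serves as the analytic oracle for the
#' numerical integrator; the repeated-eigenvalue degenerate case is handled
#' by its limiting (Jordan) form.
#'
#' @param p a [pk_parameters()] (only `k12`, `k21`, `k10` are used).
#' @param g_f initial plasma concentration.
#' @param t vector of times (min).
#' @return matrix with columns `w1`, `w3`.
#' @export
two_compartment_closed_form <- function(p, g_f, t) {
  stopifnot(inherits(p, "pk_parameters"))
  a <- -(p$k12 + p$k10); b <- p$k21
  cc <- p$k12; d <- -p$k21
  tr <- a + d; det <- a * d - b * cc
  disc <- tr^2 - 4 * det
  y0 <- c(g_f, 0)
  if (disc > .Machine$double.eps * max(1, tr^2)) {
    s <- sqrt(disc)
    l1 <- (tr + s) / 2; l2 <- (tr - s) / 2
    # eigenvectors: (b, l - a) when b != 0, (l - d, cc) when cc != 0,
    # coordinate axes for a diagonal system
    evec <- function(l) {
      if (b != 0) c(b, l - a)
      else if (cc != 0) c(l - d, cc)
      else if (abs(l - a) <= abs(l - d)) c(1, 0)
      else c(0, 1)
    }
    v1 <- evec(l1); v2 <- evec(l2)
    V <- cbind(v1, v2)
    alpha <- solve(V, y0)
    out <- vapply(t, function(tt) {
      as.numeric(V %*% (alpha * exp(c(l1, l2) * tt)))
    }, numeric(2))
  } else {
    # repeated eigenvalue: y(t) = e^{lt} (I + t (A - l I)) y0
    l <- tr / 2
    A <- matrix(c(a, cc, b, d), 2, 2)
    N <- A - diag(l, 2)
    out <- vapply(t, function(tt) {
      as.numeric(exp(l * tt) * ((diag(2) + tt * N) %*% y0))
    }, numeric(2))
  }
  m <- t(out)
  colnames(m) <- c("w1", "w3")
  m
}
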