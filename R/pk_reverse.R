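#' Reverse-path right-hand side
#'
#' Derivatives of the four-state reverse signalling system
#' `(v1, v2, m, LU)`: systemic plasma signal, sensor/tumor compartment,
#' reporter mRNA, luciferase. The sensor compartment releases into systemic
#' plasma at `k21_r`; plasma signal is lost to back-exchange `k12_r`,
#' elimination `k10` and receptor binding `k1`. The receiver output
#' `g_r = k1 * v1` drives the reporter chain
#' `dm = kr * mu * g_r - gamma_r * m`, `dLU = kp * m - gamma_p * LU`.
#' All rates must already be on the minute clock (see
#' [reverse_parameters()], which converts the h^-1 reporter constants).
#'
#' @param t time (min); system is autonomous.
#' @param state numeric length-4 vector `(v1, v2, m, LU)`.
#' @param p a [reverse_parameters()].
#' @return named numeric derivative vector.
#' @export
reverse_rhs <- function(t, state, p) {
  stopifnot(inherits(p, "reverse_parameters"))
  if (length(state) != 4 || any(!is.finite(state)))
    stop("state must be 4 finite values")
  if (any(state < 0)) stop("state must be non-negative")
  v1 <- state[1]; v2 <- state[2]; m <- state[3]; lu <- state[4]
  g_r <- p$k1 * v1
  c(v1 = p$k21_r * v2 - (p$k12_r + p$k10 + p$k1) * v1,
    v2 = p$k12_r * v1 - p$k21_r * v2,
    m = p$kr * p$mu * g_r - p$gamma_r * m,
    LU = p$kp * m - p$gamma_p * lu)
}

#' Receiver output of the reverse path
#'
#' Linear ligand-receptor capture `g_r(t) = k1 * v1(t)`.
#'
#' @param v1 plasma signal concentration, >= 0 (vectorised).
#' @param p a [reverse_parameters()].
#' @return receiver output g_r.
#' @export
receiver_output <- function(v1, p) {
  stopifnot(inherits(p, "reverse_parameters"))
  if (any(v1 < 0)) stop("v1 must be >= 0")
  p$k1 * v1
}

#' Bioluminescence intensity
#'
#' ATP-limited Michaelis-Menten light output of the luciferase level,
#' `I = alpha_l * LU * a_tp / (alpha_M + a_tp)`, plus additive zero-mean
#' Gaussian noise of variance `sigma2` (drawn from the session RNG; set
#' `sigma2 = 0` or `noiseless = TRUE` for the deterministic value). The
#' kinetic form of the light reaction is a documented reconstruction; pass
#' a different `light_fn(LU, p)` to swap it.
#'
#' @param LU luciferase level, >= 0 (vectorised).
#' @param p a [reverse_parameters()].
#' @param noiseless logical; force sigma2 = 0.
#' @param light_fn injectable light-output kernel, default the
#'   Michaelis-Menten form above.
#' @return intensity I (a.u.).
#' @export
bioluminescence_intensity <- function(LU, p, noiseless = FALSE,
                                      light_fn = NULL) {
  stopifnot(inherits(p, "reverse_parameters"))
  if (any(LU < 0)) stop("LU must be >= 0")
  if (is.null(light_fn))
    light_fn <- function(LU, p) p$alpha_l * LU * p$a_tp / (p$alpha_M + p$a_tp)
  I <- light_fn(LU, p)
  if (!noiseless && p$sigma2 > 0)
    I <- I + rnorm(length(I), mean = 0, sd = sqrt(p$sigma2))
  I
}

#' Binary threshold decision
#'
#' `c_r = 1` iff `I >= I0` (boundary inclusive), else 0.
#'
#' @param I intensity values (finite, vectorised).
#' @param I0 decision threshold (> 0).
#' @return integer vector of 0/1 decisions.
#' @export
threshold_decision <- function(I, I0) {
  if (any(!is.finite(I))) stop("I must be finite")
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be > 0")
  as.integer(I >= I0)
}

#' Simulate the reverse path
#'
#' Integrates the reverse system from `v1(0) = 0`, `v2(0) = s0`, reporter
#' levels zero, and appends the intensity column `I` (noisy unless
#' `noiseless`) and the decision column `c_r`.
#'
#' @param p a [reverse_parameters()].
#' @param horizon simulation horizon (min), default 24 h.
#' @param opts a [solver_options()].
#' @param noiseless logical; suppress the intensity noise.
#' @return a [trajectory()] with columns `v1, v2, m, LU, I, c_r`.
#' @export
simulate_reverse <- function(p, horizon = 1440, opts = solver_options(),
                             noiseless = FALSE) {
  stopifnot(inherits(p, "reverse_parameters"), horizon > 0)
  grid <- .report_grid(horizon, opts$grid_dt)
  res <- .sim_ode_cpp(2L, c(0, p$s0, 0, 0), .reverse_par_vec(p), grid,
                      opts$rtol, opts$atol, wsafe = Inf, wsafe_idx = 0L,
                      max_steps = 2e7)
  states <- res$states
  colnames(states) <- c("v1", "v2", "m", "LU")
  I <- bioluminescence_intensity(states[, "LU"], p, noiseless = noiseless)
  states <- cbind(states, I = I, c_r = threshold_decision(I, p$I0))
  trajectory(grid, states)
}

#' Fine-step explicit-Euler oracle for the reverse system
#'
#' @inheritParams simulate_reverse
#' @param dt Euler step (min).
#' @param thin record every `thin`-th step.
#' @return list: `trajectory` (states only, noiseless), `t_peak`, `v1_peak`.
#' @export
simulate_reverse_euler <- function(p, horizon = 1440, dt = 1e-3,
                                   thin = round(1 / dt)) {
  stopifnot(inherits(p, "reverse_parameters"), horizon > 0, dt > 0)
  n <- round(horizon / dt)
  res <- .sim_euler_cpp(2L, c(0, p$s0, 0, 0), .reverse_par_vec(p),
                        0, dt, n, as.integer(thin), track_idx = 0L)
  states <- res$states
  colnames(states) <- c("v1", "v2", "m", "LU")
  list(trajectory = trajectory(res$times, states),
       t_peak = res$t_peak, v1_peak = res$peak)
}

#' One-at-a-time reverse-path sweep
#'
#' Re-simulates the reverse path (noiseless) for each value of one
#' parameter, returning the family of intensity curves and their peaks.
#' Peak intensity is expected to be non-decreasing in `s0`, `k21_r` and
#' `k1`.
#'
#' @param param_name a field of [reverse_parameters()] (reporter-chain rates
#'   are addressed on the minute clock, e.g. `"kr"`).
#' @param values numeric vector of parameter values.
#' @param p baseline [reverse_parameters()].
#' @param horizon,opts passed to [simulate_reverse()].
#' @return list: `param`, `values`, `times`, `intensity` (matrix, one column
#'   per value), `peak_I` (vector).
#' @export
reverse_sweep <- function(param_name, values, p = reverse_parameters(),
                          horizon = 1440, opts = solver_options()) {
  stopifnot(inherits(p, "reverse_parameters"))
  if (!param_name %in% names(p)) stop("unknown reverse parameter: ",
                                      param_name)
  curves <- NULL
  peaks <- numeric(length(values))
  times <- NULL
  for (i in seq_along(values)) {
    pi <- p
    pi[[param_name]] <- values[i]
    traj <- simulate_reverse(pi, horizon = horizon, opts = opts,
                             noiseless = TRUE)
    if (is.null(times)) times <- traj$times
    curves <- cbind(curves, traj$states[, "I"])
    peaks[i] <- max(traj$states[, "I"])
  }
  colnames(curves) <- as.character(values)
  list(param = param_name, values = values, times = times,
       intensity = curves, peak_I = peaks)
}
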