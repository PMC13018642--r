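#' Supervisory control gains and baselines
#'
#' Thresholds and modulation gains of the discrete supervisory controller.
#' Confidence below `theta1` maps to maintenance (u = 0), `[theta1, theta2)`
#' to moderate (u = 1), `>= theta2` to intensive (u = 2). The stage linearly
#' scales the release parameters: `omega0(u) = omega_base * (1 + alpha_g u)`,
#' `delta(u) = delta_base * (1 + beta_g u)`,
#' `R_IN(u) = R_base * (1 + gamma_g u)`. The published control law gives the
#' thresholds (0.5, 0.75) but no gain values; (0.5, 0.5, 0.5) are the
#' package defaults.
#'
#' @param theta1,theta2 confidence thresholds, `0 <= theta1 < theta2 <= 1`.
#' @param alpha_g,beta_g,gamma_g non-negative modulation gains for the dose
#'   scale, release rate and release window.
#' @param omega_base baseline releasable concentration (mg/mL).
#' @param delta_base baseline release rate (min^-1); default the
#'   temperature-trigger preset.
#' @param R_base baseline release window (min).
#' @return object of class `control_gains`.
#' @export
control_gains <- function(theta1 = 0.5, theta2 = 0.75, alpha_g = 0.5,
                          beta_g = 0.5, gamma_g = 0.5, omega_base = 0.7,
                          delta_base = release_rate_preset("temperature"),
                          R_base = 60) {
  if (!(theta1 >= 0 && theta1 < theta2 && theta2 <= 1))
    stop("need 0 <= theta1 < theta2 <= 1")
  if (any(c(alpha_g, beta_g, gamma_g) < 0)) stop("gains must be >= 0")
  if (omega_base < 0 || delta_base <= 0 || R_base < 0)
    stop("invalid baselines")
  structure(list(theta1 = theta1, theta2 = theta2, alpha_g = alpha_g,
                 beta_g = beta_g, gamma_g = gamma_g,
                 omega_base = omega_base, delta_base = delta_base,
                 R_base = R_base),
            class = "control_gains")
}

#' Default intracellular safety cap
#'
#' The literature gives no numeric value for the maximum tolerable
#' intracellular concentration, so the package derives one reproducible
#' default: 1.2 times the peak `w5` of the default-parameter open-loop run
#' (single 0.7 mg/mL bolus over 24 h). Computed once per session and
#' cached.
#'
#' @return scalar w_safe.
#' @export
default_w_safe <- function() {
  if (is.null(.iobnt_cache$w_safe)) {
    traj <- simulate_forward(pk_parameters(), g_f = 0.7, horizon = 1440)
    .iobnt_cache$w_safe <- 1.2 * peak_intracellular(traj)$w5_peak
  }
  .iobnt_cache$w_safe
}

#' Layered safety policy
#'
#' Hard limits enforced by the safety supervisory layer: the intracellular
#' concentration cap `w_safe` (the binding constraint at defaults), a
#' pre-emptive guard fraction `kappa` at which the stage is stepped down,
#' plus single-dose, dose-interval and cumulative-dose limits and an
#' emergency-stop latch. Default limits other than `w_safe` are set wide so
#' that the concentration cap is the operative safeguard in the default
#' world; tighten them to study the layered-ablation behaviour.
#'
#' @param w_safe intracellular cap; default [default_w_safe()].
#' @param kappa guard fraction in (0, 1]: proposed stages are reduced once
#'   `w5 >= kappa * w_safe`.
#' @param max_single_dose largest admissible bolus (mg/mL).
#' @param min_dose_interval minimum spacing between boluses (min).
#' @param max_cumulative_dose run-total bolus budget (mg/mL).
#' @param emergency_stop initial state of the latch.
#' @return object of class `safety_policy`.
#' @export
safety_policy <- function(w_safe = default_w_safe(), kappa = 0.9,
                          max_single_dose = 1.5, min_dose_interval = 15,
                          max_cumulative_dose = 100,
                          emergency_stop = FALSE) {
  if (!(w_safe > 0 && max_single_dose > 0 && min_dose_interval > 0 &&
        max_cumulative_dose > 0))
    stop("all safety limits must be > 0")
  if (!(kappa > 0 && kappa <= 1)) stop("kappa must be in (0, 1]")
  structure(list(w_safe = w_safe, kappa = kappa,
                 max_single_dose = max_single_dose,
                 min_dose_interval = min_dose_interval,
                 max_cumulative_dose = max_cumulative_dose,
                 emergency_stop = isTRUE(emergency_stop)),
            class = "safety_policy")
}

#' Fresh controller state
#'
#' Stage, dose ledger, cumulative dose, safety-event log and the emergency
#' latch, as carried through a closed-loop run.
#'
#' @param policy a [safety_policy()]; seeds the latch.
#' @return object of class `control_state`.
#' @export
control_state <- function(policy = safety_policy()) {
  structure(list(u = 0L,
                 dose_ledger = data.frame(time = numeric(), u = integer(),
                                          omega0 = numeric(),
                                          delta = numeric(),
                                          R_IN = numeric(),
                                          dose = numeric(),
                                          stringsAsFactors = FALSE),
                 cumulative_dose = 0,
                 last_dose_time = -Inf,
                 emergency_stop = policy$emergency_stop,
                 safety_events = data.frame(time = numeric(),
                                            label = character(),
                                            stringsAsFactors = FALSE)),
            class = "control_state")
}

#' Discrete supervisory control law
#'
#' Piecewise mapping from classifier confidence to therapeutic stage with
#' inclusive lower bounds: `u = 0` for `Pc < theta1`, `u = 1` for
#' `theta1 <= Pc < theta2`, `u = 2` for `Pc >= theta2`.
#'
#' @param Pc confidence in `[0, 1]` (vectorised).
#' @param g a [control_gains()].
#' @return integer stage(s) in `{0, 1, 2}`.
#' @export
control_law <- function(Pc, g = control_gains()) {
  stopifnot(inherits(g, "control_gains"))
  if (any(!is.finite(Pc)) || any(Pc < 0) || any(Pc > 1))
    stop("Pc must lie in [0, 1]")
  as.integer(ifelse(Pc >= g$theta2, 2L, ifelse(Pc >= g$theta1, 1L, 0L)))
}

#' Stage-dependent release parameters
#'
#' Linear modulation of the baseline release parameters by the stage:
#' returns `(omega_0, delta, R_IN)` at stage `u`; `u = 0` returns the
#' baselines unchanged.
#'
#' @param u stage in `{0, 1, 2}`.
#' @param g a [control_gains()].
#' @return named list `omega_0`, `delta`, `R_IN`.
#' @export
modulate_parameters <- function(u, g = control_gains()) {
  stopifnot(inherits(g, "control_gains"))
  if (!u %in% 0:2) stop("u must be in {0, 1, 2}")
  list(omega_0 = g$omega_base * (1 + g$alpha_g * u),
       delta = g$delta_base * (1 + g$beta_g * u),
       R_IN = g$R_base * (1 + g$gamma_g * u))
}

# bolus (g_f) implied by stage u: the modulated release spec integrated
# over its window, with unit liposome count
.stage_dose <- function(u, g) {
  if (u == 0L) return(0)
  m <- modulate_parameters(u, g)
  injected_dose(release_spec(omega_R = m$omega_0, delta = m$delta,
                             xi = 1, R_IN = m$R_IN))$g_f
}

#' Safety override of a proposed stage
#'
#' Failsafe reduction of the proposed stage: never raises, never errors.
#' The stage is stepped down once when `w5 >= kappa * w_safe`, forced to 0
#' when `w5 >= w_safe`, and further reduced until the implied bolus
#' respects the single-dose, interval and cumulative limits; a violated
#' cumulative limit also sets the emergency latch, and an engaged latch
#' forces 0. Every reduction is appended to the state's safety-event log.
#'
#' @param proposed_u stage from [control_law()].
#' @param w5_current current intracellular concentration.
#' @param policy a [safety_policy()].
#' @param state a [control_state()].
#' @param t decision time (min).
#' @param g a [control_gains()] used to price candidate doses.
#' @return list: `u` (effective stage) and the updated `state`.
#' @export
safety_override <- function(proposed_u, w5_current, policy, state, t,
                            g = control_gains()) {
  u <- as.integer(proposed_u)
  log_event <- function(label) {
    state$safety_events <<- rbind(
      state$safety_events,
      data.frame(time = t, label = label, stringsAsFactors = FALSE))
  }
  if (state$emergency_stop && u > 0L) {
    u <- 0L
    log_event("emergency_latch")
  }
  if (u > 0L && w5_current >= policy$w_safe) {
    u <- 0L
    log_event("w_safe_exceeded")
  } else if (u > 0L && w5_current >= policy$kappa * policy$w_safe) {
    u <- u - 1L
    log_event("guard_fraction_stepdown")
  }
  if (u > 0L && (t - state$last_dose_time) < policy$min_dose_interval) {
    u <- 0L
    log_event("interval_limit")
  }
  while (u > 0L && .stage_dose(u, g) > policy$max_single_dose) {
    u <- u - 1L
    log_event("single_dose_limit")
  }
  while (u > 0L &&
         state$cumulative_dose + .stage_dose(u, g) >
           policy$max_cumulative_dose) {
    u <- u - 1L
    log_event("cumulative_limit")
    if (u == 0L) {
      state$emergency_stop <- TRUE
      log_event("emergency_latch_set")
    }
  }
  state$u <- u
  list(u = u, state = state)
}

#' Run the AI-guided closed loop
#'
#' Piecewise integration of the forward model under supervisory control. At
#' each decision epoch (every `dt_decision` minutes) the confidence trace is
#' read, mapped to a stage by [control_law()], filtered through
#' [safety_override()], and - for stages >= 1 - converted into a release
#' bolus (the stage-modulated release spec integrated over its window) that
#' is superimposed on the systemic plasma compartment; linear plasma
#' kinetics justify the superposition. Between epochs the forward system is
#' integrated with the hard `w5 <= w_safe` projection active (unless
#' `enforce_safety = FALSE`, the open-loop reference mode).
#'
#' @param trace a [generate_trace()] confidence trace covering the horizon.
#' @param p a [pk_parameters()].
#' @param g a [control_gains()].
#' @param policy a [safety_policy()].
#' @param horizon run length (min), default 24 h.
#' @param dt_decision decision period (min), default 15; the update rate is
#'   not pinned down by the source material and is configurable.
#' @param opts a [solver_options()].
#' @param enforce_safety logical; `FALSE` disables both the override and
#'   the concentration projection (open-loop comparison runs).
#' @return list: `trajectory` (columns `w1, w3, w2, w4, w5, w_el, u`) and
#'   `control` (final `control_state`).
#' @export
run_closed_loop <- function(trace, p = pk_parameters(),
                            g = control_gains(),
                            policy = safety_policy(), horizon = 1440,
                            dt_decision = 15, opts = solver_options(),
                            enforce_safety = TRUE) {
  stopifnot(inherits(trace, "confidence_trace"),
            inherits(p, "pk_parameters"), inherits(g, "control_gains"),
            inherits(policy, "safety_policy"), dt_decision > 0,
            horizon > 0)
  if (max(trace$times) < horizon - dt_decision)
    stop("trace does not cover the horizon")
  epochs <- seq(0, horizon - 1e-9, by = dt_decision)
  state <- control_state(policy)
  y <- c(0, 0, 0, 0, 0, 0)
  times_all <- numeric(0)
  states_all <- NULL
  u_col <- numeric(0)
  events <- data.frame(time = numeric(), label = character(),
                       stringsAsFactors = FALSE)
  wsafe_arg <- if (enforce_safety) policy$w_safe else Inf

  for (k in seq_along(epochs)) {
    t_k <- epochs[k]
    t_next <- if (k < length(epochs)) epochs[k + 1] else horizon
    pc <- trace_value_at(trace, t_k)
    u_prop <- control_law(pc, g)
    if (enforce_safety) {
      ov <- safety_override(u_prop, y[5], policy, state, t_k, g)
      u_eff <- ov$u
      state <- ov$state
    } else {
      u_eff <- u_prop
      state$u <- u_eff
    }
    if (u_eff > 0L) {
      m <- modulate_parameters(u_eff, g)
      dose <- .stage_dose(u_eff, g)
      y[1] <- y[1] + dose
      state$dose_ledger <- rbind(
        state$dose_ledger,
        data.frame(time = t_k, u = u_eff, omega0 = m$omega_0,
                   delta = m$delta, R_IN = m$R_IN, dose = dose,
                   stringsAsFactors = FALSE))
      state$cumulative_dose <- state$cumulative_dose + dose
      state$last_dose_time <- t_k
      events <- rbind(events,
                      data.frame(time = t_k, label = sprintf("dose_u%d", u_eff),
                                 stringsAsFactors = FALSE))
    }
    grid <- .report_grid(t_next, opts$grid_dt, t0 = t_k)
    res <- .sim_ode_cpp(1L, y, .forward_par_vec(p), grid, opts$rtol,
                        opts$atol, wsafe = wsafe_arg, wsafe_idx = 4L,
                        max_steps = 2e7)
    seg <- res$states
    if (res$n_clip > 0) {
      events <- rbind(events,
                      data.frame(time = res$first_clip_time,
                                 label = "w_safe_clip",
                                 stringsAsFactors = FALSE))
      state$safety_events <- rbind(
        state$safety_events,
        data.frame(time = res$first_clip_time, label = "w_safe_clip",
                   stringsAsFactors = FALSE))
    }
    y <- seg[nrow(seg), ]
    keep <- if (k == 1) seq_len(nrow(seg)) else -1L
    times_all <- c(times_all, grid[keep])
    states_all <- rbind(states_all, seg[keep, , drop = FALSE])
    u_col <- c(u_col, rep(u_eff, length(grid[keep])))
  }
  colnames(states_all) <- .forward_colnames
  traj <- trajectory(times_all, cbind(states_all, u = u_col), events)
  list(trajectory = traj, control = state)
}
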