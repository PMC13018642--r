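#' Default run configuration
#'
#' The full configuration tree with every tunable of every module at its
#' default. `load_config()` starts from this tree, so an empty config file
#' reproduces the standard simulation values exactly.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    experiment = "forward",
    seed = 1,
    out_dir = NA_character_,
    horizon = 1440,
    forward = list(
      omega0 = 0.7, k12 = 9.4e-3, k21 = 7.052e-5, k10 = 2.1e-3,
      ps = 4.9e-3, Fpv_t = 0.30, vp_t = 0.0745, ve_t = 0.454,
      U_Dox = 1.0, U_Dox_e = 1.0, k1wi = 2.257, k2wi = 0.0452,
      k3wi = 2.806e-3, k5wi = 10, kiwi = 5.29e-3, eq15_literal = FALSE
    ),
    release = list(
      omega_R = 0.7, stimulus = "temperature", delta = NA_real_, xi = 1,
      R_IN = 60
    ),
    reverse = list(
      k12_r = 0.103e-2, k21_r = 0.373, k1 = 0.1e-2, k10 = 2.1e-3, s0 = 8,
      mu = 1, kr_h = 10, kp_h = 150, gamma_r_h = 10.05, gamma_p_h = 4.15,
      alpha_M = 15, alpha_l = 0.044, a_tp = 40, sigma2 = 0.05, I0 = 0.7
    ),
    controller = list(
      theta1 = 0.5, theta2 = 0.75, alpha_g = 0.5, beta_g = 0.5,
      gamma_g = 0.5, omega_base = 0.7, delta_base = 0.0078, R_base = 60,
      dt_decision = 15
    ),
    safety = list(
      w_safe = NA_real_,  # NA -> default_w_safe()
      kappa = 0.9, max_single_dose = 1.5, min_dose_interval = 15,
      max_cumulative_dose = 100
    ),
    trace = list(
      scenario = "correct", base_level = 0.6, noise_rel = 0.10
    ),
    privacy = list(
      alpha = 3.99, beta = 0, x0 = 0.376, epsilon = 2, sensitivity = 1,
      message_length = 64, preamble_length = 16
    ),
    mc = list(n_samples = 500, log_uniform = FALSE),
    sweep = list(param = "ps", n_grid = 5),
    robustness = list(noise_rel = 0.10, n_reps = 100, base_level = 0.6),
    solver = list(rtol = 1e-8, atol = 1e-10, grid_dt = 1),
    deployment = list(
      width = 320, height = 320, bytes_per_pixel = 3, fps = 2.5,
      duration_h = 8, compression_ratio = 10, storage_capacity = 16e9
    )
  )
}

.known_experiments <- c("forward", "reverse", "closed_loop", "monte_carlo",
                        "sweep", "robustness", "privacy", "deployment")

# recursive key validation: every key in `user` must exist in `def`
.validate_keys <- function(user, def, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(def))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(user[[k]]) && is.list(def[[k]]))
      .validate_keys(user[[k]], def[[k]], here)
  }
  invisible(TRUE)
}

# warn (but run) when a forward-model override leaves its SA range
.warn_out_of_range <- function(cfg) {
  sa <- pk_sa_ranges()
  for (i in seq_len(nrow(sa))) {
    nm <- sa$name[i]
    val <- cfg$forward[[nm]]
    if (!is.null(val) && is.finite(val) &&
        (val < sa$low[i] || val > sa$high[i]))
      warning(sprintf(
        "forward.%s = %g lies outside its sensitivity range [%g, %g]",
        nm, val, sa$low[i], sa$high[i]), call. = FALSE)
  }
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a JSON config file, validates every key against the schema of
#' [default_config()] (unknown keys are errors, reported with their key
#' path), fills unset values with the defaults, and warns when a
#' forward-model override leaves its sensitivity range (ranges are
#' guidance, not hard bounds). An empty file or `NULL` path yields the full
#' default configuration.
#'
#' @param path path to a JSON configuration file, or `NULL`.
#' @return validated configuration list (class `run_config`).
#' @export
load_config <- function(path = NULL) {
  def <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt)))
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
    if (!is.list(user)) stop("config must be a JSON object")
  }
  .validate_keys(user, def)
  cfg <- modifyList(def, user)
  if (!cfg$experiment %in% .known_experiments)
    stop("unknown experiment: ", cfg$experiment, " (expected one of ",
         paste(.known_experiments, collapse = ", "), ")")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("seed must be a single integer")
  .warn_out_of_range(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Canonical hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; changes iff any config field
#' changes. Recorded in every run manifest.
#'
#' @param cfg a configuration list.
#' @return 32-character hash string.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tf))
}

# build typed objects from a validated config
.cfg_pk_parameters <- function(cfg) {
  f <- cfg$forward
  pk_parameters(k12 = f$k12, k21 = f$k21, k10 = f$k10, ps = f$ps,
                Fpv_t = f$Fpv_t, vp_t = f$vp_t, ve_t = f$ve_t,
                U_Dox = f$U_Dox, U_Dox_e = f$U_Dox_e, k1wi = f$k1wi,
                k2wi = f$k2wi, k3wi = f$k3wi, k5wi = f$k5wi,
                kiwi = f$kiwi, eq15_literal = f$eq15_literal)
}

.cfg_release_spec <- function(cfg) {
  r <- cfg$release
  release_spec(omega_R = r$omega_R, stimulus = r$stimulus,
               delta = if (is.na(r$delta)) NULL else r$delta,
               xi = r$xi, R_IN = r$R_IN)
}

.cfg_reverse_parameters <- function(cfg) {
  do.call(reverse_parameters, cfg$reverse)
}

.cfg_control_gains <- function(cfg) {
  co <- cfg$controller
  control_gains(theta1 = co$theta1, theta2 = co$theta2,
                alpha_g = co$alpha_g, beta_g = co$beta_g,
                gamma_g = co$gamma_g, omega_base = co$omega_base,
                delta_base = co$delta_base, R_base = co$R_base)
}

.cfg_safety_policy <- function(cfg) {
  s <- cfg$safety
  safety_policy(
    w_safe = if (is.na(s$w_safe)) default_w_safe() else s$w_safe,
    kappa = s$kappa, max_single_dose = s$max_single_dose,
    min_dose_interval = s$min_dose_interval,
    max_cumulative_dose = s$max_cumulative_dose)
}

.cfg_solver_options <- function(cfg) {
  do.call(solver_options, cfg$solver)
}
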