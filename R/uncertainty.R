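#' Parameter distribution for uncertainty propagation
#'
#' Independent per-parameter distributions over the sensitivity-analysis
#' bounds (see [pk_sa_ranges()]): uniform by default, with a log-uniform
#' option for rates spanning decades. Zero-width ranges pin a parameter at
#' its default.
#'
#' @param ranges data.frame with columns `name`, `low`, `default`, `high`;
#'   default [pk_sa_ranges()] restricted to the forward-model parameters
#'   plus the injected dose `omega0`.
#' @param n_samples number of draws.
#' @param seed RNG seed (mandatory; draws are reproducible).
#' @param log_uniform logical; sample each parameter log-uniformly (all
#'   bounds must then be > 0).
#' @return object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(ranges = NULL, n_samples = 500,
                                   seed = 1, log_uniform = FALSE) {
  if (is.null(ranges)) {
    ranges <- pk_sa_ranges()
    ranges <- ranges[ranges$name != "delta_l", ]
  }
  stopifnot(all(c("name", "low", "default", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$default | ranges$default > ranges$high))
    stop("each range must bracket its default (low <= default <= high)")
  if (log_uniform && any(ranges$low <= 0))
    stop("log-uniform sampling needs strictly positive bounds")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(ranges = ranges, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), log_uniform = isTRUE(log_uniform)),
            class = "parameter_distribution")
}

#' Draw parameter sets
#'
#' `n_samples` independent draws from a [parameter_distribution()],
#' reproducible under its seed.
#'
#' @param dist a [parameter_distribution()].
#' @return matrix (`n_samples` x parameters) with named columns.
#' @export
sample_parameters <- function(dist) {
  stopifnot(inherits(dist, "parameter_distribution"))
  set.seed(dist$seed)
  r <- dist$ranges
  m <- matrix(NA_real_, dist$n_samples, nrow(r),
              dimnames = list(NULL, r$name))
  for (j in seq_len(nrow(r))) {
    if (r$low[j] == r$high[j]) {
      m[, j] <- r$default[j]
    } else if (dist$log_uniform) {
      m[, j] <- exp(runif(dist$n_samples, log(r$low[j]), log(r$high[j])))
    } else {
      m[, j] <- runif(dist$n_samples, r$low[j], r$high[j])
    }
  }
  m
}

# default model runner: forward simulation at a drawn parameter row,
# initial bolus = drawn omega0 (or the default 0.7 when absent)
.default_mc_runner <- function(horizon = 1440, opts = solver_options()) {
  function(draw) {
    base <- pk_parameters()
    known <- intersect(names(draw), names(base))
    base[known] <- as.list(draw[known])
    p <- do.call(pk_parameters, base[setdiff(names(base), "eq15_literal")])
    g_f <- if ("omega0" %in% names(draw)) draw[["omega0"]] else 0.7
    traj <- simulate_forward(p, g_f = g_f, horizon = horizon, opts = opts)
    s <- trajectory_summary(traj)
    c(peak_w5 = s$peak_w5, t_peak_w5 = s$t_peak_w5,
      auc_w1 = s$auc_w1, auc_w2 = s$auc_w2, auc_w4 = s$auc_w4,
      auc_w5 = s$auc_w5)
  }
}

#' Monte-Carlo uncertainty propagation
#'
#' Runs `model_runner` on every drawn parameter set and summarises each
#' output with mean, median and the 5th/95th percentiles (the 90%
#' prediction interval). Failed runs are caught, counted and excluded; the
#' failure rate is reported. Runs are independent and reduced by sample
#' index, so results do not depend on execution order.
#'
#' @param dist a [parameter_distribution()].
#' @param model_runner pure function of one named draw (a row of the sample
#'   matrix) returning a named numeric vector of outputs; default runs the
#'   forward model and extracts peak `w5`, time-to-peak and compartment
#'   AUCs.
#' @param horizon,opts forwarded to the default runner.
#' @return object of class `mc_result`: `samples` (draw matrix), `outputs`
#'   (one row per draw), `summary` (per-output data.frame with `mean`,
#'   `median`, `p5`, `p95`), `n_failed`, `failure_rate`.
#' @export
monte_carlo <- function(dist, model_runner = NULL, horizon = 1440,
                        opts = solver_options()) {
  stopifnot(inherits(dist, "parameter_distribution"))
  if (is.null(model_runner))
    model_runner <- .default_mc_runner(horizon = horizon, opts = opts)
  draws <- sample_parameters(dist)
  out_list <- vector("list", nrow(draws))
  failed <- logical(nrow(draws))
  for (i in seq_len(nrow(draws))) {
    res <- tryCatch(model_runner(draws[i, ]), error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE else out_list[[i]] <- res
  }
  ok <- which(!failed)
  if (length(ok) == 0) stop("all Monte-Carlo runs failed")
  outputs <- do.call(rbind, out_list[ok])
  qs <- apply(outputs, 2, quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
  summ <- data.frame(output = colnames(outputs),
                     mean = colMeans(outputs),
                     median = qs[2, ], p5 = qs[1, ], p95 = qs[3, ],
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(samples = draws, outputs = outputs, summary = summ,
                 n_failed = sum(failed),
                 failure_rate = mean(failed)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d draws, %d failed (%.1f%%)\n",
              nrow(x$samples), x$n_failed, 100 * x$failure_rate))
  print(x$summary, digits = 4)
  invisible(x)
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the forward model over a grid of one parameter (a forward PK
#' parameter, the injected dose `omega0`, or the release parameters
#' `delta` / `R_IN` which modify the bolus through [injected_dose()]) and
#' reports summary outputs plus observed monotonicity flags for peak `w5`
#' and peak `w1`.
#'
#' @param param_name parameter to sweep.
#' @param grid numeric vector of values (a single value reproduces the
#'   baseline run).
#' @param base_params baseline [pk_parameters()].
#' @param release baseline [release_spec()] defining the bolus.
#' @param horizon,opts integration settings.
#' @return list: `param`, `grid`, `results` (data.frame with `value`,
#'   `peak_w5`, `t_peak_w5`, `peak_w1`, `auc_w5`), `monotone_increasing_w5`,
#'   `monotone_decreasing_w1`.
#' @export
sensitivity_sweep <- function(param_name, grid,
                              base_params = pk_parameters(),
                              release = release_spec(),
                              horizon = 1440, opts = solver_options()) {
  stopifnot(inherits(base_params, "pk_parameters"),
            inherits(release, "release_spec"), length(grid) >= 1)
  pk_names <- setdiff(names(base_params), "eq15_literal")
  rel_names <- c("omega0", "delta", "R_IN", "xi")
  if (!param_name %in% c(pk_names, rel_names))
    stop("unknown sweep parameter: ", param_name)
  rows <- lapply(grid, function(v) {
    p <- base_params
    rel <- release
    if (param_name %in% pk_names) {
      p[[param_name]] <- v
      p <- do.call(pk_parameters, p[pk_names])
    } else {
      field <- if (param_name == "omega0") "omega_R" else param_name
      rel[[field]] <- v
      rel <- release_spec(omega_R = rel$omega_R, delta = rel$delta,
                          xi = rel$xi, R_IN = rel$R_IN)
    }
    g_f <- injected_dose(rel)$g_f
    traj <- simulate_forward(p, g_f = g_f, horizon = horizon, opts = opts)
    pk5 <- peak_intracellular(traj)
    # plasma peak is taken after the bolus instant (t > 0): w1(0) is the
    # injected dose itself and would mask the elimination effect
    data.frame(value = v,
               peak_w5 = pk5$w5_peak,
               t_peak_w5 = pk5$t_peak,
               peak_w1 = max(traj$states[-1, "w1"]),
               auc_w5 = trajectory_auc(traj, "w5"))
  })
  results <- do.call(rbind, rows)
  o <- order(results$value)
  list(param = param_name, grid = grid, results = results,
       monotone_increasing_w5 = !is.unsorted(results$peak_w5[o]),
       monotone_decreasing_w1 = !is.unsorted(rev(results$peak_w1[o])))
}

#' Misclassification-robustness experiment
#'
#' Runs the closed loop once with a noiseless constant confidence trace and
#' `n_reps` times with multiplicative Gaussian noise of relative level
#' `noise_rel` (sd = `noise_rel * Pc`, truncated to `[0, 1]`), and returns
#' the maximum relative deviation of the peak intracellular concentration
#' from the noiseless reference.
#'
#' @param noise_rel relative noise level, >= 0 (0.10 reproduces the
#'   standard +/-10% scenario).
#' @param n_reps number of noisy replicates, >= 2.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param base_level constant confidence of the reference trace.
#' @param p,g,policy,horizon,dt_decision,opts closed-loop configuration
#'   (see [run_closed_loop()]).
#' @return list: `max_rel_dev` (fraction), `peak_ref`, `peaks`
#'   (per-replicate), `noise_rel`, `n_reps`.
#' @export
robustness_experiment <- function(noise_rel = 0.10, n_reps = 100, seed = 1,
                                  base_level = 0.6, p = pk_parameters(),
                                  g = control_gains(),
                                  policy = safety_policy(), horizon = 1440,
                                  dt_decision = 15,
                                  opts = solver_options()) {
  stopifnot(noise_rel >= 0, n_reps >= 2)
  ref_trace <- generate_trace("correct", base_level = base_level,
                              horizon = horizon, dt = dt_decision)
  ref <- run_closed_loop(ref_trace, p, g, policy, horizon = horizon,
                         dt_decision = dt_decision, opts = opts)
  peak_ref <- peak_intracellular(ref$trajectory)$w5_peak
  peaks <- vapply(seq_len(n_reps), function(i) {
    tr <- generate_trace("noisy", base_level = base_level,
                         horizon = horizon, dt = dt_decision,
                         seed = seed + i, noise_rel = noise_rel)
    run <- run_closed_loop(tr, p, g, policy, horizon = horizon,
                           dt_decision = dt_decision, opts = opts)
    peak_intracellular(run$trajectory)$w5_peak
  }, numeric(1))
  max_rel_dev <- if (peak_ref > 0)
    max(abs(peaks - peak_ref) / peak_ref)
  else as.numeric(any(peaks > 0)) * Inf
  list(max_rel_dev = max_rel_dev, peak_ref = peak_ref, peaks = peaks,
       noise_rel = noise_rel, n_reps = n_reps)
}
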