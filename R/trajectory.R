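#' Trajectory container
#'
#' Universal output record of the simulators: a strictly increasing time
#' grid (minutes), a state matrix with one row per time, and a list of
#' `(time, label)` event annotations (dose boluses, safety clips).
#'
#' @param times numeric vector of times (min), strictly increasing.
#' @param states numeric matrix, `length(times)` rows, named columns.
#' @param events data.frame with columns `time` and `label` (may be empty).
#' @return object of class `pk_trajectory`.
#' @export
trajectory <- function(times, states,
                       events = data.frame(time = numeric(),
                                           label = character(),
                                           stringsAsFactors = FALSE)) {
  states <- as.matrix(states)
  if (length(times) != nrow(states))
    stop("states must have one row per time point")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), states = states,
                 events = events),
            class = "pk_trajectory")
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf("<pk_trajectory> %d time points over [%g, %g] min; states: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(colnames(x$states), collapse = ", ")))
  if (nrow(x$events) > 0)
    cat(sprintf("  %d events (first: %s @ %g min)\n", nrow(x$events),
                x$events$label[1], x$events$time[1]))
  invisible(x)
}

#' @export
as.data.frame.pk_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$states, check.names = FALSE)
}

#' Peak intracellular concentration
#'
#' Location and value of the maximum of the tumor intracellular compartment
#' `w5` on the reporting grid. Ties are broken by earliest time.
#'
#' @param traj a `pk_trajectory` containing a `w5` column.
#' @return list with `t_peak` (min) and `w5_peak`.
#' @export
peak_intracellular <- function(traj) {
  peak_compartment(traj, "w5")
}

#' Peak of an arbitrary trajectory component
#'
#' @param traj a `pk_trajectory`.
#' @param component column name of the state matrix.
#' @return list with `t_peak` and `peak` (and `w5_peak` alias when
#'   `component == "w5"`).
#' @export
peak_compartment <- function(traj, component) {
  stopifnot(inherits(traj, "pk_trajectory"))
  if (length(traj$times) == 0) stop("empty trajectory")
  if (!component %in% colnames(traj$states))
    stop("no such component: ", component)
  y <- traj$states[, component]
  i <- which.max(y)  # which.max returns the first maximum: earliest-time tie-break
  out <- list(t_peak = traj$times[i], peak = y[i])
  if (component == "w5") out$w5_peak <- out$peak
  out
}

#' Trapezoidal area under a trajectory component
#'
#' @inheritParams peak_compartment
#' @return scalar AUC in concentration x min units.
#' @export
trajectory_auc <- function(traj, component) {
  stopifnot(inherits(traj, "pk_trajectory"))
  if (!component %in% colnames(traj$states))
    stop("no such component: ", component)
  y <- traj$states[, component]
  t <- traj$times
  if (length(t) < 2) return(0)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Summary statistics of a trajectory
#'
#' Per-compartment peak and AUC, used by the JSON experiment summaries and
#' the Monte-Carlo output extraction.
#'
#' @param traj a `pk_trajectory`.
#' @return named list: per component `peak_<c>` and `auc_<c>`, plus
#'   `t_peak_w5` when a `w5` column is present.
#' @export
trajectory_summary <- function(traj) {
  stopifnot(inherits(traj, "pk_trajectory"))
  comps <- colnames(traj$states)
  out <- list()
  for (cc in comps) {
    pk <- peak_compartment(traj, cc)
    out[[paste0("peak_", cc)]] <- pk$peak
    out[[paste0("auc_", cc)]] <- trajectory_auc(traj, cc)
  }
  if ("w5" %in% comps) out$t_peak_w5 <- peak_compartment(traj, "w5")$t_peak
  out
}

#' Write a trajectory as CSV
#'
#' Shared CSV schema: a `time_min` column followed by the state columns
#' (forward path: `w1, w2, w3, w4, w5, w_el`; reverse path:
#' `v1, v2, m, LU, I, c_r`; closed loop adds `u`).
#'
#' @param traj a `pk_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  # forward trajectories are reported in compartment-number order
  fwd <- c("time_min", "w1", "w2", "w3", "w4", "w5", "w_el")
  if (all(fwd %in% names(df)))
    df <- df[, c(fwd, setdiff(names(df), fwd))]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
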