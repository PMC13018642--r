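#' Synthetic classifier-confidence traces
#'
#' Generates the confidence stream `Pc(t)` standing in for the imaging
#' classifier, covering the standard failure modes:
#' * `correct`: constant `base_level`;
#' * `false_positive`: `base_level` raised above `theta2` inside a
#'   transient window (default one 60-min window centred in the horizon);
#' * `false_negative`: clamped just below `theta1` for the whole run;
#' * `noisy`: multiplicative Gaussian noise, sd `noise_rel * base_level`,
#'   truncated to `[0, 1]`;
#' * `custom`: values supplied via `values`.
#'
#' @param scenario one of `"correct"`, `"false_positive"`,
#'   `"false_negative"`, `"noisy"`, `"custom"`.
#' @param base_level nominal confidence in `[0, 1]`.
#' @param horizon trace length (min).
#' @param dt sample spacing (min); matched to the closed-loop decision grid.
#' @param seed RNG seed (mandatory for `noisy`).
#' @param noise_rel relative noise level for `noisy` (default 0.10).
#' @param theta1,theta2 thresholds used by the failure-mode scenarios.
#' @param window `c(start, end)` of the false-positive window (min);
#'   default a 60-min window centred in the horizon.
#' @param values numeric vector for `scenario = "custom"` (recycled/cropped
#'   to the grid).
#' @return object of class `confidence_trace`: `times`, `pc`, `scenario`,
#'   `seed`.
#' @export
generate_trace <- function(scenario = c("correct", "false_positive",
                                        "false_negative", "noisy",
                                        "custom"),
                           base_level = 0.6, horizon = 1440, dt = 15,
                           seed = NULL, noise_rel = 0.10, theta1 = 0.5,
                           theta2 = 0.75, window = NULL, values = NULL) {
  scenario <- match.arg(scenario)
  if (!is.finite(base_level) || base_level < 0 || base_level > 1)
    stop("base_level must lie in [0, 1]")
  times <- seq(0, horizon, by = dt)
  n <- length(times)
  pc <- switch(
    scenario,
    correct = rep(base_level, n),
    false_positive = {
      if (is.null(window)) window <- horizon / 2 + c(-30, 30)
      pc <- rep(base_level, n)
      idx <- times >= window[1] & times <= window[2]
      pc[idx] <- max(base_level, (theta2 + 1) / 2)  # artificially high
      pc
    },
    false_negative = {
      # artificially low: clamp below the detection boundary
      rep(min(base_level, theta1 * 0.9), n)
    },
    noisy = {
      if (is.null(seed)) stop("noisy traces require a seed")
      set.seed(seed)
      pmin(pmax(base_level * (1 + rnorm(n, 0, noise_rel)), 0), 1)
    },
    custom = {
      if (is.null(values)) stop("custom scenario requires values")
      rep_len(as.numeric(values), n)
    })
  if (any(pc < 0 | pc > 1)) stop("trace values escaped [0, 1]")
  structure(list(times = times, pc = pc, scenario = scenario, seed = seed),
            class = "confidence_trace")
}

#' Read a trace at a given time
#'
#' Piecewise-constant (left-continuous) lookup used by the closed-loop
#' runner at decision epochs.
#'
#' @param trace a `confidence_trace`.
#' @param t time (min) within the trace span.
#' @return confidence value.
#' @export
trace_value_at <- function(trace, t) {
  stopifnot(inherits(trace, "confidence_trace"))
  i <- findInterval(t + 1e-9, trace$times)
  if (i < 1) stop("time precedes trace start")
  trace$pc[min(i, length(trace$pc))]
}

#' @export
print.confidence_trace <- function(x, ...) {
  cat(sprintf("<confidence_trace> scenario=%s, %d points over [%g, %g] min\n",
              x$scenario, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
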