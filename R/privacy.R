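#' Chaotic-map key
#'
#' Shared-secret triple of the quadratic (logistic-type) map
#' `x_{n+1} = alpha * x_n * (1 - x_n) + beta`. With `beta = 0` and
#' `alpha = 3.99` (defaults) the map operates deep in the chaotic regime of
#' the logistic family, giving strong sensitivity to the initial condition
#' `x0`.
#'
#' @param alpha map gain.
#' @param beta additive offset.
#' @param x0 initial condition in (0, 1).
#' @return object of class `chaotic_key`.
#' @export
chaotic_key <- function(alpha = 3.99, beta = 0, x0 = 0.376) {
  if (!all(is.finite(c(alpha, beta, x0)))) stop("key must be finite")
  if (!(x0 > 0 && x0 < 1)) stop("x0 must lie in (0, 1)")
  structure(list(alpha = alpha, beta = beta, x0 = x0),
            class = "chaotic_key")
}

#' @export
print.chaotic_key <- function(x, ...) {
  # key material is never echoed
  cat("<chaotic_key> (secret)\n")
  invisible(x)
}

#' One iteration of the quadratic map
#'
#' @param x current value (finite, vectorised).
#' @param key a [chaotic_key()].
#' @return `alpha * x * (1 - x) + beta`.
#' @export
chaotic_step <- function(x, key) {
  stopifnot(inherits(key, "chaotic_key"))
  if (any(!is.finite(x))) stop("x must be finite")
  key$alpha * x * (1 - x) + key$beta
}

#' Chaotic keystream
#'
#' Iterates the map from `x0` and returns `s_n = x_{n+1}`,
#' `n = 1, ..., n`. Deterministic in the key; in the chaotic regime two
#' keys differing by 1e-6 in `x0` decorrelate within a short burn-in.
#'
#' @param key a [chaotic_key()].
#' @param n stream length, >= 1.
#' @return numeric vector of length `n`.
#' @export
keystream <- function(key, n) {
  stopifnot(inherits(key, "chaotic_key"))
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  .keystream_cpp(key$alpha, key$beta, key$x0, as.integer(n))
}

# 48-bit fixed-point lattice used by the masking layer: sums of two lattice
# values stay exactly representable in a double, so modular masking inverts
# bit-for-bit.
.MASK_SCALE <- 2^48

#' Quantise values onto the masking lattice
#'
#' The additive-mod-1 mask operates on a 48-bit fixed-point lattice
#' (resolution 2^-48, far below any sensor resolution) so that
#' encode/decode round-trips are exact. `quantize_unit()` maps arbitrary
#' `[0, 1]` values onto that lattice.
#'
#' @param values numeric in `[0, 1]`.
#' @return lattice-aligned values.
#' @export
quantize_unit <- function(values) {
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("values must lie in [0, 1]")
  round(values * .MASK_SCALE) / .MASK_SCALE
}

# keystream reduced to lattice integers in [0, SCALE)
.mask_integers <- function(key, n) {
  s <- keystream(key, n)
  (floor(s * .MASK_SCALE) %% .MASK_SCALE + .MASK_SCALE) %% .MASK_SCALE
}

#' Chaotic additive masking of sensed values
#'
#' Obfuscates `[0, 1]`-scaled sensed values by adding the chaotic keystream
#' modulo 1 on the fixed-point lattice: exactly invertible under the
#' correct key, while a wrong key leaves a mean absolute decode error
#' comparable to two independent uniform draws (about 1/3).
#'
#' @param values plaintext in `[0, 1]` (quantised to the lattice first).
#' @param key a [chaotic_key()].
#' @return ciphertext in `[0, 1)`.
#' @seealso [decode_values()], [quantize_unit()]
#' @export
encode_values <- function(values, key) {
  stopifnot(inherits(key, "chaotic_key"))
  if (length(values) == 0) return(numeric(0))
  vi <- quantize_unit(values) * .MASK_SCALE
  si <- .mask_integers(key, length(values))
  ((vi + si) %% .MASK_SCALE) / .MASK_SCALE
}

#' @rdname encode_values
#' @param ciphertext output of [encode_values()].
#' @export
decode_values <- function(ciphertext, key) {
  stopifnot(inherits(key, "chaotic_key"))
  if (length(ciphertext) == 0) return(numeric(0))
  ci <- round(ciphertext * .MASK_SCALE)
  si <- .mask_integers(key, length(ciphertext))
  (((ci - si) %% .MASK_SCALE + .MASK_SCALE) %% .MASK_SCALE) / .MASK_SCALE
}

#' Histogram Shannon entropy of a sample
#'
#' `H = -sum p_i log p_i` over `n_bins` equal-width bins spanning the
#' sample range (natural log by default, matching the printed definition;
#' base-2 available). Bounded by `0 <= H <= log(n_bins)`.
#'
#' @param samples non-empty numeric vector.
#' @param n_bins number of bins, >= 2.
#' @param base logarithm base (default `exp(1)` for nats).
#' @return entropy estimate.
#' @export
stream_entropy <- function(samples, n_bins = 16, base = exp(1)) {
  if (length(samples) == 0 || any(!is.finite(samples)))
    stop("samples must be non-empty and finite")
  if (n_bins < 2) stop("n_bins must be >= 2")
  r <- range(samples)
  if (diff(r) == 0) return(0)
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(samples)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Privacy budget
#'
#' Scalar `epsilon > 0` trading perturbation intensity against downstream
#' detection utility, with a `sensitivity` scale calibrating the noise.
#'
#' @param epsilon privacy budget, > 0.
#' @param sensitivity value-range scale, > 0.
#' @return object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon, sensitivity = 1) {
  if (!is.finite(epsilon) && !identical(epsilon, Inf))
    stop("epsilon must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  structure(list(epsilon = epsilon, sensitivity = sensitivity),
            class = "privacy_budget")
}

#' Budgeted Laplace-style perturbation
#'
#' Additive zero-mean Laplace noise with scale `sensitivity / epsilon`,
#' applied before chaotic encoding. Noise magnitude is strictly decreasing
#' in `epsilon`; `epsilon = Inf` returns the input unchanged. Uses the
#' session RNG (seed upstream for reproducibility).
#'
#' @param values numeric vector.
#' @param budget a [privacy_budget()].
#' @return perturbed values.
#' @export
privacy_perturb <- function(values, budget) {
  stopifnot(inherits(budget, "privacy_budget"))
  if (!is.finite(budget$epsilon)) return(values)
  b <- budget$sensitivity / budget$epsilon
  u <- runif(length(values), -0.5, 0.5)
  values - b * sign(u) * log1p(-2 * abs(u))
}

#' Encode a message with a known authentication preamble
#'
#' Prepends `preamble` to `payload` and chaotically encodes the whole
#' message; the receiver authenticates by decoding the preamble positions
#' and comparing against the known preamble.
#'
#' @param payload plaintext payload in `[0, 1]`.
#' @param key a [chaotic_key()].
#' @param preamble known preamble symbols in `[0, 1]`.
#' @return ciphertext vector of length `length(preamble) + length(payload)`.
#' @export
encode_message <- function(payload, key, preamble = auth_preamble()) {
  encode_values(c(preamble, payload), key)
}

#' Default authentication preamble
#'
#' A fixed, public 16-symbol preamble on the masking lattice.
#'
#' @param n preamble length.
#' @return numeric vector in `[0, 1]`.
#' @export
auth_preamble <- function(n = 16) {
  quantize_unit(((seq_len(n) * 7) %% 23) / 23)
}

#' Key-authentication score
#'
#' Negative mean absolute decode residual of the preamble positions under
#' the claimed key: close to zero for the true key, around -1/3 for an
#' unrelated key.
#'
#' @param ciphertext an [encode_message()] output.
#' @param claimed_key key under test.
#' @param preamble the known preamble used at encoding time.
#' @return scalar score (higher = more credible).
#' @export
authenticate_message <- function(ciphertext, claimed_key,
                                 preamble = auth_preamble()) {
  np <- length(preamble)
  if (length(ciphertext) < np) stop("ciphertext shorter than preamble")
  dec <- decode_values(ciphertext[seq_len(np)], claimed_key)
  -mean(abs(dec - quantize_unit(preamble)))
}

#' Rank-statistic ROC AUC
#'
#' Mann-Whitney AUC for separating two score sets: the probability that a
#' legitimate score exceeds an illegitimate one, counting ties as 1/2.
#'
#' @param legit_scores scores of the positive (legitimate) class.
#' @param illegit_scores scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
auth_auc <- function(legit_scores, illegit_scores) {
  if (any(!is.finite(c(legit_scores, illegit_scores))))
    stop("scores must be finite")
  n1 <- length(legit_scores); n0 <- length(illegit_scores)
  if (n1 == 0 || n0 == 0) stop("both score sets must be non-empty")
  r <- rank(c(legit_scores, illegit_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Key-authentication separability experiment
#'
#' Encodes random messages under per-message shared keys and scores them
#' against the registered key: legitimately keyed messages decode their
#' preamble exactly, while messages encoded under a key whose initial
#' condition is perturbed by at least `min_key_perturb` (relative) leave a
#' large decode residual. Returns the rank-statistic ROC AUC over the two
#' score populations (expected: 1, perfect separation).
#'
#' @param n_legit,n_illegit numbers of legitimate / perturbed-key messages.
#' @param message_length payload symbols per message.
#' @param preamble_length known-preamble symbols per message.
#' @param min_key_perturb minimum relative perturbation of `x0` for the
#'   illegitimate population (default 1%).
#' @param seed RNG seed.
#' @param alpha,beta map parameters of the shared keys.
#' @return list: `auc`, `legit_scores`, `illegit_scores`.
#' @export
authentication_experiment <- function(n_legit = 200, n_illegit = 200,
                                      message_length = 64,
                                      preamble_length = 16,
                                      min_key_perturb = 0.01, seed = 42,
                                      alpha = 3.99, beta = 0) {
  set.seed(seed)
  preamble <- auth_preamble(preamble_length)
  payload_len <- message_length - preamble_length
  one_message <- function(perturb) {
    x0 <- runif(1, 0.05, 0.95)
    key_tx <- chaotic_key(alpha, beta, x0)
    if (perturb) {
      # at least min_key_perturb relative offset, random sign, kept in (0,1)
      mag <- runif(1, min_key_perturb, 5 * min_key_perturb) * x0
      x0p <- x0 + sample(c(-1, 1), 1) * mag
      x0p <- min(max(x0p, 1e-6), 1 - 1e-6)
      key_tx <- chaotic_key(alpha, beta, x0p)
    }
    ct <- encode_message(runif(payload_len), key_tx, preamble)
    authenticate_message(ct, chaotic_key(alpha, beta, x0), preamble)
  }
  legit <- vapply(seq_len(n_legit), function(i) one_message(FALSE),
                  numeric(1))
  illegit <- vapply(seq_len(n_illegit), function(i) one_message(TRUE),
                    numeric(1))
  list(auc = auth_auc(legit, illegit), legit_scores = legit,
       illegit_scores = illegit)
}
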