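#' Forward-path pharmacokinetic parameters
#'
#' Constructs the parameter set of the five-compartment forward model
#' (systemic plasma, peripheral exchange, tumor plasma, tumor EES, tumor
#' intracellular, cumulative elimination). Defaults are the standard
#' simulation values of the source framework; every rate is expressed in
#' min^-1, volume fractions are dimensionless, and the protein-binding
#' factors multiply total concentration.
#'
#' Each modifiable parameter carries a sensitivity-analysis (SA) range,
#' available via [pk_sa_ranges()], used by the Monte-Carlo and sweep
#' machinery.
#'
#' @param k12,k21 exchange rates between systemic plasma and the peripheral
#'   compartment (min^-1).
#' @param k10 elimination rate from systemic plasma (min^-1).
#' @param ps permeability-surface-area product for transvascular exchange
#'   (min^-1 equivalent, used with the explicit 1/vp_t and 1/ve_t factors).
#' @param Fpv_t plasma flow coupling systemic and tumor plasma (mL/min).
#' @param vp_t,ve_t tumor plasma / extracellular volume fractions in (0, 1).
#' @param U_Dox,U_Dox_e plasma and EES protein-binding factors
#'   (dimensionless).
#' @param k1wi,k2wi,k3wi,k5wi,kiwi intracellular uptake constants: linear
#'   uptake, saturable (Michaelis-Menten) uptake, overall uptake scale,
#'   efflux, and the Michaelis constant.
#' @param eq15_literal logical; if `TRUE` the EES loss term uses the literal
#'   printed rendering (both linear coefficients over a single saturable
#'   denominator) instead of the linear-plus-saturable form. Exposed for
#'   comparison only; the default `FALSE` is the consistent form.
#' @return an object of class `pk_parameters` (named list).
#' @seealso [simulate_forward()], [pk_sa_ranges()]
#' @export
pk_parameters <- function(k12 = 9.4e-3, k21 = 7.052e-5, k10 = 2.1e-3,
                          ps = 4.9e-3, Fpv_t = 0.30, vp_t = 0.0745,
                          ve_t = 0.454, U_Dox = 1.0, U_Dox_e = 1.0,
                          k1wi = 2.257, k2wi = 0.0452, k3wi = 2.806e-3,
                          k5wi = 10, kiwi = 5.29e-3, eq15_literal = FALSE) {
  p <- list(k12 = k12, k21 = k21, k10 = k10, ps = ps, Fpv_t = Fpv_t,
            vp_t = vp_t, ve_t = ve_t, U_Dox = U_Dox, U_Dox_e = U_Dox_e,
            k1wi = k1wi, k2wi = k2wi, k3wi = k3wi, k5wi = k5wi, kiwi = kiwi,
            eq15_literal = isTRUE(eq15_literal))
  rates <- p[setdiff(names(p), c("vp_t", "ve_t", "eq15_literal"))]
  num <- unlist(rates)
  if (any(!is.finite(num))) stop("all PK parameters must be finite")
  if (any(num < 0)) stop("all PK rates and binding factors must be >= 0")
  if (!(vp_t > 0 && vp_t < 1 && ve_t > 0 && ve_t < 1))
    stop("volume fractions vp_t and ve_t must lie in (0, 1)")
  class(p) <- "pk_parameters"
  p
}

#' Sensitivity-analysis ranges for the forward model
#'
#' Per-parameter uniform bounds bracketing the defaults, including the
#' injected-dose scale `omega0` and the light-triggered release rate
#' `delta_l`. These drive [sample_parameters()] and the default sweep grids.
#'
#' @return data.frame with columns `name`, `low`, `default`, `high`.
#' @export
pk_sa_ranges <- function() {
  data.frame(
    name = c("omega0", "k12", "k10", "k21", "k1wi", "k2wi", "k3wi", "k5wi",
             "kiwi", "U_Dox", "ps", "Fpv_t", "vp_t", "ve_t", "U_Dox_e",
             "delta_l"),
    low = c(0.5, 7.5e-4, 1.5e-3, 5.0e-5, 1.8, 0.036, 2.2e-3, 8, 4.2e-3,
            0.8, 3.9e-3, 0.24, 0.06, 0.36, 0.8, 0.83e-4),
    default = c(0.7, 9.4e-3, 2.1e-3, 7.052e-5, 2.257, 0.0452, 2.806e-3, 10,
                5.29e-3, 1.0, 4.9e-3, 0.30, 0.0745, 0.454, 1.0, 1.04e-4),
    high = c(0.9, 1.1e-2, 3.0e-3, 1.0e-4, 2.7, 0.054, 3.4e-3, 12, 6.4e-3,
             1.0, 5.9e-3, 0.36, 0.09, 0.54, 1.0, 1.25e-4),
    stringsAsFactors = FALSE
  )
}

#' Metadata constants of the simulation framework
#'
#' Constants reported alongside the default simulation values that do not
#' enter any implemented forward-path equation (cumulative injected dose,
#' ATP concentration, Michaelis constant, bounding-molecule concentration,
#' temperature). Carried for reference and reporting only.
#'
#' @return named list.
#' @export
pk_metadata_constants <- function() {
  list(D_cumulative_mg = 0.85, X_atp_uM = 40, alpha_M_uM = 15,
       delta0_uM = 0.7, T_celsius = 37)
}

#' Convert a first-order rate from per hour to per minute
#'
#' Reverse-path reporter-chain constants are published in h^-1; the
#' simulator operates on a minute clock throughout, so they are divided by
#' 60 at load time. [per_min_to_per_hour()] is the exact inverse, used by
#' the round-trip unit audit.
#'
#' @param x rate in h^-1 (or min^-1 for the inverse).
#' @return rate in min^-1 (or h^-1).
#' @export
per_hour_to_per_min <- function(x) x / 60

#' @rdname per_hour_to_per_min
#' @export
per_min_to_per_hour <- function(x) x * 60

#' Reverse-path signalling parameters
#'
#' Parameters of the two-compartment reverse molecular-communication path
#' plus the reporter expression chain (mRNA -> luciferase) and the
#' ATP-limited bioluminescent light output. Reporter-chain rates (`kr`,
#' `kp`, `gamma_r`, `gamma_p`) are accepted in h^-1 (their published units)
#' and converted to min^-1 on construction; all stored rates are min^-1.
#'
#' Defaults: k12_r = 0.103e-2, k21_r = 0.373, k1 = 0.1e-2, k10 = 2.1e-3
#' min^-1; kr = 10, kp = 150, gamma_r = 10.05, gamma_p = 4.15 h^-1;
#' alpha_M = 15 uM, alpha_l = 0.044, a_tp = 40, noise variance 0.05 uM^2,
#' decision threshold I0 = 0.7 a.u., mu = 1, s0 = 8 uM.
#'
#' @param k12_r,k21_r reverse-path exchange rates (min^-1).
#' @param k1 ligand-receptor binding constant (min^-1).
#' @param k10 elimination rate (min^-1); shares its default with the
#'   forward path but is independently overridable.
#' @param s0 total sensor-released concentration (uM), the initial value of
#'   the sensor compartment v2.
#' @param mu diffusion coupling efficiency (dimensionless).
#' @param kr_h,kp_h transcription-to-signal and translation rates (h^-1).
#' @param gamma_r_h,gamma_p_h mRNA and luciferase degradation rates (h^-1).
#' @param alpha_M Michaelis constant of the light reaction (uM).
#' @param alpha_l light-yield coefficient (dimensionless).
#' @param a_tp ATP saturation argument (dimensionless, see Details).
#' @param sigma2 additive Gaussian noise variance on the intensity (uM^2).
#' @param I0 binary decision threshold on intensity (a.u.).
#' @details The ATP factor is published with an odd unit annotation; it is
#'   treated here as a dimensionless saturation argument with value 40 in
#'   the Michaelis-Menten ratio `a_tp / (alpha_M + a_tp)`.
#' @return object of class `reverse_parameters`.
#' @export
reverse_parameters <- function(k12_r = 0.103e-2, k21_r = 0.373,
                               k1 = 0.1e-2, k10 = 2.1e-3, s0 = 8, mu = 1,
                               kr_h = 0.1e2, kp_h = 1.5e2,
                               gamma_r_h = 0.1005e2, gamma_p_h = 0.0415e2,
                               alpha_M = 15, alpha_l = 0.044, a_tp = 40,
                               sigma2 = 0.5e-1, I0 = 0.007e2) {
  p <- list(k12_r = k12_r, k21_r = k21_r, k1 = k1, k10 = k10, s0 = s0,
            mu = mu,
            kr = per_hour_to_per_min(kr_h),
            kp = per_hour_to_per_min(kp_h),
            gamma_r = per_hour_to_per_min(gamma_r_h),
            gamma_p = per_hour_to_per_min(gamma_p_h),
            alpha_M = alpha_M, alpha_l = alpha_l, a_tp = a_tp,
            sigma2 = sigma2, I0 = I0)
  num <- unlist(p)
  if (any(!is.finite(num))) stop("all reverse parameters must be finite")
  rates <- c("k12_r", "k21_r", "k1", "k10", "kr", "kp", "gamma_r", "gamma_p")
  if (any(unlist(p[rates]) < 0)) stop("all reverse rates must be >= 0")
  if (p$sigma2 < 0) stop("sigma2 must be >= 0")
  if (p$I0 <= 0) stop("I0 must be > 0")
  class(p) <- "reverse_parameters"
  p
}

# flatten pk_parameters into the C++ layout
.forward_par_vec <- function(p) {
  c(p$k12, p$k21, p$k10, p$ps, p$Fpv_t, p$vp_t, p$ve_t, p$U_Dox, p$U_Dox_e,
    p$k1wi, p$k2wi, p$k3wi, p$k5wi, p$kiwi, as.numeric(p$eq15_literal))
}

.reverse_par_vec <- function(p) {
  c(p$k12_r, p$k21_r, p$k1, p$k10, p$mu, p$kr, p$gamma_r, p$kp, p$gamma_p)
}
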