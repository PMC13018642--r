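---
title: "Methods: a safety-constrained closed-loop IoBNT drug-delivery simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a safety-constrained closed-loop IoBNT drug-delivery simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iobntsim)
```

This vignette documents the models, the parameter conventions, the design
decisions taken where the source material is ambiguous, and the numerical
choices. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The forward pharmacokinetic model

The forward path tracks doxorubicin from an intravenous bolus to the tumor
intracellular space with six states:

* `w1` systemic plasma, `w3` peripheral exchange pool:
  `dw1 = -(k12 + k10) w1 + k21 w3`, `dw3 = k12 w1 - k21 w3`;
* `w2` tumor plasma:
  `dw2 = -(ps/vp_t) w2 U + (ps/vp_t) w4 Ue - Fpv_t w2 + Fpv_t w1`;
* `w4` tumor extracellular space:
  `dw4 = (ps/ve_t) w2 U - (ps/ve_t) w4 Ue - uptake(w4 Ue, w5)`;
* `w5` tumor intracellular: `dw5 = uptake(w4, w5)` with
  `uptake(x, w5) = k3wi (k1wi x + k2wi x / (kiwi + x) - k5wi w5)`;
* `w_el` cumulative eliminated mass: `dw_el = k10 w1`.

All rates are per minute; the default values and their sensitivity ranges
are in `pk_sa_ranges()`. Binding factors `U`, `Ue` multiply total
concentration and default to 1.

**Compartment-label interpretation.** The printed systemic pair uses the
labels `w1`/`w3` while its stated initial condition names `w2`; the
published figure topology is not recoverable from the text. We adopt:
`w1` systemic plasma (initialised to the bolus `g_f`), `w3` a peripheral
pool coupled only to `w1`, and a tumor chain (`w2`, `w4`, `w5`) driven by
`w1` through `Fpv_t` without back-draining it (the tumor is a
volume-negligible driven subsystem, as in standard tumor-cord microdose
models). This is an interpretation, not something the source resolves.

**Uptake form.** The extracellular loss term is printed with both linear
coefficients over a single saturable denominator, which contradicts the
intracellular gain term (linear plus saturable). We treat the printed form
as a typesetting artifact and use linear + Michaelis–Menten in both places;
`pk_parameters(eq15_literal = TRUE)` exposes the literal rendering for
comparison.

**Consequence for the `k12` sensitivity claim.** The narrative claims that
increasing `k12` increases drug near the target. Under the equations above,
`k12` moves drug from systemic plasma into the peripheral pool, and the
return rate `k21` is two orders of magnitude smaller, so the tumor chain
sees strictly less drug and peak `w5` *falls* as `k12` grows. We verified
this under the alternative reading too (routing `k12` directly into tumor
plasma): the systemic drain still dominates at the published values. The
published claim is reproducible only from the bare two-compartment system,
where the "tissue" curve is the peripheral pool `w3` (which indeed grows
with `k12`). The acceptance assertion for the claim is kept as stated and
is expected to fail; the remaining monotonicity claims (dose, permeability,
elimination, reverse path) all hold and are asserted green.

**Plasma peak convention.** `w1(0) = g_f` is the bolus itself, so the peak
of the raw plasma curve is independent of every rate. Sensitivity sweeps
therefore report the *post-bolus* plasma peak (grid times `t > 0`), which
is strictly decreasing in `k10` as expected.

## The reverse signalling model

The bio-nanosensor releases `s0` (µM) into a sensor compartment `v2` that
drains into plasma `v1` at `k21_r`; plasma signal is lost to back-exchange
`k12_r`, elimination `k10` and receptor capture `k1`, whose output
`g_r = k1 v1` drives a canonical two-stage reporter chain
`dm = kr mu g_r - gamma_r m`, `dLU = kp m - gamma_p LU`. The light output

```
I = alpha_l * LU * a_tp / (alpha_M + a_tp) + N(0, sigma2)
```

is a **reconstruction**: the source defers the intensity equation to prior
work and prints only the constants (`alpha_M` = 15 µM, `alpha_l` = 0.044,
ATP factor 40, noise variance 0.05). The Michaelis–Menten ATP limitation is
the standard luciferase kinetics; the kernel is injectable
(`bioluminescence_intensity(..., light_fn = )`) so alternative forms can be
swapped. The ATP factor is printed with an inconsistent unit annotation and
is treated as a dimensionless saturation argument. The binary decision is
boundary-inclusive: `c_r = 1` iff `I >= I0`.

Reporter-chain rates are published per hour and converted to the package's
minute clock at construction; `per_hour_to_per_min()` /
`per_min_to_per_hour()` and a round-trip test guard the factor-60 hazard.
The reverse-path `k10` defaults to the forward value but is independently
overridable, since the source does not state they are equal.

## The supervisory controller and the safety layer

Decisions happen every `dt_decision` minutes (default 15 — the source never
states the update rate; the plant time constants are hours, so any rate in
the tens of minutes behaves equivalently). At each epoch:

1. `control_law()` maps confidence to a stage `u` with inclusive lower
   bounds at thresholds (0.5, 0.75);
2. `safety_override()` reduces the stage — one step inside the guard band
   `w5 >= kappa * w_safe` (`kappa` = 0.9; the source says only
   "approaches", so a concrete margin is required and exposed), to zero at
   or above `w_safe`, and further until the implied bolus respects the
   single-dose, interval and cumulative limits; a violated cumulative limit
   latches an emergency stop. The override never raises (failsafe
   contract);
3. stages `u >= 1` fire a bolus equal to the stage-modulated release spec
   integrated over its window, superimposed on `w1` (linear plasma kinetics
   permit superposition). Stage 0 is maintenance: **no** new bolus.

Between epochs the system is integrated with a hard projection
`w5 <- min(w5, w_safe)` applied after every accepted step. The projection
is the enforcement mechanism of the hard constraint `w5(t) <= w_safe`: the
stage reductions act pre-emptively, but drug already in transit through
`w2`/`w4` can push `w5` past the cap after dosing stops, and the source's
own failure-mode table describes the outcome as concentration *clipped* at
the cap. By construction the safety-dominance property holds for arbitrary,
including adversarial, confidence traces.

**Numeric defaults with no published value.** The modulation gains default
to (0.5, 0.5, 0.5); baselines are `omega_base` = 0.7 mg/mL (the published
injected concentration), `delta_base` the temperature preset 0.0078 min^-1
(the faster trigger, so epoch-scale windows release meaningful doses) and
`R_base` = 60 min. `w_safe` defaults to 1.2× the default-parameter
open-loop peak `w5`, computed once per session and cached
(`default_w_safe()`); the source gives no numeric cap. The remaining limits
default wide (`max_single_dose` = 1.5, `min_dose_interval` = one epoch,
`max_cumulative_dose` = 100) so that the concentration cap is the operative
safeguard in the default world, matching the narrative in which the hard
constraint is the formalised safety mechanism; tight limits are exercised
in the unit tests.

**Why the robustness number is exactly zero.** Under the defaults, repeated
moderate-stage boluses saturate `w5` at the cap within a few hours, for the
noiseless reference and every noisy replicate alike, so the peak is
`w_safe` in every run and the reported maximum relative deviation is 0% —
the bounded-response behaviour the failure-mode analysis describes. The
deviation becomes non-degenerate (and visibly increasing in the noise
level) when doses are scarce, e.g. under a tight cumulative budget; the
suite tests that regime separately.

## The confidence-trace generator

`generate_trace()` emulates only the *output* of the imaging classifier: a
confidence stream on the decision grid. Scenarios: constant (correct),
transient false positive (a 60-min window centred in the horizon — the
source gives no timing), clamped false negative, multiplicative Gaussian
noise (sd = `noise_rel * Pc`, truncated to [0, 1]; the ±10% scenario is
interpreted as multiplicative, switchable to custom values). It does not
emulate image content, class structure, or temporally correlated classifier
errors — a green robustness test says the *control loop* tolerates
confidence perturbations, not that any particular classifier achieves them.

## The privacy layer

Sensed values scaled to [0, 1] are masked additively modulo 1 with the
keystream of the quadratic map `x_{n+1} = alpha x_n (1 - x_n) + beta`
(shared secret `(alpha, beta, x0)`; defaults `alpha` = 3.99, `beta` = 0 —
deep chaotic regime; the source publishes no key values). Floating-point
mod-1 addition is not exactly invertible, so masking operates on a 48-bit
fixed-point lattice: quantisation error is at most 2^-49 (far below sensor
resolution) and the round trip is then bit-exact, which the tests assert
with `identical()`. Privacy strength is scored by histogram Shannon entropy
(natural log, as printed; base-2 exposed). The privacy-budget mechanism —
additive Laplace noise of scale `sensitivity / epsilon` applied before
encoding — is a reconstruction: the source shows ε-indexed detection curves
without defining the mechanism, so only the monotone privacy–utility
tradeoff is asserted, never the printed AUC values. Authentication scores a
message by the negative mean absolute decode residual of a 16-symbol public
preamble; legitimate keys decode exactly, ≥1% key perturbations leave ≈1/3
residual, and the two score populations are disjoint, giving ROC AUC 1.0.

## Uncertainty machinery

Parameter uncertainty uses independent uniform draws over the published
sensitivity ranges (the source names ranges but no distributions; a
log-uniform option exists for rates spanning decades). Outputs are
summarised by mean, median and the 5th/95th percentiles (the 90% prediction
interval); which outputs the published intervals covered is unstated, so
the package tracks peak `w5`, time-to-peak and per-compartment AUCs. Failed
draws are counted and excluded with a reported failure rate (0 over the
published ranges). Sensitivity analysis is one-at-a-time, matching the
published sweep figures. Runs are independent and reduced by sample index,
so results are order-insensitive and bit-reproducible under (seed, n).

## Numerical choices

* **Integrator.** A Dormand–Prince 5(4) pair in C++ (Rcpp), relative
  tolerance 1e-8, absolute 1e-10, PI-like step control. Steps never cross a
  reporting grid point (default 1-min grid over 24 h), so reported states
  carry no dense-output interpolation error. The system is non-stiff at all
  published values (fastest rate 0.373 min^-1). The solver is hand-rolled
  because the deployment environment pins a package set without an ODE
  solver; it is validated against an analytic bi-exponential oracle
  (eigen-decomposition of the systemic pair, with the repeated-eigenvalue
  Jordan limit) and fixed-step Euler oracles on both full systems.
* **Oracle tolerances.** The forward Euler oracle at dt = 1e-3 min matches
  the adaptive peak `w5` to 0.1% as specified. For the *reverse* path the
  fast drain (0.373 min^-1) makes first-order Euler itself the accuracy
  bottleneck: its own error at dt = 1e-3 is ~1e-4, so the 1e-6 agreement is
  asserted at dt = 1e-5 over the transient window, where Euler's error
  clears the bar.
* **Negativity.** States in `[-10*atol, 0)` after an accepted step are
  clipped to zero; anything more negative aborts with diagnostics rather
  than being silently clipped.
* **Ties.** Peak extraction breaks ties by earliest time.
* **Degenerate inputs.** Zero-width sensitivity ranges pin parameters at
  their defaults; `omega_R = 0` or `g_f = 0` give identically zero
  trajectories; an empty trajectory is an error.

## Deployment arithmetic

The capsule profile calculator uses decimal (SI) byte prefixes — the
published 768 kB/s only reconstructs with 1 kB = 1000 B. The published
3.3 GB/hour and 2.9 GB/procedure do **not** follow from
768 kB/s × duration ÷ 10 (the arithmetic gives 2.765 GB/h raw and
2.21 GB/procedure compressed); the calculator reports the computed values
and does not force agreement. Frame counts (57 600 at 2 fps × 8 h) fall in
the published 50–60 k band.

## Known limitations

* No spatial (PDE) diffusion within the tumor cord and no cytotoxicity
  pharmacodynamics: only the compartmental ODEs are specified.
* The bioluminescence kinetics and the privacy-budget mechanism are
  documented reconstructions (injectable/composable so alternatives can be
  swapped).
* The chaotic masking layer is an obfuscation mechanism with empirical
  divergence and entropy properties; no cryptographic security claim is
  made or tested.
* The classifier itself (training, image data, explainability) is out of
  scope; the confidence generator is its stand-in.
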