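# Closed-form model equations shared by the simulator and the fitters.
# Units are fixed package-wide: mV, ms, nA, nC, mmol/L; rates in 1/s.

# exponent clamp: |x| <= 50 keeps exp() finite (exp(50) ~ 5e21) while leaving
# every physiologically reachable voltage untouched
.clamp_exp <- function(x, lim = 50) pmin(pmax(x, -lim), lim)

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

#' Two-state charge-movement parameters
#'
#' Bundles the parameters of a two-state intramembrane charge movement:
#' the Boltzmann charge distribution (`q_max`, `v_half`, `sigma`) and the
#' relaxation time at its peak (`tau_peak`, reached at `v_half`).
#'
#' @param q_max Maximal moveable charge, nC (> 0).
#' @param v_half Midpoint voltage at which half the charge has moved, mV.
#' @param sigma Boltzmann slope factor, mV (> 0); equals `kT/(q*delta)` where
#'   `delta` is the fraction of the membrane field sensed by the charge.
#' @param tau_peak Relaxation time constant at `v_half`, ms (> 0). Not a
#'   published quantity; it parametrises the bell-shaped tau/V relation.
#' @return An object of class `charge_movement_params`.
#' @examples
#' p <- charge_movement_params(q_max = 41, v_half = -57.6, sigma = 33.6,
#'                             tau_peak = 8)
#' boltzmann_charge(-57.6, p)  # Q_max / 2
#' @export
charge_movement_params <- function(q_max, v_half, sigma, tau_peak = 8) {
  .check_finite(q_max, "q_max"); .check_finite(v_half, "v_half")
  .check_finite(sigma, "sigma"); .check_finite(tau_peak, "tau_peak")
  if (q_max <= 0) stop("`q_max` must be > 0 (nC)", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0 (mV)", call. = FALSE)
  if (tau_peak <= 0) stop("`tau_peak` must be > 0 (ms)", call. = FALSE)
  structure(list(q_max = q_max, v_half = v_half, sigma = sigma,
                 tau_peak = tau_peak),
            class = "charge_movement_params")
}

#' @export
print.charge_movement_params <- function(x, ...) {
  cat(sprintf(
    "Two-state charge movement: Q_max %.3g nC, V_0.5 %.4g mV, sigma %.4g mV, tau_peak %.3g ms\n",
    x$q_max, x$v_half, x$sigma, x$tau_peak))
  invisible(x)
}

#' Boltzmann charge distribution Q(V)
#'
#' Steady-state charge moved at membrane potential `v`:
#' `Q(V) = Q_max / (1 + exp(-(V - V_0.5)/sigma))`.
#' Strictly increasing in `v`, bounded in (0, Q_max).
#'
#' @param v Membrane potential, mV (finite; vectorised).
#' @param p A [charge_movement_params()] object.
#' @return Charge in nC, same length as `v`.
#' @export
boltzmann_charge <- function(v, p) {
  stopifnot(inherits(p, "charge_movement_params"))
  .check_finite(v, "v")
  p$q_max / (1 + exp(.clamp_exp(-(v - p$v_half) / p$sigma)))
}

#' Equilibrium occupancy of the outer charge position
#'
#' The Boltzmann charge distribution normalised to (0, 1):
#' `Q(V)/Q_max`. Equals the steady-state probability that the mobile
#' charge sits in its outer position.
#'
#' @inheritParams boltzmann_charge
#' @return Fraction in (0, 1).
#' @export
equilibrium_outer_fraction <- function(v, p) {
  boltzmann_charge(v, p) / p$q_max
}

#' Unidirectional rate constants of the two-state charge movement
#'
#' Symmetric Eyring split: half the electrical field acts on each rate,
#' `k_out = exp(+(V - V_0.5)/(2 sigma)) / (2 tau_peak)` and
#' `k_in  = exp(-(V - V_0.5)/(2 sigma)) / (2 tau_peak)` (with `tau_peak` in
#' seconds). This form guarantees `k_out/(k_out + k_in)` equals
#' [equilibrium_outer_fraction()] and `1/(k_out + k_in)` equals
#' [relaxation_tau()] at every voltage. Exponents are clamped at +/-50.
#'
#' @inheritParams boltzmann_charge
#' @return A data frame with columns `v` (mV), `k_out` and `k_in` (1/s).
#' @export
rate_constants <- function(v, p) {
  stopifnot(inherits(p, "charge_movement_params"))
  .check_finite(v, "v")
  x <- .clamp_exp((v - p$v_half) / (2 * p$sigma))
  tau_s <- p$tau_peak / 1000
  data.frame(v = v,
             k_out = exp(x) / (2 * tau_s),
             k_in = exp(-x) / (2 * tau_s))
}

#' Relaxation time constant of the charge movement
#'
#' `tau(V) = tau_peak / cosh((V - V_0.5)/(2 sigma))`: a bell-shaped
#' function of voltage, maximal (`tau_peak`) at `V_0.5` and symmetric
#' about it. Identical to `1/(k_out + k_in)` from [rate_constants()].
#'
#' @inheritParams boltzmann_charge
#' @return Time constant in ms.
#' @export
relaxation_tau <- function(v, p) {
  stopifnot(inherits(p, "charge_movement_params"))
  .check_finite(v, "v")
  p$tau_peak / cosh(.clamp_exp((v - p$v_half) / (2 * p$sigma)))
}

#' Michaelis-type dose-response model
#'
#' @param k_half Apparent substrate affinity `K_0.5`, mmol/L (> 0): the
#'   concentration yielding half the maximal current.
#' @param i_max Maximal transport current, nA (negative for inward current).
#' @return An object of class `dose_response_model`.
#' @export
dose_response_model <- function(k_half, i_max) {
  .check_finite(k_half, "k_half"); .check_finite(i_max, "i_max")
  if (k_half <= 0) stop("`k_half` must be > 0 (mmol/L)", call. = FALSE)
  structure(list(k_half = k_half, i_max = i_max),
            class = "dose_response_model")
}

#' Transport current as a function of substrate concentration
#'
#' `I(S) = I_max * S / (S + K_0.5)`, algebraically identical to the
#' logistic form `I_0 = -I_max/(1 + S/K_0.5) + I_max` used when fitting
#' dose-response curves. `I(0) = 0`; `I -> I_max` as `S -> Inf`.
#'
#' @param s Substrate concentration, mmol/L (>= 0; vectorised).
#' @param m A [dose_response_model()] object.
#' @return Current in nA (inward currents negative).
#' @export
dose_response_current <- function(s, m) {
  stopifnot(inherits(m, "dose_response_model"))
  .check_finite(s, "s")
  if (any(s < 0)) stop("`s` must be >= 0 (mmol/L)", call. = FALSE)
  m$i_max * s / (s + m$k_half)
}

#' Transport efficiency |I_max| / K_0.5
#'
#' An index of transport capability at low substrate concentration,
#' reported as a positive magnitude in nA per mmol/L (published tables
#' print the ratio unsigned even though inward currents are negative).
#'
#' @param i_max Maximal current, nA (sign ignored).
#' @param k_half Apparent affinity, mmol/L (> 0).
#' @return Efficiency, nA/(mmol/L).
#' @export
transport_efficiency <- function(i_max, k_half) {
  .check_finite(i_max, "i_max"); .check_finite(k_half, "k_half")
  if (any(k_half <= 0)) stop("`k_half` must be > 0", call. = FALSE)
  abs(i_max) / k_half
}

#' Ratio of two apparent affinities
#'
#' Used to compare K_0.5 across pH conditions (e.g. pH 7.6 over pH 6.5).
#' Note that ratios published alongside rounded K_0.5 values were computed
#' from the unrounded estimates, so recomputing from table entries can
#' differ in the last decimal (e.g. 6.92/0.24 = 28.83 but 2.22/0.13 =
#' 17.08 vs a printed 17.07).
#'
#' @param k_a,k_b Affinities, mmol/L (> 0).
#' @return `k_a / k_b` (dimensionless).
#' @export
affinity_ratio <- function(k_a, k_b) {
  .check_finite(k_a, "k_a"); .check_finite(k_b, "k_b")
  if (any(k_a <= 0) || any(k_b <= 0)) {
    stop("affinities must be > 0", call. = FALSE)
  }
  k_a / k_b
}

#' Physical constants at a given temperature
#'
#' @param temperature Absolute temperature, K (> 0). Default 295.15 K
#'   (22 degrees C, typical oocyte recording-room temperature).
#' @return An object of class `physical_constants` with fields
#'   `temperature` (K) and `thermal_voltage` (kT/q in mV).
#' @export
physical_constants <- function(temperature = 295.15) {
  .check_finite(temperature, "temperature")
  if (temperature <= 0) stop("`temperature` must be > 0 K", call. = FALSE)
  # kB/q = 8.617333262e-5 V/K (CODATA exact)
  structure(list(temperature = temperature,
                 thermal_voltage = 8.617333262e-2 * temperature),
            class = "physical_constants")
}

#' Fraction of the membrane electric field sensed by the moving charge
#'
#' Inverts the slope-factor relation `sigma = kT/(q*delta)`:
#' `delta = (kT/q) / sigma`.
#'
#' @param sigma Boltzmann slope factor, mV (> 0).
#' @param consts A [physical_constants()] object.
#' @return The dimensionless field fraction `delta`.
#' @export
field_fraction <- function(sigma, consts = physical_constants()) {
  stopifnot(inherits(consts, "physical_constants"))
  .check_finite(sigma, "sigma")
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  consts$thermal_voltage / sigma
}
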