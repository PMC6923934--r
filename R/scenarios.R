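# Transport scenarios: voltage-resolved dose-response surfaces anchored at
# two reference potentials, plus passive oocyte properties.

#' Passive oocyte (cell) parameters
#'
#' Endogenous, transporter-independent properties of the clamped oocyte:
#' membrane capacitance and the time constant of its charging transient,
#' plus an ohmic leak. Values are unconstrained by published tables;
#' defaults are typical for stage V-VI *Xenopus* oocytes.
#'
#' @param c_m Membrane capacitance, nF (> 0).
#' @param tau_cap Capacitive (clamp-charging) time constant, ms (> 0).
#' @param g_leak Leak conductance, uS (> 0).
#' @param e_leak Leak reversal potential, mV.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(c_m = 220, tau_cap = 0.8, g_leak = 1, e_leak = -20) {
  .check_finite(c(c_m, tau_cap, g_leak, e_leak), "cell parameters")
  if (c_m < 0 || g_leak < 0) stop("`c_m` and `g_leak` must be >= 0",
                                  call. = FALSE)
  if (tau_cap <= 0) stop("`tau_cap` must be > 0 (ms)", call. = FALSE)
  structure(list(c_m = c_m, tau_cap = tau_cap, g_leak = g_leak,
                 e_leak = e_leak),
            class = "cell_params")
}

#' Voltage-resolved transport scenario
#'
#' Encodes the substrate dose-response surface of a transporter at one pH:
#' `K_0.5(V) = K_ref * exp(k_slope * (V - V_ref))` (log-linear affinity,
#' the minimal monotone form) and `I_max(V) = I_ref + i_slope * (V - V_ref)`
#' (linear). Slopes are solved from two anchor points, typically the
#' published -60 and -120 mV table entries.
#'
#' @param label Scenario name.
#' @param ph Extracellular pH (metadata).
#' @param anchors Data frame with columns `v` (mV), `k_half` (mmol/L, > 0)
#'   and `i_max` (nA); exactly two rows at distinct voltages.
#' @param sodium_free Metadata flag: recording in sodium-free (TMA) solution.
#'   Transport is sodium-independent, so this flag never alters the
#'   simulated currents.
#' @return An object of class `transport_scenario`.
#' @export
transport_scenario <- function(label, ph, anchors, sodium_free = FALSE) {
  stopifnot(is.data.frame(anchors),
            all(c("v", "k_half", "i_max") %in% names(anchors)))
  if (nrow(anchors) != 2 || anchors$v[1] == anchors$v[2]) {
    stop("`anchors` needs exactly two rows at distinct voltages",
         call. = FALSE)
  }
  if (any(anchors$k_half <= 0)) stop("anchor `k_half` must be > 0",
                                     call. = FALSE)
  dv <- anchors$v[2] - anchors$v[1]
  structure(list(label = label, ph = ph,
                 v_ref = anchors$v[1],
                 k_ref = anchors$k_half[1],
                 k_slope = log(anchors$k_half[2] / anchors$k_half[1]) / dv,
                 i_ref = anchors$i_max[1],
                 i_slope = (anchors$i_max[2] - anchors$i_max[1]) / dv,
                 anchors = anchors, sodium_free = isTRUE(sodium_free)),
            class = "transport_scenario")
}

#' @export
print.transport_scenario <- function(x, ...) {
  cat(sprintf(
    "Transport scenario '%s' (pH %g): K_0.5(%g mV) = %.3g mmol/L, I_max(%g mV) = %.4g nA\n",
    x$label, x$ph, x$v_ref, x$k_ref, x$v_ref, x$i_ref))
  invisible(x)
}

#' Scenario-implied K_0.5, I_max and current
#'
#' Evaluate the dose-response surface of a [transport_scenario()] at
#' arbitrary voltages: `scenario_k_half()` and `scenario_i_max()` give the
#' local Michaelis parameters, `scenario_current()` the steady transport
#' current at substrate concentration `s`.
#'
#' @param scenario A [transport_scenario()].
#' @param v Membrane potential, mV (vectorised).
#' @param s Substrate concentration, mmol/L (>= 0).
#' @return Numeric vector (mmol/L, nA, or nA respectively).
#' @export
scenario_k_half <- function(scenario, v) {
  stopifnot(inherits(scenario, "transport_scenario"))
  scenario$k_ref * exp(scenario$k_slope * (v - scenario$v_ref))
}

#' @rdname scenario_k_half
#' @export
scenario_i_max <- function(scenario, v) {
  stopifnot(inherits(scenario, "transport_scenario"))
  scenario$i_ref + scenario$i_slope * (v - scenario$v_ref)
}

#' @rdname scenario_k_half
#' @export
scenario_current <- function(scenario, v, s) {
  if (any(s < 0)) stop("`s` must be >= 0", call. = FALSE)
  scenario_i_max(scenario, v) * s / (s + scenario_k_half(scenario, v))
}

#' Preset transporter scenarios
#'
#' Named bundles of charge-movement and transport parameters for the
#' zebrafish PepT1a/PepT1b paralogues at pH 6.5 and 7.6, anchored to the
#' published Gly-Gln kinetic tables: K_0.5/I_max at -60 and -120 mV and
#' Boltzmann Q/V parameters (Q_max, V_0.5, sigma). `tau_peak` is not a
#' published value; all presets use the package default of 8 ms. The
#' PepT1b pH 7.6 I_max entries are encoded as inward (negative) currents.
#'
#' @return A named list; each element has components `charge`
#'   ([charge_movement_params()]) and `transport` ([transport_scenario()]).
#' @examples
#' pr <- scenario_presets()
#' scenario_k_half(pr$zfPepT1a_pH6.5$transport, -60)  # 0.24 mmol/L
#' @export
scenario_presets <- function() {
  mk <- function(label, ph, qmax, v50, sig, k60, i60, k120, i120) {
    list(charge = charge_movement_params(qmax, v50, sig, tau_peak = 8),
         transport = transport_scenario(
           label, ph,
           data.frame(v = c(-60, -120), k_half = c(k60, k120),
                      i_max = c(i60, i120))))
  }
  list(
    zfPepT1a_pH6.5 = mk("zfPepT1a_pH6.5", 6.5, 41, -57.6, 33.6,
                        0.24, -75.76, 0.45, -157.39),
    zfPepT1a_pH7.6 = mk("zfPepT1a_pH7.6", 7.6, 53, -110, 39.3,
                        6.92, -169.57, 3.61, -378.82),
    zfPepT1b_pH6.5 = mk("zfPepT1b_pH6.5", 6.5, 11, -108, 31.1,
                        0.13, -195.73, 0.13, -396.24),
    zfPepT1b_pH7.6 = mk("zfPepT1b_pH7.6", 7.6, 9.9, -119, 33.5,
                        2.22, -566.16, 1.01, -1142.30)
  )
}
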