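# Synthetic TEVC sweep generator. Each sweep is a sum of closed-form
# components, so the analysis chain (double-exponential isolation, charge
# integration, Boltzmann and logistic fits) is exactly correct on noiseless
# output and every derived quantity has a closed-form oracle.

.run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# lognormal factor with median 1 and coefficient of variation cv
.lognormal_scatter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Largest pre-steady-state peak current of a protocol/parameter pair
#'
#' The instantaneous peak of the transporter transient on a step to `V_new`
#' is `|dQ| / tau(V_new)` (nC/ms = uA, returned in nA). Useful to express
#' additive noise as a fraction of the largest transient ("1% peak noise").
#'
#' @param protocol A [build_protocol()] object.
#' @param charge A [charge_movement_params()] object.
#' @return Peak amplitude, nA.
#' @export
pss_peak_current <- function(protocol, charge) {
  q_h <- boltzmann_charge(protocol$v_hold, charge)
  dq_on <- boltzmann_charge(protocol$steps, charge) - q_h
  peak_on <- abs(dq_on) / relaxation_tau(protocol$steps, charge)
  peak_off <- abs(dq_on) / relaxation_tau(protocol$v_hold, charge)
  1000 * max(peak_on, peak_off)
}

#' Simulate one set of voltage-step sweeps
#'
#' Renders the full current trace for every step of `protocol`:
#' ohmic leak, a capacitive charging transient on each voltage transition,
#' the transporter pre-steady-state transient (single exponential whose
#' integral is the Boltzmann charge increment and whose time constant is
#' the two-state relaxation time at the post-step potential), the steady
#' substrate-evoked transport current, and additive Gaussian noise:
#'
#' `I(t) = g_leak (V(t) - E_leak) + I_cap(t) + I_pss(t) + I_tr(V(t), S) + eps(t)`
#'
#' with, on a transition of size `dV` at `t0`,
#' `I_cap(t) = C_m dV / tau_cap * exp(-(t - t0)/tau_cap)` and
#' `I_pss(t) = dQ / tau(V_new) * exp(-(t - t0)/tau(V_new))`,
#' `dQ = Q(V_new) - Q(V_prev)`. The pre-steady-state polarity therefore
#' follows the sign of `dQ` (depolarising and hyperpolarising steps give
#' opposite transients). `S = 0` simulates the sweep recorded in the
#' absence of substrate. Identical `seed` and inputs give bit-identical
#' output.
#'
#' @param protocol A [build_protocol()] object.
#' @param cell A [cell_params()] object; `NULL` disables leak and
#'   capacitive components.
#' @param charge A [charge_movement_params()] object; `NULL` disables the
#'   pre-steady-state component.
#' @param transport A [transport_scenario()]; `NULL` disables transport.
#' @param s Substrate concentration, mmol/L (>= 0).
#' @param noise_sd Additive Gaussian noise SD, nA.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param oocyte_id,batch_id Identifier strings carried in metadata.
#' @param substrate Substrate name (metadata).
#' @param scale Shared expression scaling applied to `Q_max` and `I_max`
#'   (one oocyte's functional expression level).
#' @return A `trace_set`: list with `protocol`, `time_ms`, `current`
#'   (samples x steps matrix, one column per step) and `metadata`.
#' @export
simulate_sweep <- function(protocol, cell = cell_params(), charge = NULL,
                           transport = NULL, s = 0, noise_sd = 0,
                           seed = NULL, oocyte_id = "oo1", batch_id = "b1",
                           substrate = "Gly-Gln", scale = 1) {
  stopifnot(inherits(protocol, "vs_protocol"))
  if (!is.null(cell)) stopifnot(inherits(cell, "cell_params"))
  if (!is.null(charge)) stopifnot(inherits(charge, "charge_movement_params"))
  if (!is.null(transport)) stopifnot(inherits(transport, "transport_scenario"))
  if (length(s) != 1 || !is.finite(s) || s < 0) {
    stop("`s` must be a single concentration >= 0", call. = FALSE)
  }
  t_ms <- protocol_times(protocol)
  seg <- protocol_segments(protocol)
  dt <- 1000 / protocol$sample_rate

  taus <- c(if (!is.null(cell) && cell$c_m > 0) cell$tau_cap,
            if (!is.null(charge))
              relaxation_tau(c(protocol$steps, protocol$v_hold), charge))
  if (length(taus) && min(taus) < 2 * dt) {
    warning(sprintf(
      "shortest transient tau (%.3g ms) is below 2 sampling intervals (%.3g ms); it cannot be resolved at this sample rate",
      min(taus), 2 * dt), call. = FALSE)
  }

  render_step <- function(v_step) {
    v_trace <- c(rep(protocol$v_hold, protocol$n_pre),
                 rep(v_step, protocol$n_pulse),
                 rep(protocol$v_hold, protocol$n_post))
    i <- numeric(length(t_ms))
    if (!is.null(cell)) i <- i + cell$g_leak * (v_trace - cell$e_leak)
    # transitions: edge times coincide with the first sample of the new level
    trans <- list()
    if (protocol$n_pulse > 0) {
      trans <- c(trans, list(list(idx = seg$pulse[1], from = protocol$v_hold,
                                  to = v_step)))
    }
    if (protocol$n_post > 0) {
      trans <- c(trans, list(list(idx = seg$post[1], from = v_step,
                                  to = protocol$v_hold)))
    }
    for (tr in trans) {
      tail_idx <- tr$idx:length(t_ms)
      trel <- t_ms[tail_idx] - t_ms[tr$idx]
      dv <- tr$to - tr$from
      if (!is.null(cell) && dv != 0 && cell$c_m > 0) {
        i[tail_idx] <- i[tail_idx] +
          cell$c_m * dv / cell$tau_cap * exp(-trel / cell$tau_cap)
      }
      if (!is.null(charge)) {
        dq <- scale * (boltzmann_charge(tr$to, charge) -
                         boltzmann_charge(tr$from, charge))
        if (dq != 0) {
          tau <- relaxation_tau(tr$to, charge)
          # nC/ms = uA -> nA
          i[tail_idx] <- i[tail_idx] + 1000 * dq / tau * exp(-trel / tau)
        }
      }
    }
    if (!is.null(transport) && s > 0) {
      i <- i + scale * scenario_current(transport, v_trace, s)
    }
    i
  }

  current <- .run_seeded(seed, {
    m <- vapply(protocol$steps, render_step, numeric(length(t_ms)))
    if (noise_sd > 0) {
      m <- m + stats::rnorm(length(m), 0, noise_sd)
    }
    m
  })
  current <- matrix(current, ncol = length(protocol$steps))
  colnames(current) <- paste0("step_", seq_along(protocol$steps))

  structure(list(
    protocol = protocol, time_ms = t_ms, current = current,
    metadata = list(
      ph = if (!is.null(transport)) transport$ph else NA_real_,
      substrate = substrate, concentration = s, with_substrate = s > 0,
      transport_associated = FALSE,
      sodium_free = if (!is.null(transport)) transport$sodium_free else FALSE,
      oocyte_id = oocyte_id, batch_id = batch_id,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      noise_sd = noise_sd, scale = scale)),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "TraceSet: %d sweeps x %d samples (%g Hz), oocyte %s, [S] = %g mmol/L%s\n",
    ncol(x$current), nrow(x$current), x$protocol$sample_rate,
    x$metadata$oocyte_id, x$metadata$concentration,
    if (isTRUE(x$metadata$transport_associated)) " (transport-associated)"
    else ""))
  invisible(x)
}

#' Simulate a multi-oocyte TEVC experiment
#'
#' For each oocyte, draws a shared expression factor (lognormal, median 1,
#' coefficient of variation `expression_scatter_cv`) applied identically to
#' `Q_max` and `I_max` — one cell expresses one amount of transporter — and
#' renders a with-substrate / without-substrate sweep pair. Deterministic
#' under `seed`.
#'
#' @inheritParams simulate_sweep
#' @param n_oocytes Number of oocytes (>= 1).
#' @param n_batches Number of donor-frog batches oocytes are assigned to
#'   (round robin; metadata only).
#' @param expression_scatter_cv CV of the oocyte-to-oocyte expression
#'   factor (>= 0; 0 makes all oocytes identical).
#' @return A list of length `n_oocytes`; each element has `with`,
#'   `without` (trace sets), `scale`, `oocyte_id`, `batch_id`.
#' @export
simulate_experiment <- function(n_oocytes = 5, n_batches = 1,
                                expression_scatter_cv = 0.2,
                                protocol = build_protocol(),
                                cell = cell_params(), charge = NULL,
                                transport = NULL, s = 1, noise_sd = 0,
                                seed = NULL) {
  stopifnot(n_oocytes >= 1, n_batches >= 1, expression_scatter_cv >= 0)
  .run_seeded(seed, {
    scales <- .lognormal_scatter(n_oocytes, expression_scatter_cv)
    lapply(seq_len(n_oocytes), function(k) {
      oid <- sprintf("oo%02d", k)
      bid <- sprintf("b%d", ((k - 1) %% n_batches) + 1)
      w <- simulate_sweep(protocol, cell, charge, transport, s = s,
                          noise_sd = noise_sd, seed = NULL, oocyte_id = oid,
                          batch_id = bid, scale = scales[k])
      wo <- simulate_sweep(protocol, cell, charge, transport, s = 0,
                           noise_sd = noise_sd, seed = NULL, oocyte_id = oid,
                           batch_id = bid, scale = scales[k])
      list(with = w, without = wo, scale = scales[k], oocyte_id = oid,
           batch_id = bid)
    })
  })
}

#' Simulate steady-state dose-response measurements
#'
#' Generates per-oocyte transport-associated current readings over a
#' concentration ladder, as obtained after trace subtraction and
#' steady-window averaging: `I = scale_oocyte * I_tr(V, S) * (1 + eps)`,
#' with `eps ~ N(0, noise_cv)` multiplicative measurement noise.
#'
#' @inheritParams simulate_experiment
#' @param transport A [transport_scenario()].
#' @param v Test potentials, mV (vectorised).
#' @param concentrations Substrate ladder, mmol/L (> 0).
#' @param noise_cv Multiplicative noise CV per reading.
#' @return Data frame with columns `oocyte`, `v`, `s`, `i`, `ph`.
#' @export
simulate_dose_points <- function(transport, v, concentrations,
                                 n_oocytes = 5, noise_cv = 0.05,
                                 expression_scatter_cv = 0, seed = NULL) {
  stopifnot(inherits(transport, "transport_scenario"),
            all(concentrations > 0), n_oocytes >= 1)
  grid <- expand.grid(s = concentrations, v = v,
                      oocyte = sprintf("oo%02d", seq_len(n_oocytes)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  .run_seeded(seed, {
    scales <- .lognormal_scatter(n_oocytes, expression_scatter_cv)
    names(scales) <- sprintf("oo%02d", seq_len(n_oocytes))
    ideal <- scenario_current(transport, grid$v, grid$s) *
      scales[grid$oocyte]
    eps <- if (noise_cv > 0) stats::rnorm(nrow(grid), 0, noise_cv) else 0
    data.frame(oocyte = grid$oocyte, v = grid$v, s = grid$s,
               i = unname(ideal * (1 + eps)), ph = transport$ph)
  })
}
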