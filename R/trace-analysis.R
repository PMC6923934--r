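# From raw sweeps to derived signals: transport-associated currents,
# steady-state I/V points, double-exponential isolation of pre-steady-state
# transients, charge and tau extraction.

#' Transport-associated currents by trace subtraction
#'
#' Pointwise difference of a with-substrate and a without-substrate sweep
#' set recorded under the same protocol on the same oocyte. Leak,
#' capacitive and pre-steady-state components cancel; the residual is the
#' substrate-evoked transport current (plus noise).
#'
#' @param with_sub,without_sub `trace_set` objects with identical protocols
#'   and sample counts, from the same oocyte.
#' @return A `trace_set` marked `transport_associated` in its metadata.
#' @export
subtract_traces <- function(with_sub, without_sub) {
  stopifnot(inherits(with_sub, "trace_set"),
            inherits(without_sub, "trace_set"))
  if (!protocols_equal(with_sub$protocol, without_sub$protocol)) {
    stop("protocols differ between the two trace sets", call. = FALSE)
  }
  if (!identical(dim(with_sub$current), dim(without_sub$current))) {
    stop("sample counts differ between the two trace sets", call. = FALSE)
  }
  if (!identical(with_sub$metadata$oocyte_id, without_sub$metadata$oocyte_id)) {
    stop("trace sets come from different oocytes", call. = FALSE)
  }
  out <- with_sub
  out$current <- with_sub$current - without_sub$current
  out$metadata$transport_associated <- TRUE
  out
}

#' Steady-state current per step
#'
#' Mean current over the last `window_ms` of each test pulse; by that time
#' transients several tau long have decayed (a window placed >= 10 tau
#' after the edge changes the mean by < 0.01%).
#'
#' @param trace A `trace_set` (usually transport-associated).
#' @param window_ms Averaging window, ms; must fit inside the pulse.
#' @return Data frame of I/V points: `v` (mV), `s` (mmol/L), `i` (nA),
#'   `ph`, `oocyte`.
#' @export
steady_state_current <- function(trace, window_ms = 100) {
  stopifnot(inherits(trace, "trace_set"))
  p <- trace$protocol
  n_win <- .n_samples(window_ms, p$sample_rate)
  if (n_win < 1 || n_win > p$n_pulse) {
    stop("`window_ms` must be positive and fit inside the pulse segment",
         call. = FALSE)
  }
  seg <- protocol_segments(p)
  idx <- utils::tail(seg$pulse, n_win)
  data.frame(v = p$steps,
             s = trace$metadata$concentration,
             i = colMeans(trace$current[idx, , drop = FALSE]),
             ph = trace$metadata$ph,
             oocyte = trace$metadata$oocyte_id)
}

# residual sum of squares for fixed (log tau_fast, log tau_slow) with
# baseline and amplitudes profiled out linearly (variable projection)
.varpro_eval <- function(ltaus, trel, y) {
  taus <- exp(ltaus)
  X <- cbind(1, exp(-trel / taus[1]), exp(-trel / taus[2]))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Double-exponential fit of a transient current segment
#'
#' Least-squares fit of
#' `baseline + A_f exp(-(t - t0)/tau_f) + A_s exp(-(t - t0)/tau_s)`
#' used to separate the fast endogenous capacitive transient from the
#' slower transporter pre-steady-state relaxation. Amplitudes and baseline
#' are profiled out linearly and the two time constants optimised by
#' Nelder-Mead from fixed starts (tau 1 and 10 ms), with three fixed
#' restart perturbations on non-convergence — the fit is deterministic for
#' given data. Components are labelled by time constant (`tau_fast <
#' tau_slow`); if the two taus differ by less than a factor of 2 the fit
#' is flagged unseparable.
#'
#' @param segment Current samples, nA.
#' @param time_ms Sample times, ms (same length as `segment`).
#' @param t0 Time of the step edge the amplitudes refer to, ms.
#' @param fit_start_ms Start of the fit window relative to `t0`; default
#'   one sampling interval (the edge sample is blanked).
#' @param fit_len_ms Length of the fit window; default to the end of the
#'   segment.
#' @param source `"on"` or `"off"` label carried into the result.
#' @return An object of class `transient_fit` with fields `baseline`,
#'   `a_fast`, `tau_fast`, `a_slow`, `tau_slow`, `rms` (residual RMS, nA),
#'   `converged`, `separable`, `source`, `n`.
#' @export
fit_transient <- function(segment, time_ms, t0, fit_start_ms = NULL,
                          fit_len_ms = NULL, source = c("on", "off")) {
  source <- match.arg(source)
  stopifnot(length(segment) == length(time_ms))
  dt <- stats::median(diff(time_ms))
  if (is.null(fit_start_ms)) fit_start_ms <- dt
  lo <- t0 + fit_start_ms - 1e-9
  hi <- if (is.null(fit_len_ms)) Inf else t0 + fit_start_ms + fit_len_ms + 1e-9
  keep <- time_ms >= lo & time_ms <= hi
  if (sum(keep) < 8) stop("fewer than 8 samples in the fit window",
                          call. = FALSE)
  trel <- time_ms[keep] - t0
  y <- segment[keep]

  # taus are confined to what the window can resolve: below ~dt/4 a
  # component is invisible, above ~1.5x the span it degenerates into the
  # baseline (A * tau then diverges)
  lb <- log(dt / 4)
  ub <- log(1.5 * (max(trel) - min(trel)))
  clamp_par <- function(p) pmin(pmax(p, lb), ub)
  obj <- function(p) .varpro_eval(clamp_par(p), trel, y)$rss

  starts <- list(log(c(1, 10)), log(c(0.5, 5)), log(c(2, 20)), log(c(0.3, 30)))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(clamp_par(st), obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- best$convergence == 0
  polish <- tryCatch(
    stats::optim(clamp_par(best$par), obj, method = "L-BFGS-B",
                 lower = lb, upper = ub,
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    converged <- converged || polish$convergence == 0
    best <- polish
  }
  sol <- .varpro_eval(clamp_par(best$par), trel, y)
  taus <- exp(clamp_par(best$par))
  amps <- sol$coef[2:3]
  amps[is.na(amps)] <- 0
  ord <- order(taus)
  taus <- taus[ord]; amps <- amps[ord]
  structure(list(baseline = unname(sol$coef[1]),
                 a_fast = unname(amps[1]), tau_fast = unname(taus[1]),
                 a_slow = unname(amps[2]), tau_slow = unname(taus[2]),
                 rms = sqrt(sol$rss / length(y)),
                 converged = converged,
                 separable = taus[2] / taus[1] >= 2,
                 source = source, n = length(y)),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf(
    "Transient fit (%s): baseline %.4g nA; fast %.4g nA / %.3g ms; slow %.4g nA / %.3g ms; RMS %.3g nA%s\n",
    x$source, x$baseline, x$a_fast, x$tau_fast, x$a_slow, x$tau_slow, x$rms,
    if (!x$separable) " [unseparable]" else ""))
  invisible(x)
}

#' Charge moved by the transporter (slow) component
#'
#' Analytic integral of the slow exponential, `Q = A_slow * tau_slow`,
#' converted from nA*ms to nC (factor 1e-3). The fast component is
#' discarded as the endogenous capacitive transient.
#'
#' @param fit A [fit_transient()] result.
#' @return Charge, nC (signed).
#' @export
extract_charge <- function(fit) {
  stopifnot(inherits(fit, "transient_fit"))
  fit$a_slow * fit$tau_slow * 1e-3
}

#' Q/V and tau/V points from a no-substrate sweep set
#'
#' Fits the on-transient (pulse segment) and the off-transient (return to
#' the holding potential) of every sweep with [fit_transient()]. For each
#' step potential `V != V_h` the Q and tau points come from the on
#' transient; at `V == V_h` no on-transient exists (the step is silent),
#' so tau is taken from the off transient of the step with the largest
#' off-response, and the Q point from the charge-conservation sum
#' `Q_on + Q_off` of that step (zero up to noise, since the off transient
#' returns the charge moved by the on transient). Charges are relative to
#' the holding potential; a Boltzmann fit absorbs the offset in `Q_0`.
#'
#' @param trace A no-substrate `trace_set`.
#' @param v_h Holding potential; defaults to the protocol's.
#' @param fit_start_ms,on_len_ms,off_len_ms Fit-window controls passed to
#'   [fit_transient()] (defaults: blank one sample, use the full segment).
#' @return A list with data frames `qv` (`v`, `q`, `oocyte`) and `tauv`
#'   (`v`, `tau`, `oocyte`), plus `on_fits`, `off_fits` and `off_source_v`
#'   (the step used for the holding-potential point).
#' @export
build_qv_tauv <- function(trace, v_h = trace$protocol$v_hold,
                          fit_start_ms = NULL, on_len_ms = NULL,
                          off_len_ms = NULL) {
  stopifnot(inherits(trace, "trace_set"))
  if (isTRUE(trace$metadata$with_substrate)) {
    stop("Q/V analysis requires sweeps recorded without substrate",
         call. = FALSE)
  }
  p <- trace$protocol
  if (p$n_post < 8) {
    stop("no off-transient segment available (post segment too short)",
         call. = FALSE)
  }
  seg <- protocol_segments(p)
  t_ms <- trace$time_ms
  t0_on <- t_ms[seg$pulse[1]]
  t0_off <- t_ms[seg$post[1]]
  oocyte <- trace$metadata$oocyte_id

  on_fits <- list(); off_fits <- list()
  for (k in seq_along(p$steps)) {
    y <- trace$current[, k]
    on_fits[[k]] <- fit_transient(y[seg$pulse], t_ms[seg$pulse], t0_on,
                                  fit_start_ms, on_len_ms, source = "on")
    off_fits[[k]] <- fit_transient(y[seg$post], t_ms[seg$post], t0_off,
                                   fit_start_ms, off_len_ms, source = "off")
  }
  q_on <- vapply(on_fits, extract_charge, numeric(1))
  q_off <- vapply(off_fits, extract_charge, numeric(1))
  # the step to V_h itself is transient-free: its "fit" is a degenerate
  # equal-tau cancellation pair, flagged unseparable; never trust those
  eligible <- which(vapply(off_fits, function(f) f$separable && f$converged,
                           logical(1)))
  if (!length(eligible)) {
    stop("no usable (separable, converged) off transient available",
         call. = FALSE)
  }
  star <- eligible[which.max(abs(q_off[eligible]))]

  qv <- data.frame(v = p$steps, q = q_on)
  tauv <- data.frame(v = p$steps,
                     tau = vapply(on_fits, function(f) f$tau_slow, numeric(1)))
  hold <- which(abs(p$steps - v_h) < 1e-9)
  if (length(hold)) {
    qv$q[hold] <- q_on[star] + q_off[star]
    tauv$tau[hold] <- off_fits[[star]]$tau_slow
  } else {
    qv <- rbind(qv, data.frame(v = v_h, q = q_on[star] + q_off[star]))
    tauv <- rbind(tauv, data.frame(v = v_h, tau = off_fits[[star]]$tau_slow))
    ord <- order(qv$v)
    qv <- qv[ord, ]; tauv <- tauv[ord, ]
  }
  qv$oocyte <- oocyte; tauv$oocyte <- oocyte
  rownames(qv) <- rownames(tauv) <- NULL
  list(qv = qv, tauv = tauv, on_fits = on_fits, off_fits = off_fits,
       off_source_v = p$steps[star])
}
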