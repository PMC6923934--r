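# Parameter estimation: Boltzmann Q/V fits, rate-constant reconstruction,
# per-voltage logistic dose-response fits, efficiency curves. All fits are
# unweighted least squares with fixed, deterministic starting values.

.nls_se <- function(fit, par_names) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  out <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
  if (!is.null(se)) out[names(se)] <- se
  out
}

#' Boltzmann fit of a Q/V relationship
#'
#' Fits `Q(V) = Q_0 + Q_max / (1 + exp(-(V - V_0.5)/sigma))` by least
#' squares (port algorithm; `sigma` constrained to (0, 200] mV). The
#' offset `Q_0` absorbs the arbitrary reference of charges integrated
#' relative to the holding potential. Starting values are a fixed rule:
#' `Q_max` = data range, `V_0.5` = mid-range voltage, `sigma` = voltage
#' span / 6, `Q_0` = minimum charge.
#'
#' @param qv Data frame with columns `v` (mV) and `q` (nC); at least five
#'   distinct voltages.
#' @return An object of class `boltzmann_fit`: `q_max`, `v_half`, `sigma`,
#'   `q0`, `se` (named vector), `converged`, `n`.
#' @export
fit_boltzmann <- function(qv) {
  stopifnot(is.data.frame(qv), all(c("v", "q") %in% names(qv)))
  qv <- qv[is.finite(qv$v) & is.finite(qv$q), ]
  if (length(unique(qv$v)) < 5) {
    stop("need at least 5 distinct voltages for a Boltzmann fit",
         call. = FALSE)
  }
  vspan <- diff(range(qv$v))
  start <- list(q0 = min(qv$q), q_max = max(diff(range(qv$q)), 1e-6),
                v_half = mean(range(qv$v)), sigma = vspan / 6)
  fit <- tryCatch(
    stats::nls(q ~ q0 + q_max / (1 + exp(-(v - v_half) / sigma)),
               data = qv, start = start, algorithm = "port",
               lower = c(q0 = -Inf, q_max = 1e-9, v_half = -Inf,
                         sigma = 1e-3),
               upper = c(q0 = Inf, q_max = Inf, v_half = Inf, sigma = 200),
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(q_max = NA_real_, v_half = NA_real_,
                          sigma = NA_real_, q0 = NA_real_,
                          se = stats::setNames(rep(NA_real_, 4),
                                               c("q0", "q_max", "v_half",
                                                 "sigma")),
                          converged = FALSE, n = nrow(qv)),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(q_max = unname(cf["q_max"]), v_half = unname(cf["v_half"]),
                 sigma = unname(cf["sigma"]), q0 = unname(cf["q0"]),
                 se = .nls_se(fit, c("q0", "q_max", "v_half", "sigma")),
                 converged = fit$convInfo$isConv, n = nrow(qv)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit: Q_max %.4g nC, V_0.5 %.4g mV, sigma %.4g mV (Q_0 %.3g; %s)\n",
    x$q_max, x$v_half, x$sigma, x$q0,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predicted charge from a Boltzmann fit
#'
#' @param object A [fit_boltzmann()] result.
#' @param v Voltages, mV.
#' @param ... Unused.
#' @return Fitted `Q(v)`, nC.
#' @export
predict.boltzmann_fit <- function(object, v, ...) {
  object$q0 + object$q_max /
    (1 + exp(.clamp_exp(-(v - object$v_half) / object$sigma)))
}

#' Normalise Q/V points to the fitted Boltzmann
#'
#' `(Q - Q_0)/Q_max`, mapping the fitted sigmoid onto (0, 1) with value
#' 0.5 at the fitted `V_0.5`.
#'
#' @param qv Data frame with columns `v`, `q`.
#' @param fit A converged [fit_boltzmann()] result.
#' @return `qv` with an added column `q_norm`.
#' @export
normalize_qv <- function(qv, fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!isTRUE(fit$converged)) stop("Boltzmann fit did not converge",
                                   call. = FALSE)
  qv$q_norm <- (qv$q - fit$q0) / fit$q_max
  qv
}

#' Reconstruct unidirectional rate constants from Q/V and tau/V
#'
#' At each measured voltage, the normalised Boltzmann value
#' `p_out = 1/(1 + exp(-(V - V_0.5)/sigma))` gives the equilibrium outer
#' occupancy, and the measured relaxation time splits it into
#' `k_out = p_out / tau` and `k_in = (1 - p_out) / tau` (tau converted to
#' seconds), so that `k_out + k_in = 1/tau` by construction.
#'
#' @param fit A converged [fit_boltzmann()] result.
#' @param tauv Data frame with columns `v` (mV) and `tau` (ms, > 0).
#' @return Data frame `v`, `p_out`, `k_out`, `k_in` (rates in 1/s).
#' @export
reconstruct_rate_constants <- function(fit, tauv) {
  stopifnot(inherits(fit, "boltzmann_fit"),
            is.data.frame(tauv), all(c("v", "tau") %in% names(tauv)))
  if (!isTRUE(fit$converged)) stop("Boltzmann fit did not converge",
                                   call. = FALSE)
  if (any(tauv$tau <= 0)) stop("all tau values must be > 0", call. = FALSE)
  p_out <- 1 / (1 + exp(.clamp_exp(-(tauv$v - fit$v_half) / fit$sigma)))
  tau_s <- tauv$tau / 1000
  data.frame(v = tauv$v, p_out = p_out,
             k_out = p_out / tau_s, k_in = (1 - p_out) / tau_s)
}

# one logistic fit; points: data.frame(s, i)
.fit_dose_one <- function(pts) {
  pts <- pts[is.finite(pts$s) & is.finite(pts$i) & pts$s >= 0, ]
  s_pos <- sort(unique(pts$s[pts$s > 0]))
  if (length(s_pos) < 4) {
    stop("need at least 4 distinct positive concentrations", call. = FALSE)
  }
  if (max(s_pos) / min(s_pos) < 10) {
    warning("concentration ladder spans less than one decade", call. = FALSE)
  }
  if (all(abs(pts$i) < 1e-12)) stop("all currents are zero", call. = FALSE)
  i_top <- pts$i[which.max(pts$s)][1]
  half_idx <- which.min(abs(pts$i - i_top / 2))
  start <- list(i_max = i_top,
                k_half = max(pts$s[half_idx], min(s_pos)))
  fit <- tryCatch(
    stats::nls(i ~ i_max * s / (s + k_half), data = pts, start = start,
               algorithm = "port",
               lower = c(i_max = -Inf, k_half = 1e-9),
               upper = c(i_max = Inf, k_half = Inf),
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(k_half = NA_real_, i_max = NA_real_,
                k_half_se = NA_real_, i_max_se = NA_real_,
                converged = FALSE, n = nrow(pts), max_s = max(s_pos)))
  }
  cf <- stats::coef(fit)
  se <- .nls_se(fit, c("i_max", "k_half"))
  list(k_half = unname(cf["k_half"]), i_max = unname(cf["i_max"]),
       k_half_se = unname(se["k_half"]), i_max_se = unname(se["i_max"]),
       converged = fit$convInfo$isConv, n = nrow(pts), max_s = max(s_pos))
}

#' Per-voltage logistic dose-response fits
#'
#' Fits `I(S) = I_max * S / (S + K_0.5)` by unweighted least squares for
#' each group of I/V points — per voltage, and per oocyte when an `oocyte`
#' column is present (each oocyte is an independent observation; summary
#' statistics are taken across oocytes afterwards, see
#' [summarize_dose_response()]). The saturation flag records whether the
#' tested ladder actually reached the fitted `K_0.5`; when it did not, the
#' estimate is an extrapolation with a wide standard error but it is
#' reported rather than refused.
#'
#' @param points Data frame with columns `s` (mmol/L), `i` (nA), `v` (mV),
#'   optionally `oocyte` and `ph`.
#' @return A data frame of class `dose_response_fits`: one row per group
#'   with `v`, `oocyte`, `ph`, `k_half`, `k_half_se`, `i_max`, `i_max_se`,
#'   `efficiency` (|I_max|/K_0.5), `n`, `saturated`, `converged`.
#' @export
fit_dose_response <- function(points) {
  stopifnot(is.data.frame(points), all(c("s", "i", "v") %in% names(points)))
  has_oocyte <- "oocyte" %in% names(points)
  key <- if (has_oocyte) interaction(points$v, points$oocyte, drop = TRUE)
         else factor(points$v)
  rows <- lapply(split(points, key), function(g) {
    f <- .fit_dose_one(g[, c("s", "i")])
    data.frame(v = g$v[1],
               oocyte = if (has_oocyte) g$oocyte[1] else NA_character_,
               ph = if ("ph" %in% names(g)) g$ph[1] else NA_real_,
               k_half = f$k_half, k_half_se = f$k_half_se,
               i_max = f$i_max, i_max_se = f$i_max_se,
               efficiency = if (is.na(f$k_half)) NA_real_
                            else transport_efficiency(f$i_max, f$k_half),
               n = f$n,
               saturated = !is.na(f$k_half) && f$max_s >= f$k_half,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$v, out$oocyte), ]
  class(out) <- c("dose_response_fits", "data.frame")
  out
}

#' Summarise per-oocyte dose-response fits across oocytes
#'
#' Mean and SEM of `K_0.5` and `I_max` per voltage, each oocyte counting
#' as one independent observation, with the efficiency recomputed from the
#' mean parameters (as done for published summary tables).
#'
#' @param fits A [fit_dose_response()] result with per-oocyte rows.
#' @return Data frame `v`, `k_half`, `k_half_sem`, `i_max`, `i_max_sem`,
#'   `efficiency`, `n_oocytes`.
#' @export
summarize_dose_response <- function(fits) {
  stopifnot(inherits(fits, "dose_response_fits"))
  rows <- lapply(split(as.data.frame(fits), fits$v), function(g) {
    n <- sum(is.finite(g$k_half))
    data.frame(v = g$v[1],
               k_half = mean(g$k_half, na.rm = TRUE),
               k_half_sem = stats::sd(g$k_half, na.rm = TRUE) / sqrt(n),
               i_max = mean(g$i_max, na.rm = TRUE),
               i_max_sem = stats::sd(g$i_max, na.rm = TRUE) / sqrt(n),
               efficiency = transport_efficiency(
                 mean(g$i_max, na.rm = TRUE), mean(g$k_half, na.rm = TRUE)),
               n_oocytes = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$v), ]
}

#' Transport-efficiency curve
#'
#' `|I_max|/K_0.5` per voltage from a set of dose-response fits (no
#' smoothing). With per-oocyte fits the curve uses the cross-oocyte
#' summary.
#'
#' @param fits A [fit_dose_response()] result (at least two voltages).
#' @return Data frame `v`, `efficiency`.
#' @export
efficiency_curve <- function(fits) {
  stopifnot(inherits(fits, "dose_response_fits"))
  if (length(unique(fits$v)) < 2) {
    stop("need fits at two or more voltages", call. = FALSE)
  }
  sm <- summarize_dose_response(fits)
  data.frame(v = sm$v, efficiency = sm$efficiency)
}
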