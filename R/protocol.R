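# Voltage-step protocol: holding segment, square test pulse, return segment.

# samples per segment: round half up so duration*rate maps to a unique count
.n_samples <- function(ms, rate) {
  n <- floor(ms * rate / 1000 + 0.5)
  as.integer(n)
}

#' Build a voltage-step protocol
#'
#' Describes the classical TEVC step protocol: the membrane is held at
#' `v_hold`, stepped to each test potential for `pulse_ms`, then returned
#' to `v_hold`. The default reproduces the standard 10-pulse protocol
#' (holding -60 mV; steps -140 to +20 mV in 20 mV increments; 700 ms
#' pulses). Pre/post holding segments (100 / 300 ms) are package defaults:
#' published protocols specify only the pulse.
#'
#' @param v_hold Holding potential, mV.
#' @param start,stop,increment First/last step potentials and increment, mV.
#'   `(stop - start)/increment` must be integral; `increment` may not be 0
#'   unless `start == stop`.
#' @param pulse_ms Test-pulse duration, ms (> 0).
#' @param sample_rate Sampling rate, Hz (> 0).
#' @param pre_ms,post_ms Holding-segment durations before/after the pulse, ms.
#' @return An object of class `vs_protocol` with fields `v_hold`, `steps`,
#'   `pre_ms`, `pulse_ms`, `post_ms`, `sample_rate` and the per-segment
#'   sample counts `n_pre`, `n_pulse`, `n_post`.
#' @examples
#' p <- build_protocol()
#' p$steps   # -140, -120, ..., +20
#' @export
build_protocol <- function(v_hold = -60, start = -140, stop = 20,
                           increment = 20, pulse_ms = 700,
                           sample_rate = 1000, pre_ms = 100, post_ms = 300) {
  .check_finite(c(v_hold, start, stop, increment, pulse_ms, sample_rate,
                  pre_ms, post_ms), "protocol arguments")
  if (pulse_ms <= 0) stop("`pulse_ms` must be > 0", call. = FALSE)
  if (sample_rate <= 0) stop("`sample_rate` must be > 0", call. = FALSE)
  if (pre_ms < 0 || post_ms < 0) stop("segment durations must be >= 0",
                                      call. = FALSE)
  if (start == stop) {
    steps <- start
  } else {
    if (increment == 0) stop("`increment` must be non-zero", call. = FALSE)
    k <- (stop - start) / increment
    if (abs(k - round(k)) > 1e-9 || k < 0) {
      stop("(stop - start)/increment must be a non-negative integer",
           call. = FALSE)
    }
    steps <- seq(start, stop, by = increment)
  }
  structure(list(v_hold = v_hold, steps = steps,
                 pre_ms = pre_ms, pulse_ms = pulse_ms, post_ms = post_ms,
                 sample_rate = sample_rate,
                 n_pre = .n_samples(pre_ms, sample_rate),
                 n_pulse = .n_samples(pulse_ms, sample_rate),
                 n_post = .n_samples(post_ms, sample_rate)),
            class = "vs_protocol")
}

#' @export
print.vs_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage-step protocol: V_h %g mV; %d steps (%g to %g mV); %g ms pulse; %g Hz\n",
    x$v_hold, length(x$steps), min(x$steps), max(x$steps), x$pulse_ms,
    x$sample_rate))
  invisible(x)
}

# shared sample time base, ms; first sample at t = 0
protocol_times <- function(protocol) {
  n <- protocol$n_pre + protocol$n_pulse + protocol$n_post
  (seq_len(n) - 1) * 1000 / protocol$sample_rate
}

# index ranges of the three segments
protocol_segments <- function(protocol) {
  n1 <- protocol$n_pre; n2 <- protocol$n_pulse; n3 <- protocol$n_post
  list(pre = seq_len(n1),
       pulse = n1 + seq_len(n2),
       post = n1 + n2 + seq_len(n3))
}

protocols_equal <- function(a, b, tol = 1e-9) {
  inherits(a, "vs_protocol") && inherits(b, "vs_protocol") &&
    length(a$steps) == length(b$steps) &&
    all(abs(a$steps - b$steps) < tol) &&
    abs(a$v_hold - b$v_hold) < tol &&
    abs(a$sample_rate - b$sample_rate) < tol &&
    a$n_pre == b$n_pre && a$n_pulse == b$n_pulse && a$n_post == b$n_post
}
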