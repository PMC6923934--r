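# Shared fixtures, built in code.

# zfPepT1a pH 6.5 parameter set used throughout (anchored to the published
# kinetic tables)
pepa65 <- function() scenario_presets()$zfPepT1a_pH6.5
pepa76 <- function() scenario_presets()$zfPepT1a_pH7.6

# standard ladder of test concentrations, mmol/L
conc_ladder <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10)

expect_rel <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}

# compact protocol for fast simulator tests (full physics, fewer samples)
small_protocol <- function(...) {
  build_protocol(pulse_ms = 200, pre_ms = 50, post_ms = 100, ...)
}

# hand-built trace set with arbitrary current columns
make_trace <- function(protocol, current, s = 0, oocyte = "oo1") {
  structure(list(
    protocol = protocol, time_ms = tevckit:::protocol_times(protocol),
    current = current,
    metadata = list(ph = 6.5, substrate = "Gly-Gln", concentration = s,
                    with_substrate = s > 0, transport_associated = FALSE,
                    sodium_free = FALSE, oocyte_id = oocyte, batch_id = "b1",
                    seed = NA_integer_, noise_sd = 0, scale = 1)),
    class = "trace_set")
}
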