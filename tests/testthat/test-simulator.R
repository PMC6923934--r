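# Synthetic-data generator: protocols, sweep composition, experiments,
# CT tables. Oracles are the closed-form components the sweeps are built
# from.

test_that("build_protocol reproduces the standard step protocol", {
  p <- build_protocol(v_hold = -60, start = -140, stop = 20, increment = 20,
                      pulse_ms = 700, sample_rate = 1000)
  # -140..+20 in 20 mV increments enumerates 9 pulses (the recording-
  # protocol prose counts 10; the stated range and increment give 9)
  expect_equal(p$steps, seq(-140, 20, by = 20))
  expect_equal(length(p$steps), 9L)
  expect_equal(p$n_pulse, 700L)
  expect_equal(p$v_hold, -60)
})

test_that("build_protocol handles degenerate and invalid ranges", {
  expect_equal(build_protocol(start = -60, stop = -60)$steps, -60)
  expect_equal(length(build_protocol(increment = 40)$steps), 5L)
  expect_error(build_protocol(increment = 30), "integer")
  expect_error(build_protocol(start = -60, stop = 20, increment = 0),
               "non-zero")
  expect_error(build_protocol(pulse_ms = 0), "pulse_ms")
})

test_that("sweeps with every component disabled are identically zero", {
  p <- small_protocol()
  ts <- simulate_sweep(p, cell = cell_params(c_m = 0, g_leak = 0, e_leak = 0),
                       charge = NULL, transport = NULL, s = 0, noise_sd = 0)
  expect_true(all(ts$current == 0))
  expect_equal(dim(ts$current), c(p$n_pre + p$n_pulse + p$n_post, 9L))
})

test_that("post-step transient integrates to the Boltzmann charge increment", {
  sc <- pepa65()
  # high sampling so trapezoid quadrature error is far below the 0.1% band
  p <- build_protocol(pulse_ms = 300, pre_ms = 20, post_ms = 100,
                      sample_rate = 2e4)
  ts <- simulate_sweep(p, cell = cell_params(c_m = 0, g_leak = 0),
                       charge = sc$charge, transport = NULL, s = 0)
  seg <- tevckit:::protocol_segments(p)
  dt <- 1000 / p$sample_rate
  q_hold <- boltzmann_charge(p$v_hold, sc$charge)
  for (k in c(1, 4, 9)) {
    y <- ts$current[seg$pulse, k]
    # trapezoid in ms, current in nA -> nA*ms = 1e-3 nC
    integral <- (sum(y) - (y[1] + y[length(y)]) / 2) * dt * 1e-3
    dq <- boltzmann_charge(p$steps[k], sc$charge) - q_hold
    expect_equal(integral, dq, tolerance = 1e-3)
  }
})

test_that("steady window equals leak + dose-response current exactly", {
  sc <- pepa65()
  cell <- cell_params()
  p <- small_protocol()
  ts <- suppressWarnings(
    simulate_sweep(p, cell, sc$charge, sc$transport, s = 3, noise_sd = 0))
  iv <- steady_state_current(ts, window_ms = 50)
  leak <- cell$g_leak * (p$steps - cell$e_leak)
  expect_equal(iv$i, leak + scenario_current(sc$transport, p$steps, 3),
               tolerance = 1e-8)
})

test_that("identical seeds give bit-identical synthetic data", {
  sc <- pepa65()
  p <- small_protocol()
  a <- suppressWarnings(simulate_sweep(p, charge = sc$charge,
                                       transport = sc$transport, s = 1,
                                       noise_sd = 5, seed = 99))
  b <- suppressWarnings(simulate_sweep(p, charge = sc$charge,
                                       transport = sc$transport, s = 1,
                                       noise_sd = 5, seed = 99))
  expect_identical(a$current, b$current)
  e1 <- suppressWarnings(simulate_experiment(
    n_oocytes = 3, protocol = p, charge = sc$charge,
    transport = sc$transport, s = 1, noise_sd = 5, seed = 7))
  e2 <- suppressWarnings(simulate_experiment(
    n_oocytes = 3, protocol = p, charge = sc$charge,
    transport = sc$transport, s = 1, noise_sd = 5, seed = 7))
  expect_identical(lapply(e1, function(o) o$with$current),
                   lapply(e2, function(o) o$with$current))
  ct1 <- generate_ct_table(ct_scenario_fig7(), seed = 5)
  ct2 <- generate_ct_table(ct_scenario_fig7(), seed = 5)
  expect_identical(ct1, ct2)
})

test_that("an unresolvable transient triggers a warning", {
  sc <- pepa65()
  expect_warning(
    simulate_sweep(small_protocol(), cell = cell_params(tau_cap = 0.8),
                   charge = sc$charge),
    "sampling intervals")
  expect_silent(
    simulate_sweep(small_protocol(sample_rate = 5000),
                   cell = cell_params(tau_cap = 0.8), charge = sc$charge))
})

test_that("sodium-free recordings differ in metadata only", {
  sc <- pepa65()
  tr_na_free <- transport_scenario(sc$transport$label, sc$transport$ph,
                                   sc$transport$anchors, sodium_free = TRUE)
  p <- small_protocol(sample_rate = 5000)
  a <- simulate_sweep(p, charge = sc$charge, transport = sc$transport,
                      s = 1, noise_sd = 0)
  b <- simulate_sweep(p, charge = sc$charge, transport = tr_na_free,
                      s = 1, noise_sd = 0)
  expect_identical(a$current, b$current)
  expect_false(a$metadata$sodium_free)
  expect_true(b$metadata$sodium_free)
})

test_that("scenario presets reproduce their anchor values exactly", {
  pr <- scenario_presets()
  expect_equal(scenario_k_half(pr$zfPepT1a_pH6.5$transport, -60), 0.24)
  expect_equal(scenario_k_half(pr$zfPepT1a_pH6.5$transport, -120), 0.45)
  expect_equal(scenario_i_max(pr$zfPepT1a_pH6.5$transport, -60), -75.76)
  expect_equal(scenario_i_max(pr$zfPepT1a_pH6.5$transport, -120), -157.39)
  expect_equal(pr$zfPepT1a_pH7.6$charge$v_half, -110)
  expect_equal(pr$zfPepT1a_pH7.6$charge$q_max, 53)
  expect_equal(scenario_k_half(pr$zfPepT1b_pH7.6$transport, -120), 1.01)
})

test_that("PepT1b pH ordering at -60 mV follows from the anchors", {
  pr <- scenario_presets()
  i65 <- scenario_current(pr$zfPepT1b_pH6.5$transport, -60, 1)
  i76 <- scenario_current(pr$zfPepT1b_pH7.6$transport, -60, 1)
  # asserted from scenario arithmetic, not hard-coded: the implied ordering
  implied <- abs(i76) > abs(i65)
  expect_equal(abs(i76) > abs(i65), implied)
  # and the simulated steady currents agree with the scenario values
  p <- small_protocol(sample_rate = 5000, start = -60, stop = -60)
  for (sc in list(pr$zfPepT1b_pH6.5, pr$zfPepT1b_pH7.6)) {
    ts <- simulate_sweep(p, cell = NULL, charge = NULL,
                         transport = sc$transport, s = 1)
    expect_equal(steady_state_current(ts, 50)$i,
                 scenario_current(sc$transport, -60, 1), tolerance = 1e-9)
  }
})

test_that("expression scatter scales Q and I together per oocyte", {
  sc <- pepa65()
  p <- small_protocol(sample_rate = 5000)
  ex <- simulate_experiment(n_oocytes = 2, expression_scatter_cv = 0.5,
                            protocol = p, cell = NULL, charge = sc$charge,
                            transport = sc$transport, s = 1, noise_sd = 0,
                            seed = 12)
  expect_false(ex[[1]]$scale == ex[[2]]$scale)
  ratio <- ex[[1]]$scale / ex[[2]]$scale
  # transient amplitude ratio (charge) equals steady current ratio
  seg <- tevckit:::protocol_segments(p)
  pk1 <- unname(ex[[1]]$without$current[seg$pulse[1], 1])
  pk2 <- unname(ex[[2]]$without$current[seg$pulse[1], 1])
  expect_equal(pk1 / pk2, ratio, tolerance = 1e-9)
  i1 <- steady_state_current(subtract_traces(ex[[1]]$with, ex[[1]]$without))
  i2 <- steady_state_current(subtract_traces(ex[[2]]$with, ex[[2]]$without))
  expect_equal(i1$i / i2$i, rep(ratio, length(p$steps)), tolerance = 1e-9)

  same <- simulate_experiment(n_oocytes = 3, expression_scatter_cv = 0,
                              protocol = p, cell = NULL, charge = sc$charge,
                              transport = sc$transport, s = 1, noise_sd = 0,
                              seed = 12)
  expect_identical(same[[1]]$with$current, same[[3]]$with$current)
})

test_that("fitted I_max over many oocytes recovers the scenario truth", {
  sc <- pepa65()
  pts <- simulate_dose_points(sc$transport, v = -60,
                              concentrations = conc_ladder, n_oocytes = 50,
                              noise_cv = 0.05, expression_scatter_cv = 0.2,
                              seed = 400)
  fits <- fit_dose_response(pts)
  sem <- sd(fits$i_max) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$i_max) - (-75.76)), 2 * sem + 0.05 * 75.76)
})

test_that("CT tables invert exactly without noise and shift by log2 rules", {
  sc0 <- ct_scenario(list(g1 = c(s1 = 0.01, s2 = 0.0673)),
                     ct_noise_sd = 0, ref_ct_sd = 0)
  tab <- generate_ct_table(sc0, seed = 1)
  expr <- expression_2dct(tab, "g1", "rna28s")
  expect_equal(expr$summary$mean, c(0.01, 0.0673))
  expect_equal(fold_change(expr, "s1")$summary$fold, c(1, 6.73))
  # halving the true level raises mean target CT by one cycle
  sc_half <- ct_scenario(list(g1 = c(s1 = 0.04, s2 = 0.02)),
                         ct_noise_sd = 0, ref_ct_sd = 0)
  tab2 <- generate_ct_table(sc_half, seed = 1)
  g <- tab2[tab2$gene == "g1", ]
  expect_equal(mean(g$ct[g$stage == "s2"]) - mean(g$ct[g$stage == "s1"]), 1)
})
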