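# Parameter estimation: Boltzmann Q/V, rate reconstruction, logistic
# dose-response, efficiency. Truth values come from the preset scenarios.

qv_points <- function(p, v = seq(-140, 20, by = 20), offset = 0) {
  data.frame(v = v, q = boltzmann_charge(v, p) + offset)
}

test_that("fit_boltzmann recovers noiseless parameters to < 0.5%", {
  truth <- pepa65()$charge
  fit <- fit_boltzmann(qv_points(truth))
  expect_true(fit$converged)
  expect_rel(fit$q_max, truth$q_max, 5e-3)
  expect_rel(fit$sigma, truth$sigma, 5e-3)
  expect_lt(abs(fit$v_half - truth$v_half), 0.5)
})

test_that("a constant charge offset is absorbed by Q_0 alone", {
  truth <- pepa65()$charge
  f0 <- fit_boltzmann(qv_points(truth))
  f1 <- fit_boltzmann(qv_points(truth, offset = -19.77))
  expect_equal(f1$q_max, f0$q_max, tolerance = 1e-5)
  expect_equal(f1$v_half, f0$v_half, tolerance = 1e-5)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-5)
  expect_equal(f1$q0, f0$q0 - 19.77, tolerance = 1e-4)
  # midpoint identity of the fitted curve
  expect_equal(predict(f1, f1$v_half), f1$q0 + f1$q_max / 2)
  expect_error(fit_boltzmann(data.frame(v = c(-60, -40, -20, 0), q = 1:4)),
               "5 distinct")
})

test_that("normalize_qv maps the sigmoid onto (0, 1)", {
  truth <- pepa65()$charge
  qv <- qv_points(truth, offset = 4)
  fit <- fit_boltzmann(qv)
  nq <- normalize_qv(qv, fit)
  expect_true(all(nq$q_norm > 0 & nq$q_norm < 1))
  mid <- normalize_qv(data.frame(v = fit$v_half,
                                 q = predict(fit, fit$v_half)), fit)
  expect_equal(mid$q_norm, 0.5)
  # round trip
  expect_equal(nq$q_norm * fit$q_max + fit$q0, qv$q)
})

test_that("reconstructed rate constants obey the tau identity", {
  truth <- pepa65()$charge
  fit <- fit_boltzmann(qv_points(truth))
  # p_out = 0.5 at tau 10 ms -> 50/50
  rk_mid <- reconstruct_rate_constants(fit,
                                       data.frame(v = fit$v_half, tau = 10))
  expect_equal(rk_mid$k_out, 50, tolerance = 1e-3)
  expect_equal(rk_mid$k_in, 50, tolerance = 1e-3)
  v <- seq(-140, 20, by = 20)
  tauv <- data.frame(v = v, tau = relaxation_tau(v, truth))
  rk <- reconstruct_rate_constants(fit, tauv)
  expect_equal(rk$k_out + rk$k_in, 1000 / tauv$tau)
  expect_error(reconstruct_rate_constants(fit, data.frame(v = 0, tau = -1)),
               "> 0")
})

test_that("end-to-end rate reconstruction matches the closed form", {
  sc <- pepa65()
  ts <- suppressWarnings(simulate_sweep(build_protocol(),
                                        charge = sc$charge))
  res <- build_qv_tauv(ts)
  fit <- fit_boltzmann(res$qv)
  rk <- reconstruct_rate_constants(fit, res$tauv)
  truth <- rate_constants(rk$v, sc$charge)
  expect_rel(rk$k_out, truth$k_out, 0.02)
  expect_rel(rk$k_in, truth$k_in, 0.02)
})

test_that("fit_dose_response recovers noiseless kinetics to < 0.5%", {
  m <- dose_response_model(0.24, -75.76)
  pts <- data.frame(v = -60, s = conc_ladder,
                    i = dose_response_current(conc_ladder, m))
  fit <- fit_dose_response(pts)
  expect_true(fit$converged)
  expect_rel(fit$k_half, 0.24, 5e-3)
  expect_rel(fit$i_max, -75.76, 5e-3)
  expect_true(fit$saturated)
  expect_equal(fit$efficiency, transport_efficiency(fit$i_max, fit$k_half))
  # scaling currents scales I_max, K_0.5 unchanged
  pts2 <- pts; pts2$i <- 3 * pts2$i
  fit2 <- fit_dose_response(pts2)
  expect_equal(fit2$i_max, 3 * fit$i_max, tolerance = 1e-6)
  expect_equal(fit2$k_half, fit$k_half, tolerance = 1e-6)
})

test_that("non-saturating ladders are fitted but flagged", {
  m <- dose_response_model(6.92, -169.57)  # low-affinity condition
  s <- c(0.01, 0.03, 0.1, 0.3, 1, 3)      # max S < K_0.5
  pts <- data.frame(v = -60, s = s, i = dose_response_current(s, m))
  fit <- fit_dose_response(pts)
  expect_false(fit$saturated)
  expect_rel(fit$k_half, 6.92, 0.02)
  expect_error(fit_dose_response(data.frame(v = 0, s = c(1, 2, 3),
                                            i = c(-1, -2, -3))),
               "4 distinct")
  expect_error(fit_dose_response(data.frame(v = 0, s = conc_ladder,
                                            i = 0 * conc_ladder)), "zero")
})

test_that("fits are deterministic given the data", {
  m <- dose_response_model(0.45, -157.39)
  withr::with_seed(71, {
    pts <- data.frame(v = -120, s = rep(conc_ladder, 2),
                      i = dose_response_current(rep(conc_ladder, 2), m) *
                        (1 + rnorm(14, 0, 0.05)))
  })
  expect_identical(fit_dose_response(pts), fit_dose_response(pts))
  truth <- pepa65()$charge
  withr::with_seed(72, {
    qv <- qv_points(truth)
    qv$q <- qv$q + rnorm(nrow(qv), 0, 0.4)
  })
  expect_identical(unclass(fit_boltzmann(qv)), unclass(fit_boltzmann(qv)))
})

test_that("efficiency_curve reports |I_max|/K_0.5 per voltage", {
  sc <- pepa65()
  v <- c(-140, -120, -100, -80, -60, -40)
  pts <- do.call(rbind, lapply(v, function(vv) {
    m <- dose_response_model(scenario_k_half(sc$transport, vv),
                             scenario_i_max(sc$transport, vv))
    data.frame(v = vv, s = conc_ladder,
               i = dose_response_current(conc_ladder, m))
  }))
  fits <- fit_dose_response(pts)
  eff <- efficiency_curve(fits)
  expect_equal(eff$efficiency,
               transport_efficiency(scenario_i_max(sc$transport, eff$v),
                                    scenario_k_half(sc$transport, eff$v)),
               tolerance = 1e-4)
  # scenario oracle decides monotonicity, not hard-coded biology
  oracle <- transport_efficiency(scenario_i_max(sc$transport, v),
                                 scenario_k_half(sc$transport, v))
  expect_equal(order(eff$efficiency), order(oracle))
  # doubling I_max doubles every efficiency
  pts2 <- pts; pts2$i <- 2 * pts2$i
  eff2 <- efficiency_curve(fit_dose_response(pts2))
  expect_equal(eff2$efficiency, 2 * eff$efficiency, tolerance = 1e-6)
})

test_that("median recovery over noisy replicates stays within 5%", {
  truth <- pepa65()
  protocol <- build_protocol()
  peak <- pss_peak_current(protocol, truth$charge)
  run_once <- function(seed, noise_frac, noise_cv) {
    ts <- suppressWarnings(simulate_sweep(
      protocol, charge = truth$charge, noise_sd = noise_frac * peak,
      seed = seed))
    bf <- fit_boltzmann(build_qv_tauv(ts)$qv)
    pts <- simulate_dose_points(truth$transport, v = -60,
                                concentrations = conc_ladder, n_oocytes = 1,
                                noise_cv = noise_cv, seed = seed + 5000L)
    df <- fit_dose_response(pts)
    c(q_max = bf$q_max, v_half = bf$v_half, sigma = bf$sigma,
      k_half = df$k_half, i_max = df$i_max)
  }
  # 1% peak noise on the pre-steady-state traces, 5% multiplicative on the
  # dose-response readings
  reps <- vapply(1:20, function(k) run_once(800L + k, 0.01, 0.05),
                 numeric(5))
  med <- apply(reps, 1, median)
  expect_rel(med["q_max"], 41, 0.05)
  expect_lt(abs(med["v_half"] - (-57.6)), 2)
  expect_rel(med["sigma"], 33.6, 0.05)
  expect_rel(med["k_half"], 0.24, 0.05)
  expect_rel(med["i_max"], -75.76, 0.05)
  # bias shrinks as noise vanishes
  reps0 <- vapply(1:5, function(k) run_once(900L + k, 1e-4, 1e-4),
                  numeric(5))
  med0 <- apply(reps0, 1, median)
  expect_lt(abs(med0["k_half"] / 0.24 - 1), abs(med["k_half"] / 0.24 - 1))
  expect_lt(abs(med0["q_max"] / 41 - 1), abs(med["q_max"] / 41 - 1))
})
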