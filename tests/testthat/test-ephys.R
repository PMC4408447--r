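test_that("peak extraction returns the injected extremum", {
  prot <- voltage_protocol(c(-90, NA, -90), c(10, 30, 10), dt = 0.1,
                           sweep_segment = 2L, sweep_voltages = -20)
  t <- seq(0, 49.9, by = 0.1)
  cur <- numeric(length(t))
  cur[t >= 10 & t < 40] <- -500 * exp(-abs(t[t >= 10 & t < 40] - 12.3))
  ens <- trace_ensemble(t, matrix(cur), prot)
  pk <- peak_iv(ens)
  expect_equal(pk$peak_pA, -500)
  expect_equal(pk$t_peak_ms, 12.3)
  # flat traces give zero peaks
  ens0 <- trace_ensemble(t, matrix(0, length(t), 1), prot)
  expect_equal(peak_iv(ens0)$peak_pA, 0)
})

test_that("peaks of a noiseless simulated family match dense analytic evaluation", {
  p <- default_gating_params("WT")
  volts <- seq(-70, 10, by = 20)
  prot <- iv_protocol(step_voltages = volts, hold_ms = 20, step_ms = 100,
                      tail_ms = 20, dt = 0.1)
  iv <- peak_iv(simulate_deterministic(p, prot))
  t_dense <- seq(0, 140, by = 0.01)
  for (r in seq_len(nrow(iv))) {
    segs <- data.frame(voltage = c(-90, iv$voltage[r], -90),
                       duration = c(20, 100, 20))
    tr <- analytic_trace(p, segs, t_dense)
    in_step <- t_dense >= 20 & t_dense < 120
    analytic_peak <- tr[in_step][which.max(abs(tr[in_step]))]
    expect_equal(iv$peak_pA[r], analytic_peak,
                 tolerance = 5e-3, label = paste("V =", iv$voltage[r]))
  }
})

test_that("Boltzmann fit inverts noiseless synthetic current-voltage data", {
  V <- seq(-80, 40, by = 5)
  truth <- list(V_half = -44.2, k = 6, G_max = 2.5, V_rev = 60)
  I <- truth$G_max * (V - truth$V_rev) /
    (1 + exp((truth$V_half - V) / truth$k))
  fit <- fit_activation(data.frame(voltage = V, peak_pA = I), v_rev = 60)
  expect_equal(fit$V_half, truth$V_half, tolerance = 1e-7)
  expect_equal(fit$k, truth$k, tolerance = 1e-7)
  expect_equal(fit$G_max, truth$G_max, tolerance = 1e-7)
  # conductance mode on the same data
  fitg <- fit_activation(data.frame(voltage = V, peak_pA = I),
                         v_rev = 60, mode = "conductance")
  expect_equal(fitg$V_half, truth$V_half, tolerance = 1e-6)
  # normalized curve endpoints
  act <- predict(fit, data.frame(voltage = c(-120, 60)))
  expect_lt(act[1], 1e-4)
  expect_gt(act[2], 0.999)
})

test_that("mono-exponential fits are exact without noise and robust with it", {
  t <- seq(0, 200, by = 0.5)
  y <- -300 * exp(-t / 25) + 5
  f <- fit_exponential(t, y)
  expect_equal(f$tau, 25, tolerance = 1e-8)
  expect_equal(f$amplitude, -300, tolerance = 1e-6)
  expect_equal(f$offset, 5, tolerance = 1e-6)
  # seeded noise: within 5% of truth and within 2% of grid-search oracle
  set.seed(42)
  yn <- y + stats::rnorm(length(y), 0, 6)
  fn <- fit_exponential(t, yn)
  expect_lt(abs(fn$tau - 25) / 25, 0.05)
  tau_grid <- grid_tau_oracle(t, yn, seq(15, 40, by = 0.05))
  expect_lt(abs(fn$tau - tau_grid) / tau_grid, 0.02)
})

test_that("decay time constants show the ~10-fold mutant slowing", {
  volts <- seq(-50, 30, by = 20)
  prot <- iv_protocol(step_voltages = volts, hold_ms = 20,
                      step_ms = 1200, tail_ms = 10, dt = 0.5)
  tw <- fit_decay_tau(simulate_deterministic(default_gating_params("WT"),
                                             prot), c(-50, 30))
  tm <- fit_decay_tau(
    simulate_deterministic(default_gating_params("M1549V"), prot),
    c(-50, 30))
  expect_true(all(tw$converged))
  ratio <- tm$tau_ms / tw$tau_ms
  expect_true(all(ratio > 7.5 & ratio < 12.5))
  # noiseless single trace recovers its tau exactly
  p <- default_gating_params("WT")
  prot1 <- iv_protocol(step_voltages = -20, hold_ms = 20, step_ms = 300,
                       tail_ms = 10, dt = 0.1)
  tt <- fit_decay_tau(simulate_deterministic(p, prot1), c(-25, -15))
  # after the activation gates settle the decay is governed by the
  # inactivation time constant at the step voltage
  expect_equal(tt$tau_ms, p$tau_inact_ref, tolerance = 0.1)
  expect_true(tt$converged && tt$monotone)
})

test_that("fraction of non-inactivated current reproduces worked ratios", {
  expect_equal(fraction_noninactivated(-400, -26.8, -20)$summary_percent,
               6.7, tolerance = 1e-9)
  expect_equal(fraction_noninactivated(-400, -9.6, -20)$summary_percent,
               2.4, tolerance = 1e-9)
  r <- fraction_noninactivated(c(-100, -100), c(-100, -50), c(-90, -20))
  expect_equal(r$table$percent, c(100, 50))
  expect_equal(r$summary_percent, 50)   # most depolarized prepulse
  expect_error(fraction_noninactivated(0, -10, -20), "zero")
})

test_that("recovery fits invert noiseless envelopes and match the grid oracle", {
  t <- c(25, 50, 100, 200, 400, 800, 1600, 3200, 6400)
  for (tau_true in c(871.4, 1689.0)) {
    y <- 1 - exp(-t / tau_true)
    f <- fit_recovery(t, y)
    expect_equal(f$tau, tau_true, tolerance = 1e-6)
  }
  set.seed(42)
  y <- 1 - exp(-t / 871.4) + stats::rnorm(length(t), 0, 0.01)
  f <- fit_recovery(t, y)
  expect_lt(abs(f$tau - 871.4) / 871.4, 0.05)
  oracle <- grid_recovery_oracle(t, y, seq(500, 1500, by = 1))
  expect_lt(abs(f$tau - oracle) / oracle, 0.02)
  expect_error(fit_recovery(c(10, 20), c(0.1, 0.2)), "five")
})

test_that("window current grows when activation shifts hyperpolarized", {
  inact <- list(V_half = -70, k = 6)
  areas <- vapply(seq(-38.9, -44.2, by = -0.5), function(vh)
    window_current(list(V_half = vh, k = 6), inact)$area, 0)
  expect_true(all(diff(areas) > 0))   # strictly increasing along the shift
  # near-rectangular curves: overlap equals the plateau width
  act <- list(V_half = -50, k = 0.01)
  inact2 <- list(V_half = -30, k = 0.01)
  w <- window_current(act, inact2, v_grid = seq(-100, 20, by = 0.01))
  expect_equal(w$area, 20, tolerance = 0.05)
  # disjoint curves have (near) zero overlap
  w0 <- window_current(list(V_half = 0, k = 0.5),
                       list(V_half = -80, k = 0.5))
  expect_lt(w0$area, 1e-6)
})

test_that("current density is the capacitance-normalized peak", {
  expect_equal(current_density(-1000, 20), -50)
  expect_equal(current_density(0, 15), 0)
  expect_error(current_density(-100, NA), "capacitance")
  expect_error(current_density(-100, 0))
  # simulated variants: mutant median peak density below wild-type
  prot <- iv_protocol(step_voltages = -30, hold_ms = 20, step_ms = 100,
                      tail_ms = 10, dt = 0.1)
  dens <- function(p) {
    pk <- peak_iv(simulate_deterministic(p, prot))$peak_pA
    current_density(pk, 15)
  }
  expect_lt(abs(dens(default_gating_params("M1549V"))),
            abs(dens(default_gating_params("WT"))))
})

test_that("noise analysis rejects unusable ensembles", {
  p <- default_gating_params("WT")
  prot <- noise_protocol(hold_ms = 20, activate_ms = 10, tail_ms = 10,
                         dt = 0.1)
  ens <- simulate_stochastic(p, prot, n_sweeps = 20, seed = 1)
  expect_error(noise_analysis(ens), "at least")
  det <- simulate_deterministic(p, prot)
  # replicate the deterministic trace into many identical sweeps
  many <- trace_ensemble(det$time,
                         det$current[, rep(1, 120)], prot)
  expect_error(noise_analysis(many), "deterministic input")
})
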