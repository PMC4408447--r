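# High-level wrappers that chain the simulator and the analysis
# operations into the standard whole-cell protocols, so that a variant's
# full biophysical fingerprint can be computed in one call each.

# peak (signed extremum, baseline subtracted) within a protocol segment
peak_in_segment <- function(ensemble, segment, baseline_segment = 1L) {
  p <- ensemble$protocol
  win <- segment_window(p, segment)
  bwin <- segment_window(p, baseline_segment)
  in_seg <- ensemble$time >= win[1] & ensemble$time < win[2]
  in_base <- ensemble$time >= bwin[1] & ensemble$time < bwin[2]
  vapply(seq_len(ncol(ensemble$current)), function(s) {
    y <- ensemble$current[in_seg, s] -
      mean(ensemble$current[in_base, s])
    y[which.max(abs(y))]
  }, 0)
}

#' Fitted activation curve from a simulated IV family
#'
#' Runs the step protocol on the deterministic simulator, extracts the
#' peak current-voltage relation and fits the Boltzmann activation curve.
#'
#' @param params A [gating_params()] object.
#' @param step_voltages Step voltages (mV).
#' @param dt Sampling interval (ms).
#' @return A list with the [fit_activation()] result (`fit`), the
#'   `iv_table` (`iv`) and the ensemble.
#' @export
run_activation_fit <- function(params,
                               step_voltages = seq(-90, 50, by = 10),
                               dt = 0.1) {
  prot <- iv_protocol(step_voltages = step_voltages, dt = dt)
  ens <- simulate_deterministic(params, prot)
  iv <- peak_iv(ens)
  list(fit = fit_activation(iv, v_rev = params$V_rev), iv = iv,
       ensemble = ens)
}

#' Fraction of non-inactivated channels via the 5-s prepulse protocol
#'
#' Measures the test-pulse peak at -20 mV before and after 5-s prepulses
#' to a range of voltages on the deterministic simulator and reports the
#' percentage of current remaining, summarized at the most depolarized
#' prepulse.
#'
#' @param params A [gating_params()] object.
#' @param prepulse_voltages Prepulse voltages (mV), default -90..-20 in
#'   5 mV increments.
#' @param prepulse_ms Prepulse duration (ms), default 5000.
#' @param test_v Test voltage (mV), default -20.
#' @param dt Sampling interval (ms).
#' @return The [fraction_noninactivated()] result.
#' @export
run_fraction_noninactivated <- function(params,
                                        prepulse_voltages =
                                          seq(-90, -20, by = 5),
                                        prepulse_ms = 5000,
                                        test_v = -20, dt = 0.25) {
  pre_prot <- voltage_protocol(c(-90, test_v), c(200, 100), dt = dt)
  pre_ens <- simulate_deterministic(params, pre_prot)
  pre_peak <- peak_in_segment(pre_ens, 2L)
  post_prot <- voltage_protocol(c(-90, NA, test_v),
                                c(200, prepulse_ms, 100), dt = dt,
                                sweep_segment = 2L,
                                sweep_voltages = prepulse_voltages)
  post_ens <- simulate_deterministic(params, post_prot)
  post_peak <- peak_in_segment(post_ens, 3L)
  fraction_noninactivated(rep(pre_peak, length(post_peak)), post_peak,
                          prepulse_voltages)
}

#' Recovery from inactivation via the envelope protocol
#'
#' Inactivates channels with a 5-s pulse to -20 mV, holds at -90 mV for
#' increasing durations and measures the relative test-pulse peak at
#' -20 mV; the relative peaks against the recovery interval are fitted
#' with [fit_recovery()].
#'
#' @param params A [gating_params()] object.
#' @param intervals_ms Recovery intervals (ms).
#' @param dt Sampling interval (ms).
#' @return A list with `fit` (an `exp_fit`; `tau` is the recovery time
#'   constant) and `envelope` (data frame `interval_ms`, `rel_peak`).
#' @export
run_recovery <- function(params,
                         intervals_ms = c(25, 50, 100, 200, 400, 800,
                                          1600, 3200, 6400),
                         dt = 0.25) {
  rel <- vapply(intervals_ms, function(dt_rec) {
    prot <- voltage_protocol(c(-90, -20, -90, -20),
                             c(200, 5000, dt_rec, 100), dt = dt)
    ens <- simulate_deterministic(params, prot)
    peaks <- peak_in_segment_multi(ens, c(2L, 4L))
    peaks[2] / peaks[1]
  }, 0)
  env <- data.frame(interval_ms = intervals_ms, rel_peak = rel)
  list(fit = fit_recovery(env$interval_ms, env$rel_peak), envelope = env)
}

peak_in_segment_multi <- function(ensemble, segments) {
  vapply(segments, function(sg) peak_in_segment(ensemble, sg)[1], 0)
}

#' Unitary current by non-stationary noise analysis of simulated cells
#'
#' Simulates one or more "cells" (independent stochastic ensembles) under
#' the tail-current noise protocol and averages the unitary-current
#' estimates from [noise_analysis()].
#'
#' @param params A [gating_params()] object.
#' @param n_sweeps Sweeps per cell.
#' @param n_cells Number of independent cells.
#' @param seed Base seed; cell `c` uses `seed + c`.
#' @param dt Sampling interval (ms).
#' @return A list with `i_fA` (mean across cells), `per_cell` (vector)
#'   and the last cell's `noise_fit`.
#' @export
run_noise_unitary <- function(params, n_sweeps = 2000, n_cells = 4, seed,
                              dt = 0.2) {
  prot <- noise_protocol(dt = dt)
  fits <- lapply(seq_len(n_cells), function(cc) {
    ens <- simulate_stochastic(params, prot, n_sweeps = n_sweeps,
                               seed = seed + cc)
    noise_analysis(ens)
  })
  per_cell <- vapply(fits, function(f) f$i_fA, 0)
  list(i_fA = mean(per_cell), per_cell = per_cell,
       noise_fit = fits[[length(fits)]])
}

#' Full electrophysiological fingerprint of a variant
#'
#' Runs the activation, inactivation-fraction, recovery and (optionally)
#' noise-analysis pipelines for a parameter set and collects the headline
#' numbers.
#'
#' @param params A [gating_params()] object, e.g.
#'   [default_gating_params()].
#' @param seed Seed for the stochastic noise-analysis stage.
#' @param noise Logical: run the (slower) stochastic noise stage.
#' @param n_sweeps,n_cells Passed to [run_noise_unitary()].
#' @return A list with `V_half`, `k`, `fraction_noninactivated_pct`,
#'   `tau_rec_ms` and (when `noise`) `i_fA`.
#' @export
ephys_fingerprint <- function(params, seed = 1, noise = TRUE,
                              n_sweeps = 400, n_cells = 4) {
  act <- run_activation_fit(params)
  frac <- run_fraction_noninactivated(params)
  rec <- run_recovery(params)
  out <- list(V_half = act$fit$V_half, k = act$fit$k,
              fraction_noninactivated_pct = frac$summary_percent,
              tau_rec_ms = rec$fit$tau)
  if (noise)
    out$i_fA <- run_noise_unitary(params, n_sweeps = n_sweeps,
                                  n_cells = n_cells, seed = seed)$i_fA
  out
}
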