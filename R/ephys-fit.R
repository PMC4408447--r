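#' Peak current-voltage extraction
#'
#' For each sweep of an IV family, subtracts the baseline (mean current
#' over the holding segment preceding the step) and records the signed
#' extremum of current within the step window together with its time.
#' Inward currents are negative by the usual electrophysiological
#' convention, so the "peak" of an inward current is the most negative
#' sample.
#'
#' @param ensemble A [trace_ensemble()] whose protocol has a sweep-varying
#'   step segment.
#' @return A data frame of class `iv_table`: `voltage` (mV), `peak_pA`,
#'   `t_peak_ms` (relative to protocol start).
#' @export
peak_iv <- function(ensemble) {
  stopifnot(inherits(ensemble, "trace_ensemble"))
  p <- ensemble$protocol
  if (is.null(p) || is.na(p$sweep_segment))
    stop("protocol does not define a sweep-varying step segment")
  win <- segment_window(p, p$sweep_segment)
  if (win[2] > max(ensemble$time) + p$dt)
    stop("step window lies outside the recorded traces")
  base_win <- segment_window(p, p$sweep_segment - 1L)
  in_step <- ensemble$time >= win[1] & ensemble$time < win[2]
  in_base <- ensemble$time >= base_win[1] & ensemble$time < base_win[2]
  if (!any(in_step)) stop("step window contains no samples")
  volts <- ensemble$sweep_voltages
  rows <- lapply(seq_len(ncol(ensemble$current)), function(s) {
    tr <- ensemble$current[, s]
    baseline <- mean(tr[in_base])
    y <- tr[in_step] - baseline
    i_ext <- which.max(abs(y))
    data.frame(voltage = volts[s], peak_pA = y[i_ext],
               t_peak_ms = ensemble$time[in_step][i_ext])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("iv_table", class(out))
  out
}

#' Boltzmann fit of the voltage dependence of activation
#'
#' Fits the peak current-voltage relation with a Boltzmann activation
#' curve under a linear (ohmic) driving force,
#' `I(V) = G_max (V - V_rev) / (1 + exp((V_half - V)/k))`,
#' reporting the half-maximal activation voltage `V_half`, the slope
#' factor `k` and the maximal conductance `G_max`.  Alternatively
#' (`mode = "conductance"`) the currents are first converted to
#' conductances `G = I/(V - V_rev)` and the plain Boltzmann is fitted.
#' The reversal potential is fixed, not fitted.
#'
#' @param iv An `iv_table` from [peak_iv()], or any data frame with
#'   columns `voltage` and `peak_pA`.
#' @param v_rev Reversal potential (mV), default +60.
#' @param mode `"current"` (default) or `"conductance"`.
#' @param k_init Initial slope factor (mV).
#' @return An object of class `boltzmann_fit`: `V_half`, `k`, `G_max`
#'   (nS), `V_rev`, `residual_norm`, `converged`, `mode`, and the fitted
#'   data.
#' @export
fit_activation <- function(iv, v_rev = 60, mode = c("current",
                                                    "conductance"),
                           k_init = 6) {
  mode <- match.arg(mode)
  stopifnot(all(c("voltage", "peak_pA") %in% names(iv)))
  iv <- iv[order(iv$voltage), , drop = FALSE]
  if (nrow(iv) < 5)
    stop("at least five voltages spanning the rising phase are required")
  V <- iv$voltage
  I <- iv$peak_pA
  # data-driven initial values: half-amplitude crossing on the rising phase
  i_big <- which.max(abs(I))
  g_init <- I[i_big] / (V[i_big] - v_rev)          # nS (pA/mV)
  rising <- seq_len(i_big)
  half_idx <- rising[which.min(abs(abs(I[rising]) - abs(I[i_big]) / 2))]
  v_half_init <- V[half_idx]
  df <- data.frame(V = V, I = I, G = I / (V - v_rev))
  fit <- NULL
  converged <- FALSE
  if (mode == "current") {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ gmax * (V - v_rev) / (1 + exp((vh - V) / k)),
        data = df,
        start = list(gmax = g_init, vh = v_half_init, k = k_init),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        G ~ gmax / (1 + exp((vh - V) / k)),
        data = df,
        start = list(gmax = g_init, vh = v_half_init, k = k_init),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    cf <- c(gmax = g_init, vh = v_half_init, k = k_init)
    res_norm <- NA_real_
  } else {
    cf <- stats::coef(fit)
    res_norm <- sqrt(sum(stats::residuals(fit)^2))
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(list(V_half = unname(cf["vh"]), k = abs(unname(cf["k"])),
                 G_max = unname(cf["gmax"]), V_rev = v_rev,
                 residual_norm = res_norm, converged = converged,
                 mode = mode, data = df),
            class = "boltzmann_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann activation fit (", x$mode, " mode)\n",
      "  V_half = ", format(x$V_half, digits = 4), " mV,  k = ",
      format(x$k, digits = 3), " mV,  G_max = ",
      format(x$G_max, digits = 3), " nS (V_rev fixed at ",
      x$V_rev, " mV)\n",
      if (!x$converged) "  [fit did not converge]\n", sep = "")
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V_half = object$V_half, k = object$k, G_max = object$G_max)
}

#' Normalized Boltzmann activation curve
#'
#' @param object A `boltzmann_fit`.
#' @param newdata Optional data frame with a `voltage` column; defaults to
#'   the fitted voltages.
#' @param ... Unused.
#' @return Normalized open fraction in `[0, 1]` at each voltage.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$V else newdata$voltage
  1 / (1 + exp((object$V_half - V) / object$k))
}

#' Mono-exponential fit
#'
#' Fits `y(t) = amplitude * exp(-(t - t0)/tau) + offset` by nonlinear
#' least squares with a log-linear initial estimate.  Used for current
#' decay (inactivation) time constants and, through [fit_recovery()], for
#' recovery from inactivation.
#'
#' @param t Time values (ms).
#' @param y Signal values.
#' @param t0 Reference time subtracted from `t` (default `t[1]`).
#' @return An object of class `exp_fit`: `tau` (ms), `amplitude`,
#'   `offset`, `window` (range of `t`), `converged`.
#' @export
fit_exponential <- function(t, y, t0 = t[1]) {
  stopifnot(length(t) == length(y), length(t) >= 4)
  ts <- t - t0
  offset0 <- mean(y[ts >= max(ts) * 0.8])
  amp_sign <- sign(y[1] - offset0)
  z <- amp_sign * (y - offset0)
  pos <- z > max(z) * 1e-4
  tau0 <- if (sum(pos) >= 3) {
    cf <- stats::coef(stats::lm(log(z[pos]) ~ ts[pos]))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / unname(cf[2]) else max(ts) / 3
  } else max(ts) / 3
  amp0 <- amp_sign * max(z)
  df <- data.frame(ts = ts, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-ts / tau) + c0, data = df,
                      start = list(a = amp0, tau = tau0, c0 = offset0),
                      lower = c(-Inf, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(a = amp0, tau = tau0, c0 = offset0)
    converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["a"]),
                 offset = unname(cf["c0"]), window = range(t),
                 converged = converged),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Mono-exponential fit: tau = ", format(x$tau, digits = 4),
      " ms, amplitude = ", format(x$amplitude, digits = 3),
      ", offset = ", format(x$offset, digits = 3),
      if (!x$converged) "  [did not converge]", "\n", sep = "")
  invisible(x)
}

#' Inactivation time constants from current decay
#'
#' For each sweep whose step voltage lies in `voltage_range`, fits a
#' mono-exponential to the baseline-subtracted current from the time of
#' peak to the end of the step, yielding the inactivation time constant at
#' that voltage.  Sweeps whose decay is non-monotone beyond noise are
#' flagged (`converged = FALSE` or `monotone = FALSE`), not dropped.
#'
#' @param ensemble A [trace_ensemble()] with an IV-style protocol.
#' @param voltage_range Length-2 numeric: sweeps with step voltages inside
#'   this closed range are fitted (default `c(-50, 30)`).
#' @return A data frame of class `tau_table`: `voltage`, `tau_ms`,
#'   `amplitude`, `converged`, `monotone`.
#' @export
fit_decay_tau <- function(ensemble, voltage_range = c(-50, 30)) {
  stopifnot(inherits(ensemble, "trace_ensemble"))
  p <- ensemble$protocol
  if (is.null(p) || is.na(p$sweep_segment))
    stop("protocol does not define a sweep-varying step segment")
  win <- segment_window(p, p$sweep_segment)
  base_win <- segment_window(p, p$sweep_segment - 1L)
  in_step <- ensemble$time >= win[1] & ensemble$time < win[2]
  in_base <- ensemble$time >= base_win[1] & ensemble$time < base_win[2]
  volts <- ensemble$sweep_voltages
  keep <- which(volts >= voltage_range[1] & volts <= voltage_range[2])
  rows <- lapply(keep, function(s) {
    tr <- ensemble$current[, s] - mean(ensemble$current[in_base, s])
    tt <- ensemble$time[in_step]
    yy <- tr[in_step]
    i_peak <- which.max(abs(yy))
    tt <- tt[i_peak:length(yy)]; yy <- yy[i_peak:length(yy)]
    if (length(yy) < 8)
      return(data.frame(voltage = volts[s], tau_ms = NA_real_,
                        amplitude = NA_real_, converged = FALSE,
                        monotone = NA))
    f <- fit_exponential(tt, yy)
    # monotone decay check on a smoothed magnitude envelope
    sm <- stats::filter(abs(yy), rep(1 / 21, 21), sides = 2)
    sm <- sm[!is.na(sm)]
    monotone <- !any(diff(sm) > 0.02 * max(abs(yy)))
    data.frame(voltage = volts[s], tau_ms = f$tau,
               amplitude = f$amplitude, converged = f$converged,
               monotone = monotone)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tau_table", class(out))
  out
}

#' Fraction of non-inactivated channels after long prepulses
#'
#' Ratio (in percent) of the test-pulse peak current after a long
#' inactivating prepulse to the peak before it, per prepulse voltage;
#' magnitudes are used so that the sign convention of inward currents does
#' not matter.  The single-number summary is taken at the most depolarized
#' prepulse, where inactivation is maximal.
#'
#' @param pre_peaks Peak currents (pA) before the prepulse, one per
#'   prepulse voltage.
#' @param post_peaks Peak currents (pA) after the prepulse.
#' @param prepulse_voltages Prepulse voltages (mV).
#' @return A list with `table` (data frame `voltage`, `percent`) and
#'   `summary_percent` (value at the most depolarized prepulse).
#' @examples
#' fraction_noninactivated(-400, -26.8, -20)$summary_percent  # 6.7
#' @export
fraction_noninactivated <- function(pre_peaks, post_peaks,
                                    prepulse_voltages) {
  stopifnot(length(pre_peaks) == length(post_peaks),
            length(pre_peaks) == length(prepulse_voltages))
  if (any(pre_peaks == 0)) stop("pre-pulse peak current of zero")
  pct <- 100 * abs(post_peaks) / abs(pre_peaks)
  tab <- data.frame(voltage = prepulse_voltages, percent = pct)
  list(table = tab,
       summary_percent = pct[which.max(prepulse_voltages)])
}

#' Recovery from inactivation (envelope protocol fit)
#'
#' Fits `y(t) = y0 + a (1 - exp(-t/tau_rec))` to the relative test-pulse
#' peak amplitudes versus the time spent at the recovery potential,
#' returning the recovery time constant.
#'
#' @param interval_ms Recovery interval durations (ms), at least five.
#' @param rel_peak Relative peak amplitudes (post/pre).
#' @return An `exp_fit` whose `tau` is the recovery time constant;
#'   `amplitude` is the recovered fraction `a`, `offset` is `y0`.
#' @export
fit_recovery <- function(interval_ms, rel_peak) {
  stopifnot(length(interval_ms) == length(rel_peak))
  if (length(interval_ms) < 5)
    stop("at least five recovery intervals are required")
  o <- order(interval_ms)
  t <- interval_ms[o]; y <- rel_peak[o]
  # log-linear initialisation on the approach to the plateau
  plateau0 <- max(y)
  z <- plateau0 * 1.02 - y
  pos <- z > 0
  tau0 <- if (sum(pos) >= 3) {
    cf <- stats::coef(stats::lm(log(z[pos]) ~ t[pos]))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / unname(cf[2]) else max(t) / 3
  } else max(t) / 3
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + a * (1 - exp(-t / tau)), data = df,
                      start = list(y0 = min(y), a = plateau0 - min(y),
                                   tau = tau0),
                      lower = c(-Inf, 0, 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(y0 = min(y), a = plateau0 - min(y), tau = tau0)
    converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["a"]),
                 offset = unname(cf["y0"]), window = range(t),
                 converged = converged),
            class = "exp_fit")
}

#' Window current between activation and inactivation curves
#'
#' The steady window current arises in the voltage range where the
#' normalized activation and steady-state inactivation curves overlap, so
#' that a fraction of channels is persistently open.  The overlap is
#' quantified as the integral of `min(act(V), inact(V))` over a voltage
#' grid (trapezoidal rule), together with the voltage of maximal overlap.
#'
#' @param act A [fit_activation()] result, or a list with `V_half` and
#'   `k` (mV) describing a rising Boltzmann.
#' @param inact A list with `V_half` and `k` describing the falling
#'   steady-state inactivation Boltzmann.
#' @param v_grid Voltage grid (mV) for the numerical integral.
#' @return A list with `area` (mV, since the curves are dimensionless),
#'   `v_max_overlap` (mV) and the `overlap` curve.
#' @export
window_current <- function(act, inact, v_grid = seq(-100, 20, by = 0.1)) {
  act_curve <- 1 / (1 + exp((act$V_half - v_grid) / abs(act$k)))
  inact_curve <- 1 / (1 + exp((v_grid - inact$V_half) / abs(inact$k)))
  overlap <- pmin(act_curve, inact_curve)
  dv <- diff(v_grid)
  area <- sum((overlap[-1] + overlap[-length(overlap)]) / 2 * dv)
  list(area = area, v_max_overlap = v_grid[which.max(overlap)],
       overlap = data.frame(voltage = v_grid, overlap = overlap))
}

#' Whole-cell current density
#'
#' @param peak_pA Peak current (pA).
#' @param capacitance_pF Cell capacitance (pF), must be positive.
#' @return Current density in pA/pF.
#' @export
current_density <- function(peak_pA, capacitance_pF) {
  if (any(is.na(capacitance_pF)))
    stop("capacitance is required for current density")
  stopifnot(all(capacitance_pF > 0))
  peak_pA / capacitance_pF
}
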