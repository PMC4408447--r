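#' Voltage-clamp protocol
#'
#' An ordered sequence of constant-voltage segments.  Exactly one segment
#' may be sweep-varying, holding one voltage per sweep (the step segment of
#' an IV family or the prepulse of an inactivation protocol).
#'
#' @param voltages Numeric vector: the voltage (mV) of each segment.  For
#'   the sweep-varying segment supply `NA` here and the per-sweep voltages
#'   in `sweep_voltages`.
#' @param durations Segment durations in ms (same length as `voltages`).
#' @param dt Sampling interval in ms.
#' @param sweep_segment Index of the sweep-varying segment, or `NA` for a
#'   fixed protocol.
#' @param sweep_voltages Per-sweep voltages (mV) applied in the
#'   sweep-varying segment.
#' @return A list of class `voltage_protocol`.
#' @examples
#' iv_protocol()
#' @export
voltage_protocol <- function(voltages, durations, dt = 0.1,
                             sweep_segment = NA_integer_,
                             sweep_voltages = NULL) {
  stopifnot(length(voltages) == length(durations), all(durations > 0),
            dt > 0)
  if (!is.na(sweep_segment)) {
    stopifnot(sweep_segment >= 1, sweep_segment <= length(voltages),
              length(sweep_voltages) >= 1)
  }
  structure(list(voltages = voltages, durations = durations, dt = dt,
                 sweep_segment = sweep_segment,
                 sweep_voltages = sweep_voltages),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @param step_voltages Step voltages of the IV family (mV).
#' @param hold Holding potential (mV).
#' @param hold_ms,step_ms,tail_ms Segment durations (ms).
#' @export
iv_protocol <- function(step_voltages = seq(-90, 50, by = 10), hold = -90,
                        hold_ms = 50, step_ms = 300, tail_ms = 100,
                        dt = 0.1) {
  voltage_protocol(c(hold, NA, hold), c(hold_ms, step_ms, tail_ms),
                   dt = dt, sweep_segment = 2L,
                   sweep_voltages = step_voltages)
}

#' @rdname voltage_protocol
#' @param test_v Test/activation voltage (mV).
#' @param activate_ms Duration of the activating step (ms).
#' @export
noise_protocol <- function(hold = -90, test_v = -20, hold_ms = 100,
                           activate_ms = 50, tail_ms = 40, dt = 0.1) {
  voltage_protocol(c(hold, test_v, hold),
                   c(hold_ms, activate_ms, tail_ms), dt = dt)
}

n_sweeps <- function(protocol) {
  if (is.na(protocol$sweep_segment)) 1L else length(protocol$sweep_voltages)
}

# sample times (ms, from protocol start) and segment index of each sample
protocol_grid <- function(protocol) {
  total <- sum(protocol$durations)
  t <- seq(0, total - protocol$dt / 2, by = protocol$dt)
  edges <- cumsum(c(0, protocol$durations))
  seg <- findInterval(t, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  seg[seg > length(protocol$durations)] <- length(protocol$durations)
  list(t = t, seg = seg, edges = edges)
}

# start/end times of a segment
segment_window <- function(protocol, segment) {
  edges <- cumsum(c(0, protocol$durations))
  c(edges[segment], edges[segment + 1])
}

#' Ensemble of whole-cell current traces
#'
#' @param time Sample times (ms), uniform spacing.
#' @param current Numeric matrix of currents (pA), one column per sweep.
#' @param protocol The generating [voltage_protocol()].
#' @param capacitance Cell capacitance (pF), optional.
#' @param sweep_voltages Step voltage per sweep (mV); defaults to the
#'   protocol's sweep voltages.
#' @return A list of class `trace_ensemble`.
#' @export
trace_ensemble <- function(time, current, protocol, capacitance = NA_real_,
                           sweep_voltages = NULL) {
  current <- as.matrix(current)
  stopifnot(length(time) == nrow(current), length(time) >= 2)
  dt <- diff(time)
  stopifnot(all(abs(dt - dt[1]) < 1e-9), dt[1] > 0)
  if (is.null(sweep_voltages) && inherits(protocol, "voltage_protocol") &&
      !is.na(protocol$sweep_segment))
    sweep_voltages <- protocol$sweep_voltages
  structure(list(time = time, current = current, protocol = protocol,
                 capacitance = capacitance,
                 sweep_voltages = sweep_voltages),
            class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cat("Trace ensemble: ", ncol(x$current), " sweep(s) x ",
      nrow(x$current), " samples at dt = ",
      x$time[2] - x$time[1], " ms\n", sep = "")
  invisible(x)
}

#' Write / read a trace ensemble as TSV with a YAML protocol sidecar
#'
#' The TSV stores the time vector (ms) in column 1 and one sweep (pA) per
#' remaining column.  The sidecar (same path with extension
#' `.protocol.yaml`) stores the segment table, sampling interval, sweep
#' voltages and capacitance.
#'
#' @param ensemble A [trace_ensemble()].
#' @param path TSV file path.
#' @return `write_ensemble_tsv` returns `path` invisibly;
#'   `read_ensemble_tsv` returns a `trace_ensemble`.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trace_ensemble"))
  df <- data.frame(time_ms = ensemble$time, ensemble$current)
  names(df) <- c("time_ms", paste0("sweep", seq_len(ncol(ensemble$current))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (requireNamespace("yaml", quietly = TRUE)) {
    p <- ensemble$protocol
    side <- list(voltages_mV = as.numeric(p$voltages),
                 durations_ms = as.numeric(p$durations),
                 dt_ms = p$dt,
                 sweep_segment = p$sweep_segment,
                 sweep_voltages_mV = as.numeric(p$sweep_voltages),
                 capacitance_pF = ensemble$capacitance)
    yaml::write_yaml(side, paste0(path, ".protocol.yaml"))
  }
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  df <- utils::read.delim(path)
  sidecar <- paste0(path, ".protocol.yaml")
  protocol <- NULL
  capacitance <- NA_real_
  if (file.exists(sidecar) && requireNamespace("yaml", quietly = TRUE)) {
    s <- yaml::read_yaml(sidecar)
    protocol <- voltage_protocol(
      s$voltages_mV, s$durations_ms, dt = s$dt_ms,
      sweep_segment = if (is.null(s$sweep_segment)) NA_integer_
                      else s$sweep_segment,
      sweep_voltages = s$sweep_voltages_mV)
    if (!is.null(s$capacitance_pF)) capacitance <- s$capacitance_pF
  }
  trace_ensemble(df[[1]], as.matrix(df[, -1, drop = FALSE]), protocol,
                 capacitance = capacitance)
}
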