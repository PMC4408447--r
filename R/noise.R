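#' Non-stationary noise analysis of a trace ensemble
#'
#' Across many repetitions of an identical voltage protocol, the
#' channel-gating (Lorentzian) noise at each time point obeys
#' `sigma^2 = N i^2 p (1-p)` with macroscopic current `I = N p i`, giving
#' the parabolic variance-mean relation `sigma^2 = i <I> - <I>^2 / N`.
#' The unitary current `i` is the initial slope of the variance against
#' the mean isochronal current; when the open probability stays low only
#' the initial, nearly linear part of the parabola is sampled, which
#' still yields `i` but leaves `N` and `p` undetermined — in that case
#' this function deliberately refuses to report them.
#'
#' The variance of the holding segment preceding activation is regarded
#' as background variance and subtracted.
#'
#' @param ensemble A [trace_ensemble()] recorded at a fixed voltage
#'   protocol (no sweep-varying segment), typically the tail segment
#'   after an activating pulse.
#' @param analysis_segment Index of the protocol segment to analyse
#'   (default: the last segment, the tail pulse).
#' @param background_ms Length (ms) of the holding-segment window, ending
#'   at the activating step, used for background variance (default 50).
#' @param fit_fraction Points with `|mean current|` at or below this
#'   fraction of the maximal mean magnitude enter the initial-slope fit
#'   (default 0.3).
#' @param min_sweeps Minimum number of sweeps (default 100).
#' @return An object of class `noise_fit`: `i_fA` (unitary current
#'   magnitude, fA), `i_pA` (signed slope, pA), `background_var_pA2`,
#'   `fit_fraction`, `points` (data frame of isochronal `mean_pA`,
#'   `var_pA2`, `used`), `n_sweeps`, `n_channels` and `open_prob` (both
#'   `NA` with an explanatory `note` when curvature is unresolved).
#' @export
noise_analysis <- function(ensemble, analysis_segment = NULL,
                           background_ms = 50, fit_fraction = 0.3,
                           min_sweeps = 100) {
  stopifnot(inherits(ensemble, "trace_ensemble"))
  M <- ncol(ensemble$current)
  if (M < min_sweeps)
    stop("noise analysis requires at least ", min_sweeps, " sweeps")
  p <- ensemble$protocol
  if (is.null(p)) stop("ensemble carries no protocol")
  if (!is.na(p$sweep_segment))
    stop("noise analysis requires a fixed (non sweep-varying) protocol")
  if (is.null(analysis_segment)) analysis_segment <- length(p$voltages)
  awin <- segment_window(p, analysis_segment)
  # background: end of the first (holding) segment
  hwin <- segment_window(p, 1L)
  bg_start <- max(hwin[1], hwin[2] - background_ms)
  in_bg <- ensemble$time >= bg_start & ensemble$time < hwin[2]
  in_an <- ensemble$time >= awin[1] & ensemble$time < awin[2]
  if (!any(in_bg) || !any(in_an))
    stop("background or analysis window contains no samples")
  bg_var <- mean(apply(ensemble$current[in_bg, , drop = FALSE], 1,
                       stats::var))
  mean_t <- rowMeans(ensemble$current[in_an, , drop = FALSE])
  var_t <- apply(ensemble$current[in_an, , drop = FALSE], 1, stats::var)
  if (all(var_t < 1e-12))
    stop("deterministic input: ensemble variance is zero")
  # reference the mean current to its asymptote so the parabola passes
  # through the origin (fully deactivated level)
  baseline <- mean(ensemble$current[in_bg, , drop = FALSE])
  mean_c <- mean_t - baseline
  var_c <- var_t - bg_var
  used <- abs(mean_c) <= fit_fraction * max(abs(mean_c))
  if (sum(used) < 3)
    stop("too few points in the initial-slope region")
  fit <- stats::lm(var_c[used] ~ mean_c[used])
  slope <- unname(stats::coef(fit)[2])
  structure(list(i_fA = abs(slope) * 1000, i_pA = slope,
                 background_var_pA2 = bg_var,
                 fit_fraction = fit_fraction,
                 points = data.frame(time_ms = ensemble$time[in_an],
                                     mean_pA = mean_c, var_pA2 = var_c,
                                     used = used),
                 n_sweeps = M,
                 n_channels = NA_real_, open_prob = NA_real_,
                 note = paste("only the initial part of the variance-mean",
                              "parabola is sampled; N and p are not",
                              "determined")),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat("Non-stationary noise analysis (", x$n_sweeps, " sweeps)\n",
      "  unitary current |i| = ", format(x$i_fA, digits = 4), " fA\n",
      "  background variance = ",
      format(x$background_var_pA2, digits = 3), " pA^2\n",
      "  N, p: not determined (", x$note, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.noise_fit <- function(x, ...) {
  plot(x$points$mean_pA, x$points$var_pA2,
       col = ifelse(x$points$used, "black", "grey70"),
       xlab = "mean current (pA)", ylab = "variance (pA^2)", ...)
  graphics::abline(0, x$i_pA, lty = 2)
  invisible(x)
}
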