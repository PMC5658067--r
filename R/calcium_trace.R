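#' Construct a calcium trace
#'
#' A `calcium_trace` is a uniformly sampled fiber-photometry series, either
#' raw fluorescence (arbitrary units) or relative fluorescence change
#' (delta-f/f, unitless).
#'
#' @param values Numeric vector of samples; must be finite, length >= 2.
#' @param fs_hz Sampling rate in samples/second.
#' @param t0_s Time of the first sample in seconds.
#' @param units One of `"raw"` or `"dff"`.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(values, fs_hz, t0_s = 0, units = c("dff", "raw")) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("calcium_trace needs at least 2 samples")
  if (!all(is.finite(values))) stop("calcium_trace values must be finite")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0")
  structure(
    list(values = values, fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), units = units),
    class = "calcium_trace"
  )
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d samples @ %g Hz (%.1f s), units = %s\n",
              length(x$values), x$fs_hz, length(x$values) / x$fs_hz, x$units))
  invisible(x)
}

#' @export
length.calcium_trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param trace A `calcium_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$values) - 1L) / trace$fs_hz
}

#' Downsample a trace by block averaging
#'
#' Each output sample is the arithmetic mean of `factor` consecutive input
#' samples (the convention used to take 2 kHz photometry to 1 kHz).  Trailing
#' samples that do not fill a complete block are dropped.
#'
#' @param trace A `calcium_trace`.
#' @param factor Integer decimation factor (>= 1).
#' @return A `calcium_trace` at `fs_hz / factor`.
#' @export
downsample_by_averaging <- function(trace, factor = 2L) {
  stopifnot(inherits(trace, "calcium_trace"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  n <- length(trace$values)
  if (factor > n) stop("factor exceeds trace length")
  if (factor == 1L) return(trace)
  nout <- n %/% factor
  m <- matrix(trace$values[seq_len(nout * factor)], nrow = factor)
  calcium_trace(colMeans(m), fs_hz = trace$fs_hz / factor,
                t0_s = trace$t0_s, units = trace$units)
}

#' Convert raw fluorescence to delta-f/f
#'
#' Computes (f - f0)/f0 with f0 a rolling low-percentile baseline estimated
#' in shifted windows and spline-interpolated between window centers.
#'
#' @param trace A raw-unit `calcium_trace`.
#' @param baseline_window_s Window length in seconds for the rolling baseline.
#' @param prob Quantile used as the baseline within each window.
#' @return A `calcium_trace` with `units = "dff"`.
#' @export
compute_dff <- function(trace, baseline_window_s = 30, prob = 0.1) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (trace$units != "raw") stop("compute_dff expects a raw-unit trace")
  w <- max(2L, round(baseline_window_s * trace$fs_hz))
  f0 <- two_pass_baseline(trace$values, window = w, prob = prob)
  if (any(f0 <= 0)) stop("baseline f0 is non-positive; cannot form delta-f/f")
  calcium_trace((trace$values - f0) / f0, fs_hz = trace$fs_hz,
                t0_s = trace$t0_s, units = "dff")
}

# two-pass robust baseline: a `prob`-quantile pass flags suprathreshold
# excursions, then the per-window median of the remaining samples (unbiased
# at the window centre for symmetric noise and smooth drift) is splined
two_pass_baseline <- function(x, window, prob = 0.1) {
  b0 <- rolling_quantile_baseline(x, window, prob)
  r <- x - b0
  sigma <- stats::mad(r[r <= stats::median(r)], center = 0)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::mad(r)
  excl <- r > 5 * sigma
  if (all(excl)) excl[] <- FALSE
  rolling_quantile_baseline(x, window, prob = 0.5, exclude = excl)
}

# Rolling-quantile baseline with spline interpolation across window centres.
# Windows of `window` samples shifted by `window/2`; within each window the
# `prob` quantile is taken, optionally ignoring samples flagged in `exclude`
# (TRUE = suprathreshold excursion).  Windows with fewer than `min_frac`
# usable samples contribute no knot and are bridged by the spline.
rolling_quantile_baseline <- function(x, window, prob = 0.1, exclude = NULL,
                                      min_frac = 0.2) {
  n <- length(x)
  window <- min(window, n)
  stride <- max(1L, window %/% 2L)
  starts <- seq(1L, max(1L, n - window + 1L), by = stride)
  centers <- starts + (window - 1) / 2
  q <- vapply(starts, function(s) {
    idx <- s:min(n, s + window - 1L)
    if (!is.null(exclude)) {
      keep <- idx[!exclude[idx]]
      if (length(keep) < min_frac * length(idx)) return(NA_real_)
      idx <- keep
    }
    stats::quantile(x[idx], prob, names = FALSE, type = 7)
  }, numeric(1))
  ok <- is.finite(q)
  if (sum(ok) < 2L) {
    # degenerate: fall back to global quantile
    return(rep(stats::quantile(x, prob, names = FALSE), n))
  }
  stats::spline(centers[ok], q[ok], xout = seq_len(n), method = "natural")$y
}

#' Baseline-correct a trace
#'
#' Estimates a slowly varying baseline in multiple shifted windows (default
#' 2500 samples wide), regresses it across the trace with a spline, and
#' subtracts it.  The estimator is a low-quantile statistic computed after
#' masking suprathreshold excursions, so transients of interest do not drag
#' the baseline upward even when a wave occupies most of a window.
#'
#' @param trace A `calcium_trace`.
#' @param window_samples Window width in samples.
#' @param prob Quantile taken inside each window.
#' @param mask_events If `TRUE` (default) a first pass (window `prob`
#'   quantile) flags samples more than 5 robust noise SDs above the
#'   provisional baseline; the second pass takes the median of the
#'   remaining event-free samples per window, which is unbiased for
#'   symmetric noise and drift.  With `FALSE` a single `prob`-quantile
#'   pass is used.
#' @return The corrected `calcium_trace`.
#' @export
baseline_correct <- function(trace, window_samples = 2500L, prob = 0.1,
                             mask_events = TRUE) {
  stopifnot(inherits(trace, "calcium_trace"))
  x <- trace$values
  n <- length(x)
  if (window_samples >= n) stop("window_samples must be < trace length")
  b <- if (mask_events) {
    two_pass_baseline(x, window_samples, prob)
  } else {
    rolling_quantile_baseline(x, window_samples, prob)
  }
  out <- trace
  out$values <- x - b
  out
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass with unit DC gain.
#'
#' @param trace A `calcium_trace`.
#' @param cutoff_hz Cutoff frequency, 0 < cutoff < fs/2.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return The filtered `calcium_trace`.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 100, order = 4L) {
  stopifnot(inherits(trace, "calcium_trace"))
  nyq <- trace$fs_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  x <- trace$values
  n <- length(x)
  # odd-reflection padding suppresses filtfilt edge transients and makes
  # constants and linear trends pass through exactly
  np <- min(n - 1L, max(20L, round(3 * trace$fs_hz / cutoff_hz)))
  xp <- c(2 * x[1L] - rev(x[2:(np + 1L)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  out <- trace
  out$values <- y[(np + 1L):(np + n)]
  out
}

#' Exponential moving average filter
#'
#' Recursive smoother y_t = alpha x_t + (1 - alpha) y_(t-1) with
#' alpha = 2/(N + 1), N = round(window_ms * fs / 1000), initialized at
#' y_1 = x_1.  This is the segmentation filter used to separate slow-wave
#' activity from quiescence.
#'
#' @param trace A `calcium_trace`.
#' @param window_ms EMA window in milliseconds (default 25).
#' @return The EMA-filtered `calcium_trace`.
#' @export
ema_filter <- function(trace, window_ms = 25) {
  stopifnot(inherits(trace, "calcium_trace"))
  N <- max(1L, round(window_ms * trace$fs_hz / 1000))
  alpha <- 2 / (N + 1)
  x <- trace$values
  y <- c(x[1L],
         as.numeric(stats::filter(alpha * x[-1L], 1 - alpha,
                                  method = "recursive", init = x[1L])))
  out <- trace
  out$values <- y
  out
}

#' Standard preprocessing for raw photometry recordings
#'
#' Downsample (2 kHz -> 1 kHz by default), zero-phase low-pass, and
#' baseline-correct, returning the trace on which event detection and wave
#' quantification operate.
#'
#' @param trace A `calcium_trace` (delta-f/f).
#' @param downsample_factor Block-averaging factor (default 2).
#' @param lowpass_hz Low-pass cutoff (default 100 Hz).
#' @param baseline_window Baseline window in samples at the downsampled rate
#'   (default 2500).
#' @return A preprocessed `calcium_trace`.
#' @export
preprocess_calcium <- function(trace, downsample_factor = 2L,
                               lowpass_hz = 100, baseline_window = 2500L) {
  out <- downsample_by_averaging(trace, downsample_factor)
  out <- lowpass_filter(out, lowpass_hz)
  baseline_correct(out, window_samples = baseline_window)
}
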