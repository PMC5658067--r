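#' Detection configuration for slow calcium waves
#'
#' Parameters of the EMA-filter segmentation of slow-wave activity from
#' quiescence and of the post-processing rules applied to raw suprathreshold
#' segments.
#'
#' @param ema_window_ms EMA filter window, ms (default 25).
#' @param onset_threshold_frac Onset threshold as a fraction of the
#'   reference amplitude (default 0.70).
#' @param termination_frac_of_threshold Termination level as a fraction of
#'   the onset threshold (default 0.50).
#' @param merge_gap_ms Segments separated by gaps strictly below this are
#'   merged into one wave (default 100 ms).
#' @param min_duration_ms Segments strictly shorter than this are discarded
#'   (default 600 ms).
#' @param intensity_percentile Events must peak above this quantile of the
#'   reference amplitude distribution (default 0.90).
#' @param intensity_ref Distribution defining the intensity rule:
#'   `"subthreshold"` (quantile of the sub-onset-threshold amplitude
#'   histogram, a noise-floor rule; default) or `"all_samples"` (quantile of
#'   the full-trace amplitude histogram).
#' @param noise_refine Apply noise-level termination refinement (default
#'   TRUE).
#' @param trim_quantile Quantile of the filtered-trace amplitude histogram
#'   taken as the "maximum" reference amplitude, robust to single-sample
#'   artifacts (default 0.999).
#' @return A `detection_config` list.
#' @export
detection_config <- function(ema_window_ms = 25,
                             onset_threshold_frac = 0.70,
                             termination_frac_of_threshold = 0.50,
                             merge_gap_ms = 100,
                             min_duration_ms = 600,
                             intensity_percentile = 0.90,
                             intensity_ref = c("subthreshold", "all_samples"),
                             noise_refine = TRUE,
                             trim_quantile = 0.999) {
  stopifnot(onset_threshold_frac > 0, onset_threshold_frac <= 1,
            termination_frac_of_threshold > 0,
            termination_frac_of_threshold <= 1,
            ema_window_ms > 0, merge_gap_ms > 0, min_duration_ms > 0)
  structure(list(ema_window_ms = ema_window_ms,
                 onset_threshold_frac = onset_threshold_frac,
                 termination_frac_of_threshold = termination_frac_of_threshold,
                 merge_gap_ms = merge_gap_ms,
                 min_duration_ms = min_duration_ms,
                 intensity_percentile = intensity_percentile,
                 intensity_ref = match.arg(intensity_ref),
                 noise_refine = noise_refine,
                 trim_quantile = trim_quantile),
            class = "detection_config")
}

#' Onset and termination thresholds from the amplitude histogram
#'
#' The reference amplitude is a trimmed maximum of the (baseline-corrected,
#' EMA-filtered) trace: the `trim_quantile` point of the sample-amplitude
#' histogram, which honours the percent-of-maximum convention while
#' rejecting isolated spikes.  The onset threshold is
#' `onset_threshold_frac * reference`; the termination threshold is
#' `termination_frac_of_threshold * onset_threshold`.
#'
#' @param trace A baseline-corrected, EMA-filtered `calcium_trace`.
#' @param config A `detection_config`.
#' @return List with `onset_threshold`, `termination_threshold`, and
#'   `reference` (all delta-f/f).
#' @export
compute_threshold <- function(trace, config = detection_config()) {
  x <- trace$values
  ref <- stats::quantile(x, config$trim_quantile, names = FALSE)
  if (!is.finite(ref) || ref <= 0 || diff(range(x)) == 0)
    stop("no dynamic range: trace has no positive trimmed maximum")
  on <- config$onset_threshold_frac * ref
  list(onset_threshold = on,
       termination_threshold = config$termination_frac_of_threshold * on,
       reference = ref)
}

# raw suprathreshold segments: start at upward crossing of `on`, end at the
# first subsequent downward crossing of `term`; returns index pairs
raw_segments <- function(x, on, term) {
  above_on <- x >= on
  below_term <- x < term
  starts <- which(diff(above_on) == 1L) + 1L
  if (above_on[1L]) starts <- c(1L, starts)
  res <- matrix(integer(0), ncol = 2)
  last_end <- 0L
  term_idx <- which(diff(below_term) == 1L) + 1L  # falls below term
  if (below_term[1L]) term_idx <- c(1L, term_idx)
  for (s in starts) {
    if (s <= last_end) next
    e <- term_idx[term_idx > s]
    e <- if (length(e)) e[1L] - 1L else length(x)  # last sample above term
    res <- rbind(res, c(s, e))
    last_end <- e
  }
  res
}

#' Detect slow calcium waves
#'
#' EMA-filters the preprocessed trace, derives onset/termination thresholds
#' from the amplitude histogram, extracts raw suprathreshold segments
#' (upward crossing of the onset threshold to downward crossing of the
#' termination threshold), applies the post-processing rules
#' ([postprocess_events()]) and, if configured, the noise-level termination
#' refinement ([refine_terminations()]).
#'
#' @param trace A preprocessed (downsampled, low-passed, baseline-corrected)
#'   `calcium_trace`.
#' @param config A `detection_config`.
#' @return An `event_array` of detected waves.
#' @export
detect_events <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "calcium_trace"))
  filt <- ema_filter(trace, config$ema_window_ms)
  if (diff(range(filt$values)) == 0)   # flat trace: nothing to detect
    return(event_array(numeric(0), numeric(0),
                       length(trace$values) / trace$fs_hz))
  thr <- compute_threshold(filt, config)
  seg <- raw_segments(filt$values, thr$onset_threshold,
                      thr$termination_threshold)
  fs <- trace$fs_hz
  T <- length(trace$values) / fs
  if (nrow(seg) == 0L) return(event_array(numeric(0), numeric(0), T))
  onsets <- trace$t0_s + (seg[, 1] - 1L) / fs
  durations <- (seg[, 2] - seg[, 1] + 1L) / fs
  raw <- event_array(onsets, durations, T)
  ev <- postprocess_events(raw, filt, config, thresholds = thr)
  if (config$noise_refine && n_events(ev) > 0)
    ev <- refine_terminations(ev, trace)
  ev
}

#' Post-process raw detected segments
#'
#' Applies, in order: (1) merge waves separated by gaps strictly below
#' `merge_gap_ms`; (2) discard waves strictly shorter than
#' `min_duration_ms`; (3) discard waves whose peak does not reach the
#' `intensity_percentile` point of the reference amplitude histogram (see
#' [detection_config()] for the two histogram conventions).
#'
#' @param raw An `event_array` of raw segments.
#' @param trace The EMA-filtered `calcium_trace` the segments were detected
#'   on.
#' @param config A `detection_config`.
#' @param thresholds Optional precomputed result of [compute_threshold()].
#' @return The filtered `event_array`.
#' @export
postprocess_events <- function(raw, trace, config = detection_config(),
                               thresholds = NULL) {
  if (n_events(raw) == 0L) return(raw)
  fs <- trace$fs_hz
  x <- trace$values
  o <- raw$onsets_s
  e <- raw$onsets_s + raw$durations_s
  # (1) merge gaps strictly below merge_gap_ms
  gap_s <- config$merge_gap_ms / 1000
  mo <- o[1L]; me <- e[1L]
  onsets <- numeric(0); ends <- numeric(0)
  for (i in seq_along(o)[-1L]) {
    if (o[i] - me < gap_s - 1e-12) {
      me <- max(me, e[i])
    } else {
      onsets <- c(onsets, mo); ends <- c(ends, me)
      mo <- o[i]; me <- e[i]
    }
  }
  onsets <- c(onsets, mo); ends <- c(ends, me)
  # (2) minimum duration, strict <
  keep <- (ends - onsets) >= config$min_duration_ms / 1000 - 1e-12
  onsets <- onsets[keep]; ends <- ends[keep]
  # (3) intensity rule
  if (length(onsets)) {
    if (is.null(thresholds)) thresholds <- compute_threshold(trace, config)
    ref_samples <- switch(config$intensity_ref,
      subthreshold = x[x < thresholds$onset_threshold],
      all_samples = x)
    level <- stats::quantile(ref_samples, config$intensity_percentile,
                             names = FALSE)
    i0 <- pmax(1L, floor((onsets - trace$t0_s) * fs) + 1L)
    i1 <- pmin(length(x), ceiling((ends - trace$t0_s) * fs))
    peaks <- vapply(seq_along(i0),
                    function(i) max(x[i0[i]:i1[i]]), numeric(1))
    keep <- peaks >= level
    onsets <- onsets[keep]; ends <- ends[keep]
  }
  event_array(onsets, ends - onsets, raw$session_duration_s)
}

# robust noise SD from the lower (event-free) tail of the amplitude
# distribution of a baseline-corrected trace
estimate_noise_sd <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.25), names = FALSE)
  sd <- (q[2] - q[1]) / (stats::qnorm(0.25) - stats::qnorm(0.05))
  if (!is.finite(sd) || sd <= 0)
    sd <- max(1e-9, stats::mad(diff(x)) / sqrt(2))
  sd
}

#' Refine event terminations by noise level
#'
#' The EMA segmentation is precise for onsets but terminates events while
#' the signal is still well above baseline.  Each termination is extended
#' forward to the last sample exceeding baseline + 2 noise SD before the
#' signal stays below that level for at least `persist_ms`.  Terminations
#' are clamped to the next event onset and the session end.
#'
#' @param events An `event_array`.
#' @param trace The preprocessed (un-EMA-filtered) `calcium_trace`.
#' @param noise_sd Noise SD; estimated from the event-free amplitude
#'   distribution when NULL.
#' @param persist_ms Time the signal must stay below the level, ms.
#' @return The refined `event_array`.
#' @export
refine_terminations <- function(events, trace, noise_sd = NULL,
                                persist_ms = 50) {
  if (n_events(events) == 0L) return(events)
  x <- trace$values
  fs <- trace$fs_hz
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(x)
  level <- 2 * noise_sd
  persist <- max(1L, round(persist_ms / 1000 * fs))
  n <- length(x)
  o <- events$onsets_s
  ends <- o + events$durations_s
  lim <- c(o[-1L], events$session_duration_s)  # next onset / session end
  for (i in seq_along(o)) {
    i_end <- min(n, max(1L, round((ends[i] - trace$t0_s) * fs)))
    i_lim <- min(n, floor((lim[i] - trace$t0_s) * fs))
    if (i_lim <= i_end) { ends[i] <- lim[i]; next }
    seg <- x[i_end:i_lim] < level
    r <- rle(seg)
    pos <- cumsum(r$lengths) - r$lengths + 1L  # run starts
    hit <- which(r$values & r$lengths >= persist)
    if (length(hit)) {
      ends[i] <- ends[i] + (pos[hit[1L]] - 2L) / fs  # last sample above level
      ends[i] <- max(ends[i], o[i] + 1 / fs)
    } else {
      ends[i] <- lim[i]  # never settles below before next event
    }
  }
  ends <- pmin(ends, lim)
  event_array(o, ends - o, events$session_duration_s)
}

# interpolated crossing time of `level` in x (indices idx), last crossing at
# or before index `before`, on the rising flank
cross_time_up <- function(x, level, peak_idx) {
  below <- which(x[seq_len(peak_idx)] < level)
  if (!length(below)) return(NA_real_)
  i <- max(below)
  if (i >= peak_idx) return(NA_real_)
  i + (level - x[i]) / (x[i + 1L] - x[i])  # fractional sample index
}

# first sustained downward crossing after the peak: the signal must stay
# below `level` for at least `persist` samples (or to the end of the slice)
cross_time_down <- function(x, level, peak_idx, persist = 100L) {
  n <- length(x)
  i <- peak_idx
  while (i < n) {
    if (x[i] >= level && x[i + 1L] < level) {
      j <- min(n, i + persist)
      if (all(x[(i + 1L):j] < level))
        return(i + (x[i] - level) / (x[i] - x[i + 1L]))
    }
    i <- i + 1L
  }
  if (x[n] >= level) return(as.numeric(n))
  NA_real_
}

#' Quantify per-wave parameters
#'
#' For each detected event computes, on the preprocessed trace:
#' * rise time: interval between transient onset and the half-maximum
#'   crossing; the onset is recovered by extrapolating the 25--75% rising
#'   flank down to baseline, which is exact for a linear rise and robust to
#'   noise,
#' * duration: time between the first and last sample exceeding 50% of the
#'   peak (above the local baseline),
#' * amplitude: difference between the local pre-onset baseline and the
#'   peak; the peak is estimated as the mean of all samples within two
#'   noise SDs of the maximum, which is unbiased for plateaued waves.
#'
#' The local baseline is the mean of a 200 ms window ending 300 ms before
#' the detected onset (clear of the threshold-crossing lag).
#'
#' @param events An `event_array`.
#' @param trace The preprocessed `calcium_trace` the events were detected
#'   on (not EMA-filtered).
#' @param noise_sd Noise SD; estimated from the trace when NULL.
#' @return A data.frame with one row per quantified event: `onset_s`,
#'   `rise_time_ms`, `duration_ms`, `amplitude_dff`, `flagged`.
#' @export
quantify_wave_params <- function(events, trace, noise_sd = NULL) {
  x <- trace$values
  fs <- trace$fs_hz
  n <- length(x)
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(x)
  o <- events$onsets_s - trace$t0_s
  e <- o + events$durations_s
  lim <- c(o[-1L], n / fs)
  out <- vector("list", length(o))
  for (i in seq_along(o)) {
    i_on <- floor(o[i] * fs) + 1L
    # keep the window clear of the next event's rising flank
    i_end <- min(n, ceiling(min(e[i] + 1, lim[i] - 0.2) * fs))
    if (i_end - i_on < 2L) {
      warning(sprintf("event %d shorter than 2 samples; skipped", i))
      next
    }
    # local baseline: 200 ms window ending 300 ms before the detected onset
    b0 <- max(1L, i_on - round(0.5 * fs))
    b1 <- max(1L, i_on - round(0.3 * fs))
    baseline <- mean(x[b0:b1])
    i_start <- max(1L, i_on - round(0.8 * fs))  # include pre-onset rise
    seg <- x[i_start:i_end] - baseline
    pk <- which.max(seg)
    m <- seg[pk]
    if (m <= 2 * noise_sd) {
      out[[i]] <- data.frame(onset_s = events$onsets_s[i], rise_time_ms = NA,
                             duration_ms = NA, amplitude_dff = 0,
                             flagged = TRUE)
      next
    }
    near_peak <- seg >= m - 2 * noise_sd
    amp <- mean(seg[near_peak])
    t25 <- cross_time_up(seg, 0.25 * amp, pk)
    t50 <- cross_time_up(seg, 0.50 * amp, pk)
    t75 <- cross_time_up(seg, 0.75 * amp, pk)
    t50d <- cross_time_down(seg, 0.50 * amp, pk)
    flagged <- anyNA(c(t25, t50, t75, t50d))
    t_onset <- (3 * t25 - t75) / 2  # extrapolate rising flank to baseline
    out[[i]] <- data.frame(
      onset_s = events$onsets_s[i],
      rise_time_ms = (t50 - t_onset) / fs * 1000,
      duration_ms = (t50d - t50) / fs * 1000,
      amplitude_dff = amp,
      flagged = flagged
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Calibrate the onset threshold fraction against BOLD activation
#'
#' Runs detection at each candidate threshold fraction, maps the resulting
#' event regressor onto the paired BOLD session with a canonical-HRF GLM,
#' counts suprathreshold voxels (uncorrected p < 0.05), and returns the
#' fraction at the inflection of the voxel-count curve (maximum discrete
#' second difference).  If the curve carries no inflection the default 0.70
#' is returned with a warning.
#'
#' @param trace A preprocessed `calcium_trace`.
#' @param bold A `bold_session` (see [bold_session()]).
#' @param candidate_fracs Candidate onset threshold fractions (>= 4 values).
#' @param config Base `detection_config` (the onset fraction is overridden).
#' @return The selected fraction.
#' @export
calibrate_threshold <- function(trace, bold, candidate_fracs,
                                config = detection_config()) {
  if (length(candidate_fracs) < 4L)
    stop("need >=4 points for second difference")
  candidate_fracs <- sort(candidate_fracs)
  hrf <- canonical_hrf(bold$tr_s)
  counts <- vapply(candidate_fracs, function(f) {
    cfg <- config
    cfg$onset_threshold_frac <- f
    ev <- tryCatch(detect_events(trace, cfg),
                   error = function(e) NULL)
    if (is.null(ev) || n_events(ev) == 0L) return(0)
    sw <- binarize_to_tr(ev, bold$tr_s, n_volumes(bold))
    reg <- make_regressor(sw, hrf)
    glm <- fit_glm(bold, matrix(reg, ncol = 1))
    tm <- t_test_map(glm, contrast = 1, correction = "none", alpha = 0.05)
    sum(tm$suprathreshold, na.rm = TRUE)
  }, numeric(1))
  if (diff(range(counts)) == 0) {
    warning("identical voxel counts across candidate fractions; using default 0.70")
    return(0.70)
  }
  d2 <- diff(counts, differences = 2)
  if (max(d2) <= 0) {
    warning("no inflection point in voxel-count curve; using default 0.70")
    return(0.70)
  }
  candidate_fracs[which.max(d2) + 1L]
}
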