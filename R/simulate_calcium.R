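#' Configuration for the synthetic calcium-trace generator
#'
#' The generator emulates fiber-photometry recordings of slow
#' oscillation-associated calcium waves under anesthesia: stereotyped
#' transients (fast linear rise, sustained up-state plateau, exponential
#' indicator decay) separated by quiescent periods, riding on slow baseline
#' drift plus white photon noise.
#'
#' Per-event parameters (rise time, plateau duration, peak amplitude) are
#' drawn log-normally around the configured means with the given
#' coefficients of variation, mimicking the wave-to-wave variability of real
#' recordings.  The half-maximum duration of an event is by construction
#' `rise_time + plateau + decay_tau * log(2)`.
#'
#' @param duration_s Session length, seconds.
#' @param fs_hz Sampling rate (native photometry rate, default 2000).
#' @param event_rate_per_min Mean event rate, events/minute.
#' @param isi_model Inter-onset interval model; `"poisson_with_refractory"`
#'   draws `refractory_s + Exp(mean = 60/rate - refractory_s)`.
#' @param refractory_s Hard refractory period between onsets, seconds.
#' @param rise_time_ms Mean onset-to-half-maximum interval, ms; the linear
#'   ramp reaches peak at `2 * rise_time_ms`.
#' @param rise_cv Coefficient of variation of per-event rise times.
#' @param plateau_ms Mean up-state plateau duration at peak, ms.
#' @param plateau_cv Coefficient of variation of per-event plateaus.
#' @param decay_tau_ms Exponential decay constant after the plateau, ms.
#' @param amplitude_dff Mean peak amplitude, delta-f/f.
#' @param amplitude_cv Coefficient of variation of per-event amplitudes.
#' @param drift_amplitude Amplitude of sinusoidal baseline drift, delta-f/f.
#' @param drift_period_s Period of the drift, seconds.
#' @param noise_sd White-noise SD, delta-f/f.
#' @param n_events If non-NULL, plant exactly this many events with
#'   uniformly jittered onsets (respecting the refractory gap) instead of
#'   the renewal-process count.
#' @param seed RNG seed.
#' @return A `calcium_sim_config` list.
#' @export
calcium_sim_config <- function(duration_s = 1800, fs_hz = 2000,
                               event_rate_per_min = 10.9,
                               isi_model = "poisson_with_refractory",
                               refractory_s = 2.5,
                               rise_time_ms = 72, rise_cv = 0.15,
                               plateau_ms = 902.8, plateau_cv = 0.3,
                               decay_tau_ms = 550,
                               amplitude_dff = 2.6, amplitude_cv = 0.05,
                               drift_amplitude = 0.1, drift_period_s = 300,
                               noise_sd = 0.05, n_events = NULL, seed = 1L) {
  stopifnot(duration_s > 0, fs_hz > 0, event_rate_per_min >= 0,
            refractory_s >= 0, amplitude_dff > 0, rise_time_ms > 0,
            decay_tau_ms > 0, plateau_ms >= 0)
  cfg <- list(duration_s = duration_s, fs_hz = fs_hz,
              event_rate_per_min = event_rate_per_min,
              isi_model = isi_model, refractory_s = refractory_s,
              rise_time_ms = rise_time_ms, rise_cv = rise_cv,
              plateau_ms = plateau_ms, plateau_cv = plateau_cv,
              decay_tau_ms = decay_tau_ms,
              amplitude_dff = amplitude_dff, amplitude_cv = amplitude_cv,
              drift_amplitude = drift_amplitude,
              drift_period_s = drift_period_s,
              noise_sd = noise_sd, n_events = n_events, seed = seed)
  class(cfg) <- "calcium_sim_config"
  cfg
}

#' Indicator presets for the calcium generator
#'
#' Returns a `calcium_sim_config` whose wave statistics match the reported
#' in-scanner values for the given indicator: OGB-1 (fast synthetic dye,
#' rise 72 ms) or GCaMP6f (genetically encoded, slower rise 163 ms); both
#' share mean duration 1356 ms, amplitude 2.6 delta-f/f and a mean rate of
#' 10.9 events/min.  The plateau is derived so the mean half-maximum
#' duration equals `duration_ms`.
#'
#' @param preset `"ogb1"` or `"gcamp6f"`.
#' @param duration_ms Target mean half-maximum wave duration, ms.
#' @param ... Overrides passed to [calcium_sim_config()].
#' @return A `calcium_sim_config`.
#' @export
calcium_preset <- function(preset = c("ogb1", "gcamp6f"),
                           duration_ms = 1356, ...) {
  preset <- match.arg(preset)
  rise <- switch(preset, ogb1 = 72, gcamp6f = 163)
  decay_tau <- 550
  plateau <- duration_ms - rise - decay_tau * log(2)
  if (plateau < 0) stop("duration_ms too short for this rise/decay")
  calcium_sim_config(rise_time_ms = rise, plateau_ms = plateau,
                     decay_tau_ms = decay_tau, ...)
}

# single wave waveform sampled at times t_rel (s, from ramp start)
wave_shape <- function(t_rel, rise_s, plateau_s, tau_s, amp) {
  ramp <- 2 * rise_s
  y <- numeric(length(t_rel))
  i1 <- t_rel >= 0 & t_rel < ramp
  y[i1] <- amp * t_rel[i1] / ramp
  i2 <- t_rel >= ramp & t_rel < ramp + plateau_s
  y[i2] <- amp
  i3 <- t_rel >= ramp + plateau_s
  y[i3] <- amp * exp(-(t_rel[i3] - ramp - plateau_s) / tau_s)
  y
}

# mean-parameterized log-normal draws
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a calcium trace with planted slow waves
#'
#' @param config A `calcium_sim_config`.
#' @return A list of class `calcium_sim_result` with elements `trace`
#'   (a `calcium_trace`, delta-f/f) and `truth_events` (an `event_array`
#'   whose durations are the planted half-maximum durations).
#' @export
simulate_calcium_trace <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  set.seed(config$seed)
  fs <- config$fs_hz
  T <- config$duration_s
  n <- round(T * fs)
  tau_s <- config$decay_tau_ms / 1000

  # --- onsets -------------------------------------------------------------
  rate <- config$event_rate_per_min / 60  # events/s
  onsets <- numeric(0)
  if (!is.null(config$n_events)) {
    k <- config$n_events
    g <- config$refractory_s
    usable <- T - 5 - k * g  # keep a tail margin for the last wave
    if (usable <= 0) stop("n_events incompatible with refractory period")
    u <- sort(stats::runif(k, 0, usable))
    onsets <- u + (seq_len(k) - 1) * g + g / 2
  } else if (rate > 0) {
    mean_isi <- 1 / rate
    if (mean_isi <= config$refractory_s)
      stop("event rate incompatible with refractory period (expected ISI < refractory)")
    exp_mean <- mean_isi - config$refractory_s
    t <- stats::rexp(1, 1 / mean_isi)  # first onset
    while (t < T - 5) {
      onsets <- c(onsets, t)
      t <- t + config$refractory_s + stats::rexp(1, 1 / exp_mean)
    }
  }
  k <- length(onsets)

  # --- per-event parameters ------------------------------------------------
  rise_s <- rlnorm_mean(k, config$rise_time_ms / 1000, config$rise_cv)
  plateau_s <- rlnorm_mean(k, config$plateau_ms / 1000, config$plateau_cv)
  amp <- rlnorm_mean(k, config$amplitude_dff, config$amplitude_cv)
  half_dur <- rise_s + plateau_s + tau_s * log(2)

  # rare long plateaus would overlap the next onset; clip the planted
  # half-max duration to the available gap
  if (k > 1L) {
    gap <- c(diff(onsets), Inf) - 1e-3
    half_dur <- pmin(half_dur, gap)
  }
  # drop any event whose half-max duration spills past the session end
  keep <- onsets + half_dur <= T
  onsets <- onsets[keep]; rise_s <- rise_s[keep]
  plateau_s <- plateau_s[keep]; amp <- amp[keep]
  half_dur <- half_dur[keep]
  k <- length(onsets)

  # --- assemble trace ------------------------------------------------------
  x <- numeric(n)
  support_s <- function(r, p) 2 * r + p + tau_s * log(1e4)
  for (i in seq_len(k)) {
    i0 <- floor(onsets[i] * fs) + 1L
    i1 <- min(n, i0 + ceiling(support_s(rise_s[i], plateau_s[i]) * fs))
    idx <- i0:i1
    t_rel <- (idx - 1) / fs - onsets[i]
    x[idx] <- x[idx] + wave_shape(t_rel, rise_s[i], plateau_s[i], tau_s, amp[i])
  }
  tt <- (seq_len(n) - 1) / fs
  if (config$drift_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + config$drift_amplitude *
      sin(2 * pi * tt / config$drift_period_s + phase)
  }
  if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)

  truth <- event_array(onsets, half_dur, T)
  structure(list(
    trace = calcium_trace(x, fs_hz = fs, units = "dff"),
    truth_events = truth,
    truth_params = data.frame(onset_s = onsets,
                              rise_time_ms = rise_s * 1000,
                              duration_ms = half_dur * 1000,
                              amplitude_dff = amp)
  ), class = "calcium_sim_result")
}
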