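# shared fixture builders for the test suite (all generated in code)

# trace containing rectangular pulses of given onsets/durations (s)
pulse_trace <- function(onsets, durations, amp = 1, fs = 1000, T = NULL,
                        noise_sd = 0) {
  if (is.null(T)) T <- max(onsets + durations) + 2
  n <- round(T * fs)
  x <- numeric(n)
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- min(n, round((onsets[i] + durations[i]) * fs))
    x[i0:i1] <- amp
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  calcium_trace(x, fs_hz = fs, units = "dff")
}

# single wave: linear rise over rise_s, then exponential decay tau_s
ramp_decay_trace <- function(onset = 1, rise_s = 0.1, tau_s = 0.5, amp = 2,
                             fs = 1000, T = 8) {
  n <- round(T * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  ris <- t >= onset & t < onset + rise_s
  x[ris] <- amp * (t[ris] - onset) / rise_s
  dec <- t >= onset + rise_s
  x[dec] <- amp * exp(-(t[dec] - onset - rise_s) / tau_s)
  calcium_trace(x, fs_hz = fs, units = "dff")
}

# tiny BOLD session built directly from a voxel x time percent matrix
bold_from_pct <- function(pct, dims3, tr = 1) {
  stopifnot(nrow(pct) == prod(dims3))
  bold_session(array(100 * (1 + pct / 100), c(dims3, ncol(pct))), tr_s = tr)
}
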