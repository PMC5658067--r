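test_that("threshold derivation follows the percent-of-maximum rules", {
  x <- c(rep(0, 998), 1, 1)
  tr <- calcium_trace(x, fs_hz = 1000)
  thr <- compute_threshold(tr)
  expect_equal(thr$onset_threshold, 0.70, tolerance = 1e-9)
  expect_equal(thr$termination_threshold, 0.35, tolerance = 1e-9)

  thr2 <- compute_threshold(calcium_trace(2.6 * x, fs_hz = 1000))
  expect_equal(thr2$onset_threshold, 1.82, tolerance = 1e-9)
  expect_equal(thr2$termination_threshold, 0.91, tolerance = 1e-9)

  expect_error(compute_threshold(calcium_trace(rep(0, 100), fs_hz = 1000)),
               "dynamic range")
})

test_that("trimmed maximum rejects single-sample artifacts", {
  set.seed(4)
  x <- runif(1e6)
  x[12345] <- 100
  ref <- compute_threshold(calcium_trace(x, fs_hz = 1000))$reference
  expect_lt(abs(ref - 1), 0.01)
})

test_that("detection finds well-separated pulses with onset precision", {
  tr <- pulse_trace(c(2, 5, 8), rep(1, 3), amp = 1, fs = 1000, T = 12)
  ev <- detect_events(tr, detection_config(noise_refine = FALSE))
  expect_equal(n_events(ev), 3)
  expect_lt(max(abs(ev$onsets_s - c(2, 5, 8))), 0.030)
})

test_that("flat trace yields an empty event array", {
  tr <- calcium_trace(rep(0, 5000), fs_hz = 1000)
  ev <- detect_events(tr)
  expect_equal(n_events(ev), 0)
})

test_that("merge rule is strict at the 100 ms boundary", {
  # 50 ms gap: merged into one wave
  tr <- pulse_trace(c(2, 2.85), c(0.8, 0.8), amp = 1, fs = 1000, T = 6)
  ev <- detect_events(tr, detection_config(noise_refine = FALSE))
  expect_equal(n_events(ev), 1)

  # exactly 100 ms gap: NOT merged
  tr2 <- pulse_trace(c(2, 2.9), c(0.8, 0.8), amp = 1, fs = 1000, T = 6)
  ev2 <- detect_events(tr2, detection_config(noise_refine = FALSE))
  expect_equal(n_events(ev2), 2)
})

test_that("duration rule is strict at the 600 ms boundary", {
  raw5 <- event_array(2, 0.5, 10)
  raw6 <- event_array(2, 0.6, 10)
  tr <- pulse_trace(2, 0.6, amp = 1, fs = 1000, T = 10)
  filt <- ema_filter(tr, 25)
  cfg <- detection_config()
  expect_equal(n_events(postprocess_events(raw5, filt, cfg)), 0)
  expect_equal(n_events(postprocess_events(raw6, filt, cfg)), 1)
})

test_that("termination refinement finds the noise-level decay crossing", {
  # decay tau = 500 ms from peak 2.0; 2-sigma floor 0.02
  tr <- ramp_decay_trace(onset = 1, rise_s = 0.001, tau_s = 0.5, amp = 2,
                         fs = 1000, T = 8)
  ev <- event_array(1, 0.5, 8)  # deliberately early termination
  ref <- refine_terminations(ev, tr, noise_sd = 0.01)
  t_term <- ref$onsets_s + ref$durations_s
  expect_equal(t_term, 1.001 + 0.5 * log(2 / 0.02), tolerance = 0.005)

  # already-correct termination stays put
  ref2 <- refine_terminations(ref, tr, noise_sd = 0.01)
  expect_equal(ref2$durations_s, ref$durations_s, tolerance = 0.003)

  # event abutting the session end is clamped
  late <- event_array(7.5, 0.4, 8)
  trc <- pulse_trace(7.5, 0.5, amp = 2, fs = 1000, T = 8)
  refl <- refine_terminations(late, trc, noise_sd = 0.01)
  expect_lte(refl$onsets_s + refl$durations_s, 8)
})

test_that("binarization uses the half-open overlap convention", {
  ev <- event_array(3.4, 1.2, 10)
  sw <- binarize_to_tr(ev, 1, 10)
  expect_equal(which(sw$bins == 1L), c(4, 5))  # volumes 3 and 4, 0-based

  expect_equal(sum(binarize_to_tr(event_array(numeric(0), numeric(0), 10),
                                  1, 10)$bins), 0)

  sw2 <- binarize_to_tr(event_array(2, 1, 10), 1, 10)
  expect_equal(which(sw2$bins == 1L), 3)  # [2, 3) marks volume 2 only

  expect_error(binarize_to_tr(event_array(9.5, 1, 11), 1, 10), "beyond")
})

test_that("binarization approximately conserves per-event time", {
  set.seed(5)
  for (i in 1:10) {
    o <- sort(runif(5, 0, 80))
    o <- o[c(TRUE, diff(o) > 3)]
    d <- runif(length(o), 0.5, 2)
    ev <- event_array(o, d, 100)
    for (j in seq_along(o)) {
      cnt <- sum(binarize_to_tr(event_array(o[j], d[j], 100), 1, 100)$bins)
      # the overlap convention can add at most one volume at each edge
      expect_gt(cnt, d[j] - 1)
      expect_lt(cnt, d[j] + 2)
    }
  }
})

test_that("event frequency is computed per 100 s bin", {
  ev <- event_array(seq(5, 95, by = 10), rep(0.5, 10), 100)
  f <- event_frequency(ev, 100)
  expect_equal(f$bin_hz, 0.1)
  expect_equal(f$events_per_min, 6)

  f0 <- event_frequency(event_array(numeric(0), numeric(0), 300), 100)
  expect_equal(f0$mean_hz, 0)
})

test_that("wave quantification matches closed-form wave geometry", {
  # linear rise 0 -> 2.0 over 100 ms then exponential decay tau = 500 ms
  tr <- ramp_decay_trace(onset = 2, rise_s = 0.1, tau_s = 0.5, amp = 2,
                         fs = 1000, T = 10)
  ev <- event_array(2.0, 1.5, 10)
  wp <- quantify_wave_params(ev, tr, noise_sd = 1e-4)
  expect_equal(wp$rise_time_ms, 50, tolerance = 3)
  expect_equal(wp$amplitude_dff, 2.0, tolerance = 0.01)
  expect_equal(wp$duration_ms, (100 + 500 * log(2)) - 50, tolerance = 5)

  # flat event region: amplitude 0, flagged
  flat <- calcium_trace(rep(0, 10000), fs_hz = 1000)
  wpf <- quantify_wave_params(event_array(2, 1, 10), flat, noise_sd = 0.01)
  expect_true(wpf$flagged)
  expect_equal(wpf$amplitude_dff, 0)
})

test_that("noiseless pulse detection has unit sensitivity and precision", {
  onsets <- c(3, 7, 11, 15, 19)
  tr <- pulse_trace(onsets, rep(0.8, 5), amp = 1.5, fs = 1000, T = 23)
  ev <- detect_events(tr, detection_config(noise_refine = FALSE))
  expect_equal(n_events(ev), 5)           # precision = sensitivity = 1
  expect_lt(max(abs(ev$onsets_s - onsets)), 0.030)
  # output invariants: non-overlap and minimum duration
  ends <- ev$onsets_s + ev$durations_s
  expect_true(all(ends[-5] <= ev$onsets_s[-1]))
  expect_true(all(ev$durations_s >= 0.6))
})

test_that("event mirroring reflects onsets and is an involution", {
  ev <- event_array(10, 2, 100)
  m <- mirror_events(ev)
  expect_equal(m$onsets_s, 88)
  expect_equal(m$durations_s, 2)
  mm <- mirror_events(m)
  expect_equal(mm$onsets_s, ev$onsets_s)
  expect_equal(n_events(mirror_events(event_array(numeric(0), numeric(0), 50))), 0)
})

test_that("event swapping clips to the target session", {
  ev <- event_array(c(10, 40), c(2, 2), 50)
  same <- swap_events(ev, 50)
  expect_equal(same$onsets_s, ev$onsets_s)

  expect_warning(clipped <- swap_events(ev, 41), "clipped")
  expect_equal(clipped$durations_s[2], 1)
  expect_error(swap_events(event_array(45, 2, 50), 40), "beyond")
})

test_that("threshold calibration guards its inputs", {
  tr <- pulse_trace(c(2, 6), c(1, 1), amp = 1, fs = 1000, T = 10)
  bold <- bold_from_pct(matrix(rnorm(8 * 60), 8), c(2, 2, 2))
  expect_error(calibrate_threshold(tr, bold, c(0.5, 0.7)), ">=4 points")
})

test_that("threshold calibration finds the knee of the voxel-count curve", {
  # true coupled waves (amp 2.6) mixed with uncoupled distractor transients
  # (amp 1.1): voxel counts rise once distractors fall below threshold and
  # drop once true events are lost; the calibrated fraction sits at the
  # upper knee of the clean-detection plateau
  s1 <- simulate_calcium_trace(calcium_sim_config(
    duration_s = 300, event_rate_per_min = 8, noise_sd = 0.05,
    drift_amplitude = 0, amplitude_dff = 2.6, amplitude_cv = 0.03,
    seed = 61))
  s2 <- simulate_calcium_trace(calcium_sim_config(
    duration_s = 300, event_rate_per_min = 8, noise_sd = 0,
    drift_amplitude = 0, amplitude_dff = 1.1, amplitude_cv = 0.03,
    seed = 62))
  tr <- preprocess_calcium(calcium_trace(s1$trace$values + s2$trace$values,
                                         fs_hz = 2000, units = "dff"))
  bs <- simulate_bold_session(
    bold_sim_config(grid_shape = c(8, 8, 3), n_volumes = 300,
                    cortical_mask_fraction = 1 / 3, seed = 63),
    s1$truth_events)
  f <- calibrate_threshold(tr, bs$bold, seq(0.2, 0.8, by = 0.1))
  expect_true(f %in% c(0.6, 0.7))
})
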