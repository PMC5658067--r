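test_that("BOLD preprocessing discards, smooths, and high-passes", {
  # volume count: 1205 in, 5 discarded -> 1200
  arr <- array(100, c(2, 2, 1, 1205))
  b <- bold_session(arr, tr_s = 1, voxel_size_mm = c(1, 1, 1))
  out <- preprocess_bold(b, fwhm_mm = 0)
  expect_equal(n_volumes(out), 1200)
  # constant series unchanged (DC retained through the high-pass)
  expect_equal(max(abs(out$data - 100)), 0, tolerance = 1e-8)

  # slow drift (period 256 s, cosine phase) attenuated > 90%
  nt <- 512
  tt <- seq_len(nt)
  s <- cos(2 * pi * tt / 256)
  arr2 <- array(rep(100 + s, each = 4), c(2, 2, 1, nt))
  b2 <- bold_session(arr2, tr_s = 1, voxel_size_mm = c(1, 1, 1))
  out2 <- preprocess_bold(b2, fwhm_mm = 0, n_discard = 0)
  resid <- out2$data[1, 1, 1, ] - mean(out2$data[1, 1, 1, ])
  expect_lt(sd(resid) / sd(s), 0.1)

  # arbitrary-phase drift equals the discrete-cosine projection oracle
  s2 <- sin(2 * pi * tt / 256 + 0.7)
  arr3 <- array(rep(100 + s2, each = 4), c(2, 2, 1, nt))
  out3 <- preprocess_bold(bold_session(arr3, tr_s = 1,
                                       voxel_size_mm = c(1, 1, 1)),
                          fwhm_mm = 0, n_discard = 0)
  K <- floor(2 * nt / 128)
  D <- qr.Q(qr(vapply(seq_len(K), function(k)
    cos(pi * k * (2 * tt - 1) / (2 * nt)), numeric(nt))))
  oracle <- 100 + s2 - D %*% crossprod(D, s2)
  expect_equal(out3$data[1, 1, 1, ], as.numeric(oracle), tolerance = 1e-9)

  expect_warning(preprocess_bold(b, fwhm_mm = 0.1), "skipped")
  expect_error(preprocess_bold(bold_session(array(1, c(2, 2, 1, 30)), 1)),
               "too few")
})

test_that("Gaussian smoothing preserves constants and spreads point sources", {
  arr <- array(0, c(9, 9, 1, 45))
  arr[5, 5, 1, ] <- 1
  arr <- arr + 100
  b <- bold_session(arr, tr_s = 1, voxel_size_mm = c(0.35, 0.35, 1.2))
  out <- preprocess_bold(b, fwhm_mm = 0.5, n_discard = 0,
                         highpass_cutoff_s = Inf)
  sl <- out$data[, , 1, 1] - 100
  expect_lt(sl[5, 5], 1)                  # peak spread out
  expect_gt(sl[4, 5], 0)                  # into neighbours
  expect_equal(sum(sl), 1, tolerance = 1e-6)  # mass preserved
})

test_that("regressor construction is a discrete convolution", {
  hrf <- canonical_hrf(1)
  sw <- structure(list(bins = as.integer(seq_len(100) == 10), tr_s = 1),
                  class = "slow_wave_vector")
  r <- make_regressor(sw, hrf, mean_center = FALSE)
  expect_equal(r[10:42], hrf$values, tolerance = 1e-9)

  # two far-apart events: superposition of shifted kernels
  sw2 <- structure(list(bins = as.integer(seq_len(120) %in% c(10, 70)),
                        tr_s = 1), class = "slow_wave_vector")
  r2 <- make_regressor(sw2, hrf, mean_center = FALSE)
  expect_equal(r2[10:42], hrf$values, tolerance = 1e-9)
  expect_equal(r2[70:102], hrf$values, tolerance = 1e-9)

  # overlapping responses equal a direct convolution oracle
  set.seed(8)
  bins <- as.integer(runif(80) < 0.2)
  bins[1] <- 1L
  sw3 <- structure(list(bins = bins, tr_s = 1), class = "slow_wave_vector")
  r3 <- make_regressor(sw3, hrf, mean_center = FALSE)
  oracle <- numeric(80)
  for (v in which(bins == 1L)) {
    idx <- v:min(80, v + length(hrf$values) - 1L)
    oracle[idx] <- oracle[idx] + hrf$values[seq_along(idx)]
  }
  expect_equal(r3, oracle, tolerance = 1e-12)

  empty <- structure(list(bins = integer(50), tr_s = 1),
                     class = "slow_wave_vector")
  expect_error(make_regressor(empty, hrf), "no events")
})

test_that("GLM recovers noiseless effects exactly", {
  hrf <- canonical_hrf(1)
  sw <- structure(list(bins = as.integer(seq_len(200) %in% c(20, 90, 150)),
                       tr_s = 1), class = "slow_wave_vector")
  reg <- make_regressor(sw, hrf)
  pct <- rbind(2 * reg, -reg, matrix(0, 6, 200))
  bold <- bold_from_pct(pct, c(2, 2, 2))
  glm <- fit_glm(bold, matrix(reg, ncol = 1), ar1 = 0)
  expect_equal(as.numeric(glm$betas[1, 2]), 2, tolerance = 1e-6)
  expect_equal(as.numeric(glm$betas[2, 2]), -1, tolerance = 1e-6)
})

test_that("pooled AR(1) estimate recovers the simulated coefficient", {
  cfg <- bold_sim_config(grid_shape = c(4, 4, 4), n_volumes = 2000,
                         response_amplitude_pct = 0, drift_amplitude_pct = 0,
                         ar1_coeff = 0.4, seed = 3)
  bs <- simulate_bold_session(cfg, event_array(numeric(0), numeric(0), 2000))
  reg <- rnorm(2000)
  glm <- fit_glm(bs$bold, matrix(reg, ncol = 1))
  expect_equal(glm$rho, 0.40, tolerance = 0.03)
})

test_that("collinear regressors are rejected with a diagnostic", {
  x <- rnorm(100)
  bold <- bold_from_pct(matrix(rnorm(400), 4), c(2, 2, 1))
  expect_error(fit_glm(bold, cbind(x, x)), "collinear")
})

test_that("F statistics equal the brute-force extra-sum-of-squares ratio", {
  set.seed(9)
  nt <- 8
  X <- cbind(rnorm(nt), rnorm(nt))
  y <- 0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(nt, 0, 0.3)
  pct <- matrix(rep(y, each = 4), 4)
  bold <- bold_from_pct(pct, c(2, 2, 1))
  glm <- fit_glm(bold, X, ar1 = 0)
  ft <- f_test(glm, 1:2)

  # oracle on the same normalized series
  yv <- bold$data[1, 1, 1, ]
  full <- lm(yv ~ X)
  red <- lm(yv ~ 1)
  f_oracle <- ((sum(resid(red)^2) - sum(resid(full)^2)) / 2) /
    (sum(resid(full)^2) / (nt - 3))
  expect_equal(ft$f_map[1, 1, 1], f_oracle, tolerance = 1e-6)

  # regressor exactly orthogonal to the data: F = 0
  y2 <- rep(c(1, -1), nt / 2)
  x2 <- rep(c(1, 1, -1, -1), nt / 4)     # orthogonal to y2 and to 1
  pct2 <- matrix(rep(y2, each = 4), 4)
  glm2 <- fit_glm(bold_from_pct(pct2, c(2, 2, 1)),
                  matrix(x2, ncol = 1), ar1 = 0)
  expect_lt(max(f_test(glm2, 1)$f_map), 1e-9)
  expect_error(f_test(glm2, integer(0)), "empty")

  # perfect fit: F flagged as +Inf
  pct3 <- matrix(rep(as.numeric(X[, 1]), each = 4), 4)
  glm3 <- fit_glm(bold_from_pct(pct3, c(2, 2, 1)),
                  X[, 1, drop = FALSE], ar1 = 0)
  expect_true(all(is.infinite(f_test(glm3, 1)$f_map)))
})

test_that("t-maps control family-wise error and detect planted effects", {
  set.seed(10)
  nt <- 300
  hrf <- canonical_hrf(1)
  sw <- structure(list(bins = as.integer(seq_len(nt) %% 17 == 3), tr_s = 1),
                  class = "slow_wave_vector")
  reg <- make_regressor(sw, hrf)
  nvox <- 125
  truth <- rep(c(TRUE, FALSE), c(40, 85))
  pct <- matrix(rnorm(nvox * nt, 0, 0.3), nvox, nt)
  pct[truth, ] <- pct[truth, ] + matrix(rep(reg, each = 40), 40) * 2
  bold <- bold_from_pct(pct, c(5, 5, 5))
  glm <- fit_glm(bold, matrix(reg, ncol = 1))
  tm <- t_test_map(glm, 1, correction = "FWE", alpha = 0.05)
  supra <- as.vector(tm$suprathreshold)
  expect_gte(mean(supra[truth]), 0.95)
  expect_lte(sum(supra[!truth]), 1)
  expect_error(t_test_map(glm, 0), "zeros")
})

test_that("FIR-derived and canonical kernels give comparable ROI t-values", {
  sim <- simulate_calcium_trace(calcium_preset("ogb1", duration_s = 905,
                                               seed = 70))
  trace <- preprocess_calcium(sim$trace)
  ev <- detect_events(trace)
  bs <- simulate_bold_session(bold_sim_config(n_volumes = 905L, seed = 71), ev)
  bold <- preprocess_bold(bs$bold)
  ev_al <- shift_events(ev, 5)
  nt <- n_volumes(bold)
  # session-extracted response kernel (FIR route)
  fit <- fit_fir(bold, build_fir_design(ev_al, fir_config(), n_volumes = nt))
  hr <- extract_mean_hr(fit, select_top_voxels(fit))
  sel <- hr$times_s >= 0 & hr$times_s <= 15
  fir_kernel <- hemodynamic_response(hr$times_s[sel],
                                     hr$values[sel] / max(hr$values[sel]))
  roi_t <- vapply(list(fir_kernel, canonical_hrf(1)), function(kern) {
    reg <- make_regressor(onset_vector(ev_al, 1, nt), kern)
    glm <- fit_glm(bold, matrix(reg, ncol = 1))
    tm <- t_test_map(glm, 1)
    roi_stats(tm$t_map, bs$cortical_mask)
  }, numeric(1))
  expect_lt(abs(roi_t[1] - roi_t[2]) / roi_t[1], 0.15)
})

test_that("whitened residuals lose their serial correlation", {
  cfg <- bold_sim_config(grid_shape = c(4, 4, 2), n_volumes = 1200,
                         response_amplitude_pct = 0, drift_amplitude_pct = 0,
                         ar1_coeff = 0.4, seed = 4)
  bs <- simulate_bold_session(cfg, event_array(numeric(0), numeric(0), 1200))
  glm <- fit_glm(bs$bold, matrix(rnorm(1200), ncol = 1))
  R <- glm$Yw - glm$Xw %*% t(glm$betas)
  r1 <- sum(R[-1, ] * R[-1200, ]) / sum(R^2)
  expect_lt(abs(r1), 0.05)
})

test_that("ROI statistics and automatic test selection behave", {
  map <- array(rnorm(27), c(3, 3, 3))
  roi <- array(FALSE, c(3, 3, 3)); roi[1:2, 1, 1] <- TRUE
  expect_equal(roi_stats(map, roi), mean(map[1:2, 1, 1]))
  expect_error(roi_stats(map, array(FALSE, c(3, 3, 3))), "empty")

  set.seed(11)
  a <- rnorm(16)
  same <- compare_rois(a, a)
  expect_gt(same$p_value, 0.99)

  # Gaussian samples shifted by 2 sigma: t-test selected and significant
  hits <- 0
  for (i in 1:20) {
    x <- rnorm(16); y <- rnorm(16) + 2
    res <- compare_rois(x, y)
    if (res$test == "t" && res$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 17)

  # heavily skewed sample routes to the rank-sum test
  skew <- exp(rnorm(100, 0, 1.5))
  res2 <- compare_rois(skew, rnorm(100))
  expect_equal(res2$test, "wilcoxon")
})
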