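test_that("gamma-variate shape solver reproduces descriptive parameters", {
  p <- gamma_variate_params_from_shape(ttp_s = 6.5, fwhm_s = 6.8,
                                       t0_s = 0.7, amp = 0.17)
  t <- seq(0, 40, by = 0.001)
  y <- gamma_variate(t, p)
  expect_equal(t[which.max(y)], 6.5, tolerance = 0.002)
  expect_equal(max(y), 0.17, tolerance = 1e-9)
  above <- range(t[y >= max(y) / 2])
  expect_equal(diff(above), 6.8, tolerance = 0.01)
  expect_equal(gamma_variate(p$t0_s, p), 0)  # zero before onset
})

test_that("FIR design places one indicator per bin for a single onset", {
  sw <- structure(list(bins = as.integer(seq_len(60) == 25), tr_s = 1),
                  class = "slow_wave_vector")
  X <- build_fir_design(sw, fir_config())
  expect_equal(colSums(X), rep(1, 40))
  bt <- attr(X, "bin_times")
  for (j in seq_len(40)) expect_equal(which(X[, j] == 1), 25 + bt[j])

  empty <- structure(list(bins = integer(60), tr_s = 1),
                     class = "slow_wave_vector")
  expect_error(build_fir_design(empty, fir_config()), "no event onsets")
})

test_that("FIR betas equal the pseudo-inverse solution and recover kernels", {
  set.seed(6)
  nt <- 400
  ev <- event_array(sort(c(30, 80, 150, 210, 270, 330)), rep(1, 6), nt)
  X <- build_fir_design(ev, fir_config(), n_volumes = nt)
  kernel <- gamma_variate(0:19, gamma_variate_params_from_shape())
  post <- attr(X, "bin_times") >= 0
  sig <- as.numeric(X[, post] %*% kernel)
  pct <- rbind(sig, sig + rnorm(nt, 0, 0.05), rnorm(nt, 0, 0.05),
               matrix(0, 5, nt))
  bold <- bold_from_pct(pct, c(2, 2, 2))
  fit <- fit_fir(bold, X)

  # oracle: normal equations on the identically normalized data
  M <- matrix(bold$data, ncol = nt)
  Yn <- 100 * (t(M / rowMeans(M)) - 1)
  Xf <- cbind(1, X)
  B <- solve(crossprod(Xf), crossprod(Xf, Yn))
  expect_lt(max(abs(fit$betas - t(B[-1, ]))), 1e-6)

  # noiseless voxel: betas reproduce the kernel (up to mean normalization)
  mu1 <- rowMeans(M)[1]
  expect_equal(unname(fit$betas[1, post] * mu1 / 100), kernel,
               tolerance = 1e-9)
  expect_lt(max(abs(fit$betas[1, !post])) * mu1 / 100, 1e-9)

  # pure-noise voxel: omnibus F not significant
  expect_gt(fit$p[3], 0.01)
})

test_that("rank-deficient FIR designs are rejected", {
  ev <- event_array(30, 1, 100)
  X <- build_fir_design(ev, fir_config(), n_volumes = 100)
  X[, 2] <- X[, 1]
  attr(X, "bin_times") <- attr(X, "bin_times")
  bold <- bold_from_pct(matrix(rnorm(800), 8), c(2, 2, 2))
  expect_error(fit_fir(bold, X), "collinear")
})

test_that("top-voxel selection takes the strongest voxels per slice", {
  dims <- c(5, 5, 3)
  f <- array(0, dims)
  f[] <- seq_len(prod(dims))          # strictly increasing with index
  fit <- list(f = as.numeric(f), p = rep(1e-6, prod(dims)), dims = dims)
  vox <- select_top_voxels(fit, n_per_slice = 10)
  # slice 3 holds the largest values; per slice the top-10 must be selected
  nxy <- 25
  expected <- c(sapply(1:3, function(z) (z * nxy):(z * nxy - 9)))
  expect_setequal(vox, expected)

  # exclusion mask: next-ranked voxel substituted
  excl <- array(FALSE, dims)
  excl[5, 5, 3] <- TRUE   # the single largest voxel
  vox2 <- select_top_voxels(fit, n_per_slice = 10, exclusion_mask = excl)
  expect_false(prod(dims) %in% vox2)
  expect_true((prod(dims) - 10) %in% vox2)

  fit0 <- list(f = rep(0, prod(dims)), p = rep(1, prod(dims)), dims = dims)
  expect_error(select_top_voxels(fit0), "no active voxels")
})

test_that("mean HR extraction averages and baselines correctly", {
  bt <- -20:19
  kernel <- c(rep(0, 20), gamma_variate(0:19, gamma_variate_params_from_shape()))
  fit <- list(betas = matrix(rep(kernel, each = 30), nrow = 30),
              bin_times = bt)
  hr <- extract_mean_hr(fit, 1:30)
  expect_equal(hr$values, kernel)       # identical HRs -> that HR
  hr1 <- extract_mean_hr(fit, 1)
  expect_equal(hr1$values, kernel)      # single voxel -> identity

  set.seed(7)
  noisy <- fit
  noisy$betas <- noisy$betas + matrix(rnorm(30 * 40, 0, 0.05), 30)
  hrn <- extract_mean_hr(noisy, 1:30)
  expect_lt(max(abs(hrn$values - kernel)), 5 * 0.05 / sqrt(30))
  expect_error(extract_mean_hr(fit, integer(0)), "at least one voxel")
})

test_that("leave-one-out HRF averaging excludes the held-out session", {
  tt <- 0:19
  mk <- function(amp) hemodynamic_response(tt, amp * gamma_variate(
    tt, gamma_variate_params_from_shape()))
  hrs <- list(mk(1), mk(2), mk(4))
  k <- assemble_leave_n_out_hrf(hrs, held_out = 1, response_support_s = c(0, 15))
  expected <- (hrs[[2]]$values + hrs[[3]]$values) / 2
  expected <- expected[tt <= 15] / max(expected[tt <= 15])
  expect_equal(k$values, expected)
  expect_equal(max(k$values), 1)

  same <- list(mk(1), mk(1), mk(1))
  k2 <- assemble_leave_n_out_hrf(same, 2)
  expect_equal(k2$values, mk(1)$values[tt <= 15] / max(mk(1)$values))

  expect_error(assemble_leave_n_out_hrf(hrs[1], 1), "circular")
  expect_error(assemble_leave_n_out_hrf(hrs, 5), "out of range")
})

test_that("canonical HRF has the conventional double-gamma shape", {
  h <- canonical_hrf(1)
  expect_equal(h$values[1], 0, tolerance = 1e-6)      # zero at t = 0
  expect_gt(sum(h$values), 0)                          # positive integral
  expect_true(h$times_s[which.max(h$values)] %in% c(5, 6))
})

test_that("gamma-variate fitting is exact on self-consistent data", {
  truth <- gamma_variate_params(1, 2, 1.5, amp = 0.2)
  tt <- seq(-5, 20, by = 1)
  hr <- hemodynamic_response(tt, gamma_variate(tt, truth))
  fit <- fit_gamma_variate(hr)
  expect_equal(fit$params$t0_s, 1, tolerance = 1e-5)
  expect_equal(fit$params$alpha, 2, tolerance = 1e-4)
  expect_equal(fit$params$beta_s, 1.5, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)
  # closed-form peak location
  q <- quantify_hr(hr, fit)
  expect_equal(q$ttp_s, 1 + 2 * 1.5, tolerance = 1e-4)

  flat <- hemodynamic_response(tt, rep(0, length(tt)))
  expect_error(fit_gamma_variate(flat), "flat")
})

test_that("HR quantification matches constructed geometry", {
  # curve constructed to the reported response parameters
  p <- gamma_variate_params_from_shape(6.5, 6.8, 0.7, 0.17)
  tt <- -5:20
  hr <- hemodynamic_response(tt, gamma_variate(tt, p))
  q <- quantify_hr(hr, fit_gamma_variate(hr))
  expect_equal(q$ttp_s, 6.5, tolerance = 0.2)
  expect_equal(q$dsa_pct, 0.17, tolerance = 0.17 * 0.02)
  expect_equal(q$hmd_s, 6.8, tolerance = 0.2)

  # symmetric triangle, base 10 s, apex 1.0 at 5 s (sampled route)
  tt2 <- 0:10
  tri <- hemodynamic_response(tt2, pmax(0, 1 - abs(tt2 - 5) / 5))
  q2 <- quantify_hr(tri)
  expect_equal(q2$ttp_s, 5)
  expect_equal(q2$hmd_s, 5, tolerance = 1e-9)

  zero <- hemodynamic_response(tt2, rep(0, 11))
  expect_true(quantify_hr(zero)$flagged)
})

test_that("quantification inverts gamma-variate construction", {
  for (ttp in c(5, 6.5, 8)) {
    p <- gamma_variate_params_from_shape(ttp, 6, 0.5, 0.2)
    tt <- -5:20
    hr <- hemodynamic_response(tt, gamma_variate(tt, p))
    q <- quantify_hr(hr, fit_gamma_variate(hr))
    expect_equal(q$ttp_s, ttp, tolerance = 0.2)
    expect_equal(q$dsa_pct, 0.2, tolerance = 0.2 * 0.02)
    expect_equal(q$hmd_s, 6, tolerance = 0.2)
  }
})
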