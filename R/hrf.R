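#' Gamma-variate parameter set
#'
#' Unit-peak gamma-variate parameterization of a hemodynamic response:
#' `y(t) = amp * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t > t0`, else 0.  The peak of height `amp` occurs at
#' `t0 + alpha*beta`.
#'
#' @param t0_s Onset latency, seconds.
#' @param alpha Shape parameter (> 0, unitless).
#' @param beta_s Scale parameter, seconds (> 0).
#' @param amp Peak amplitude (percent signal change for BOLD responses).
#' @return A `gamma_variate_params` list.
#' @export
gamma_variate_params <- function(t0_s, alpha, beta_s, amp = 1) {
  stopifnot(alpha > 0, beta_s > 0)
  structure(list(t0_s = t0_s, alpha = alpha, beta_s = beta_s, amp = amp),
            class = "gamma_variate_params")
}

#' Evaluate a gamma-variate curve
#'
#' @param t Times, seconds.
#' @param params A `gamma_variate_params`.
#' @return Numeric vector of curve values.
#' @export
gamma_variate <- function(t, params) {
  u <- (t - params$t0_s) / (params$alpha * params$beta_s)
  y <- numeric(length(t))
  pos <- u > 0
  y[pos] <- params$amp * u[pos]^params$alpha * exp(params$alpha * (1 - u[pos]))
  y
}

# relative half-maximum width of a unit-peak gamma variate: the two
# solutions of alpha*(log x + 1 - x) = -log 2, scaled by alpha*beta
gv_halfwidth_rel <- function(alpha) {
  f <- function(x) alpha * (log(x) + 1 - x) + log(2)
  x1 <- stats::uniroot(f, c(1e-8, 1), tol = 1e-12)$root
  x2 <- stats::uniroot(f, c(1, 50), tol = 1e-12)$root
  x2 - x1
}

#' Gamma-variate parameters from descriptive response shape
#'
#' Derives `(t0, alpha, beta)` from the descriptive quantities a response
#' is usually reported by: time-to-peak, full width at half maximum, and
#' onset latency.  Defaults reproduce the slow-wave BOLD response: peak
#' 0.17% signal change at 6.5 s with half-maximum duration 6.8 s and onset
#' latency 0.7 s.
#'
#' @param ttp_s Time-to-peak from event onset, seconds.
#' @param fwhm_s Full width at half maximum, seconds.
#' @param t0_s Onset latency, seconds.
#' @param amp Peak amplitude.
#' @return A `gamma_variate_params`.
#' @export
gamma_variate_params_from_shape <- function(ttp_s = 6.5, fwhm_s = 6.8,
                                            t0_s = 0.7, amp = 0.17) {
  p <- ttp_s - t0_s
  stopifnot(p > 0, fwhm_s > 0)
  g <- function(a) gv_halfwidth_rel(a) - fwhm_s / p
  alpha <- stats::uniroot(g, c(0.3, 80), tol = 1e-10)$root
  gamma_variate_params(t0_s, alpha, p / alpha, amp)
}

#' FIR basis configuration
#'
#' @param n_bins Number of FIR time bins (default 40).
#' @param bin_s Bin width, seconds (default 1, equal to the TR).
#' @param window_start_s Start of the estimation window relative to event
#'   onset, seconds (default -20; with 40 bins of 1 s the window spans
#'   -20 s to +20 s).
#' @param response_support_s Interval treated as the response proper when a
#'   curve is re-used as a convolution kernel (default 0 to 15 s, where the
#'   timecourse has returned to baseline).
#' @return A `fir_config` list.
#' @export
fir_config <- function(n_bins = 40L, bin_s = 1, window_start_s = -20,
                       response_support_s = c(0, 15)) {
  stopifnot(n_bins >= 1, bin_s > 0)
  structure(list(n_bins = as.integer(n_bins), bin_s = bin_s,
                 window_start_s = window_start_s,
                 response_support_s = response_support_s),
            class = "fir_config")
}

# onset volumes from a slow-wave vector: starts of 1-runs
sw_onset_volumes <- function(sw) {
  b <- sw$bins
  which(diff(c(0L, b)) == 1L)
}

#' Build an FIR design matrix
#'
#' Column j carries a 1 at volume v iff an event onset occurred at volume
#' `v - offset_j`, with offsets spanning the estimation window.  Onsets are
#' the rising edges of the slow-wave vector (or the onset volumes of an
#' `event_array`).
#'
#' @param sw A `slow_wave_vector` (or an `event_array`; then `n_volumes`
#'   must be given).
#' @param config A `fir_config`.
#' @param n_volumes Number of volumes (required for an `event_array`).
#' @return Numeric design matrix (volumes x n_bins) with attribute
#'   `"bin_times"` (lag of each column, seconds).
#' @export
build_fir_design <- function(sw, config = fir_config(), n_volumes = NULL) {
  if (inherits(sw, "event_array")) {
    if (is.null(n_volumes)) stop("n_volumes required with an event_array")
    tr <- config$bin_s
    ons <- onset_volumes(sw, tr, n_volumes)
    nt <- n_volumes
  } else {
    ons <- sw_onset_volumes(sw)
    nt <- length(sw$bins)
  }
  if (!length(ons)) stop("no event onsets in the slow-wave vector")
  offsets <- round(config$window_start_s / config$bin_s) + seq_len(config$n_bins) - 1L
  X <- matrix(0, nrow = nt, ncol = config$n_bins)
  for (j in seq_len(config$n_bins)) {
    v <- ons + offsets[j]
    v <- v[v >= 1L & v <= nt]
    X[v, j] <- X[v, j] + 1
  }
  attr(X, "bin_times") <- offsets * config$bin_s
  X
}

#' Fit the FIR model voxel-wise
#'
#' Ordinary least squares of each voxel timecourse on the FIR basis plus an
#' intercept.  Voxel timecourses are normalized to percent signal change
#' about their temporal mean, so betas are in percent units.
#'
#' @param bold A (preprocessed) `bold_session`.
#' @param design FIR design matrix from [build_fir_design()].
#' @return A `fir_fit` list: `betas` (voxel x bin matrix, percent), `f`
#'   and `p` (omnibus F-test over all bins, per voxel), `df`, `bin_times`,
#'   `dims` (grid), `mask`.
#' @export
fit_fir <- function(bold, design) {
  stopifnot(inherits(bold, "bold_session"))
  nt <- n_volumes(bold)
  stopifnot(nrow(design) == nt)
  bt <- attr(design, "bin_times")
  hp_df <- 0L
  if (!is.null(bold$hp_basis)) {   # match the session's high-pass filtering
    D <- bold$hp_basis
    design <- design - D %*% crossprod(D, design)
    hp_df <- ncol(D)
  }
  X <- cbind(intercept = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)]) - 1L
    stop("rank-deficient FIR design; collinear bins: ",
         paste(bad, collapse = ", "))
  }
  M <- bold_matrix(bold)               # voxels x time
  mu <- rowMeans(M)
  mu[mu == 0] <- 1
  Y <- 100 * (t(M / mu) - 1)           # time x voxels, percent
  B <- qr.coef(qrX, Y)                 # p x voxels
  fitted <- X %*% B
  rss_full <- colSums((Y - fitted)^2)
  rss_red <- colSums(sweep(Y, 2, colMeans(Y))^2)
  q <- ncol(design)
  df2 <- nt - ncol(X) - hp_df
  f <- ((rss_red - rss_full) / q) / (rss_full / df2)
  f[rss_full <= 1e-12] <- Inf
  p <- stats::pf(f, q, df2, lower.tail = FALSE)
  structure(list(betas = t(B[-1L, , drop = FALSE]),
                 f = f, p = p, df = c(q, df2),
                 bin_times = bt,
                 dims = dim(bold$data)[1:3],
                 mask = bold$brain_mask),
            class = "fir_fit")
}

#' Select the most active voxels for timecourse extraction
#'
#' Identifies the slice (third array dimension) containing the most
#' suprathreshold voxels in the F-map, then takes the `n_per_slice` voxels
#' of highest F in that slice and its two neighbours (30 voxels in total
#' for the default 10/slice).  Voxels under the exclusion mask (e.g. the
#' sinus vein) are skipped; ties are broken by ascending linear index.
#'
#' @param fit A `fir_fit` (or any list with `f`, `p`, `dims`).
#' @param n_per_slice Voxels taken per slice (default 10).
#' @param exclusion_mask Optional logical 3D array; TRUE = excluded.
#' @param alpha Significance level applied to the per-voxel omnibus p-values
#'   (default 0.05, uncorrected).
#' @return Integer vector of linear voxel indices.
#' @export
select_top_voxels <- function(fit, n_per_slice = 10L, exclusion_mask = NULL,
                              alpha = 0.05) {
  dims <- fit$dims
  f <- array(fit$f, dims)
  p <- array(fit$p, dims)
  eligible <- p < alpha & f > 0
  if (!is.null(exclusion_mask)) eligible <- eligible & !exclusion_mask
  if (!any(eligible, na.rm = TRUE)) stop("no active voxels")
  per_slice <- apply(eligible, 3, sum, na.rm = TRUE)
  # ties between equally active slices: prefer the most active 3-slice window
  nb <- per_slice +
    c(per_slice[-1], 0) + c(0, per_slice[-length(per_slice)])
  z0 <- which.max(per_slice + 1e-3 * nb / max(1, max(nb)))
  slices <- unique(pmin(pmax(z0 + (-1:1), 1L), dims[3]))
  sel <- integer(0)
  nxy <- dims[1] * dims[2]
  for (z in slices) {
    idx <- (z - 1L) * nxy + seq_len(nxy)
    ok <- idx[eligible[idx]]
    if (!length(ok)) next
    if (length(ok) < n_per_slice)
      warning(sprintf("slice %d has only %d eligible voxels", z, length(ok)))
    ord <- ok[order(-f[ok], ok)]
    sel <- c(sel, ord[seq_len(min(n_per_slice, length(ord)))])
  }
  sel
}

#' Construct a hemodynamic response curve
#'
#' @param times_s Bin times relative to event onset, strictly increasing.
#' @param values Percent signal change per bin.
#' @param baseline_def Description of the baseline convention.
#' @return A `hemodynamic_response` object.
#' @export
hemodynamic_response <- function(times_s, values,
                                 baseline_def = "mean of 5 s pre-onset") {
  stopifnot(length(times_s) == length(values),
            !is.unsorted(times_s, strictly = TRUE), all(is.finite(values)))
  structure(list(times_s = times_s, values = values,
                 baseline_def = baseline_def),
            class = "hemodynamic_response")
}

#' Extract the mean hemodynamic response of selected voxels
#'
#' Averages the per-voxel FIR beta series over the selected voxels and
#' subtracts the baseline, defined as the mean of the bins in the 5 s
#' preceding onset.
#'
#' @param fit A `fir_fit`.
#' @param voxels Linear voxel indices (>= 1 voxel).
#' @return A `hemodynamic_response`.
#' @export
extract_mean_hr <- function(fit, voxels) {
  if (!length(voxels)) stop("need at least one voxel")
  hr <- colMeans(fit$betas[voxels, , drop = FALSE])
  tt <- fit$bin_times
  pre <- tt >= -5 & tt < 0
  if (any(pre)) hr <- hr - mean(hr[pre])
  hemodynamic_response(tt, hr)
}

#' Assemble a leave-one-out HRF kernel
#'
#' Averages the hemodynamic responses of all sessions except the held-out
#' one (avoiding circular analysis), truncates to the response support
#' (default 0 to 15 s, where the timecourses have returned to baseline),
#' and normalizes to unit peak for use as a convolution kernel.
#'
#' @param hrs List of `hemodynamic_response` objects on a common time grid.
#' @param held_out Index of the session being analyzed.
#' @param response_support_s Kept interval, seconds.
#' @return A `hemodynamic_response` kernel (unit peak).
#' @export
assemble_leave_n_out_hrf <- function(hrs, held_out,
                                     response_support_s = c(0, 15)) {
  if (length(hrs) < 2L)
    stop("need at least 2 sessions to avoid circular analysis")
  if (held_out < 1L || held_out > length(hrs))
    stop("held_out index out of range")
  keep <- hrs[-held_out]
  tt <- keep[[1L]]$times_s
  for (h in keep) stopifnot(isTRUE(all.equal(h$times_s, tt)))
  avg <- rowMeans(vapply(keep, function(h) h$values, numeric(length(tt))))
  sel <- tt >= response_support_s[1] & tt <= response_support_s[2]
  v <- avg[sel]
  if (max(v) <= 0) stop("averaged HR has non-positive peak")
  hemodynamic_response(tt[sel], v / max(v), baseline_def = "unit peak kernel")
}

#' Canonical double-gamma HRF
#'
#' The conventional canonical hemodynamic response modeled as the
#' difference of two gamma densities (response peak 6 s, undershoot peak
#' 16 s, undershoot ratio 1/6), sampled at the TR and normalized to unit
#' peak.
#'
#' @param tr_s Repetition time, seconds.
#' @param duration_s Kernel length, seconds (default 32).
#' @return A `hemodynamic_response` kernel.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  hemodynamic_response(t, h / max(h), baseline_def = "unit peak kernel")
}

#' Fit a gamma-variate function to a hemodynamic response
#'
#' Nonlinear least squares of the unit-peak gamma-variate model (see
#' [gamma_variate_params()]) to the post-onset part of a response curve,
#' with multi-start initial values derived from the curve's peak location
#' and width.  An optional centered moving-average smoothing (as applied to
#' noisy per-voxel curves) can be requested via `smooth_n`.
#'
#' @param hr A `hemodynamic_response` covering at least 0--15 s.
#' @param support_s Time interval used for fitting (default 0--20 s).
#' @param smooth_n Moving-average width in bins (odd; 1 = no smoothing).
#' @return A list: `params` (`gamma_variate_params`), `r_squared`,
#'   `fitted` (values on the fitted time grid), `times_s`.
#' @export
fit_gamma_variate <- function(hr, support_s = c(0, 20), smooth_n = 1L) {
  tt <- hr$times_s
  y <- hr$values
  if (smooth_n > 1L) {
    k <- rep(1 / smooth_n, smooth_n)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    ok <- !is.na(y)
    tt <- tt[ok]; y <- y[ok]
  }
  sel <- tt >= support_s[1] & tt <= support_s[2]
  tt <- tt[sel]; y <- y[sel]
  if (length(tt) < 6L) stop("response must cover the fitting support")
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("flat or non-positive response; cannot fit gamma variate")
  ttp0 <- tt[which.max(y)]
  amp0 <- max(y)
  model <- function(t, t0, alpha, beta, amp) {
    u <- pmax(t - t0, 0) / (alpha * beta)
    ifelse(u > 0, amp * u^alpha * exp(alpha * (1 - u)), 0)
  }
  best <- NULL
  for (t00 in unique(pmax(0, c(0, 0.5, 1, ttp0 / 4)))) {
    for (alpha0 in c(2, 4, 8)) {
      p0 <- max(ttp0 - t00, 0.5)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ model(tt, t0, alpha, beta, amp),
          start = list(t0 = t00, alpha = alpha0, beta = p0 / alpha0,
                       amp = amp0),
          lower = c(t0 = -5, alpha = 0.1, beta = 0.01, amp = 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("gamma-variate fit did not converge from any start")
  cf <- stats::coef(best$fit)
  params <- gamma_variate_params(unname(cf["t0"]), unname(cf["alpha"]),
                                 unname(cf["beta"]), unname(cf["amp"]))
  sst <- sum((y - mean(y))^2)
  list(params = params,
       r_squared = 1 - best$rss / sst,
       fitted = model(tt, cf["t0"], cf["alpha"], cf["beta"], cf["amp"]),
       times_s = tt)
}

# interpolated width at half of the peak for a sampled curve
half_max_width <- function(tt, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  up <- cross_time_generic(tt, y, half, pk, rising = TRUE)
  dn <- cross_time_generic(tt, y, half, pk, rising = FALSE)
  if (is.na(up) || is.na(dn)) return(NA_real_)
  dn - up
}

cross_time_generic <- function(tt, y, level, pk, rising = TRUE) {
  if (rising) {
    below <- which(y[seq_len(pk)] < level)
    if (!length(below)) return(tt[1L])
    i <- max(below)
    tt[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (tt[i + 1L] - tt[i])
  } else {
    above <- which(y[pk:length(y)] >= level) + pk - 1L
    i <- max(above)
    if (i >= length(y)) return(tt[length(y)])
    tt[i] + (y[i] - level) / (y[i] - y[i + 1L]) * (tt[i + 1L] - tt[i])
  }
}

#' Quantify a hemodynamic response
#'
#' Computes time-to-peak (TTP), normalized peak amplitude over the
#' pre-onset baseline (delta-SA), half-maximum duration (HMD), and onset
#' latency.  When a gamma-variate fit is supplied the quantities are
#' evaluated on the fitted curve (TTP = t0 + alpha*beta, amplitude = fitted
#' peak, HMD solved on the continuous curve, latency = t0); otherwise they
#' are read off the sampled response with linear interpolation at the
#' half-maximum crossings.
#'
#' @param hr A `hemodynamic_response`.
#' @param fit Optional result of [fit_gamma_variate()].
#' @return A list of class `hr_quant`: `ttp_s`, `dsa_pct`, `hmd_s`,
#'   `onset_latency_s`, `flagged`.
#' @export
quantify_hr <- function(hr, fit = NULL) {
  if (!is.null(fit)) {
    p <- fit$params
    ttp <- p$t0_s + p$alpha * p$beta_s
    curve_t <- seq(max(0, p$t0_s), max(fit$times_s) + 10, by = 0.01)
    curve <- gamma_variate(curve_t, p)
    hmd <- half_max_width(curve_t, curve)
    out <- list(ttp_s = ttp, dsa_pct = p$amp, hmd_s = hmd,
                onset_latency_s = p$t0_s, flagged = FALSE)
  } else {
    tt <- hr$times_s
    y <- hr$values
    post <- tt >= 0
    yp <- y[post]; tp <- tt[post]
    pk <- which.max(yp)
    if (yp[pk] <= 0) {
      out <- list(ttp_s = NA_real_, dsa_pct = yp[pk], hmd_s = NA_real_,
                  onset_latency_s = NA_real_, flagged = TRUE)
    } else {
      hmd <- half_max_width(tp, yp)
      out <- list(ttp_s = tp[pk], dsa_pct = yp[pk], hmd_s = hmd,
                  onset_latency_s = NA_real_,
                  flagged = is.na(hmd))
    }
  }
  class(out) <- "hr_quant"
  out
}

#' @export
print.hr_quant <- function(x, ...) {
  cat(sprintf("<hr_quant> TTP %.2f s, dSA %.3f%%, HMD %.2f s, onset %.2f s\n",
              x$ttp_s, x$dsa_pct, x$hmd_s,
              ifelse(is.na(x$onset_latency_s), NA, x$onset_latency_s)))
  invisible(x)
}
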