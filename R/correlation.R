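#' Label connected clusters in a 3D mask
#'
#' Connected-component labelling with 26-neighbourhood connectivity
#' (faces, edges and corners).
#'
#' @param mask Logical 3D array.
#' @return Integer 3D array of cluster labels (0 = background).
#' @export
label_clusters <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  lab <- array(0L, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(mask)
  nxt <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      co <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        nb <- co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
          (nb[ok, 3] - 1L) * dims[1] * dims[2]
        new <- lin[mask[lin] & lab[lin] == 0L]
        if (length(new)) {
          lab[new] <- nxt
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# keep clusters of at least min_voxels; returns list(mask, clusters)
filter_clusters <- function(mask, min_voxels) {
  lab <- label_clusters(mask)
  sizes <- tabulate(lab)
  keep_lab <- which(sizes >= min_voxels)
  out <- array(lab %in% keep_lab, dim(mask))
  clusters <- lapply(keep_lab, function(l) which(lab == l))
  list(mask = out, clusters = clusters)
}

#' Seed-based correlation map
#'
#' Correlates the mean timecourse of a seed region with every voxel of the
#' target mask, thresholds the r-map, and retains connected clusters
#' (26-connectivity) of at least `min_cluster` voxels.
#'
#' @param bold A preprocessed `bold_session`.
#' @param seed_mask Logical 3D array defining the seed.
#' @param target_mask Logical 3D array of voxels to correlate (default:
#'   the session brain mask).
#' @param r_thresh Correlation threshold (default 0.5).
#' @param min_cluster Minimum cluster extent in voxels (default 300).
#' @return A `correlation_map`: `r_volume` (3D), `threshold`, `clusters`
#'   (list of voxel index vectors), `n_clusters`, `supra_mask`.
#' @export
seed_correlation_map <- function(bold, seed_mask, target_mask = NULL,
                                 r_thresh = 0.5, min_cluster = 300L) {
  stopifnot(inherits(bold, "bold_session"))
  if (is.null(target_mask)) target_mask <- bold$brain_mask
  M <- bold_matrix(bold)
  seed_tc <- colMeans(M[as.vector(seed_mask), , drop = FALSE])
  if (stats::sd(seed_tc) == 0) stop("seed timecourse has zero variance")
  tv <- which(as.vector(target_mask))
  r <- rep(NA_real_, nrow(M))
  r[tv] <- suppressWarnings(
    as.numeric(stats::cor(seed_tc, t(M[tv, , drop = FALSE]))))
  r_vol <- array(r, dim(bold$data)[1:3])
  supra <- !is.na(r_vol) & r_vol >= r_thresh
  fc <- filter_clusters(supra, min_cluster)
  structure(list(r_volume = r_vol, threshold = r_thresh,
                 clusters = fc$clusters, n_clusters = length(fc$clusters),
                 supra_mask = fc$mask),
            class = "correlation_map")
}

# event-locked average response per voxel: rows = voxels, cols = post-onset
# volumes 0..n_post-1; per-event baseline (mean of n_base pre-onset volumes)
# subtracted before averaging
event_locked_responses <- function(M, onset_vols, n_post, n_base = 5L) {
  nt <- ncol(M)
  ok <- onset_vols[onset_vols - n_base >= 1L & onset_vols + n_post - 1L <= nt]
  if (length(ok) < 1L) stop("no events with a complete response window")
  acc <- matrix(0, nrow(M), n_post)
  for (o in ok) {
    seg <- M[, o:(o + n_post - 1L), drop = FALSE]
    base <- rowMeans(M[, (o - n_base):(o - 1L), drop = FALSE])
    acc <- acc + (seg - base)
  }
  acc / length(ok)
}

#' Calcium-informed correlation and TTP mapping
#'
#' Computes the event-locked average BOLD response of every voxel (after
#' per-voxel baseline correction with a 100 s rolling window), correlates
#' it with the reference response averaged over an ROI, thresholds at
#' `r_thresh`, removes clusters smaller than `min_cluster` contiguous
#' voxels, and derives a time-to-peak map (onset to maximum of the
#' event-locked response) over the surviving region.
#'
#' @param bold A `bold_session` (smoothed; drift handled internally).
#' @param events An `event_array` of slow-wave onsets (>= 5 events).
#' @param roi_mask Logical 3D array defining the reference ROI.
#' @param r_thresh Correlation threshold (default 0.8).
#' @param min_cluster Minimum cluster extent, voxels (default 70).
#' @param window_s Post-onset response window, seconds (default 20).
#' @param baseline_window_s Rolling-baseline window, seconds (default 100).
#' @return A `correlation_map` with additional elements `ttp_volume`
#'   (seconds; NA outside the surviving region) and `reference`
#'   (the reference response curve).
#' @export
calcium_informed_map <- function(bold, events, roi_mask, r_thresh = 0.8,
                                 min_cluster = 70L, window_s = 20,
                                 baseline_window_s = 100) {
  stopifnot(inherits(bold, "bold_session"))
  if (n_events(events) < 5L) stop("insufficient events (need >= 5)")
  nt <- n_volumes(bold)
  tr <- bold$tr_s
  M <- bold_matrix(bold)
  # rolling-median baseline per voxel, window 100 s
  w <- max(4L, round(baseline_window_s / tr))
  Mb <- t(apply(M, 1, function(v)
    v - rolling_quantile_baseline(v, window = w, prob = 0.5)))
  onset_vols <- onset_volumes(events, tr, nt)
  n_post <- round(window_s / tr) + 1L
  EL <- event_locked_responses(Mb, onset_vols, n_post)
  ref <- colMeans(EL[as.vector(roi_mask), , drop = FALSE])
  if (stats::sd(ref) == 0) stop("reference response has zero variance")
  r <- suppressWarnings(as.numeric(stats::cor(ref, t(EL))))
  r_vol <- array(r, dim(bold$data)[1:3])
  supra <- !is.na(r_vol) & r_vol > r_thresh
  fc <- filter_clusters(supra, min_cluster)
  ttp <- array(NA_real_, dim(r_vol))
  surv <- which(fc$mask)
  if (length(surv)) {
    ttp[surv] <- (apply(EL[surv, , drop = FALSE], 1, which.max) - 1L) * tr
  }
  structure(list(r_volume = r_vol, threshold = r_thresh,
                 clusters = fc$clusters, n_clusters = length(fc$clusters),
                 supra_mask = fc$mask, ttp_volume = ttp,
                 reference = ref),
            class = "correlation_map")
}

#' Regress covariates out of a BOLD session
#'
#' Removes, per voxel, the least-squares projection onto the given
#' covariate timecourses (plus an intercept), leaving the residual signal.
#'
#' @param bold A `bold_session`.
#' @param covariates Numeric matrix (volumes x k) of covariate
#'   timecourses (e.g. slow-wave regressors to be eliminated).
#' @return A `bold_session` containing the residuals.
#' @export
regress_out <- function(bold, covariates) {
  covariates <- as.matrix(covariates)
  nt <- n_volumes(bold)
  stopifnot(nrow(covariates) == nt)
  if (ncol(covariates) + 1L >= nt) stop("covariates must span fewer than n_volumes")
  X <- cbind(1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear covariates")
  M <- bold_matrix(bold)
  R <- t(qr.resid(qrX, t(M)))
  out <- bold
  out$data <- array(R, dim(bold$data))
  out
}

#' Lagged cross-correlation of two equally sampled signals
#'
#' Pearson correlation at every integer-sample lag within `max_lag_s`,
#' with the convention that a positive peak lag means `b` lags `a`.
#'
#' @param a,b Numeric vectors of equal length.
#' @param max_lag_s Maximum lag, seconds.
#' @param fs_hz Common sampling rate, Hz.
#' @return List with `lags_s`, `r`, `peak_lag_s`, `peak_r`.
#' @export
cross_correlate <- function(a, b, max_lag_s, fs_hz) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input")
  lag_max <- round(max_lag_s * fs_hz)
  cc <- stats::ccf(a, b, lag.max = lag_max, plot = FALSE, demean = TRUE)
  # ccf lag k correlates a_{t+k} with b_t; flip so positive lag = b delayed
  lags <- -as.numeric(cc$lag) / fs_hz
  r <- as.numeric(cc$acf)
  ord <- order(lags)
  lags <- lags[ord]; r <- r[ord]
  pk <- which.max(r)
  list(lags_s = lags, r = r, peak_lag_s = lags[pk], peak_r = r[pk])
}
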