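#' Preprocess a BOLD session
#'
#' Discards the initial volumes (steady-state), smooths each volume with a
#' 3D Gaussian kernel of the given FWHM (converted to voxel units via the
#' header geometry; edge-renormalized so constant images are preserved),
#' and removes low-frequency drift with a discrete-cosine high-pass set
#' (cutoff `1/highpass_cutoff_s`; the voxel mean/DC component is retained).
#'
#' @param raw A `bold_session`.
#' @param fwhm_mm Gaussian smoothing FWHM, mm (default 0.5).  Smoothing is
#'   skipped with a warning if `fwhm_mm` is below a quarter of the smallest
#'   voxel edge.
#' @param highpass_cutoff_s High-pass cutoff period, seconds (default 128).
#' @param n_discard Initial volumes to discard (default 5).
#' @return The preprocessed `bold_session`.
#' @export
preprocess_bold <- function(raw, fwhm_mm = 0.5, highpass_cutoff_s = 128,
                            n_discard = 5L) {
  stopifnot(inherits(raw, "bold_session"))
  nt <- n_volumes(raw)
  if (nt < n_discard + 40) stop("too few volumes after discarding")
  data <- raw$data[, , , (n_discard + 1L):nt, drop = FALSE]
  dims <- dim(data)
  # --- spatial smoothing --------------------------------------------------
  if (fwhm_mm < min(raw$voxel_size_mm) / 4) {
    if (fwhm_mm > 0)
      warning("FWHM below voxel size / 4; smoothing skipped")
  } else {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / raw$voxel_size_mm
    for (ax in 1:3) {
      if (dims[ax] > 1 && sigma_vox[ax] > 0.05)
        data <- smooth_along_axis(data, ax, sigma_vox[ax])
    }
  }
  # --- discrete-cosine high-pass -----------------------------------------
  ntv <- dims[4]
  K <- floor(2 * (ntv * raw$tr_s) / highpass_cutoff_s)
  D <- NULL
  if (K >= 1L) {
    t_idx <- seq_len(ntv)
    D <- vapply(seq_len(K), function(k)
      cos(pi * k * (2 * t_idx - 1) / (2 * ntv)), numeric(ntv))
    D <- qr.Q(qr(D))
    M <- matrix(data, nrow = prod(dims[1:3]), ncol = ntv)  # voxels x time
    M <- M - t(D %*% crossprod(D, t(M)))
    data <- array(M, dims)
  }
  out <- bold_session(data, tr_s = raw$tr_s,
                      voxel_size_mm = raw$voxel_size_mm,
                      brain_mask = raw$brain_mask,
                      n_discarded = raw$n_discarded + n_discard)
  # the high-pass basis must also be projected out of any design fitted to
  # this session (Frisch-Waugh); model fitters pick it up from here
  out$hp_basis <- D
  out
}

# separable Gaussian smoothing along one spatial axis of a 4D array,
# kernel renormalized at the edges
smooth_along_axis <- function(data, axis, sigma_vox) {
  dims <- dim(data)
  n <- dims[axis]
  half <- max(1L, ceiling(3 * sigma_vox))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    G[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  perm <- c(axis, setdiff(1:4, axis))
  a <- aperm(data, perm)
  da <- dim(a)
  m <- G %*% matrix(a, nrow = n)
  aperm(array(m, da), order(perm))
}

#' Build an event regressor by HRF convolution
#'
#' Convolves the slow-wave vector (a boxcar covering each event's detected
#' onset and duration at volume resolution) with an HRF kernel sampled at
#' the TR, truncates to the session length, and mean-centers.
#'
#' @param sw A `slow_wave_vector`.
#' @param hrf A `hemodynamic_response` kernel sampled at the TR (e.g. from
#'   [canonical_hrf()] or [assemble_leave_n_out_hrf()]).
#' @param mean_center Mean-center the regressor (default TRUE).
#' @return Numeric regressor of length `n_volumes`.
#' @export
make_regressor <- function(sw, hrf, mean_center = TRUE) {
  if (!any(sw$bins > 0)) stop("slow-wave vector contains no events")
  k <- hrf$values
  r <- as.numeric(stats::convolve(as.numeric(sw$bins), rev(k),
                                  type = "open"))[seq_along(sw$bins)]
  if (mean_center) r <- r - mean(r)
  r
}

#' Fit a per-voxel GLM with AR(1) prewhitening
#'
#' Ordinary least squares of every in-mask voxel on `[intercept,
#' regressors]`; serial autocorrelation is handled by estimating a single
#' global AR(1) coefficient from the pooled lag-1 autocorrelation of the
#' OLS residuals and refitting on Cochrane-Orcutt prewhitened data.
#'
#' @param bold A preprocessed `bold_session`.
#' @param regressors Numeric matrix (volumes x k) of regressors.
#' @param ar1 `"auto"` (estimate rho; default), a numeric rho, or 0 to
#'   disable whitening.
#' @return A `glm_result`: `betas` (voxel x p), `sigma2`, `df`, `rho`,
#'   `xtx_inv`, `dims`, `mask`, plus the whitened design and data needed
#'   for F-tests.
#' @export
fit_glm <- function(bold, regressors, ar1 = "auto") {
  stopifnot(inherits(bold, "bold_session"))
  regressors <- as.matrix(regressors)
  nt <- n_volumes(bold)
  stopifnot(nrow(regressors) == nt)
  hp_df <- 0L
  if (!is.null(bold$hp_basis)) {   # match the session's high-pass filtering
    D <- bold$hp_basis
    regressors <- regressors - D %*% crossprod(D, regressors)
    hp_df <- ncol(D)
  }
  X <- cbind(intercept = 1, regressors)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    cc <- stats::cor(X[, -1L, drop = FALSE])
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf("collinear regressors (e.g. columns %d and %d)",
                 worst[1], worst[2]))
  }
  M <- bold_matrix(bold)
  mask_v <- as.vector(bold$brain_mask)
  Y <- t(M)                                # time x voxels
  B <- qr.coef(qrX, Y)
  R <- Y - X %*% B
  rho <- 0
  if (identical(ar1, "auto")) {
    Rm <- R[, mask_v, drop = FALSE]
    rho <- sum(Rm[-1L, ] * Rm[-nt, ]) / sum(Rm^2)
  } else if (is.numeric(ar1)) rho <- ar1
  if (abs(rho) > 1e-3) {
    W <- function(A) {
      A2 <- A[-1L, , drop = FALSE] - rho * A[-nt, , drop = FALSE]
      rbind(sqrt(1 - rho^2) * A[1L, , drop = FALSE], A2)
    }
    Xw <- W(X); Yw <- W(Y)
    qrX <- qr(Xw)
    B <- qr.coef(qrX, Yw)
    R <- Yw - Xw %*% B
  } else {
    Xw <- X; Yw <- Y
  }
  df <- nt - p - hp_df
  sigma2 <- colSums(R^2) / df
  structure(list(betas = t(B), sigma2 = sigma2, df = df, rho = rho,
                 xtx_inv = chol2inv(chol(crossprod(Xw))),
                 Xw = Xw, Yw = Yw,
                 dims = dim(bold$data)[1:3], mask = bold$brain_mask,
                 n_regressors = p - 1L),
            class = "glm_result")
}

#' Extra-sum-of-squares F-test on a fitted GLM
#'
#' Compares the full model against the model with the given regressor
#' subset removed, per voxel.
#'
#' @param glm A `glm_result`.
#' @param regressor_subset Indices of the regressors tested (1-based,
#'   excluding the intercept); default all.
#' @return List with `f_map` and `p_map` (3D arrays) and `df`.
#' @export
f_test <- function(glm, regressor_subset = seq_len(glm$n_regressors)) {
  if (!length(regressor_subset)) stop("regressor subset is empty")
  cols_drop <- regressor_subset + 1L           # skip intercept
  keep <- setdiff(seq_len(ncol(glm$Xw)), cols_drop)
  rss_full <- glm$sigma2 * glm$df
  Xr <- glm$Xw[, keep, drop = FALSE]
  Br <- qr.coef(qr(Xr), glm$Yw)
  rss_red <- colSums((glm$Yw - Xr %*% Br)^2)
  q <- length(cols_drop)
  f <- ((rss_red - rss_full) / q) / (rss_full / glm$df)
  f[rss_full <= 1e-12] <- Inf
  p <- stats::pf(f, q, glm$df, lower.tail = FALSE)
  f[!as.vector(glm$mask)] <- NA
  p[!as.vector(glm$mask)] <- NA
  list(f_map = array(f, glm$dims), p_map = array(p, glm$dims),
       df = c(q, glm$df))
}

#' Thresholded t-map for a contrast
#'
#' Per-voxel t statistic for a contrast of the regressor coefficients,
#' with family-wise error control by Bonferroni correction over the
#' in-mask voxels (or uncorrected thresholding).
#'
#' @param glm A `glm_result`.
#' @param contrast Numeric contrast over the regressors (recycled to
#'   length; the intercept is not part of the contrast).
#' @param correction `"FWE"` (Bonferroni; default) or `"none"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `t_map`, `p_map`, `suprathreshold` (logical 3D),
#'   `threshold_info`.
#' @export
t_test_map <- function(glm, contrast, correction = c("FWE", "none"),
                       alpha = 0.05) {
  correction <- match.arg(correction)
  k <- glm$n_regressors
  contrast <- rep_len(as.numeric(contrast), k)
  if (all(contrast == 0)) stop("contrast is all zeros")
  cvec <- c(0, contrast)
  eff <- as.numeric(glm$betas %*% cvec)
  se <- sqrt(glm$sigma2 * as.numeric(t(cvec) %*% glm$xtx_inv %*% cvec))
  tt <- eff / se
  p <- 2 * stats::pt(abs(tt), glm$df, lower.tail = FALSE)
  mask_v <- as.vector(glm$mask)
  n_test <- sum(mask_v)
  thr_p <- if (correction == "FWE") alpha / n_test else alpha
  supra <- p < thr_p & mask_v
  tt[!mask_v] <- NA
  p[!mask_v] <- NA
  list(t_map = array(tt, glm$dims), p_map = array(p, glm$dims),
       suprathreshold = array(supra, glm$dims),
       threshold_info = list(alpha = alpha, correction = correction,
                             n_tests = n_test, p_threshold = thr_p))
}

#' Mean statistic inside an ROI
#'
#' @param map 3D statistic array.
#' @param roi_mask Logical 3D array.
#' @return Mean of the map inside the ROI.
#' @export
roi_stats <- function(map, roi_mask) {
  stopifnot(all(dim(map) == dim(roi_mask)))
  if (!any(roi_mask)) stop("empty ROI")
  mean(map[roi_mask], na.rm = TRUE)
}

#' Compare two ROI samples with automatic test selection
#'
#' Tests each sample for normality with the Lilliefors adaptation of the
#' Kolmogorov-Smirnov test; if normality is not rejected for either
#' (p > 0.05) a two-tailed Student t-test is used, otherwise the
#' Wilcoxon rank-sum (or signed-rank, if paired) test.
#'
#' @param a,b Numeric samples (e.g. voxel values of two ROIs).
#' @param paired Paired comparison (default FALSE).
#' @return List with `test` ("t" or "wilcoxon"), `p_value`,
#'   `normality_p` (per sample).
#' @export
compare_rois <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5L || length(b) < 5L)
    stop("need at least 5 finite values per sample")
  pnorm_a <- tryCatch(nortest::lillie.test(a)$p.value, error = function(e) 0)
  pnorm_b <- tryCatch(nortest::lillie.test(b)$p.value, error = function(e) 0)
  if (pnorm_a > 0.05 && pnorm_b > 0.05) {
    res <- stats::t.test(a, b, paired = paired)
    test <- "t"
  } else {
    res <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
    test <- "wilcoxon"
  }
  list(test = test, p_value = res$p.value,
       normality_p = c(a = pnorm_a, b = pnorm_b))
}
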