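#' Construct a BOLD session
#'
#' A 4D voxel-by-time BOLD array with acquisition metadata.
#'
#' @param data 4D numeric array, dimensions (x, y, z, volume).
#' @param tr_s Repetition time, seconds.
#' @param voxel_size_mm Voxel edge lengths (dx, dy, dz) in mm.
#' @param brain_mask Logical 3D array matching the grid; default all-TRUE.
#' @param n_discarded Number of initial volumes already discarded.
#' @return An object of class `bold_session`.
#' @export
bold_session <- function(data, tr_s, voxel_size_mm = c(0.35, 0.325, 1.2),
                         brain_mask = NULL, n_discarded = 0L) {
  stopifnot(length(dim(data)) == 4L, tr_s > 0)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(data)[1:3])
  stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
  structure(list(data = data, tr_s = tr_s,
                 voxel_size_mm = voxel_size_mm,
                 brain_mask = brain_mask,
                 n_discarded = as.integer(n_discarded)),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_session> %dx%dx%d grid, %d volumes @ TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Number of volumes in a session
#' @param bold A `bold_session`.
#' @return Integer volume count.
#' @export
n_volumes <- function(bold) dim(bold$data)[4L]

# voxel x time matrix view (rows = voxels in array order)
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Configuration for the synthetic BOLD generator
#'
#' Emulates an EPI session in which "cortical" voxels carry the slow-wave
#' event vector convolved with a gamma-variate hemodynamic response
#' (default: peak latency 6.5 s, amplitude 0.17% signal change, half-max
#' width 6.8 s, onset latency 0.7 s) on a mean-100 baseline, plus slow
#' drift and temporally autocorrelated AR(1) noise; non-cortical voxels
#' carry drift and noise only.
#'
#' @param grid_shape Voxel grid (nx, ny, nz).
#' @param n_volumes Number of volumes (> 45).
#' @param tr_s Repetition time, seconds (default 1).
#' @param cortical_mask_fraction Fraction of voxels carrying signal; the
#'   mask is a contiguous slab of upper z-slices.
#' @param hrf_params `gamma_variate_params` of the planted response.
#' @param response_amplitude_pct Peak percent signal change of the response
#'   to a single isolated event.
#' @param noise_sd_pct Stationary noise SD, percent of baseline.
#' @param ar1_coeff AR(1) coefficient of the noise, in [0, 1).
#' @param drift_amplitude_pct Amplitude of sinusoidal drift, percent.
#' @param drift_period_s Drift period, seconds.
#' @param stimulus `"impulse"` (one event marker at the onset volume;
#'   default) or `"boxcar"` (markers across the event duration).
#' @param amplitude_profile `"hotspot"` (default): response amplitude falls
#'   off smoothly from a most-responsive in-plane location (peak exactly
#'   `response_amplitude_pct`) to `profile_base` of it at the slab edges,
#'   as over a somatosensory hotspot; `"uniform"`: all cortical voxels
#'   carry the full amplitude.
#' @param profile_base Floor of the hotspot profile (fraction of peak).
#' @param profile_sigma_vox In-plane Gaussian width of the hotspot, voxels.
#' @param voxel_size_mm Voxel geometry, mm.
#' @param seed RNG seed.
#' @return A `bold_sim_config` list.
#' @export
bold_sim_config <- function(grid_shape = c(16, 16, 6), n_volumes = 1800,
                            tr_s = 1, cortical_mask_fraction = 0.5,
                            hrf_params = gamma_variate_params_from_shape(),
                            response_amplitude_pct = 0.17,
                            noise_sd_pct = 0.65, ar1_coeff = 0.3,
                            drift_amplitude_pct = 0.3, drift_period_s = 300,
                            stimulus = c("impulse", "boxcar"),
                            amplitude_profile = c("hotspot", "uniform"),
                            profile_base = 0.85, profile_sigma_vox = 6,
                            voxel_size_mm = c(0.35, 0.325, 1.2),
                            seed = 1L) {
  stopifnot(n_volumes > 45, ar1_coeff >= 0, ar1_coeff < 1,
            cortical_mask_fraction >= 0, cortical_mask_fraction <= 1)
  structure(list(grid_shape = grid_shape, n_volumes = n_volumes,
                 tr_s = tr_s,
                 cortical_mask_fraction = cortical_mask_fraction,
                 hrf_params = hrf_params,
                 response_amplitude_pct = response_amplitude_pct,
                 noise_sd_pct = noise_sd_pct, ar1_coeff = ar1_coeff,
                 drift_amplitude_pct = drift_amplitude_pct,
                 drift_period_s = drift_period_s,
                 stimulus = match.arg(stimulus),
                 amplitude_profile = match.arg(amplitude_profile),
                 profile_base = profile_base,
                 profile_sigma_vox = profile_sigma_vox,
                 voxel_size_mm = voxel_size_mm, seed = seed),
            class = "bold_sim_config")
}

#' Simulate a BOLD session coupled to calcium events
#'
#' @param config A `bold_sim_config`.
#' @param events An `event_array`; all events must lie within
#'   `n_volumes * tr_s`.
#' @return A list with `bold` (a `bold_session`, baseline mean 100),
#'   `cortical_mask` (logical 3D ground-truth mask), and `kernel_pct`
#'   (the planted response sampled at TR, percent signal change).
#' @export
simulate_bold_session <- function(config, events) {
  stopifnot(inherits(config, "bold_sim_config"),
            inherits(events, "event_array"))
  T <- config$n_volumes * config$tr_s
  if (length(events$onsets_s) &&
      any(events$onsets_s + events$durations_s > T + 1e-9))
    stop("events extend beyond the session (n_volumes * tr_s)")
  set.seed(config$seed)
  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  nz <- config$grid_shape[3]
  nvox <- nx * ny * nz
  nt <- config$n_volumes

  # ground-truth cortical slab: upper z-slices
  mask <- array(FALSE, c(nx, ny, nz))
  n_cort <- round(config$cortical_mask_fraction * nvox)
  if (n_cort > 0) {
    idx <- seq(nvox - n_cort + 1L, nvox)  # last voxels in array order
    mask[idx] <- TRUE
  }

  # event vector at TR resolution
  stim <- if (config$stimulus == "boxcar") {
    as.numeric(binarize_to_tr(events, config$tr_s, nt)$bins)
  } else {
    v <- numeric(nt)
    v[onset_volumes(events, config$tr_s, nt)] <- 1
    v
  }

  # planted response kernel, percent signal change
  kt <- seq(0, 32, by = config$tr_s)
  kernel <- gamma_variate(kt, config$hrf_params)
  if (max(kernel) > 0) kernel <- kernel / max(kernel)
  kernel_pct <- kernel * config$response_amplitude_pct
  sig <- if (any(stim > 0)) {
    as.numeric(stats::convolve(stim, rev(kernel_pct), type = "open"))[seq_len(nt)]
  } else numeric(nt)

  # noise: AR(1) with stationary SD noise_sd_pct, innovations scaled so the
  # marginal SD is exact
  eps <- matrix(stats::rnorm(nt * nvox), nrow = nt)
  if (config$ar1_coeff > 0) {
    noise <- stats::filter(eps, config$ar1_coeff, method = "recursive")
    noise <- matrix(as.numeric(noise), nrow = nt) *
      sqrt(1 - config$ar1_coeff^2)
  } else noise <- eps
  noise <- noise * config$noise_sd_pct

  tt <- (seq_len(nt) - 1) * config$tr_s
  phases <- stats::runif(nvox, 0, 2 * pi)
  drift <- config$drift_amplitude_pct *
    sin(outer(2 * pi * tt / config$drift_period_s, phases, "+"))

  pct <- noise + drift
  mvox <- which(as.vector(mask))
  if (length(mvox) && any(stim > 0)) {
    profile <- rep(1, length(mvox))
    if (config$amplitude_profile == "hotspot") {
      co <- arrayInd(mvox, c(nx, ny, nz))
      cx <- floor((nx + 1) / 2); cy <- floor((ny + 1) / 2)
      d2 <- (co[, 1] - cx)^2 + (co[, 2] - cy)^2
      profile <- config$profile_base + (1 - config$profile_base) *
        exp(-d2 / (2 * config$profile_sigma_vox^2))
    }
    pct[, mvox] <- pct[, mvox] + outer(sig, profile)
  }
  data <- array(100 * (1 + t(pct) / 100), c(nx, ny, nz, nt))

  list(bold = bold_session(data, tr_s = config$tr_s,
                           voxel_size_mm = config$voxel_size_mm),
       cortical_mask = mask,
       kernel_pct = kernel_pct)
}
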