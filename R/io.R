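#' Write / read a calcium trace as delimited text
#'
#' Two tab-separated columns `time_s`, `dff` with a header line.
#'
#' @param trace A `calcium_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace_times(trace), dff = trace$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param units Units flag for the trace being read.
#' @return For `read_trace`, a `calcium_trace`.
#' @export
read_trace <- function(path, units = "dff") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "dff") %in% names(df)))
    stop("trace file must have columns time_s and dff")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-increasing time column")
  fs <- 1 / stats::median(dt)
  calcium_trace(df$dff, fs_hz = fs, t0_s = df$time_s[1], units = units)
}

#' Write / read an event array as JSON
#'
#' @param events An `event_array`.
#' @param path File path.
#' @return `path` (write) or an `event_array` (read).
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(list(onsets_s = events$onsets_s,
                            durations_s = events$durations_s,
                            session_duration_s = events$session_duration_s),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("onsets_s", "durations_s", "session_duration_s")
  if (!all(need %in% names(x)))
    stop("events JSON must contain onsets_s, durations_s, session_duration_s")
  event_array(as.numeric(unlist(x$onsets_s)),
              as.numeric(unlist(x$durations_s)),
              x$session_duration_s)
}

#' Write / read a hemodynamic response curve as JSON
#'
#' @param hr A `hemodynamic_response`.
#' @param path File path.
#' @return `path` (write) or a `hemodynamic_response` (read).
#' @export
write_hrf_json <- function(hr, path) {
  jsonlite::write_json(list(times_s = hr$times_s, values = hr$values,
                            baseline_def = hr$baseline_def),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hrf_json
#' @export
read_hrf_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hemodynamic_response(as.numeric(x$times_s), as.numeric(x$values),
                       baseline_def = x$baseline_def)
}

#' Write / read a BOLD session as NIfTI-1
#'
#' The voxel geometry and TR are carried in the NIfTI pixdim field.
#'
#' @param bold A `bold_session`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `path` (write) or a `bold_session` (read).
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(dim(img)) != 4L) stop("expected a 4D NIfTI volume")
  bold_session(array(as.numeric(img), dim(img)),
               tr_s = if (length(pd) >= 4) pd[4] else 1,
               voxel_size_mm = pd[1:3])
}

#' Write a statistic volume as NIfTI-1
#'
#' @param map 3D numeric array.
#' @param path File path.
#' @param voxel_size_mm Voxel geometry.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = c(0.35, 0.325, 1.2)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# default nested configuration of the full pipeline
default_pipeline_config <- function() {
  list(
    seed = 1L,
    calcium = list(preset = "ogb1", duration_s = 1800),
    preprocess = list(downsample_factor = 2L, lowpass_hz = 100,
                      baseline_window = 2500L),
    detection = list(ema_window_ms = 25, onset_threshold_frac = 0.70,
                     termination_frac_of_threshold = 0.50,
                     merge_gap_ms = 100, min_duration_ms = 600,
                     intensity_percentile = 0.90, noise_refine = TRUE),
    bold_sim = list(grid_shape = c(16L, 16L, 4L), n_volumes = 1805L,
                    tr_s = 1, cortical_mask_fraction = 0.25,
                    noise_sd_pct = 0.5, ar1_coeff = 0.3),
    glm = list(fwhm_mm = 0.5, highpass_cutoff_s = 128, n_discard = 5L,
               hrf = "fir", correction = "FWE", alpha = 0.05),
    fir = list(n_bins = 40L, bin_s = 1, window_start_s = -20)
  )
}

# recursively merge user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key: %s%s", path, k))
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with nested sections mirroring the pipeline stages; unknown
#' keys are rejected, missing keys take their defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return A validated nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  cfg
}
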