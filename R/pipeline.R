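#' Shift event times
#'
#' Shifts all onsets by `offset_s` (e.g. after discarding initial BOLD
#' volumes) and drops events that fall before the new session start.
#'
#' @param events An `event_array`.
#' @param offset_s Amount subtracted from every onset, seconds.
#' @param new_duration_s New session duration (default: old minus offset).
#' @return The shifted `event_array`.
#' @export
shift_events <- function(events, offset_s,
                         new_duration_s = events$session_duration_s - offset_s) {
  o <- events$onsets_s - offset_s
  d <- events$durations_s
  keep <- o >= 0 & o + d <= new_duration_s + 1e-9
  event_array(o[keep], d[keep], new_duration_s)
}

#' MD5 hash of a configuration
#'
#' Canonical (serialized) hash of a nested configuration list, recorded in
#' every pipeline output so results can be traced to their settings.
#'
#' @param config A configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full slow-wave to BOLD analysis pipeline
#'
#' Executes the end-to-end analysis: calcium preprocessing, slow-wave
#' detection and quantification, binarization to TR resolution, FIR
#' extraction of the hemodynamic response from the paired BOLD session,
#' gamma-variate quantification (TTP, delta-SA, HMD), and an event-related
#' GLM activation map using either the extracted response or the canonical
#' HRF as convolution kernel.  With no inputs, paired data are simulated
#' from the configuration, giving a fully self-contained round trip.
#'
#' @param config Nested configuration from [read_pipeline_config()].
#' @param calcium Optional `calcium_trace` (delta-f/f, native rate).
#' @param bold Optional raw `bold_session` paired with the trace.
#' @param hrf_kernel Optional `hemodynamic_response` kernel (e.g. a
#'   leave-one-out average from other sessions) used for the GLM; when
#'   NULL, `config$glm$hrf` selects the session's own FIR response
#'   (`"fir"`) or the canonical HRF (`"canonical"`).
#' @param out_dir Optional directory; when given, events, response curves
#'   and maps are written there (JSON / text / NIfTI).
#' @return A result list: `events`, `wave_params`, `sw_vector`, `hr`,
#'   `gamma_fit`, `hr_quant`, `glm`, `t_map`, `config`, and (when
#'   simulated) `truth`.
#' @export
run_pipeline <- function(config = read_pipeline_config(), calcium = NULL,
                         bold = NULL, hrf_kernel = NULL, out_dir = NULL) {
  truth <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(calcium)) {
    sim <- stage("simulate_calcium", {
      ccfg <- calcium_preset(config$calcium$preset,
                             duration_s = config$calcium$duration_s,
                             seed = config$seed)
      simulate_calcium_trace(ccfg)
    })
    calcium <- sim$trace
    truth <- list(events = sim$truth_events, params = sim$truth_params)
  }
  pp <- config$preprocess
  trace <- stage("calcium_preprocess",
                 preprocess_calcium(calcium,
                                    downsample_factor = pp$downsample_factor,
                                    lowpass_hz = pp$lowpass_hz,
                                    baseline_window = pp$baseline_window))
  det_cfg <- do.call(detection_config, config$detection)
  events <- stage("slow_wave_detection", detect_events(trace, det_cfg))
  if (n_events(events) == 0L) stop("[slow_wave_detection] no events detected")
  wave_params <- stage("wave_quantification",
                       quantify_wave_params(events, trace))

  if (is.null(bold)) {
    bsim <- stage("simulate_bold", {
      bcfg <- do.call(bold_sim_config, c(config$bold_sim,
                                         list(seed = config$seed + 1L)))
      simulate_bold_session(bcfg, if (is.null(truth)) events else truth$events)
    })
    bold <- bsim$bold
    if (!is.null(truth)) truth$cortical_mask <- bsim$cortical_mask
  }

  g <- config$glm
  bold_pp <- stage("bold_preprocess",
                   preprocess_bold(bold, fwhm_mm = g$fwhm_mm,
                                   highpass_cutoff_s = g$highpass_cutoff_s,
                                   n_discard = g$n_discard))
  ev_al <- shift_events(events, g$n_discard * bold_pp$tr_s)
  nt <- n_volumes(bold_pp)
  sw <- stage("binarize", binarize_to_tr(ev_al, bold_pp$tr_s, nt))

  fir_cfg <- do.call(fir_config, config$fir)
  fir <- stage("fir_extraction", {
    X <- build_fir_design(ev_al, fir_cfg, n_volumes = nt)
    fit_fir(bold_pp, X)
  })
  vox <- stage("voxel_selection", select_top_voxels(fir))
  hr <- stage("hr_extraction", extract_mean_hr(fir, vox))
  gamma_fit <- stage("gamma_fit", fit_gamma_variate(hr))
  hrq <- quantify_hr(hr, gamma_fit)

  kernel <- hrf_kernel
  if (is.null(kernel)) {
    kernel <- if (identical(g$hrf, "canonical")) {
      canonical_hrf(bold_pp$tr_s)
    } else {
      sel <- hr$times_s >= fir_cfg$response_support_s[1] &
        hr$times_s <= fir_cfg$response_support_s[2]
      v <- hr$values[sel]
      hemodynamic_response(hr$times_s[sel], v / max(v),
                           baseline_def = "unit peak kernel")
    }
  }
  reg <- stage("regressor", make_regressor(sw, kernel))
  glm <- stage("glm", fit_glm(bold_pp, matrix(reg, ncol = 1)))
  tmap <- stage("t_map", t_test_map(glm, contrast = 1,
                                    correction = g$correction,
                                    alpha = g$alpha))

  res <- list(events = events, wave_params = wave_params, sw_vector = sw,
              hr = hr, gamma_fit = gamma_fit, hr_quant = hrq,
              glm = glm, t_map = tmap, config = config,
              config_hash = config_hash(config), truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_hash = res$config_hash,
           package_version = as.character(utils::packageVersion("slowbold")),
           config = config),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
    write_events_json(events, file.path(out_dir, "events.json"))
    write_hrf_json(hr, file.path(out_dir, "hr.json"))
    utils::write.table(data.frame(volume = seq_len(nt), sw = sw$bins),
                       file.path(out_dir, "slow_wave_vector.txt"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_map_nifti(tmap$t_map, file.path(out_dir, "t_map.nii.gz"),
                    bold_pp$voxel_size_mm)
  }
  res
}
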