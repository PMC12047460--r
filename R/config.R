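#' Detector configuration
#'
#' Collects every tunable parameter of the detection pipeline in one list so
#' that the trigger, template, morphology and burden stages share a single
#' source of truth.  Defaults correspond to a subcutaneous single-vector
#' monitor: a 0.5--40 Hz analysis band at a 256 Hz working rate, a 200 ms
#' beat refractory, and a 2-hour NSR template refresh cadence.
#'
#' @param working_fs Working sampling rate after preconditioning (Hz).
#' @param band_lo,band_hi Band-pass corner frequencies (Hz).
#' @param refractory Minimum beat-to-beat separation enforced by the
#'   detector (s).
#' @param template_period How often template formation is attempted during
#'   orchestration (s); default 7200 (every 2 hours).
#' @param template_warmup Time of the first template-formation attempt (s).
#' @param template_k Number of recent qualifying beats averaged into the NSR
#'   template.
#' @param template_nmin Minimum number of qualifying beats for a template to
#'   be declared valid.
#' @param template_rr_tol Relative RR-interval tolerance around the local
#'   median for a beat to qualify as NSR during template formation.
#' @param template_min_corr Minimum correlation of a qualifying beat to the
#'   running template mean.
#' @param window_ms QRS analysis window length centred on the fiducial (ms).
#' @param max_shift Maximum DCWA alignment shift (samples at `working_fs`).
#' @param premature_factor Trigger prematurity threshold: a beat whose
#'   prematurity (RR-prev over local mean RR) is at or below this value is a
#'   PVC candidate.
#' @param amp_lo,amp_hi Trigger amplitude-ratio gates: a beat whose peak
#'   amplitude ratio to its neighbours falls outside `[amp_lo, amp_hi]` is a
#'   candidate even when on time (ventricular ectopy is not strictly
#'   required to be premature).
#' @param rr_history Number of trailing non-candidate RR intervals defining
#'   the local mean RR.
#' @param grid_tol Relative tolerance for the conducted-beat exemption: a
#'   beat following a candidate is released from candidacy when its span
#'   since the last non-candidate beat is a whole multiple of the local RR
#'   (within this tolerance) and its next interval resumes a normal cycle.
#' @param noise_win Sliding noise-analysis window (s).
#' @param noise_hf_lo,noise_hf_hi Band whose power fraction flags
#'   myopotential/broadband noise (Hz).
#' @param noise_hf_frac Power fraction in the high band above which a window
#'   is marked noisy.
#' @param noise_merge_gap Noise intervals closer than this are merged (s).
#' @param rail_uv Amplitude treated as ADC saturation (uV).
#' @param rail_ms Minimum saturation dwell time to mark noise (ms).
#' @param min_mean_r_uv Amplitude quality-control floor: records whose mean
#'   R-wave amplitude falls below this are rejected (uV); default 100.
#' @param burden_threshold_pct Daily-burden alert threshold (percent);
#'   default 5, the device's configurable minimum.
#' @param ... Overrides for any of the above.
#'
#' @return A named list of class `ectopy_config`.
#' @export
#' @examples
#' cfg <- detector_config(premature_factor = 0.85)
#' cfg$premature_factor
detector_config <- function(working_fs = 256,
                            band_lo = 0.5,
                            band_hi = 40,
                            refractory = 0.20,
                            template_period = 7200,
                            template_warmup = 30,
                            template_k = 16,
                            template_nmin = 8,
                            template_rr_tol = 0.125,
                            template_min_corr = 0.95,
                            window_ms = 200,
                            max_shift = 10,
                            premature_factor = 0.88,
                            amp_lo = 0.4,
                            amp_hi = 2.2,
                            rr_history = 8,
                            grid_tol = 0.12,
                            noise_win = 1.0,
                            noise_hf_lo = 45,
                            noise_hf_hi = 100,
                            noise_hf_frac = 0.5,
                            noise_merge_gap = 0.5,
                            rail_uv = 8000,
                            rail_ms = 50,
                            min_mean_r_uv = 100,
                            burden_threshold_pct = 5,
                            ...) {
  cfg <- list(working_fs = working_fs, band_lo = band_lo, band_hi = band_hi,
              refractory = refractory, template_period = template_period,
              template_warmup = template_warmup, template_k = template_k,
              template_nmin = template_nmin, template_rr_tol = template_rr_tol,
              template_min_corr = template_min_corr, window_ms = window_ms,
              max_shift = max_shift, premature_factor = premature_factor,
              amp_lo = amp_lo, amp_hi = amp_hi, rr_history = rr_history,
              grid_tol = grid_tol,
              noise_win = noise_win, noise_hf_lo = noise_hf_lo,
              noise_hf_hi = noise_hf_hi, noise_hf_frac = noise_hf_frac,
              noise_merge_gap = noise_merge_gap, rail_uv = rail_uv,
              rail_ms = rail_ms, min_mean_r_uv = min_mean_r_uv,
              burden_threshold_pct = burden_threshold_pct)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$band_lo < 0 || cfg$band_lo >= cfg$band_hi ||
      cfg$band_hi >= cfg$working_fs / 2)
    stop("invalid band: need 0 <= band_lo < band_hi < working_fs/2")
  structure(cfg, class = "ectopy_config")
}

#' @export
print.ectopy_config <- function(x, ...) {
  cat("<ectopy_config>\n")
  cat(sprintf("  band %.1f-%.1f Hz @ %g Hz, window %g ms, refractory %g s\n",
              x$band_lo, x$band_hi, x$working_fs, x$window_ms, x$refractory))
  cat(sprintf("  trigger: prematurity <= %.2f, amp ratio outside [%.1f, %.1f]\n",
              x$premature_factor, x$amp_lo, x$amp_hi))
  cat(sprintf("  template: K=%d (min %d) every %g s; burden alert >= %g%%\n",
              x$template_k, x$template_nmin, x$template_period,
              x$burden_threshold_pct))
  invisible(x)
}

#' Read a detector configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos in configuration files fail loudly.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON file whose top-level
#'   keys are `detector_config()` parameter names.
#' @return An `ectopy_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configuration")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(detector_config, as.list(vals))
}
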