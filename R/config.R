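#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' acquisition and analysis settings used throughout: 320 nm
#' nearest-neighbour radius, 15% co-fusion intensity drop, regression of
#' compartment exit from 50 s onward, plasma-membrane plateau window
#' 900-1200 s, alpha 0.05.
#'
#' @param threshold_method segmentation threshold: `"otsu"` (per frame),
#'   `"background"` (robust background floor: median + `bg_k_mad` MADs of
#'   the smoothed frame - appropriate for sparse spots over a uniform
#'   background, where between-class thresholds are ill-posed), or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold intensity cutoff when `threshold_method = "fixed"`.
#' @param segment_smooth_sigma_px Gaussian pre-smoothing applied before
#'   thresholding (px; 0 disables). Suppresses shot noise so the threshold
#'   separates structures from background rather than splitting the
#'   background mode.
#' @param bg_k_mad MAD multiplier for the `"background"` threshold.
#' @param min_object_px minimum object size kept after thresholding (px).
#' @param nn_threshold_nm nearest-neighbour distance threshold in nm.
#' @param cofusion_drop_fraction fractional drop in partner-channel maximum
#'   intensity that declares a co-fusion event (strict `>`).
#' @param alpha significance level for divergence testing.
#' @param regression_start_s start of the exit-slope regression window (s).
#' @param plateau_window_s two-element window (s) for plateau means.
#' @param seed integer seed echoed into provenance.
#' @param log_sigma_px Laplacian-of-Gaussian scale for spot detection (px);
#'   a vector gives a scale range searched per spot.
#' @param detect_k_sigma detection threshold in robust SDs of the filtered
#'   image.
#' @param min_sep_px minimum separation between detected spots (px).
#' @param max_link_distance_px maximum frame-to-frame link distance for
#'   tracking (px).
#' @param max_gap_frames frames a track may skip during gap closing.
#' @param fusion_absence_frames frames a spot must be absent before its
#'   appearance counts as a candidate fusion event.
#' @param fusion_confirm_frames frames after onset within which spread or
#'   decay must confirm a fusion event.
#' @param fusion_window_r_px half-width of the fixed square window used to
#'   read per-frame maximum intensities around an event.
#' @param bleach_prefix_s initial movie span excluded from fusion detection
#'   (pre-bleach frames).
#' @param mask_dilate_px dilation margin applied to the photoactivated
#'   endosome mask before it is subtracted in recycling quantification.
#' @param pm_band_width_px width of the plasma-membrane band (px).
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(threshold_method = c("otsu", "background", "fixed"),
                            fixed_threshold = NULL,
                            segment_smooth_sigma_px = 1,
                            bg_k_mad = 4,
                            min_object_px = 4L,
                            nn_threshold_nm = 320,
                            cofusion_drop_fraction = 0.15,
                            alpha = 0.05,
                            regression_start_s = 50,
                            plateau_window_s = c(900, 1200),
                            seed = 1L,
                            log_sigma_px = 1.5,
                            detect_k_sigma = 5,
                            min_sep_px = 3,
                            max_link_distance_px = 5,
                            max_gap_frames = 1L,
                            fusion_absence_frames = 3L,
                            fusion_confirm_frames = 5L,
                            fusion_window_r_px = 3L,
                            bleach_prefix_s = 0,
                            mask_dilate_px = 2L,
                            pm_band_width_px = 4L) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_object_px >= 1L, nn_threshold_nm > 0,
            cofusion_drop_fraction > 0, cofusion_drop_fraction < 1,
            alpha > 0, alpha < 1, length(plateau_window_s) == 2L,
            plateau_window_s[1L] < plateau_window_s[2L],
            all(log_sigma_px > 0), detect_k_sigma > 0,
            max_link_distance_px > 0, max_gap_frames >= 0L)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` required when threshold_method = \"fixed\"")
  stopifnot(segment_smooth_sigma_px >= 0)
  cfg <- list(threshold_method = threshold_method,
              fixed_threshold = fixed_threshold,
              segment_smooth_sigma_px = segment_smooth_sigma_px,
              bg_k_mad = bg_k_mad,
              min_object_px = as.integer(min_object_px),
              nn_threshold_nm = nn_threshold_nm,
              cofusion_drop_fraction = cofusion_drop_fraction,
              alpha = alpha,
              regression_start_s = regression_start_s,
              plateau_window_s = as.numeric(plateau_window_s),
              seed = as.integer(seed),
              log_sigma_px = log_sigma_px,
              detect_k_sigma = detect_k_sigma,
              min_sep_px = min_sep_px,
              max_link_distance_px = max_link_distance_px,
              max_gap_frames = as.integer(max_gap_frames),
              fusion_absence_frames = as.integer(fusion_absence_frames),
              fusion_confirm_frames = as.integer(fusion_confirm_frames),
              fusion_window_r_px = as.integer(fusion_window_r_px),
              bleach_prefix_s = bleach_prefix_s,
              mask_dilate_px = as.integer(mask_dilate_px),
              pm_band_width_px = as.integer(pm_band_width_px))
  class(cfg) <- "analysis_config"
  cfg
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns an `analysis_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param cfg an `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
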