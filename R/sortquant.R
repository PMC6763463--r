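#' Threshold an image into an endosomal-compartment mask
#'
#' Gaussian-smooths the frame (`segment_smooth_sigma_px`; set 0 to
#' threshold raw pixels), thresholds it (Otsu's method by default, or a
#' fixed cutoff from the configuration), zeroes the background, and
#' removes connected objects smaller than `min_object_px`.
#'
#' @param image numeric matrix.
#' @param cfg an [analysis_config()].
#' @return logical matrix.
#' @export
segment_endosomes <- function(image, cfg = analysis_config()) {
  stopifnot(is.matrix(image), length(image) > 0)
  work <- image
  if (cfg$segment_smooth_sigma_px > 0 && min(dim(image)) > 8L)
    work <- as.matrix(EBImage::gblur(EBImage::Image(image),
                                     sigma = cfg$segment_smooth_sigma_px))
  if (cfg$threshold_method == "otsu") {
    rng <- range(work)
    if (diff(range(image)) == 0)
      stop("constant image: Otsu threshold undefined; use a fixed threshold")
    thr <- EBImage::otsu(EBImage::Image(work), range = rng, levels = 256L)
    mask <- work > thr
  } else if (cfg$threshold_method == "background") {
    thr <- stats::median(work) + cfg$bg_k_mad * stats::mad(work)
    mask <- work > thr
  } else {
    mask <- work >= cfg$fixed_threshold   # fixed cutoff is inclusive
  }
  if (any(mask) && cfg$min_object_px > 1L) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= cfg$min_object_px)
    mask <- matrix(as.integer(lab) %in% keep, nrow(image))
  }
  mask
}

#' Per-frame percentage of photoactivated signal inside a marker compartment
#'
#' For each frame, both channels are thresholded into masks and the
#' percentage of endosomal photoactivated (PA) intensity residing in the
#' marker compartment is
#' `100 * sum(PA within PA-mask AND marker-mask) / sum(PA within PA-mask)`.
#' Intensities are background-corrected before summing (the median PA
#' level outside the PA mask is subtracted, negatives clipped), so the
#' percentage reflects signal rather than the relative areas of the two
#' masks. Frames with an empty PA mask yield `NA` (the quantity is
#' undefined there, not zero).
#'
#' @param movie a [time_lapse_movie()].
#' @param pa_channel,marker_channel channel names or indices.
#' @param cfg an [analysis_config()].
#' @param denominator `"endosomal"` (default: PA-mask total, the endosomal
#'   photoactivated pool) or `"whole_image"`.
#' @param marker_mask optional fixed marker mask (logical matrix) used for
#'   every frame instead of per-frame thresholding.
#' @return an [intensity_trace()] with `percent_of_endosomal`
#'   normalization, times relative to the first photoactivation frame.
#' @export
endosomal_incorporation_trace <- function(movie, pa_channel = 1L,
                                          marker_channel = 2L,
                                          cfg = analysis_config(),
                                          denominator = c("endosomal",
                                                          "whole_image"),
                                          marker_mask = NULL) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  denominator <- match.arg(denominator)
  if (is.null(movie$channels[[pa_channel]]) ||
      is.null(movie$channels[[marker_channel]]))
    stop("missing channel")
  vals <- rep(NA_real_, movie$n_frames)
  for (f in seq_len(movie$n_frames)) {
    pa <- movie_frame(movie, pa_channel, f)
    pm <- tryCatch(segment_endosomes(pa, cfg), error = function(e) NULL)
    if (is.null(pm) || !any(pm)) next
    mm <- if (!is.null(marker_mask)) marker_mask
      else tryCatch(segment_endosomes(movie_frame(movie, marker_channel, f),
                                      cfg),
                    error = function(e) NULL)
    if (is.null(mm)) next
    bg <- if (all(pm)) 0 else stats::median(pa[!pm])
    pa_c <- pmax(pa - bg, 0)
    den <- if (denominator == "endosomal") sum(pa_c[pm]) else sum(pa_c)
    if (den <= 0) next
    vals[f] <- 100 * sum(pa_c[pm & mm]) / den
  }
  if (all(is.na(vals))) stop("PA mask empty in every frame")
  t0 <- if (length(movie$pa_frames))
    movie$frame_times_s[min(movie$pa_frames)] else movie$frame_times_s[1L]
  intensity_trace(movie$frame_times_s - t0, pmin(pmax(vals, 0), 100),
                  units = "percent",
                  normalization = "percent_of_endosomal")
}

#' Linear regression of compartment exit
#'
#' Ordinary least-squares fit of trace value against time over
#' `[regression_start_s, end]`; the slope (percent per s) summarises the
#' rate at which photoactivated cargo leaves the compartment.
#'
#' @param trace an [intensity_trace()].
#' @param cfg an [analysis_config()]; `regression_start_s` sets the window
#'   start (default 50 s).
#' @return list of class `regression_fit`: `slope`, `intercept`,
#'   `slope_se`, `n_points`, `window`.
#' @export
exit_slope <- function(trace, cfg = analysis_config()) {
  stopifnot(inherits(trace, "intensity_trace"))
  sel <- trace$times_s >= cfg$regression_start_s & is.finite(trace$values)
  if (sum(sel) < 3L)
    stop("need at least 3 timepoints at or after regression_start_s")
  t <- trace$times_s[sel]; v <- trace$values[sel]
  fit <- stats::lm(v ~ t)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope_se <- if (nrow(sm) > 1L && is.finite(sm["t", "Std. Error"]))
    sm["t", "Std. Error"] else 0
  structure(list(slope = unname(stats::coef(fit)["t"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_se = slope_se,
                 n_points = length(t),
                 window = c(min(t), max(t))),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: slope %.4g /s (SE %.3g), intercept %.4g, n = %d over [%g, %g] s\n",
              x$slope, x$slope_se, x$intercept, x$n_points,
              x$window[1L], x$window[2L]))
  invisible(x)
}

#' Time to half-maximal signal
#'
#' The plateau is the mean of the final three finite timepoints; the
#' half-maximal time is the first time the trace crosses plateau/2,
#' linearly interpolated between the bracketing frames. Photoactivation
#' start defines t = 0 (trace times are already relative).
#'
#' @param trace an [intensity_trace()].
#' @return list: `time_s` (`NA` if the trace never reaches plateau/2),
#'   `reached` (logical), `plateau`.
#' @export
half_maximal_time <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  ok <- is.finite(trace$values)
  t <- trace$times_s[ok]; v <- trace$values[ok]
  if (length(v) < 4L) stop("need at least 4 finite timepoints")
  plateau <- mean(utils::tail(v, 3L))
  half <- plateau / 2
  idx <- which(v >= half)
  if (!length(idx))
    return(list(time_s = NA_real_, reached = FALSE, plateau = plateau))
  i <- idx[1L]
  if (i == 1L)
    return(list(time_s = t[1L], reached = TRUE, plateau = plateau))
  frac <- (half - v[i - 1L]) / (v[i] - v[i - 1L])
  list(time_s = t[i - 1L] + frac * (t[i] - t[i - 1L]),
       reached = TRUE, plateau = plateau)
}

#' Total half-maximal recycling time
#'
#' Sum of the sorting and recycling half-maximal times: the time for cargo
#' to reach the recycling compartment plus the time to return from it to
#' the plasma membrane.
#'
#' @param t_sort_s half-maximal sorting time (s, >= 0).
#' @param t_recycle_s half-maximal recycling time (s, >= 0).
#' @return numeric seconds, with attribute `"formatted"` as `"M min S s"`.
#' @export
total_recycling_halftime <- function(t_sort_s, t_recycle_s) {
  if (t_sort_s < 0 || t_recycle_s < 0) stop("half-times must be >= 0")
  total <- t_sort_s + t_recycle_s
  structure(total, formatted = format_min_s(total))
}

#' Format seconds as "M min S s"
#'
#' @param seconds non-negative seconds.
#' @return character scalar, e.g. `"9 min 21.6 s"`.
#' @export
format_min_s <- function(seconds) {
  stopifnot(seconds >= 0)
  m <- floor(seconds / 60)
  s <- seconds - 60 * m
  sprintf("%d min %g s", as.integer(m), round(s, 6))
}

#' Plasma-membrane recycling trace
#'
#' Per frame, a photoactivated-endosome mask - the pixels brighter than
#' `endo_mask_frac` of the way from the frame background (median) to the
#' frame maximum, i.e. the bright photoactivated compartment - is dilated
#' by a safety margin and removed, so only plasma-membrane signal
#' remains; the remaining signal is summed within the plasma-membrane
#' band (a morphological ring inside the cell outline, or an explicit
#' band mask). The trace is reported as percent increase over the mean of
#' the pre-activation baseline frames, or raw band totals.
#'
#' @param movie a [time_lapse_movie()] with photoactivation frames
#'   flagged.
#' @param pscfp_channel cargo channel name or index.
#' @param cfg an [analysis_config()] (`mask_dilate_px`,
#'   `pm_band_width_px`).
#' @param cell_outline optional cell-outline [roi_circle()]/[roi_polygon()];
#'   the band is derived from it via [pm_band_mask()].
#' @param pm_band optional explicit logical band mask (overrides
#'   `cell_outline`).
#' @param endo_mask_frac fractional height between frame background and
#'   frame maximum defining the photoactivated-compartment mask (0.5
#'   default). The compartment is much brighter than membrane signal, so
#'   this isolates it without swallowing the band.
#' @param normalization `"percent_increase_over_baseline"` (default) or
#'   `"raw"` band totals.
#' @return an [intensity_trace()], times relative to the first
#'   photoactivation frame.
#' @export
plasma_membrane_recycling_trace <- function(movie, pscfp_channel = 1L,
                                            cfg = analysis_config(),
                                            cell_outline = NULL,
                                            pm_band = NULL,
                                            endo_mask_frac = 0.5,
                                            normalization = c("percent_increase_over_baseline",
                                                              "raw")) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  normalization <- match.arg(normalization)
  if (!length(movie$pa_frames))
    stop("photoactivation frames must be flagged on the movie")
  if (is.null(pm_band)) {
    if (is.null(cell_outline))
      stop("provide `pm_band` or `cell_outline`")
    cell <- rasterize_roi(cell_outline, movie$height, movie$width)
    pm_band <- pm_band_mask(cell, cfg$pm_band_width_px)
  }
  baseline_frames <- setdiff(seq_len(min(movie$pa_frames) - 1L),
                             movie$pa_frames)
  if (!length(baseline_frames)) stop("no pre-activation baseline frames")
  brush <- EBImage::makeBrush(2L * cfg$mask_dilate_px + 1L, "disc")
  vals <- numeric(movie$n_frames)
  for (f in seq_len(movie$n_frames)) {
    img <- movie_frame(movie, pscfp_channel, f)
    bg <- stats::median(img)
    thr <- bg + endo_mask_frac * (max(img) - bg)
    endo <- img > thr
    if (any(endo) && cfg$min_object_px > 1L) {
      lab <- EBImage::bwlabel(EBImage::Image(endo * 1))
      keep <- which(tabulate(as.integer(lab)) >= cfg$min_object_px)
      endo <- matrix(as.integer(lab) %in% keep, movie$height)
    }
    if (any(endo))
      endo <- as.matrix(EBImage::dilate(EBImage::Image(endo * 1), brush)) > 0.5
    vals[f] <- sum(img[pm_band & !endo])
  }
  t0 <- movie$frame_times_s[min(movie$pa_frames)]
  if (normalization == "raw")
    return(intensity_trace(movie$frame_times_s - t0, vals,
                           units = "camera units", normalization = "raw"))
  v0 <- mean(vals[baseline_frames])
  if (!is.finite(v0) || v0 <= 0)
    stop("baseline band signal is zero; use normalization = \"raw\"")
  intensity_trace(movie$frame_times_s - t0, 100 * (vals - v0) / v0,
                  units = "percent",
                  normalization = "percent_increase_over_baseline")
}
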