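#' Parameters for the recycling (plasma-membrane delivery) simulation
#'
#' Defaults mirror the two-photon recycling protocol: photoactivation of an
#' intracellular compartment every 30 s for 10 consecutive cycles, then
#' imaging every 30 s; the trace extends beyond the 900-1200 s plateau
#' window. The default delivery rate corresponds to a half-maximal
#' recycling time of 375 s (`k = ln 2 / 375`).
#'
#' @param recycled_fraction fraction of the photoactivated compartment
#'   intensity eventually delivered to the plasma membrane, in `[0, 1]`.
#' @param k_delivery_per_s first-order delivery rate (per s).
#' @param n_baseline_frames pre-activation frames (baseline for the percent
#'   increase normalization).
#' @param pa_pulses photoactivation cycles.
#' @param n_chase_frames frames imaged after the last pulse.
#' @param frame_interval_s acquisition interval (s).
#' @param height,width,pixel_size_nm image geometry.
#' @param cell_radius_px cell outline radius (px).
#' @param compartment_radius_px photoactivated compartment radius (px).
#' @param i0_total total photoactivated intensity accumulated over the
#'   pulses (camera units).
#' @param vesicle_quantum intensity carried by one delivered vesicle in the
#'   Poisson-thinned stream (noisy mode).
#' @param aggregated logical: render the compartment as a few bright
#'   clusters instead of one disc (optogenetic-aggregation control).
#' @param n_clusters cluster count in aggregated mode.
#' @param background,read_noise_sd,noise camera model as in
#'   [sorting_sim_params()].
#' @return list of class `recycling_sim_params`.
#' @export
recycling_sim_params <- function(recycled_fraction = 0.6,
                                 k_delivery_per_s = log(2) / 375,
                                 n_baseline_frames = 3L,
                                 pa_pulses = 10L,
                                 n_chase_frames = 40L,
                                 frame_interval_s = 30,
                                 height = 96L, width = 96L,
                                 pixel_size_nm = 160,
                                 cell_radius_px = 40,
                                 compartment_radius_px = 8,
                                 i0_total = 2e5,
                                 vesicle_quantum = 2000,
                                 aggregated = FALSE,
                                 n_clusters = 4L,
                                 background = 10,
                                 read_noise_sd = 2,
                                 noise = TRUE) {
  if (recycled_fraction < 0 || recycled_fraction > 1)
    stop("recycled_fraction must lie in [0, 1]")
  stopifnot(k_delivery_per_s >= 0, n_baseline_frames >= 1L)
  p <- as.list(environment())
  class(p) <- "recycling_sim_params"
  p
}

#' Simulate the two-photon recycling assay
#'
#' A photoactivated pool builds up in a central intracellular compartment
#' over the pulse frames; cargo then leaves it with first-order kinetics
#' and accumulates in a plasma-membrane band just inside the cell outline.
#' In noisy mode departures form a Poisson-thinned stream of discrete
#' vesicle quanta deposited at random positions on the band; in noise-free
#' mode the transfer is the deterministic expected flux, so total intensity
#' is conserved exactly. Channels: `cargo` (photoactivated signal) and
#' `marker` (static compartment marker). Frame times place t = 0 at the
#' first photoactivation frame (baseline frames at negative times).
#'
#' @param params a [recycling_sim_params()].
#' @param seed integer seed.
#' @return list with `movie`, `truth` (per-frame `cum_pm_fraction` of the
#'   photoactivated pool delivered to the membrane, `i0`, geometry ROIs)
#'   and `rois` (cell outline and photoactivation circles).
#' @export
simulate_recycling_assay <- function(params = recycling_sim_params(),
                                     seed = 1L) {
  stopifnot(inherits(params, "recycling_sim_params"))
  p <- params
  with_seed(seed, {
    nb <- p$n_baseline_frames
    total_frames <- nb + p$pa_pulses + p$n_chase_frames
    dt <- p$frame_interval_s
    times <- (seq_len(total_frames) - 1 - nb) * dt   # t = 0 at first pulse
    pa_frames <- nb + seq_len(p$pa_pulses)
    cx <- (p$width - 1) / 2; cy <- (p$height - 1) / 2

    px <- matrix(rep(0:(p$width - 1), each = p$height), p$height)
    py <- matrix(rep(0:(p$height - 1), p$width), p$height)
    cell <- (px - cx)^2 + (py - cy)^2 <= p$cell_radius_px^2
    band <- cell & ((px - cx)^2 + (py - cy)^2 >=
                      (p$cell_radius_px - 4)^2)
    if (p$aggregated) {
      ang <- stats::runif(p$n_clusters, 0, 2 * pi)
      rad <- stats::runif(p$n_clusters, 2, p$compartment_radius_px)
      ccx <- cx + rad * cos(ang); ccy <- cy + rad * sin(ang)
      comp <- matrix(FALSE, p$height, p$width)
      for (k in seq_len(p$n_clusters))
        comp <- comp | ((px - ccx[k])^2 + (py - ccy[k])^2 <= 2.5^2)
    } else {
      comp <- (px - cx)^2 + (py - cy)^2 <= p$compartment_radius_px^2
    }
    n_comp_px <- sum(comp); n_band_px <- sum(band)

    # photoactivated pool builds linearly over the pulses; delivery starts
    # after the last pulse with first-order kinetics
    i0_after_pulse <- p$i0_total * seq_len(p$pa_pulses) / p$pa_pulses
    t_start <- times[pa_frames[p$pa_pulses]]
    released_frac <- function(t)   # fraction of final pool released by t
      ifelse(t <= t_start, 0,
             p$recycled_fraction *
               (1 - exp(-p$k_delivery_per_s * (t - t_start))))

    cargo <- array(0, dim = c(p$height, p$width, total_frames))
    marker <- array(0, dim = c(p$height, p$width, total_frames))
    marker_amp <- if (p$noise)
      snr_amplitude(8, p$background, p$read_noise_sd) else 50
    marker_base <- matrix(0, p$height, p$width)
    marker_base[comp] <- marker_amp

    cum_pm <- numeric(total_frames)     # delivered intensity (camera units)
    pm_img <- matrix(0, p$height, p$width)
    delivered <- 0
    band_idx <- which(band)
    for (f in seq_len(total_frames)) {
      pool <- if (f < pa_frames[1L]) 0
        else if (f <= pa_frames[p$pa_pulses])
          i0_after_pulse[f - nb] else p$i0_total
      target <- released_frac(times[f]) * p$i0_total
      flux <- max(0, target - delivered)
      if (p$noise && flux > 0) {
        n_ves <- stats::rpois(1L, flux / p$vesicle_quantum)
        flux <- min(n_ves * p$vesicle_quantum, pool - delivered)
        # delivered cargo equilibrates by lateral diffusion in the
        # membrane within a frame interval, so the accumulated plasma-
        # membrane pool renders as a diffuse band, not immobile spots
        if (flux > 0)
          pm_img[band_idx] <- pm_img[band_idx] + flux / n_band_px
      } else if (flux > 0) {
        pm_img[band_idx] <- pm_img[band_idx] + flux / n_band_px
      }
      delivered <- delivered + flux
      cum_pm[f] <- delivered
      comp_int <- pool - delivered
      frame <- matrix(0, p$height, p$width)
      frame[comp] <- comp_int / n_comp_px
      frame <- frame + pm_img
      if (p$noise) {
        cargo[, , f] <- camera_noise(frame + p$background, p$read_noise_sd)
        marker[, , f] <- camera_noise(marker_base + p$background,
                                      p$read_noise_sd)
      } else {
        cargo[, , f] <- frame
        marker[, , f] <- marker_base
      }
    }

    movie <- time_lapse_movie(
      list(cargo = cargo, marker = marker),
      pixel_size_nm = p$pixel_size_nm, frame_times_s = times,
      pa_frames = pa_frames,
      metadata = list(generator = "simulate_recycling_assay", seed = seed))
    rois <- list(
      cell_outline = roi_circle(cx, cy, p$cell_radius_px,
                                role = "cell_outline"),
      photoactivation = roi_circle(cx, cy, p$compartment_radius_px + 2,
                                   role = "photoactivation"))
    truth <- list(cum_pm_fraction = cum_pm / p$i0_total,
                  cum_pm_intensity = cum_pm,
                  i0 = p$i0_total, times_s = times,
                  t_delivery_start_s = t_start,
                  compartment_mask = comp, pm_band_mask = band)
    list(movie = movie, truth = truth, rois = rois)
  })
}
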