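#' Parameters for the TIRF fusion-event simulation
#'
#' Emulates TIRF imaging of vesicle-plasma-membrane fusion: events appear
#' as diffraction-limited spots that simultaneously decay in intensity and
#' spread laterally as the vesicle collapses into the membrane. Frame
#' intervals are in the 20-200 ms range typical of such recordings.
#'
#' @param event_rate_per_min mean fusion-event rate (per minute, >= 0).
#' @param duration_s movie duration (s).
#' @param frame_interval_s frame interval (s); default 0.2 (200 ms).
#' @param cofusion_fraction probability an event carries the partner
#'   protein (its partner-channel spot decays), in `[0, 1]`.
#' @param partner_drop fractional partner-channel intensity drop for
#'   partner-carrying events (default 0.5); non-carrying events show a
#'   static partner spot (drop 0).
#' @param snr event peak SNR.
#' @param psf_sigma_px initial spot sigma (px).
#' @param decay_tau_s event-channel intensity decay constant (s).
#' @param spread_rate_per_s fractional Gaussian-width growth per second.
#' @param profile_frames frames after onset over which the event profile
#'   (and the partner decay) runs; must be >= 3.
#' @param height,width,pixel_size_nm geometry.
#' @param background,read_noise_sd,noise camera model.
#' @return list of class `tirf_sim_params`.
#' @export
tirf_sim_params <- function(event_rate_per_min = 2,
                            duration_s = 600,
                            frame_interval_s = 0.2,
                            cofusion_fraction = 0.5,
                            partner_drop = 0.5,
                            snr = 8,
                            psf_sigma_px = 1.3,
                            decay_tau_s = 1,
                            spread_rate_per_s = 0.5,
                            profile_frames = 5L,
                            height = 64L, width = 64L,
                            pixel_size_nm = 107,
                            background = 10,
                            read_noise_sd = 2,
                            noise = TRUE) {
  if (event_rate_per_min < 0) stop("event_rate_per_min must be >= 0")
  stopifnot(cofusion_fraction >= 0, cofusion_fraction <= 1,
            profile_frames >= 3L)
  p <- as.list(environment())
  class(p) <- "tirf_sim_params"
  p
}

#' Simulate a TIRF movie of plasma-membrane fusion events
#'
#' Event count is Poisson(`rate * duration`); onsets are uniform in time
#' (leaving room for the post-onset profile) and uniform in space with a
#' border margin and a minimum spacing of 6 px between events overlapping
#' in time. In the event channel a spot appears at onset with peak SNR
#' `snr`, decays exponentially (`decay_tau_s`) and spreads
#' (`spread_rate_per_s`). Every event carries a coincident partner-channel
#' spot; for partner-carrying events (probability `cofusion_fraction`) its
#' peak decays linearly by `partner_drop` over `profile_frames`, otherwise
#' it stays constant.
#'
#' @param params a [tirf_sim_params()].
#' @param seed integer seed.
#' @return list with `movie` (channels `event`, `partner`) and `truth`
#'   (data.frame `events`: onset frame, x, y, partner_present).
#' @export
simulate_tirf_fusion <- function(params = tirf_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "tirf_sim_params"))
  p <- params
  with_seed(seed, {
    dt <- p$frame_interval_s
    n_frames <- round(p$duration_s / dt)
    times <- (seq_len(n_frames) - 1) * dt
    n_events <- stats::rpois(1L, p$event_rate_per_min * p$duration_s / 60)
    margin <- 6
    # event visible until amplitude < 2% of peak
    vis_frames <- max(p$profile_frames,
                      ceiling(-log(0.02) * p$decay_tau_s / dt))
    last_onset <- max(1L, n_frames - vis_frames - 1L)
    ev <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                     partner_present = logical(0))
    if (n_events > 0) {
      onset <- sort(sample.int(last_onset, n_events, replace = TRUE))
      xg <- yg <- numeric(n_events)
      for (k in seq_len(n_events)) {
        repeat {
          cand_x <- stats::runif(1, margin, p$width - 1 - margin)
          cand_y <- stats::runif(1, margin, p$height - 1 - margin)
          # keep temporally overlapping events spatially separate
          overl <- which(abs(onset[seq_len(k - 1L)] - onset[k]) <= vis_frames)
          if (!length(overl) ||
              min((xg[overl] - cand_x)^2 + (yg[overl] - cand_y)^2) > 36)
            break
        }
        xg[k] <- cand_x; yg[k] <- cand_y
      }
      ev <- data.frame(frame = onset, x = xg, y = yg,
                       partner_present =
                         stats::runif(n_events) < p$cofusion_fraction)
    }

    amp <- if (p$noise) snr_amplitude(p$snr, p$background, p$read_noise_sd)
           else 100
    partner_amp <- amp
    event_ch <- array(0, dim = c(p$height, p$width, n_frames))
    partner_ch <- array(0, dim = c(p$height, p$width, n_frames))
    for (f in seq_len(n_frames)) {
      exs <- eys <- eamps <- esigs <- numeric(0)
      pxs <- pys <- pamps <- numeric(0)
      if (nrow(ev)) {
        act <- which(ev$frame <= f & f <= ev$frame + vis_frames)
        for (k in act) {
          tau <- (f - ev$frame[k]) * dt
          exs <- c(exs, ev$x[k]); eys <- c(eys, ev$y[k])
          eamps <- c(eamps, amp * exp(-tau / p$decay_tau_s))
          esigs <- c(esigs, p$psf_sigma_px * (1 + p$spread_rate_per_s * tau))
        }
        # partner spots persist over the profile window only
        pact <- which(ev$frame <= f & f <= ev$frame + p$profile_frames)
        for (k in pact) {
          j <- f - ev$frame[k]
          drop <- if (ev$partner_present[k])
            p$partner_drop * j / p$profile_frames else 0
          pxs <- c(pxs, ev$x[k]); pys <- c(pys, ev$y[k])
          pamps <- c(pamps, partner_amp * (1 - drop))
        }
      }
      e_img <- render_spots(p$height, p$width, exs, eys, eamps,
                            if (length(esigs)) esigs else p$psf_sigma_px)
      p_img <- render_spots(p$height, p$width, pxs, pys, pamps,
                            p$psf_sigma_px)
      if (p$noise) {
        event_ch[, , f] <- camera_noise(e_img + p$background,
                                        p$read_noise_sd)
        partner_ch[, , f] <- camera_noise(p_img + p$background,
                                          p$read_noise_sd)
      } else {
        event_ch[, , f] <- e_img
        partner_ch[, , f] <- p_img
      }
    }
    movie <- time_lapse_movie(
      list(event = event_ch, partner = partner_ch),
      pixel_size_nm = p$pixel_size_nm, frame_times_s = times,
      metadata = list(generator = "simulate_tirf_fusion", seed = seed))
    list(movie = movie, truth = list(events = ev, duration_s = p$duration_s))
  })
}
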