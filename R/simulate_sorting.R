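#' Parameters for the endosomal-sorting simulation
#'
#' Defaults mirror the pulse-chase acquisition protocol of the sorting
#' assay: five photoactivation pulses at 2.5 s intervals followed by
#' imaging every 2.5 s for 150 frames.
#'
#' @param n_vesicles number of photoactivated cargo vesicles (split evenly
#'   across the pulses).
#' @param k_entry_per_s first-order rate of a free photoactivated vesicle
#'   entering the labelled compartment (per s, >= 0).
#' @param k_exit_per_s first-order exit rate (per s, >= 0).
#' @param pa_pulses number of photoactivation pulse frames.
#' @param pa_interval_s interval between pulses (s).
#' @param n_frames chase frames imaged after the pulses.
#' @param frame_interval_s imaging interval (s).
#' @param psf_sigma_px Gaussian PSF sigma used to render diffraction-limited
#'   spots (px).
#' @param snr peak signal-to-noise ratio (peak / background SD).
#' @param diffusion_step_px per-frame Brownian step SD for free vesicles.
#' @param exit_kick_px displacement applied in a random direction when a
#'   vesicle exits a compartment, emulating the rapid budding and motor
#'   transport of the nascent carrier away from the donor endosome.
#' @param drift_to_centre_px_per_frame constant centripetal drift magnitude
#'   applied to free vesicles (emulates minus-end-directed transport).
#' @param pericentre_radius_px radius of the pericentriolar region; inside
#'   it the drift switches off, so transported vesicles accumulate in an
#'   extended central region rather than collapsing onto a point.
#' @param height,width image size (px).
#' @param pixel_size_nm physical pixel size.
#' @param n_endosomes number of static marker-labelled endosomes.
#' @param endosome_radius_px endosome disc radius (px).
#' @param pa_roi photoactivation region ([roi_circle()]); default: circle of
#'   radius 16 px offset from the cell centre.
#' @param background mean background photon count per pixel.
#' @param read_noise_sd Gaussian read-noise SD (camera units).
#' @param noise logical; `FALSE` renders noise-free, background-free images
#'   (used for conservation checks).
#' @return list of class `sorting_sim_params`.
#' @export
sorting_sim_params <- function(n_vesicles = 200L,
                               k_entry_per_s = 0.02,
                               k_exit_per_s = 0.005,
                               pa_pulses = 5L,
                               pa_interval_s = 2.5,
                               n_frames = 150L,
                               frame_interval_s = 2.5,
                               psf_sigma_px = 1.5,
                               snr = 5,
                               diffusion_step_px = 1.2,
                               exit_kick_px = 5,
                               drift_to_centre_px_per_frame = 0.1,
                               pericentre_radius_px = 14,
                               height = 128L, width = 128L,
                               pixel_size_nm = 160,
                               n_endosomes = 12L,
                               endosome_radius_px = 4,
                               pa_roi = NULL,
                               background = 10,
                               read_noise_sd = 2,
                               noise = TRUE) {
  if (k_entry_per_s < 0 || k_exit_per_s < 0)
    stop("rates must be non-negative")
  if (is.null(pa_roi))
    pa_roi <- roi_circle(width * 0.32, height * 0.32, 16,
                         role = "photoactivation")
  p <- as.list(environment())
  class(p) <- "sorting_sim_params"
  p
}

#' Simulate the photoactivation sorting assay
#'
#' Generates a 2-channel movie (photoactivated cargo + compartment marker)
#' with ground truth. Cargo vesicles appear inside the photoactivation ROI
#' during the pulse frames, then alternate between a free state (Brownian
#' walk plus centripetal drift) and an in-compartment state (docked at a
#' marker endosome) as a continuous-time two-state process with rates
#' `k_entry_per_s` and `k_exit_per_s`, discretised exactly per frame
#' (`P(free -> in) = 1 - exp(-k_entry * dt)`). The marker channel holds
#' static disc-shaped endosomes. Images carry Poisson shot noise plus
#' Gaussian read noise unless `noise = FALSE`.
#'
#' @param params a [sorting_sim_params()].
#' @param seed integer seed; the generator is deterministic given
#'   `(params, seed)`.
#' @return list with `movie` (a [time_lapse_movie()]) and `truth` - a list
#'   holding `occupancy_fraction` (per frame, over activated vesicles),
#'   `membership` (vesicle x frame matrix: 1 in-compartment, 0 free, NA not
#'   yet activated), endosome geometry, and the per-vesicle activation
#'   frames.
#' @export
simulate_sorting_assay <- function(params = sorting_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sorting_sim_params"))
  p <- params
  min_dim <- min(p$height, p$width)
  if (p$n_vesicles > 0.25 * p$height * p$width)
    stop("image too small for requested n_vesicles")
  with_seed(seed, {
    total_frames <- p$pa_pulses + p$n_frames
    dt <- p$frame_interval_s
    times <- (seq_len(total_frames) - 1) * dt
    margin <- ceiling(4 * p$psf_sigma_px) + 1

    # static endosomes, separated discs
    er <- p$endosome_radius_px
    ex <- ey <- numeric(0)
    tries <- 0L
    while (length(ex) < p$n_endosomes && tries < 5000L) {
      cx <- stats::runif(1, margin + er, p$width - 1 - margin - er)
      cy <- stats::runif(1, margin + er, p$height - 1 - margin - er)
      if (!length(ex) || min((ex - cx)^2 + (ey - cy)^2) > (2.5 * er)^2) {
        ex <- c(ex, cx); ey <- c(ey, cy)
      }
      tries <- tries + 1L
    }
    n_endo <- length(ex)
    # excluded volume: a free vesicle cannot sit inside an endosome
    # footprint (single optical plane); push offenders out radially
    repel <- function(xv, yv) {
      if (!n_endo) return(cbind(xv, yv))
      for (k in seq_len(n_endo)) {
        d2 <- (xv - ex[k])^2 + (yv - ey[k])^2
        hit <- which(d2 < (er + 1)^2)
        if (length(hit)) {
          d <- pmax(sqrt(d2[hit]), 1e-6)
          xv[hit] <- ex[k] + (xv[hit] - ex[k]) / d * (er + 1.5)
          yv[hit] <- ey[k] + (yv[hit] - ey[k]) / d * (er + 1.5)
        }
      }
      cbind(xv, yv)
    }

    # activation schedule: vesicles split across pulses
    per_pulse <- rep(p$n_vesicles %/% p$pa_pulses, p$pa_pulses)
    rem <- p$n_vesicles - sum(per_pulse)
    if (rem > 0) per_pulse[seq_len(rem)] <- per_pulse[seq_len(rem)] + 1L
    act_frame <- rep(seq_len(p$pa_pulses), times = per_pulse)

    n <- p$n_vesicles
    x <- y <- rep(NA_real_, n)
    state <- rep(NA_integer_, n)          # 0 free, 1 in-compartment
    endo_of <- rep(NA_integer_, n)
    membership <- matrix(NA_integer_, n, total_frames)
    xs <- ys <- matrix(NA_real_, n, total_frames)

    p_in <- 1 - exp(-p$k_entry_per_s * dt)
    p_out <- 1 - exp(-p$k_exit_per_s * dt)
    ctr_x <- (p$width - 1) / 2; ctr_y <- (p$height - 1) / 2

    for (f in seq_len(total_frames)) {
      # activate this pulse's cohort inside the PA ROI
      newly <- which(act_frame == f)
      if (length(newly)) {
        ang <- stats::runif(length(newly), 0, 2 * pi)
        rad <- p$pa_roi$r * sqrt(stats::runif(length(newly)))
        x[newly] <- p$pa_roi$cx + rad * cos(ang)
        y[newly] <- p$pa_roi$cy + rad * sin(ang)
        pos <- repel(x[newly], y[newly])
        x[newly] <- pos[, 1L]; y[newly] <- pos[, 2L]
        state[newly] <- 0L
      }
      # transitions and motion apply from the frame after activation, so a
      # vesicle's occupancy is exactly 0 at its own activation frame
      alive <- which(!is.na(state) & act_frame < f)
      if (f > 1L && length(alive)) {
        # state transitions (exact per-frame discretisation of the CTMC)
        u <- stats::runif(length(alive))
        enter <- alive[state[alive] == 0L][u[state[alive] == 0L] < p_in]
        leave <- alive[state[alive] == 1L][u[state[alive] == 1L] < p_out]
        if (length(enter) && n_endo > 0) {
          for (v in enter) {
            d2 <- (ex - x[v])^2 + (ey - y[v])^2
            endo_of[v] <- which.min(d2)
            jit <- stats::runif(2, -er / 3, er / 3)
            x[v] <- ex[endo_of[v]] + jit[1L]
            y[v] <- ey[endo_of[v]] + jit[2L]
          }
          state[enter] <- 1L
        }
        if (length(leave)) {
          state[leave] <- 0L
          endo_of[leave] <- NA_integer_
          # carrier buds off and is transported away from the endosome
          ang <- stats::runif(length(leave), 0, 2 * pi)
          x[leave] <- reflect_into(x[leave] + p$exit_kick_px * cos(ang),
                                   margin, p$width - 1 - margin)
          y[leave] <- reflect_into(y[leave] + p$exit_kick_px * sin(ang),
                                   margin, p$height - 1 - margin)
        }
        # motion of free vesicles
        fr <- alive[state[alive] == 0L]
        if (length(fr)) {
          dxv <- ctr_x - x[fr]; dyv <- ctr_y - y[fr]
          nrm <- pmax(sqrt(dxv^2 + dyv^2), 1e-9)
          # drift only outside the pericentriolar region
          drift <- ifelse(nrm > p$pericentre_radius_px,
                          p$drift_to_centre_px_per_frame, 0)
          x[fr] <- x[fr] + stats::rnorm(length(fr), sd = p$diffusion_step_px) +
            drift * dxv / nrm
          y[fr] <- y[fr] + stats::rnorm(length(fr), sd = p$diffusion_step_px) +
            drift * dyv / nrm
          x[fr] <- reflect_into(x[fr], margin, p$width - 1 - margin)
          y[fr] <- reflect_into(y[fr], margin, p$height - 1 - margin)
          pos <- repel(x[fr], y[fr])
          x[fr] <- pos[, 1L]; y[fr] <- pos[, 2L]
        }
      }
      membership[, f] <- state
      xs[, f] <- x; ys[, f] <- y
    }

    amp <- if (p$noise) snr_amplitude(p$snr, p$background, p$read_noise_sd)
           else 100
    marker_amp <- amp
    marker_base <- matrix(0, p$height, p$width)
    px <- matrix(rep(0:(p$width - 1), each = p$height), p$height)
    py <- matrix(rep(0:(p$height - 1), p$width), p$height)
    for (k in seq_len(n_endo))
      marker_base[(px - ex[k])^2 + (py - ey[k])^2 <= er^2] <- marker_amp
    marker_base <- pmax(as.matrix(EBImage::gblur(EBImage::Image(marker_base),
                                                 sigma = 1)), 0)

    cargo <- array(0, dim = c(p$height, p$width, total_frames))
    marker <- array(0, dim = c(p$height, p$width, total_frames))
    for (f in seq_len(total_frames)) {
      alive <- which(!is.na(membership[, f]))
      spots <- render_spots(p$height, p$width, xs[alive, f], ys[alive, f],
                            amp, p$psf_sigma_px)
      if (p$noise) {
        cargo[, , f] <- camera_noise(spots + p$background, p$read_noise_sd)
        marker[, , f] <- camera_noise(marker_base + p$background,
                                      p$read_noise_sd)
      } else {
        cargo[, , f] <- spots
        marker[, , f] <- marker_base
      }
    }

    activated <- outer(act_frame, seq_len(total_frames), "<=")
    occ <- colSums(membership == 1L, na.rm = TRUE) /
      pmax(colSums(activated), 1L)
    movie <- time_lapse_movie(
      list(cargo = cargo, marker = marker),
      pixel_size_nm = p$pixel_size_nm, frame_times_s = times,
      pa_frames = seq_len(p$pa_pulses),
      metadata = list(generator = "simulate_sorting_assay", seed = seed))
    truth <- list(occupancy_fraction = occ, membership = membership,
                  activation_frame = act_frame,
                  endosomes = data.frame(x = ex, y = ey, r = er),
                  positions_x = xs, positions_y = ys,
                  times_s = times)
    list(movie = movie, truth = truth)
  })
}
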