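#' Simulate grouped per-cell traces with a known divergence time
#'
#' Two groups of per-cell time series on a common grid. Group A follows a
#' baseline curve plus i.i.d. Gaussian noise; group B is exchangeable with
#' A before `divergence_time_s` and shifted by
#' `-effect_size_sd * noise_sd` at timepoints `>= divergence_time_s`
#' (a knockout-like reduction). `divergence_time_s = Inf` gives the null
#' (no divergence).
#'
#' @param n_per_group cells per group (>= 2).
#' @param divergence_time_s true divergence time (s), or `Inf`.
#' @param effect_size_sd shift after divergence, in units of `noise_sd`.
#' @param noise_sd per-observation Gaussian noise SD.
#' @param times_s common time grid (s).
#' @param seed integer seed.
#' @param baseline function of time giving the group-A mean curve; default
#'   a saturating rise `80 * (1 - exp(-0.03 t))`.
#' @return list with matrices `a`, `b` (cells x timepoints), `times_s`, and
#'   `truth` (the divergence time).
#' @export
simulate_group_traces <- function(n_per_group = 15L,
                                  divergence_time_s = 50,
                                  effect_size_sd = 5,
                                  noise_sd = 1,
                                  times_s = seq(0, 100, by = 2.5),
                                  seed = 1L,
                                  baseline = function(t) 80 * (1 - exp(-0.03 * t))) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (!is.infinite(divergence_time_s) &&
      (divergence_time_s < min(times_s) || divergence_time_s > max(times_s)))
    stop("divergence_time_s must lie within the time grid (or be Inf)")
  with_seed(seed, {
    nt <- length(times_s)
    mu <- baseline(times_s)
    a <- matrix(rep(mu, each = n_per_group), n_per_group, nt) +
      matrix(stats::rnorm(n_per_group * nt, sd = noise_sd), n_per_group)
    shift <- ifelse(times_s >= divergence_time_s,
                    -effect_size_sd * noise_sd, 0)
    b <- matrix(rep(mu + shift, each = n_per_group), n_per_group, nt) +
      matrix(stats::rnorm(n_per_group * nt, sd = noise_sd), n_per_group)
    list(a = a, b = b, times_s = times_s,
         truth = list(divergence_time_s = divergence_time_s))
  })
}

#' Parameters for the optogenetic-aggregation simulation
#'
#' @param n_vesicles initial vesicle count.
#' @param merge_factor vesicles merged per cluster at the switch (k >= 1);
#'   a remainder not divisible by k is left unmerged with a warning.
#' @param switch_frame frame at which merging occurs.
#' @param n_frames,frame_interval_s movie length and interval.
#' @param height,width,pixel_size_nm geometry.
#' @param amp per-vesicle peak amplitude before merging.
#' @param psf_sigma_px spot sigma (px).
#' @param background,read_noise_sd,noise camera model.
#' @return list of class `aggregation_sim_params`.
#' @export
aggregation_sim_params <- function(n_vesicles = 40L,
                                   merge_factor = 4L,
                                   switch_frame = 10L,
                                   n_frames = 20L,
                                   frame_interval_s = 30,
                                   height = 128L, width = 128L,
                                   pixel_size_nm = 160,
                                   amp = 50,
                                   psf_sigma_px = 1.5,
                                   background = 10,
                                   read_noise_sd = 2,
                                   noise = TRUE) {
  stopifnot(merge_factor >= 1L, n_vesicles >= 1L,
            switch_frame >= 1L, switch_frame <= n_frames)
  p <- as.list(environment())
  class(p) <- "aggregation_sim_params"
  p
}

#' Simulate optogenetic vesicle aggregation
#'
#' Renders `n_vesicles` stationary spots on a coarse grid (integer pixel
#' positions, well separated). At `switch_frame` the vesicles merge in
#' groups of `merge_factor`: each group collapses onto the position of its
#' first member with the summed intensity, conserving total intensity
#' exactly in noise-free mode. Emulates blue-light-induced clustering of
#' CIB1/Cry2-tagged Rab compartments.
#'
#' @param params an [aggregation_sim_params()].
#' @param seed integer seed.
#' @return list with `movie` (channel `vesicles`) and `truth` (per-frame
#'   `n_vesicles` and `mean_intensity` - mean integrated intensity per
#'   vesicle in camera units - plus per-frame position/intensity tables).
#' @export
simulate_aggregation <- function(params = aggregation_sim_params(),
                                 seed = 1L) {
  stopifnot(inherits(params, "aggregation_sim_params"))
  p <- params
  with_seed(seed, {
    k <- as.integer(p$merge_factor)
    n <- as.integer(p$n_vesicles)
    if (n %% k != 0L)
      warning(sprintf("merge_factor %d does not divide n_vesicles %d; %d vesicle(s) left unmerged",
                      k, n, n %% k))
    margin <- ceiling(4 * p$psf_sigma_px) + 2L
    step <- 10L
    gx <- seq(margin, p$width - 1L - margin, by = step)
    gy <- seq(margin, p$height - 1L - margin, by = step)
    grid <- expand.grid(x = gx, y = gy)
    if (nrow(grid) < n) stop("image too small for requested n_vesicles")
    sel <- grid[sample.int(nrow(grid), n), ]
    x0 <- sel$x; y0 <- sel$y
    int0 <- rep(p$amp, n)                # peak amplitudes, equal spots

    n_groups <- n %/% k
    grp <- c(rep(seq_len(n_groups), each = k),
             rep(NA_integer_, n %% k))   # remainder unmerged
    merged_x <- vapply(seq_len(n_groups),
                       function(g) x0[which(grp == g)[1L]], numeric(1))
    merged_y <- vapply(seq_len(n_groups),
                       function(g) y0[which(grp == g)[1L]], numeric(1))
    merged_amp <- vapply(seq_len(n_groups),
                         function(g) sum(int0[which(grp == g)]), numeric(1))
    rem <- which(is.na(grp))

    sig_int <- 2 * pi * p$psf_sigma_px^2   # integral of a unit-peak spot
    arr <- array(0, dim = c(p$height, p$width, p$n_frames))
    count <- integer(p$n_frames); meanint <- numeric(p$n_frames)
    per_frame <- vector("list", p$n_frames)
    for (f in seq_len(p$n_frames)) {
      if (f < p$switch_frame) {
        xs <- x0; ys <- y0; amps <- int0
      } else {
        xs <- c(merged_x, x0[rem]); ys <- c(merged_y, y0[rem])
        amps <- c(merged_amp, int0[rem])
      }
      img <- render_spots(p$height, p$width, xs, ys, amps, p$psf_sigma_px)
      arr[, , f] <- if (p$noise)
        camera_noise(img + p$background, p$read_noise_sd) else img
      count[f] <- length(xs)
      meanint[f] <- mean(amps) * sig_int
      per_frame[[f]] <- data.frame(x = xs, y = ys,
                                   integrated = amps * sig_int)
    }
    movie <- time_lapse_movie(
      list(vesicles = arr), pixel_size_nm = p$pixel_size_nm,
      frame_times_s = (seq_len(p$n_frames) - 1) * p$frame_interval_s,
      metadata = list(generator = "simulate_aggregation", seed = seed))
    truth <- list(n_vesicles = count, mean_intensity = meanint,
                  per_frame = per_frame, switch_frame = p$switch_frame)
    list(movie = movie, truth = truth)
  })
}
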