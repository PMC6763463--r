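#' Detect plasma-membrane fusion events in a TIRF movie
#'
#' Automated formalisation of fusion-event identification: an event is
#' declared at a spot that (a) has no detection nearby in the previous
#' `fusion_absence_frames` frames (sudden appearance), (b) peaks at least
#' `detect_k_sigma` robust SDs above local background, and (c) within
#' `fusion_confirm_frames` frames shows a Gaussian-width increase of at
#' least 20% or a peak decay below 50% of its maximum (the collapse of the
#' vesicle into the membrane). The spot must additionally persist into the
#' following frame, which rejects single-frame noise spikes. Each event carries per-frame maximum
#' intensities read in a fixed `(2r+1)^2` window around the detected
#' position (the window does not re-centre), for the event channel and,
#' when given, a partner channel.
#'
#' @param movie a [time_lapse_movie()].
#' @param channel event channel name or index.
#' @param cfg an [analysis_config()] (`fusion_absence_frames`,
#'   `fusion_confirm_frames`, `fusion_window_r_px`, `detect_k_sigma`,
#'   `bleach_prefix_s`).
#' @param partner_channel optional partner channel for co-fusion
#'   classification.
#' @return list of `fusion_event` objects: `onset_frame`, `x`, `y`,
#'   `frames`, `profile_event`, `profile_partner` (or `NULL`),
#'   `cofusion` (`NA` until classified).
#' @export
detect_fusion_events <- function(movie, channel = 1L,
                                 cfg = analysis_config(),
                                 partner_channel = NULL) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  N <- cfg$fusion_absence_frames; m <- cfg$fusion_confirm_frames
  if (movie$n_frames < N + m + 1L)
    stop("movie shorter than absence + confirmation window")
  first_frame <- if (cfg$bleach_prefix_s > 0)
    max(1L, sum(movie$frame_times_s <
                  movie$frame_times_s[1L] + cfg$bleach_prefix_s) + 1L)
    else 1L
  dets <- vector("list", movie$n_frames)
  for (f in seq_len(movie$n_frames))
    dets[[f]] <- detect_vesicles(movie_frame(movie, channel, f), cfg)
  events <- list()
  profile_len <- max(m, 3L)
  for (f in seq((first_frame + N), movie$n_frames - profile_len)) {
    d <- dets[[f]]
    if (!nrow(d)) next
    for (k in seq_len(nrow(d))) {
      # (a) absence in the N previous frames (within 2 px)
      appeared <- TRUE
      for (g in (f - N):(f - 1L)) {
        dg <- dets[[g]]
        if (nrow(dg) &&
            min((dg$x - d$x[k])^2 + (dg$y - d$y[k])^2) <= 4) {
          appeared <- FALSE; break
        }
      }
      if (!appeared) next
      # a genuine event stays visible while it decays; single-frame noise
      # spikes do not
      persists <- nrow(dets[[f + 1L]]) > 0 &&
        min((dets[[f + 1L]]$x - d$x[k])^2 +
              (dets[[f + 1L]]$y - d$y[k])^2) <= 4
      if (!persists) next
      # avoid double-declaring the same event on consecutive frames
      if (length(events)) {
        prev <- vapply(events, function(e)
          abs(e$onset_frame - f) <= 1L &&
            (e$x - d$x[k])^2 + (e$y - d$y[k])^2 <= 4, logical(1L))
        if (any(prev)) next
      }
      prof <- .event_profile(movie, channel, d$x[k], d$y[k],
                             f:(f + profile_len), cfg$fusion_window_r_px)
      # (c) spread or decay confirmation
      widths <- .event_widths(movie, channel, d$x[k], d$y[k],
                              f:(f + m), cfg$fusion_window_r_px + 2L)
      w0 <- widths[1L]
      spread_ok <- is.finite(w0) && w0 > 0 &&
        any(widths[-1L] / w0 >= 1.2, na.rm = TRUE)
      pk <- prof - min(prof)
      decay_ok <- max(pk) > 0 && min(pk[-1L]) < 0.5 * max(pk)
      if (!spread_ok && !decay_ok) next
      partner_prof <- if (!is.null(partner_channel))
        .event_profile(movie, partner_channel, d$x[k], d$y[k],
                       f:(f + profile_len), cfg$fusion_window_r_px)
        else NULL
      events[[length(events) + 1L]] <- structure(
        list(onset_frame = f, x = d$x[k], y = d$y[k],
             frames = f:(f + profile_len),
             profile_event = prof, profile_partner = partner_prof,
             cofusion = NA),
        class = "fusion_event")
    }
  }
  events
}

# per-frame maximum intensity inside the fixed (2r+1)^2 window
.event_profile <- function(movie, channel, x, y, frames, r) {
  i0 <- max(1L, round(y) + 1L - r); i1 <- min(movie$height, round(y) + 1L + r)
  j0 <- max(1L, round(x) + 1L - r); j1 <- min(movie$width, round(x) + 1L + r)
  vapply(frames, function(f)
    max(movie$channels[[channel]][i0:i1, j0:j1, f]), numeric(1L))
}

# Gaussian-width estimate (RMS radius of the background-subtracted window)
.event_widths <- function(movie, channel, x, y, frames, r) {
  i0 <- max(1L, round(y) + 1L - r); i1 <- min(movie$height, round(y) + 1L + r)
  j0 <- max(1L, round(x) + 1L - r); j1 <- min(movie$width, round(x) + 1L + r)
  xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
  vapply(frames, function(f) {
    win <- movie$channels[[channel]][i0:i1, j0:j1, f]
    bg <- stats::median(c(win[1L, ], win[nrow(win), ],
                          win[, 1L], win[, ncol(win)]))
    wgt <- pmax(win - bg, 0)
    s <- sum(wgt)
    if (s <= 0) return(NA_real_)
    mx <- sum(colSums(wgt) * xs) / s; my <- sum(rowSums(wgt) * ys) / s
    vx <- sum(colSums(wgt) * (xs - mx)^2) / s
    vy <- sum(rowSums(wgt) * (ys - my)^2) / s
    sqrt((vx + vy) / 2)
  }, numeric(1L))
}

#' Classify a fusion event as a co-fusion
#'
#' A fusion event is counted as containing the partner protein when the
#' partner channel's mean maximum intensity over the last three profile
#' frames has dropped by strictly more than `cofusion_drop_fraction`
#' (default 15%) relative to the maximum intensity of the initial frame:
#' `(I_init - mean(last three maxima)) / I_init > drop`.
#'
#' @param event a `fusion_event` with a partner profile of at least 4
#'   frames.
#' @param cfg an [analysis_config()].
#' @param on `"partner"` (default: the channel of the protein being tested
#'   for presence) or `"event"` to measure the drop on the event channel.
#' @return `TRUE`, `FALSE`, or `NA` when the initial intensity is
#'   non-positive (unclassifiable).
#' @export
classify_cofusion <- function(event, cfg = analysis_config(),
                              on = c("partner", "event")) {
  stopifnot(inherits(event, "fusion_event"))
  on <- match.arg(on)
  prof <- if (on == "partner") event$profile_partner else event$profile_event
  if (is.null(prof)) stop("event has no partner-channel profile")
  if (length(prof) < 4L)
    stop("profile must cover the initial frame plus at least 3 frames")
  i_init <- prof[1L]
  if (!is.finite(i_init) || i_init <= 0) return(NA)
  drop <- (i_init - mean(utils::tail(prof, 3L))) / i_init
  drop > cfg$cofusion_drop_fraction
}

#' Classify all events in place
#'
#' @param events list of `fusion_event`s.
#' @param cfg an [analysis_config()].
#' @inheritParams classify_cofusion
#' @return the list with the `cofusion` field filled in.
#' @export
classify_events <- function(events, cfg = analysis_config(),
                            on = c("partner", "event")) {
  on <- match.arg(on)
  lapply(events, function(e) {
    e$cofusion <- classify_cofusion(e, cfg, on)
    e
  })
}

#' Fusion-event rate
#'
#' @param events list of fusion events (or anything with a length).
#' @param observation_duration_s observation time (s, > 0).
#' @return events per minute.
#' @export
fusion_rate <- function(events, observation_duration_s) {
  if (!is.numeric(observation_duration_s) || observation_duration_s <= 0)
    stop("observation duration must be positive")
  60 * length(events) / observation_duration_s
}

#' Percentage of classified fusion events that are co-fusions
#'
#' Unclassifiable events (`cofusion` `NA`) are excluded from numerator and
#' denominator.
#'
#' @param events list of classified `fusion_event`s (see
#'   [classify_events()]).
#' @return percent in `[0, 100]`.
#' @export
cofusion_fraction <- function(events) {
  if (!length(events)) stop("no events")
  cls <- vapply(events, function(e) {
    if (is.null(e$cofusion)) NA else as.logical(e$cofusion)
  }, logical(1L))
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("zero classified events")
  100 * sum(cls) / length(cls)
}
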