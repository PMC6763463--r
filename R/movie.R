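#' Multi-channel time-lapse movie with physical calibration
#'
#' Container for a 2D multi-channel fluorescence time-lapse. Each channel is
#' a `height x width x n_frames` numeric array of non-negative intensities in
#' arbitrary camera units; all channels share the same geometry. Physical
#' calibration (pixel size in nm, per-frame acquisition times in s) is
#' mandatory because downstream thresholds (e.g. the 320 nm nearest-neighbour
#' radius) are physical distances.
#'
#' @param channels named list of numeric arrays, each `height x width x
#'   n_frames` (a matrix is accepted as a single frame).
#' @param pixel_size_nm pixel edge length in nanometres (> 0).
#' @param frame_times_s strictly increasing acquisition times in seconds, one
#'   per frame.
#' @param pa_frames integer indices (1-based) of photoactivation frames.
#'   These frames are flagged so that baseline and plateau statistics can
#'   exclude them.
#' @param metadata free-form named list.
#' @return object of class `time_lapse_movie`.
#' @export
time_lapse_movie <- function(channels, pixel_size_nm, frame_times_s,
                             pa_frames = integer(), metadata = list()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("each channel must be a height x width x n_frames array")
    storage.mode(ch) <- "double"
    ch
  })
  dims <- dim(channels[[1L]])
  for (ch in channels)
    if (!identical(dim(ch), dims))
      stop("all channels must share identical (height, width, n_frames)")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1L))))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  frame_times_s <- as.numeric(frame_times_s)
  if (length(frame_times_s) != dims[3L])
    stop("`frame_times_s` must have one entry per frame")
  if (dims[3L] > 1L && any(diff(frame_times_s) <= 0))
    stop("`frame_times_s` must be strictly increasing")
  pa_frames <- as.integer(pa_frames)
  if (length(pa_frames) && (any(pa_frames < 1L) || any(pa_frames > dims[3L])))
    stop("`pa_frames` indices out of frame range")
  structure(list(
    channels = channels,
    n_frames = dims[3L], height = dims[1L], width = dims[2L],
    pixel_size_nm = as.numeric(pixel_size_nm),
    frame_times_s = frame_times_s,
    pa_frames = pa_frames,
    metadata = metadata
  ), class = "time_lapse_movie")
}

#' @export
print.time_lapse_movie <- function(x, ...) {
  cat(sprintf("time_lapse_movie: %d channel(s) [%s], %d x %d px, %d frames\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$height, x$width, x$n_frames))
  cat(sprintf("  pixel size %.1f nm; t = %.3g .. %.3g s", x$pixel_size_nm,
              x$frame_times_s[1L], x$frame_times_s[x$n_frames]))
  if (length(x$pa_frames))
    cat(sprintf("; %d photoactivation frame(s)", length(x$pa_frames)))
  cat("\n")
  invisible(x)
}

#' Extract one frame of one channel
#'
#' @param movie a [time_lapse_movie()].
#' @param channel channel name or index.
#' @param frame frame index (1-based).
#' @return numeric matrix.
#' @export
movie_frame <- function(movie, channel, frame) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  ch <- movie$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  if (frame < 1L || frame > movie$n_frames) stop("frame out of range")
  ch[, , frame]
}

# internal scale used to store camera units in 16-bit TIFF pages
.TIFF_MAX <- 65535

#' Write a movie as a multi-page TIFF with a JSON calibration sidecar
#'
#' Frames are written as interleaved pages (channel fastest:
#' frame1/ch1, frame1/ch2, frame2/ch1, ...) or channel-blocked series.
#' Physical calibration and the channel layout are stored in a JSON sidecar
#' `<path>.json`, since baseline TIFF tags carry no calibration.
#' Intensities are stored as 16-bit integers; values must lie in
#' `[0, 65535]` and are rounded, so integer-valued camera data round-trip
#' bit-identically.
#'
#' @param movie a [time_lapse_movie()].
#' @param path output TIFF path.
#' @param layout `"interleaved"` (pages ordered frame-major) or `"blocked"`
#'   (all frames of channel 1, then channel 2, ...).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, layout = c("interleaved", "blocked")) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  layout <- match.arg(layout)
  rng <- range(unlist(lapply(movie$channels, range)))
  if (rng[2L] > .TIFF_MAX)
    stop("intensities exceed the 16-bit storage range [0, 65535]")
  pages <- list()
  if (layout == "interleaved") {
    for (f in seq_len(movie$n_frames))
      for (ch in movie$channels)
        pages[[length(pages) + 1L]] <- ch[, , f] / .TIFF_MAX
  } else {
    for (ch in movie$channels)
      for (f in seq_len(movie$n_frames))
        pages[[length(pages) + 1L]] <- ch[, , f] / .TIFF_MAX
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  sidecar <- list(
    channel_names = names(movie$channels),
    layout = layout,
    n_frames = movie$n_frames,
    pixel_size_nm = movie$pixel_size_nm,
    frame_times_s = movie$frame_times_s,
    pa_frames = movie$pa_frames,
    intensity_scale = .TIFF_MAX,
    metadata = movie$metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF time-lapse as a calibrated movie
#'
#' Accepts both page layouts produced by [write_movie()] (and by common
#' OME-TIFF exports converted to plain TIFF): channel-interleaved pages or
#' channel-blocked series. Calibration is taken from the JSON sidecar written
#' by [write_movie()] when present; explicit arguments override the sidecar.
#' Missing calibration with no override is an error - there is no silent
#' 1-pixel default, because all downstream distance thresholds are physical.
#'
#' @param path TIFF path.
#' @param channel_names character vector naming the channels; length must
#'   divide the page count.
#' @param pixel_size_nm,frame_times_s,frame_interval_s calibration overrides.
#'   Provide either `frame_times_s` (one per frame) or a constant
#'   `frame_interval_s` (times start at 0).
#' @param layout page layout; default taken from the sidecar, else
#'   `"interleaved"`.
#' @param intensity_scale factor mapping the stored `[0, 1]` pixel values
#'   back to camera units (default from sidecar, else 65535).
#' @param pa_frames photoactivation-frame override.
#' @return a [time_lapse_movie()].
#' @export
read_movie <- function(path, channel_names, pixel_size_nm = NULL,
                       frame_times_s = NULL, frame_interval_s = NULL,
                       layout = NULL, intensity_scale = NULL,
                       pa_frames = NULL) {
  if (!file.exists(path)) stop("cannot read movie: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar_path <- paste0(path, ".json")
  side <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list()
  if (missing(channel_names) || is.null(channel_names))
    channel_names <- side$channel_names
  if (is.null(channel_names))
    stop("`channel_names` required (no sidecar present)")
  n_ch <- length(channel_names)
  if (length(pages) %% n_ch != 0L)
    stop(sprintf("page count (%d) is not a multiple of channel count (%d)",
                 length(pages), n_ch))
  n_frames <- length(pages) %/% n_ch
  if (is.null(layout)) layout <- side$layout %||% "interleaved"
  layout <- match.arg(layout, c("interleaved", "blocked"))
  if (is.null(intensity_scale))
    intensity_scale <- side$intensity_scale %||% .TIFF_MAX
  if (is.null(pixel_size_nm)) pixel_size_nm <- side$pixel_size_nm
  if (is.null(pixel_size_nm))
    stop("pixel size missing from metadata; pass `pixel_size_nm` explicitly")
  if (is.null(frame_times_s)) {
    if (!is.null(frame_interval_s)) {
      frame_times_s <- (seq_len(n_frames) - 1) * frame_interval_s
    } else {
      frame_times_s <- side$frame_times_s
    }
  }
  if (is.null(frame_times_s))
    stop("frame times missing from metadata; pass `frame_times_s` or `frame_interval_s`")
  if (length(frame_times_s) != n_frames)
    stop("frame time count does not match frame count")
  if (n_frames > 1L && any(diff(frame_times_s) <= 0))
    stop("non-monotone frame timestamps")
  if (is.null(pa_frames)) pa_frames <- side$pa_frames %||% integer()
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  channels <- vector("list", n_ch)
  names(channels) <- channel_names
  for (c_i in seq_len(n_ch)) {
    arr <- array(0, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      idx <- if (layout == "interleaved") (f - 1L) * n_ch + c_i
             else (c_i - 1L) * n_frames + f
      p <- pages[[idx]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # grey stored with alpha etc.
      arr[, , f] <- round(p * intensity_scale, 6)
    }
    channels[[c_i]] <- arr
  }
  time_lapse_movie(channels, pixel_size_nm = pixel_size_nm,
                   frame_times_s = frame_times_s, pa_frames = pa_frames,
                   metadata = if (is.list(side$metadata)) side$metadata else list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
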