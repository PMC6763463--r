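#' Detect diffraction-limited vesicles in a single frame
#'
#' Laplacian-of-Gaussian blob detection: the image is convolved with
#' scale-normalised negative-LoG kernels at the scales in
#' `cfg$log_sigma_px`, local maxima of the response above
#' `detect_k_sigma` robust SDs are kept (closest-first suppression at
#' `min_sep_px`), and positions are refined to subpixel precision by an
#' intensity-weighted centroid on the background-subtracted image.
#'
#' @param image numeric matrix.
#' @param cfg an [analysis_config()] (`log_sigma_px`, `detect_k_sigma`,
#'   `min_sep_px`).
#' @return data.frame with columns `x`, `y` (0-based subpixel),
#'   `peak_intensity`, `integrated_intensity`, `radius_px`, sorted by
#'   descending peak intensity. May have zero rows.
#' @export
detect_vesicles <- function(image, cfg = analysis_config()) {
  stopifnot(is.matrix(image), length(image) > 0)
  h <- nrow(image); w <- ncol(image)
  best <- matrix(-Inf, h, w); best_sig <- matrix(cfg$log_sigma_px[1L], h, w)
  for (sig in cfg$log_sigma_px) {
    resp <- as.matrix(EBImage::filter2(EBImage::Image(image),
                                       .log_kernel(sig)))
    upd <- resp > best
    best[upd] <- resp[upd]; best_sig[upd] <- sig
  }
  sd_r <- stats::mad(best)
  if (!is.finite(sd_r) || sd_r == 0) sd_r <- stats::sd(best)
  if (!is.finite(sd_r) || sd_r == 0)
    return(.empty_detections())
  thr <- stats::median(best) + cfg$detect_k_sigma * sd_r
  is_max <- .local_maxima(best) & best > thr
  idx <- which(is_max)
  if (!length(idx)) return(.empty_detections())
  ord <- idx[order(best[idx], decreasing = TRUE)]
  ii <- (ord - 1L) %% h + 1L; jj <- (ord - 1L) %/% h + 1L
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    if (k == 1L) { keep[k] <- TRUE; next }
    acc <- which(keep[seq_len(k - 1L)])
    keep[k] <- min((ii[acc] - ii[k])^2 + (jj[acc] - jj[k])^2) >
      cfg$min_sep_px^2
  }
  ii <- ii[keep]; jj <- jj[keep]
  sigs <- best_sig[cbind(ii, jj)]
  out <- lapply(seq_along(ii), function(k) {
    r <- max(2L, ceiling(2 * sigs[k]))
    i0 <- max(1L, ii[k] - r); i1 <- min(h, ii[k] + r)
    j0 <- max(1L, jj[k] - r); j1 <- min(w, jj[k] + r)
    win <- image[i0:i1, j0:j1]
    bg <- stats::median(c(win[1L, ], win[nrow(win), ],
                          win[, 1L], win[, ncol(win)]))
    wgt <- pmax(win - bg, 0)
    s <- sum(wgt)
    if (s <= 0) return(NULL)
    xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
    c(x = sum(colSums(wgt) * xs) / s,
      y = sum(rowSums(wgt) * ys) / s,
      peak_intensity = image[ii[k], jj[k]] - bg,
      integrated_intensity = s,
      radius_px = sqrt(2) * sigs[k])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) return(.empty_detections())
  out <- as.data.frame(out)
  out[order(out$peak_intensity, decreasing = TRUE), , drop = FALSE]
}

.empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), peak_intensity = numeric(0),
             integrated_intensity = numeric(0), radius_px = numeric(0))
}

# scale-normalised, zero-mean negative-LoG kernel (bright blobs -> positive
# response; zero mean kills constant background)
.log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  d <- seq(-r, r)
  g <- exp(-d^2 / (2 * sigma^2))
  G <- g %o% g
  r2 <- outer(d^2, d^2, "+")
  k <- -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 * G
  k - mean(k)
}

# strict local maxima over the 8-neighbourhood (ties broken by the
# suppression pass)
.local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  res <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj]
    res <- res & (m >= nb)
  }
  # require strict inequality against at least one neighbour to drop flats
  res & m > apply_min_neighbour(pad, h, w)
}

apply_min_neighbour <- function(pad, h, w) {
  mn <- matrix(Inf, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj]
    mn <- pmin(mn, nb)
  }
  mn
}

#' Remove detections inside an exclusion region
#'
#' Drops detections whose centroid pixel falls inside the exclusion mask
#' or ROI; a centroid exactly on a mask boundary pixel is excluded
#' (boundary pixels belong to the mask).
#'
#' @param detections data.frame from [detect_vesicles()].
#' @param exclusion logical matrix or an [roi_circle()]/[roi_polygon()].
#' @param height,width image size (required when `exclusion` is an ROI).
#' @return filtered data.frame.
#' @export
exclude_region <- function(detections, exclusion, height = NULL,
                           width = NULL) {
  if (!nrow(detections)) return(detections)
  if (inherits(exclusion, "roi")) {
    if (is.null(height) || is.null(width))
      stop("height/width required to rasterize an ROI exclusion")
    exclusion <- rasterize_roi(exclusion, height, width)
  }
  stopifnot(is.matrix(exclusion))
  i <- pmin(pmax(round(detections$y) + 1L, 1L), nrow(exclusion))
  j <- pmin(pmax(round(detections$x) + 1L, 1L), ncol(exclusion))
  detections[!exclusion[cbind(i, j)], , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking, closest pairs first,
#' with gap closing up to `max_gap_frames`; detections left unlinked start
#' new tracks.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (plus any
#'   detection columns).
#' @param cfg an [analysis_config()] (`max_link_distance_px`,
#'   `max_gap_frames`).
#' @return the input data.frame with a `track_id` column, ordered by
#'   (track_id, frame).
#' @export
track_vesicles <- function(detections, cfg = analysis_config()) {
  if (!nrow(detections)) {
    detections$track_id <- integer(0)
    return(detections)
  }
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  next_id <- 1L
  # active track state: id, last frame, last position
  act <- data.frame(id = integer(0), frame = integer(0),
                    x = numeric(0), y = numeric(0))
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    cand <- which(act$frame >= f - 1L - cfg$max_gap_frames & act$frame < f)
    if (length(cand) && length(rows)) {
      dx <- outer(act$x[cand], det$x[rows], "-")
      dy <- outer(act$y[cand], det$y[rows], "-")
      dd <- sqrt(dx^2 + dy^2)
      pairs <- which(dd <= cfg$max_link_distance_px, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(dd[pairs]), , drop = FALSE]
        used_t <- logical(length(cand)); used_d <- logical(length(rows))
        for (pidx in seq_len(nrow(pairs))) {
          ti <- pairs[pidx, 1L]; di <- pairs[pidx, 2L]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          id <- act$id[cand[ti]]
          det$track_id[rows[di]] <- id
          act$frame[cand[ti]] <- f
          act$x[cand[ti]] <- det$x[rows[di]]
          act$y[cand[ti]] <- det$y[rows[di]]
        }
      }
    }
    new_rows <- rows[is.na(det$track_id[rows])]
    for (rr in new_rows) {
      det$track_id[rr] <- next_id
      act <- rbind(act, data.frame(id = next_id, frame = f,
                                   x = det$x[rr], y = det$y[rr]))
      next_id <- next_id + 1L
    }
    act <- act[act$frame >= f - 1L - cfg$max_gap_frames, , drop = FALSE]
  }
  det[order(det$track_id, det$frame), , drop = FALSE]
}

#' Fraction of A-vesicles with a B-neighbour within the distance threshold
#'
#' For each detection in A the Euclidean nearest neighbour in B is found;
#' returns `100 * #{distance <= nn_threshold_nm} / |A|`. Distances are 2D
#' centroid-to-centroid in physical units; ties at the threshold count as
#' within.
#'
#' @param detections_a,detections_b data.frames with `x`, `y` (pixels,
#'   same frame geometry).
#' @param cfg an [analysis_config()] (`nn_threshold_nm`).
#' @param pixel_size_nm physical pixel size.
#' @return percent in `[0, 100]`, or `NA` when A is empty (undefined).
#' @export
nn_fraction <- function(detections_a, detections_b,
                        cfg = analysis_config(), pixel_size_nm) {
  stopifnot(is.finite(pixel_size_nm), pixel_size_nm > 0)
  na <- nrow(detections_a)
  if (na == 0L) return(NA_real_)
  if (nrow(detections_b) == 0L) return(0)
  dx <- outer(detections_a$x, detections_b$x, "-")
  dy <- outer(detections_a$y, detections_b$y, "-")
  dmin <- sqrt(apply(dx^2 + dy^2, 1L, min)) * pixel_size_nm
  100 * sum(dmin <= cfg$nn_threshold_nm) / na
}

#' Randomised control for the nearest-neighbour fraction
#'
#' Repositions each A-detection uniformly at random within the cell mask
#' (minus an optional exclusion region), recomputes [nn_fraction()]
#' against the fixed B set, and returns the mean over `n_iter` iterations.
#' Deterministic given `seed`. This is the chance-level colocalization
#' expected for the observed A count and B geometry.
#'
#' @inheritParams nn_fraction
#' @param cell_mask logical matrix of admissible positions.
#' @param exclusion optional logical matrix removed from the support.
#' @param n_iter iterations (>= 1).
#' @param seed integer seed.
#' @return list: `mean_percent`, `per_iteration` (length `n_iter`).
#' @export
randomized_nn_fraction <- function(detections_a, cell_mask, detections_b,
                                   cfg = analysis_config(), pixel_size_nm,
                                   n_iter = 100L, seed = 1L,
                                   exclusion = NULL) {
  stopifnot(is.matrix(cell_mask), n_iter >= 1L)
  support <- cell_mask
  if (!is.null(exclusion)) support <- support & !exclusion
  idx <- which(support)
  if (!length(idx)) stop("empty support for randomisation")
  na <- nrow(detections_a)
  h <- nrow(cell_mask)
  with_seed(seed, {
    vals <- vapply(seq_len(n_iter), function(it) {
      s <- sample(idx, na, replace = TRUE)
      # uniform within the chosen pixel keeps positions continuous
      rx <- (s - 1L) %/% h + stats::runif(na, -0.5, 0.5)
      ry <- (s - 1L) %% h + stats::runif(na, -0.5, 0.5)
      nn_fraction(data.frame(x = rx, y = ry), detections_b, cfg,
                  pixel_size_nm)
    }, numeric(1L))
    list(mean_percent = mean(vals), per_iteration = vals)
  })
}

#' Per-frame vesicle counts outside an exclusion region
#'
#' Runs [detect_vesicles()] on every frame of a channel, removes
#' detections inside the exclusion region, and returns the counts as a
#' trace (units "vesicles").
#'
#' @param movie a [time_lapse_movie()].
#' @param channel channel name or index.
#' @param exclusion optional ROI or logical matrix.
#' @param cfg an [analysis_config()].
#' @return an [intensity_trace()] of counts.
#' @export
vesicle_count_trace <- function(movie, channel = 1L, exclusion = NULL,
                                cfg = analysis_config()) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  counts <- integer(movie$n_frames)
  for (f in seq_len(movie$n_frames)) {
    det <- detect_vesicles(movie_frame(movie, channel, f), cfg)
    if (!is.null(exclusion))
      det <- exclude_region(det, exclusion, movie$height, movie$width)
    counts[f] <- nrow(det)
  }
  intensity_trace(movie$frame_times_s, counts, units = "vesicles")
}
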