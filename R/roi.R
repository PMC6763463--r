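#' Regions of interest
#'
#' ROIs are circles or polygons in 0-based pixel coordinates (x = column,
#' y = row, positions refer to pixel centres). Each ROI carries a role tag:
#' `photoactivation` (the pulsed region), `cell_outline`, `pm_band`
#' (plasma-membrane band) or `exclusion`.
#'
#' @param cx,cy circle centre (0-based pixel coordinates).
#' @param r circle radius in pixels (> 0).
#' @param role one of `"photoactivation"`, `"cell_outline"`, `"pm_band"`,
#'   `"exclusion"`.
#' @return object of class `roi`.
#' @export
roi_circle <- function(cx, cy, r, role = "photoactivation") {
  if (!is.finite(r) || r <= 0) stop("circle radius must be > 0")
  structure(list(shape = "circle", cx = as.numeric(cx), cy = as.numeric(cy),
                 r = as.numeric(r), role = .check_roi_role(role)),
            class = "roi")
}

#' @rdname roi_circle
#' @param x,y polygon vertex coordinates (0-based pixels; at least 3
#'   vertices).
#' @export
roi_polygon <- function(x, y, role = "cell_outline") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("a polygon ROI needs at least 3 vertices")
  structure(list(shape = "polygon", x = x, y = y, role = .check_roi_role(role)),
            class = "roi")
}

.roi_roles <- c("photoactivation", "cell_outline", "pm_band", "exclusion")

.check_roi_role <- function(role) {
  if (!is.character(role) || length(role) != 1L || !(role %in% .roi_roles))
    stop("unknown ROI role: ", paste(role, collapse = ", "))
  role
}

#' @export
print.roi <- function(x, ...) {
  if (x$shape == "circle")
    cat(sprintf("roi: circle centre (%.2f, %.2f) r=%.2f px [%s]\n",
                x$cx, x$cy, x$r, x$role))
  else
    cat(sprintf("roi: polygon with %d vertices [%s]\n", length(x$x), x$role))
  invisible(x)
}

#' Read / write an ROI as JSON
#'
#' Schema: `{"shape": "circle", "cx":, "cy":, "r":, "role":}` or
#' `{"shape": "polygon", "x": [...], "y": [...], "role":}`.
#'
#' @param path JSON file path.
#' @return [load_roi()] returns an `roi`; [write_roi()] returns `path`
#'   invisibly.
#' @export
load_roi <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$shape)) stop("malformed ROI JSON: missing `shape`")
  switch(as.character(j$shape),
    circle = roi_circle(j$cx, j$cy, j$r, role = j$role),
    polygon = roi_polygon(j$x, j$y, role = j$role),
    stop("malformed ROI JSON: unknown shape ", j$shape))
}

#' @rdname load_roi
#' @param roi an `roi` object.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize an ROI to a boolean pixel mask
#'
#' A pixel belongs to the mask when its centre lies inside or on the boundary
#' of the ROI (boundary pixels belong to the region).
#'
#' @param roi an `roi` object.
#' @param height,width raster size in pixels.
#' @return logical `height x width` matrix.
#' @export
rasterize_roi <- function(roi, height, width) {
  stopifnot(inherits(roi, "roi"))
  xs <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  if (roi$shape == "circle") {
    (xs - roi$cx)^2 + (ys - roi$cy)^2 <= roi$r^2
  } else {
    matrix(.point_in_polygon(as.vector(xs), as.vector(ys), roi$x, roi$y),
           nrow = height)
  }
}

# even-odd ray casting; points on an edge count as inside
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # edge hit test (collinear and within bounding box)
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- pmin(xi, xj) - 1e-9 <= px & px <= pmax(xi, xj) + 1e-9 &
              pmin(yi, yj) - 1e-9 <= py & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Morphological ring just inside a cell outline
#'
#' Builds the plasma-membrane band used by recycling quantification: the set
#' of cell pixels within `band_width_px` of the cell boundary (cell mask
#' minus its erosion by the band width).
#'
#' @param cell_mask logical matrix (cell interior TRUE).
#' @param band_width_px band width in pixels.
#' @return logical matrix.
#' @export
pm_band_mask <- function(cell_mask, band_width_px = 4L) {
  stopifnot(is.matrix(cell_mask))
  brush <- EBImage::makeBrush(2L * as.integer(band_width_px) + 1L, "disc")
  eroded <- EBImage::erode(EBImage::Image(cell_mask * 1), brush)
  cell_mask & !(as.matrix(eroded) > 0.5)
}
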