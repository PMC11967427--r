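# Morphometry of binary particle masks and contours.
#
# Conventions (documented in the methods vignette):
#  * pixel coordinates are 0-based, x right / y down; a pixel occupies the
#    unit square centred on its integer coordinate;
#  * feret diameters are computed on the pixel-corner point set, so an
#    axis-aligned w x h block reports feret_h = w and feret_v = h exactly;
#  * perimeter is the polygonal length of the traced 8-connected boundary
#    chain (pixel-edge outline for very small shapes).

#' Feret diameters of a contour
#'
#' Computes the horizontal and vertical feret diameters (axis-aligned
#' bounding-box extents), the maximum feret (longest caliper width over all
#' directions) and the minimum feret (narrowest caliper width) of a set of
#' boundary pixel coordinates. The calipers are applied to the pixel-corner
#' point set (each boundary pixel expanded by half a pixel in each direction)
#' so that extents match pixel counts.
#'
#' @param contour numeric matrix with two columns (x, y) of 0-based boundary
#'   pixel coordinates; at least one point.
#' @return named numeric vector with elements `feret_h`, `feret_v`,
#'   `feret_max`, `feret_min` (all in pixels).
#' @examples
#' # an axis-aligned 10 x 4 rectangle of boundary pixels
#' pts <- as.matrix(expand.grid(x = 0:9, y = 0:3))
#' feret_diameters(pts)
#' @export
feret_diameters <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 1L || ncol(contour) != 2L)
    stop("contour must be an n x 2 matrix of (x, y) coordinates")
  x <- contour[, 1]
  y <- contour[, 2]
  feret_h <- diff(range(x)) + 1
  feret_v <- diff(range(y)) + 1
  # corner point set: centres +/- 0.5 in each axis
  cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  pts <- cbind(cx, cy)
  hull <- pts[chull(pts), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1L) {
    return(c(feret_h = 1, feret_v = 1, feret_max = 1, feret_min = 1))
  }
  d <- as.matrix(stats::dist(hull))
  feret_max <- max(d)
  # minimum caliper width: for each hull edge, the largest distance of any
  # hull vertex from the edge's supporting line
  if (n == 2L) {
    feret_min <- 1  # degenerate (collinear) contour: line width convention
  } else {
    widths <- vapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      ex <- hull[j, 1] - hull[i, 1]
      ey <- hull[j, 2] - hull[i, 2]
      len <- sqrt(ex^2 + ey^2)
      if (len == 0) return(Inf)
      max(abs((hull[, 1] - hull[i, 1]) * ey - (hull[, 2] - hull[i, 2]) * ex)) / len
    }, numeric(1))
    feret_min <- min(widths)
    if (!is.finite(feret_min) || feret_min < 1) feret_min <- max(1, feret_min)
  }
  c(feret_h = feret_h, feret_v = feret_v,
    feret_max = feret_max, feret_min = feret_min)
}

#' Shape statistics of a binary mask
#'
#' Measures area, perimeter, feret diameters, circularity
#' (4 pi area / perimeter^2), aspect ratio (feret_max / feret_min), pixel size
#' (`size_px`, the rounded maximum feret) and metric size
#' (`size_um = size_px * pixel_scale`) of a single connected binary mask.
#'
#' @param mask logical (or 0/1) matrix; rows are y, columns are x. Must
#'   contain at least one foreground pixel.
#' @param pixel_scale micrometres per pixel (default 18).
#' @return a one-row data.frame of class statistics (`area_px`,
#'   `perimeter_px`, `feret_h_px`, `feret_v_px`, `feret_max_px`,
#'   `feret_min_px`, `circularity`, `aspect_ratio`, `size_px`, `size_um`).
#' @examples
#' m <- disk_mask(20)
#' shape_stats(m)
#' @export
shape_stats <- function(mask, pixel_scale = 18) {
  mask <- mask_logical(mask)
  area <- sum(mask)
  if (area == 0L) stop("empty mask")
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  chain <- .trace_boundary_cpp(mask)
  if (nrow(chain) >= 8L) {
    dx <- diff(c(chain[, 1], chain[1, 1]))
    dy <- diff(c(chain[, 2], chain[1, 2]))
    perim <- sum(sqrt(dx^2 + dy^2))
  } else {
    # tiny shapes: the traced chain under-samples, use pixel-edge outline
    perim <- .edge_perimeter_cpp(mask)
  }
  # boundary pixels (any foreground pixel touching background, 4-connectivity)
  bnd <- boundary_pixels(mask)
  fer <- feret_diameters(bnd)
  circ <- 4 * pi * area / perim^2
  size_px <- max(1L, as.integer(round(fer[["feret_max"]])))
  data.frame(
    area_px = area,
    perimeter_px = perim,
    feret_h_px = fer[["feret_h"]],
    feret_v_px = fer[["feret_v"]],
    feret_max_px = fer[["feret_max"]],
    feret_min_px = fer[["feret_min"]],
    circularity = circ,
    aspect_ratio = fer[["feret_max"]] / fer[["feret_min"]],
    size_px = size_px,
    size_um = size_px * pixel_scale
  )
}

#' Size category of a particle
#'
#' Assigns the four descriptive size classes used for reporting:
#' small (< 6 px), medium (6-10 px), large (10-20 px) and extra_large
#' (>= 20 px); at the default scale of 18 um per pixel the boundaries fall at
#' 108, 180 and 360 um. Intervals are half-open with boundary values going to
#' the larger category.
#'
#' @param size numeric vector of particle sizes (maximum feret).
#' @param pixel_scale micrometres per pixel (default 18).
#' @param units `"px"` (default) or `"um"`.
#' @return factor with levels `small`, `medium`, `large`, `extra_large`.
#' @examples
#' size_category(c(5, 6, 10, 20))
#' size_category(c(107, 108, 360), units = "um")
#' @export
size_category <- function(size, pixel_scale = 18, units = c("px", "um")) {
  units <- match.arg(units)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("sizes must be positive and finite")
  px <- if (units == "um") size / pixel_scale else size
  lev <- c("small", "medium", "large", "extra_large")
  cut(px, breaks = c(0, 6, 10, 20, Inf), labels = lev, right = FALSE)
}

#' @rdname shape_stats
#' @details `size_category_levels()` returns the category level names in
#'   increasing size order.
#' @export
size_category_levels <- function() c("small", "medium", "large", "extra_large")

# ---- internal helpers -------------------------------------------------------

mask_logical <- function(mask) {
  if (is.logical(mask)) return(mask)
  m <- mask > 0
  storage.mode(m) <- "logical"
  m
}

# (x, y) coordinates (0-based) of foreground pixels touching background
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  up    <- pad[1:H, 2:(W + 1L)]
  down  <- pad[3:(H + 2L), 2:(W + 1L)]
  left  <- pad[2:(H + 1L), 1:W]
  right <- pad[2:(H + 1L), 3:(W + 2L)]
  b <- matrix(core & !(up & down & left & right), H, W)
  idx <- which(b, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

# all foreground pixel coordinates, 0-based (x, y)
mask_pixels <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

mask_centroid <- function(mask) {
  p <- mask_pixels(mask)
  c(x = mean(p[, 1]), y = mean(p[, 2]))
}

#' Rasterize a disk mask
#'
#' Convenience generator of a filled disk of the given diameter in pixels,
#' used throughout the examples and tests.
#'
#' @param diameter_px disk diameter in pixels.
#' @param pad background margin in pixels around the disk.
#' @return logical matrix.
#' @export
disk_mask <- function(diameter_px, pad = 2) {
  r <- diameter_px / 2
  n <- as.integer(ceiling(diameter_px)) + 2L * as.integer(pad)
  cx <- (n - 1) / 2
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  (xs - cx)^2 + (ys - cx)^2 < r^2
}
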