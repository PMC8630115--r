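# Geometry helpers shared by morphology, boundary and orientation code.
# Coordinates: x = column - 1, y measured upward (y = -(row - 1)) so angles
# are counter-clockwise from +x, matching the package-wide convention.

mask_xy <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  cbind(x = cc - 1, y = -(r - 1))
}

# Second-moment (best-fit ellipse) summary of a binary mask.
mask_moments <- function(mask) {
  xy <- mask_xy(mask)
  n <- nrow(xy)
  mu <- colMeans(xy)
  d <- sweep(xy, 2, mu)
  # add 1/12 per axis: each pixel is a unit square, not a point
  cxx <- mean(d[, 1]^2) + 1 / 12
  cyy <- mean(d[, 2]^2) + 1 / 12
  cxy <- mean(d[, 1] * d[, 2])
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  theta <- theta %% 180
  list(centroid = mu, n = n, major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       aspect_ratio = sqrt(l1 / l2), eccentricity = sqrt(1 - l2 / l1),
       theta_deg = theta)
}

# Convex hull (indices into pts, counter-clockwise) via Andrew's monotone
# chain; pts is an n x 2 matrix.
convex_hull_ccw <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])   # returned clockwise
  rev(h)
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Corner cloud of the mask's pixels: each pixel is a unit square centred on
# its (x, y) coordinate. The convex hull of these corners is the hull of the
# pixelated region itself (Minkowski sum of the centre hull with the unit
# square), so hull areas and Feret diameters are measured on solid pixels,
# never on pixel centres.
mask_corner_points <- function(mask) {
  xy <- mask_xy(mask)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  ctr <- xy[h, , drop = FALSE]
  corners <- rbind(
    sweep(ctr, 2, c(-0.5, -0.5), "+"), sweep(ctr, 2, c(0.5, -0.5), "+"),
    sweep(ctr, 2, c(-0.5, 0.5), "+"),  sweep(ctr, 2, c(0.5, 0.5), "+"))
  corners[grDevices::chull(corners[, 1], corners[, 2]), , drop = FALSE]
}

# Min/max Feret (caliper) diameters by rotating calipers on the corner hull.
feret_diameters <- function(mask) {
  hull <- mask_corner_points(mask)
  n <- nrow(hull)
  if (n == 1L) return(c(min = 1, max = 1))
  dmat <- as.matrix(stats::dist(hull))
  fmax <- max(dmat)
  # min Feret: for each hull edge, width = max distance of vertices from the
  # edge's supporting line
  fmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(-e[2], e[1]) / len
    w <- abs((hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2])
    fmin <- min(fmin, max(w))
  }
  c(min = fmin, max = fmax)
}

#' Global morphological features of a nucleus
#'
#' Area (pixel count scaled to square micrometres), perimeter (arc length of
#' the smoothed boundary contour), aspect ratio and eccentricity from the
#' mask's second moments, and min/max caliper (Feret) diameters by rotating
#' calipers over the convex hull of the pixel region.
#'
#' @param n a `nucleus_crop`.
#' @return Named numeric vector: `area_um2`, `perimeter_um`, `aspect_ratio`,
#'   `eccentricity`, `min_caliper_um`, `max_caliper_um`. All NA for masks
#'   under 3 pixels (degenerate).
#' @export
morphology_features <- function(n) {
  stopifnot(inherits(n, "nucleus_crop"))
  nm <- c("area_um2", "perimeter_um", "aspect_ratio", "eccentricity",
          "min_caliper_um", "max_caliper_um")
  ps <- n$crop$pixel_size_um
  if (sum(n$mask) < 3L)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  mom <- mask_moments(n$mask)
  fer <- feret_diameters(n$mask)
  per <- tryCatch(contour_perimeter_px(n$mask), error = function(e) NA_real_)
  stats::setNames(
    c(sum(n$mask) * ps^2, per * ps, mom$aspect_ratio, mom$eccentricity,
      fer["min"] * ps, fer["max"] * ps),
    nm)
}

#' Axial orientation of a nucleus
#'
#' Angle of the best-fit ellipse's major axis to the image x axis,
#' counter-clockwise, reduced to [0, 180) degrees (orientations are axial:
#' theta and theta + 180 are the same direction).
#'
#' @param mask binary matrix (rows = y, columns = x) with >= 3 pixels.
#' @param ar_undefined_below aspect ratio under which the angle is reported
#'   NA (near-circular masks have no meaningful axis; default 1.05).
#' @return Angle in degrees in [0, 180), or NA if undefined.
#' @export
nucleus_orientation <- function(mask, ar_undefined_below = 1.05) {
  mask <- as.matrix(mask) != 0
  if (sum(mask) < 3L) return(NA_real_)
  mom <- mask_moments(mask)
  if (mom$aspect_ratio < ar_undefined_below) return(NA_real_)
  mom$theta_deg
}
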