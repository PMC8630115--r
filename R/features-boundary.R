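# Boundary contour machinery: extraction, equal-arc resampling, circular
# Gaussian smoothing, signed curvature.

# Oriented boundary contour of the largest object in a binary mask, as an
# n x 2 matrix in (x, y-up) coordinates, counter-clockwise.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(0 + mask)))
  if (!length(oc)) stop("mask_contour: no boundary found")
  sizes <- vapply(oc, nrow, integer(1))
  p <- oc[[which.max(sizes)]]            # (x, y) 0-based, y = row downward
  xy <- cbind(x = p[, 1], y = -p[, 2])
  # enforce counter-clockwise orientation (positive signed area)
  x <- xy[, 1]; y <- xy[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

# Resample a closed polygon at n_points equally spaced arc-length positions.
resample_closed <- function(xy, n_points = 200L) {
  xy2 <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(xy2[, 1])^2 + diff(xy2[, 2])^2)
  keep <- seg > 1e-12
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  if (total < 1e-9) stop("resample_closed: degenerate contour")
  s <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- stats::approx(cs, xy2[, 1], xout = s)$y
  y <- stats::approx(cs, xy2[, 2], xout = s)$y
  cbind(x = x, y = y)
}

# Circular Gaussian smoothing of a closed-contour coordinate sequence,
# sigma in resampled-point units.
smooth_closed <- function(xy, sigma = 2) {
  if (sigma <= 0) return(xy)
  n <- nrow(xy)
  half <- min(ceiling(4 * sigma), floor((n - 1) / 2))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(v) {
    vv <- c(v[(n - half + 1):n], v, v[1:half])
    stats::filter(vv, k, sides = 2)[(half + 1):(half + n)]
  }
  cbind(x = as.numeric(smooth1(xy[, 1])), y = as.numeric(smooth1(xy[, 2])))
}

# Signed curvature at each point of a closed contour by central finite
# differences; positive = locally convex for a counter-clockwise contour.
closed_curvature <- function(xy) {
  n <- nrow(xy)
  ip <- c(n, 1:(n - 1)); inx <- c(2:n, 1)
  xp <- (xy[inx, 1] - xy[ip, 1]) / 2
  yp <- (xy[inx, 2] - xy[ip, 2]) / 2
  xpp <- xy[inx, 1] - 2 * xy[, 1] + xy[ip, 1]
  ypp <- xy[inx, 2] - 2 * xy[, 2] + xy[ip, 2]
  den <- (xp^2 + yp^2)^1.5
  den[den < 1e-12] <- NA_real_
  (xp * ypp - yp * xpp) / den
}

# Count the pixels of the mask's bounding box whose centres fall inside the
# convex hull of the mask's pixel centres. For a convex rasterized shape
# this equals the mask pixel count exactly, so relative concavity has a
# clean zero baseline.
pixels_in_hull <- function(mask) {
  xy <- mask_xy(mask)
  h <- xy[grDevices::chull(xy), , drop = FALSE]
  if (nrow(h) < 3L) return(sum(mask))
  # force counter-clockwise orientation so "inside" is cross >= 0
  a2 <- sum(h[, 1] * c(h[-1, 2], h[1, 2]) - c(h[-1, 1], h[1, 1]) * h[, 2])
  if (a2 < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  allx <- rep(0:(nc - 1L), each = nr)
  ally <- rep(-(0:(nr - 1L)), nc)
  inside <- rep(TRUE, nr * nc)
  nh <- nrow(h)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- h[j, 1] - h[i, 1]; ey <- h[j, 2] - h[i, 2]
    inside <- inside & (ex * (ally - h[i, 2]) - ey * (allx - h[i, 1]) >= -1e-7)
  }
  sum(inside)
}

# Perimeter of the smoothed resampled boundary, in pixels.
contour_perimeter_px <- function(mask, n_points = 200L, sigma = 5) {
  xy <- smooth_closed(resample_closed(mask_contour(mask), n_points), sigma)
  xy2 <- rbind(xy, xy[1, ])
  sum(sqrt(diff(xy2[, 1])^2 + diff(xy2[, 2])^2))
}

#' Nuclear boundary features
#'
#' The boundary contour is resampled at `n_points` equal arc-length
#' positions, smoothed with a circular Gaussian (`smooth_sigma`, in
#' resampled-point units), and its signed curvature estimated by finite
#' differences (positive = locally convex). Reported are the arc-length
#' fractions of the perimeter with positive and negative curvature, the
#' standard deviation of curvature over the negatively curved segments
#' (0 when there are none), and the relative concavity
#' (convex-hull area - area) / convex-hull area, with both areas measured
#' by pixel counting so a convex rasterized shape scores exactly 0.
#'
#' @param n a `nucleus_crop` whose mask is one connected region.
#' @param smooth_sigma contour smoothing sigma (default 5 points; strong
#'   enough to suppress the curvature ripple of pixelated boundaries).
#' @param n_points number of resampled contour points (default 200).
#' @return Named numeric vector: `frac_perimeter_positive_curved`,
#'   `frac_perimeter_negative_curved`, `sd_negative_curvature`,
#'   `relative_concavity`. Curvatures are per-pixel (1/px).
#' @export
boundary_features <- function(n, smooth_sigma = 5, n_points = 200L) {
  stopifnot(inherits(n, "nucleus_crop"))
  nm <- c("frac_perimeter_positive_curved", "frac_perimeter_negative_curved",
          "sd_negative_curvature", "relative_concavity")
  if (sum(n$mask) < 3L)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  xy <- smooth_closed(resample_closed(mask_contour(n$mask), n_points),
                      smooth_sigma)
  kap <- closed_curvature(xy)
  kap <- kap[is.finite(kap)]
  fpos <- mean(kap > 0)
  fneg <- mean(kap < 0)
  sdneg <- if (sum(kap < 0) >= 2L) stats::sd(kap[kap < 0]) else 0
  hull_a <- pixels_in_hull(n$mask)
  area <- sum(n$mask)
  rc <- max(0, (hull_a - area) / hull_a)
  stats::setNames(c(fpos, fneg, sdneg, rc), nm)
}
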