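# Intensity statistics, Otsu thresholding and intensity-distribution
# features (PDI, centre-of-mass separation, Hu moment invariants).

# Per-nucleus 0-255 rescale of the masked intensities. The QC thresholds
# (median >= 10, sd >= 2) are defined on this scale.
rescale_255 <- function(v) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1]) * 255
}

# 256-bin histogram of values in [0, 255]: bin b counts values in [b, b+1),
# with 255 included in the last bin.
hist_256 <- function(v) {
  b <- pmin(floor(v), 255)
  tabulate(b + 1L, 256L)
}

# Otsu threshold on a 256-bin histogram: returns the bin index t (0..254)
# maximizing between-class variance for the split {<= t} vs {> t}, computed
# via cumulative moments. NA when one class would be empty for every split.
otsu_threshold_hist <- function(counts) {
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)[1:255]
  m0 <- cumsum(counts * lev)[1:255]
  w1 <- n - w0
  mu_t <- sum(counts * lev)
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_integer_)
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  which.max(bcv) - 1L
}

# Otsu split of a continuous vector: threshold between sorted unique values
# maximizing between-class variance; returns the threshold value.
otsu_threshold_values <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(th) {
    a <- v[v <= th]; b <- v[v > th]
    length(a) * length(b) * (mean(a) - mean(b))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

#' Global intensity features of a nucleus
#'
#' Computed on the in-mask pixels, by default after linear rescaling to the
#' 0-255 scale (brightest in-mask pixel = 255). Reported: mean, median,
#' standard deviation, histogram mode, Shannon entropy of the 256-bin
#' intensity histogram (bits), and the heterochromatin/euchromatin pixel
#' ratio = (#pixels above the per-nucleus Otsu split) / (#pixels at or
#' below it).
#'
#' @param n a `nucleus_crop`.
#' @param rescale rescale in-mask intensities to 0-255 first (default TRUE).
#'   With FALSE the pixel values must already be on a 0-255 scale.
#' @return Named numeric vector: `mean_intensity`, `median_intensity`,
#'   `sd_intensity`, `mode_intensity`, `intensity_entropy`, `hc_ec_ratio`.
#'   A constant nucleus yields sd 0, entropy 0 and hc_ec_ratio 0
#'   (degenerate: no split exists).
#' @export
intensity_features <- function(n, rescale = TRUE) {
  stopifnot(inherits(n, "nucleus_crop"))
  v <- n$crop$pixels[n$mask]
  if (rescale) v <- rescale_255(v)
  counts <- hist_256(v)
  p <- counts[counts > 0] / sum(counts)
  entropy <- -sum(p * log2(p))
  thr <- otsu_threshold_hist(counts)
  hc_ec <- if (is.na(thr)) 0 else {
    b <- pmin(floor(v), 255)
    lo <- sum(b <= thr)
    hi <- sum(b > thr)
    if (lo == 0) 0 else hi / lo
  }
  md <- counts
  mode_v <- which.max(md) - 1
  c(mean_intensity = mean(v), median_intensity = stats::median(v),
    sd_intensity = stats::sd(v), mode_intensity = as.numeric(mode_v),
    intensity_entropy = entropy, hc_ec_ratio = hc_ec)
}

# 7 Hu rotation-invariant moments of the masked intensity distribution.
hu_moments <- function(pixels, mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  y <- ((idx - 1L) %% nr)
  x <- ((idx - 1L) %/% nr)
  w <- pixels[idx]
  m00 <- sum(w)
  if (m00 <= 0) stop("hu_moments: zero total intensity")
  xb <- sum(w * x) / m00; yb <- sum(w * y) / m00
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(w * dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Intensity-distribution features of a nucleus
#'
#' Peripheral distribution index (PDI): the intensity-weighted mean squared
#' distance of in-mask pixels to the mask centroid, normalized by the
#' unweighted mean squared distance; 1 for uniform intensity, > 1 when
#' signal is peripherally enriched, < 1 when centrally concentrated. Also
#' the separation between the intensity-weighted centre of mass and the
#' mask centroid (micrometres), and Hu's 7 rotation-invariant moments of
#' the masked intensity, signed-log transformed
#' (sign(h) * log10(|h| + 1e-30)) for numerical range.
#'
#' @param n a `nucleus_crop` with positive total in-mask intensity.
#' @return Named numeric vector: `pdi`, `com_centroid_separation_um`,
#'   `hu_moment_1` .. `hu_moment_7`.
#' @export
distribution_features <- function(n) {
  stopifnot(inherits(n, "nucleus_crop"))
  w <- n$crop$pixels[n$mask]
  if (sum(w) <= 0) stop("distribution_features: zero total intensity")
  idx <- which(n$mask)
  nr <- nrow(n$mask)
  y <- (idx - 1L) %% nr
  x <- (idx - 1L) %/% nr
  cx <- mean(x); cy <- mean(y)
  d2 <- (x - cx)^2 + (y - cy)^2
  pdi <- (sum(w * d2) / sum(w)) / mean(d2)
  comx <- sum(w * x) / sum(w); comy <- sum(w * y) / sum(w)
  sep <- sqrt((comx - cx)^2 + (comy - cy)^2) * n$crop$pixel_size_um
  hu <- hu_moments(n$crop$pixels * n$mask, n$mask)
  hu_t <- sign(hu) * log10(abs(hu) + 1e-30)
  out <- c(pdi, sep, hu_t)
  names(out) <- c("pdi", "com_centroid_separation_um",
                  paste0("hu_moment_", 1:7))
  out
}
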