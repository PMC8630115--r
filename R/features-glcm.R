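#' Gray-level co-occurrence (Haralick) texture features of a nucleus
#'
#' For each pixel offset distance d, a symmetric, normalized co-occurrence
#' matrix is accumulated over the four offset angles (0, 45, 90, 135
#' degrees), counting only pixel pairs with *both* pixels inside the nucleus
#' mask. In-mask intensities are rescaled to 0-255 and quantized into
#' `levels` equal-width gray levels. From the pooled matrix six Haralick
#' statistics are reported per distance: contrast, homogeneity,
#' dissimilarity, entropy (bits), ASM (angular second moment / energy) and
#' correlation. The distance d is the texture length scale in pixels, and
#' is appended to each feature name (for example `glcm_contrast_3`).
#'
#' @param n a `nucleus_crop`.
#' @param distances integer pixel offsets (default c(1, 3, 5, 11, 21)).
#' @param levels number of gray levels (default 64).
#' @param angles offset angles in degrees, a subset of c(0, 45, 90, 135).
#' @param rescale rescale in-mask intensities to 0-255 first (default TRUE).
#' @return Named numeric vector of 6 * length(distances) features. A
#'   distance with no valid in-mask pixel pair yields NA for its six
#'   features.
#' @export
glcm_features <- function(n, distances = c(1, 3, 5, 11, 21), levels = 64L,
                          angles = c(0, 45, 90, 135), rescale = TRUE) {
  stopifnot(inherits(n, "nucleus_crop"), levels >= 2L, all(distances >= 1))
  q <- quantize_crop(n, levels, rescale)
  out <- numeric(0)
  for (d in distances) {
    P <- glcm_matrix(q, n$mask, d, levels, angles)
    f <- if (is.null(P)) stats::setNames(rep(NA_real_, 6), glcm_stat_names())
         else glcm_stats(P)
    names(f) <- paste0("glcm_", glcm_stat_names(), "_", d)
    out <- c(out, f)
  }
  out
}

glcm_stat_names <- function() {
  c("contrast", "homogeneity", "dissimilarity", "entropy", "asm", "correlation")
}

# Quantize in-mask intensities to levels {0 .. levels-1}; out-of-mask = NA.
quantize_crop <- function(n, levels, rescale = TRUE) {
  q <- matrix(NA_integer_, nrow(n$mask), ncol(n$mask))
  v <- n$crop$pixels[n$mask]
  if (rescale) v <- rescale_255(v)
  q[n$mask] <- pmin(as.integer(floor(v / 256 * levels)), levels - 1L)
  q
}

# Pooled symmetric normalized co-occurrence matrix at distance d, or NULL
# if no valid pair exists. Angles follow the y-up convention: 45 degrees
# pairs a pixel with its upper-right in-mask neighbour.
glcm_matrix <- function(q, mask, d, levels, angles = c(0, 45, 90, 135)) {
  nr <- nrow(q); nc <- ncol(q)
  offs <- list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L),
               `135` = c(-d, -d))
  counts <- matrix(0, levels, levels)
  total <- 0
  for (a in as.character(angles)) {
    o <- offs[[a]]
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a1 <- q[r1, c1, drop = FALSE]
    a2 <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    i <- a1[ok]; j <- a2[ok]
    tab <- table(factor(i, levels = 0:(levels - 1L)),
                 factor(j, levels = 0:(levels - 1L)))
    counts <- counts + tab + t(tab)          # symmetric
    total <- total + 2 * sum(tab)
  }
  if (total == 0) return(NULL)
  counts / total
}

# Haralick statistics of a normalized symmetric GLCM.
glcm_stats <- function(P) {
  L <- nrow(P)
  lev <- 0:(L - 1)
  I <- matrix(lev, L, L)
  J <- t(I)
  Dm <- I - J
  pnz <- P[P > 0]
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  var_i <- sum((I - mu_i)^2 * P); var_j <- sum((J - mu_j)^2 * P)
  corr <- if (var_i <= 1e-15 || var_j <= 1e-15) 1 else
    sum((I - mu_i) * (J - mu_j) * P) / sqrt(var_i * var_j)
  c(contrast = sum(P * Dm^2),
    homogeneity = sum(P / (1 + Dm^2)),
    dissimilarity = sum(P * abs(Dm)),
    entropy = -sum(pnz * log2(pnz)),
    asm = sum(P^2),
    correlation = corr)
}
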