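#' Grayscale image with physical pixel size
#'
#' Lightweight container for a single-channel image: a numeric matrix of
#' non-negative intensities plus the physical pixel size in micrometres.
#' Pixel coordinates are 0-based with x = column, y = row; angles are
#' measured counter-clockwise from the +x axis.
#'
#' @param pixels numeric matrix (rows = y, columns = x) of finite,
#'   non-negative intensities; at least 2x2.
#' @param pixel_size_um micrometres per pixel (scalar > 0).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size_um = 1) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("gray_image: pixels must be at least 2x2")
  if (!all(is.finite(pixels)))
    stop("gray_image: pixels must be finite")
  if (any(pixels < 0))
    stop("gray_image: pixels must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("gray_image: pixel_size_um must be a positive scalar")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Instance label mask
#'
#' Integer matrix the same shape as its source image: 0 is background and
#' k >= 1 marks the pixels of nucleus instance k. Labels form the contiguous
#' set \{0..K\} and each instance is 4-connected.
#'
#' @param labels integer matrix of instance labels.
#' @param pixel_size_um micrometres per pixel.
#' @param relabel if TRUE (default), relabel so that labels are contiguous
#'   and every instance is split into its 4-connected components.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um = 1, relabel = TRUE) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("label_mask: labels must be >= 0")
  if (relabel) labels <- relabel_4connected(labels)
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d instances, %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), x$pixel_size_um))
  invisible(x)
}

# Split every labelled region into 4-connected components and renumber
# 1..K in raster order of the component's first pixel.
relabel_4connected <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(labels > 0L & out == 0L)
  for (p in todo) {
    if (out[p] != 0L) next
    nxt <- nxt + 1L
    lab <- labels[p]
    # BFS flood fill within pixels of the same source label
    queue <- p
    out[p] <- nxt
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (d in 1:4) {
        rn <- r + c(-1L, 1L, 0L, 0L)[d]
        cn <- cc + c(0L, 0L, -1L, 1L)[d]
        ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
        idx <- (cn[ok] - 1L) * nr + rn[ok]
        idx <- idx[labels[idx] == lab & out[idx] == 0L]
        if (length(idx)) {
          out[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  out
}

#' Single segmented nucleus
#'
#' A grayscale crop restricted to one instance's bounding box, the matching
#' binary mask, the instance centroid in source-image pixel coordinates
#' (0-based, x = column), and provenance identifiers.
#'
#' @param crop `gray_image` restricted to the instance bounding box.
#' @param mask logical/0-1 matrix, same shape as `crop$pixels`.
#' @param centroid_xy numeric length-2, centroid in source-image pixels.
#' @param tissue_id character tissue identifier.
#' @param label integer instance label in the source mask.
#' @param touches_border flag: instance touched the source-image border.
#' @return An object of class `nucleus_crop`.
#' @export
nucleus_crop <- function(crop, mask, centroid_xy = c(NA_real_, NA_real_),
                         tissue_id = "tissue", label = 1L,
                         touches_border = FALSE) {
  stopifnot(inherits(crop, "gray_image"))
  mask <- as.matrix(mask) != 0
  if (!identical(dim(mask), dim(crop$pixels)))
    stop("nucleus_crop: crop and mask shapes differ")
  if (!any(mask)) stop("nucleus_crop: mask must have >= 1 foreground pixel")
  structure(list(crop = crop, mask = mask, centroid_xy = as.numeric(centroid_xy),
                 tissue_id = tissue_id, label = as.integer(label),
                 touches_border = isTRUE(touches_border)),
            class = "nucleus_crop")
}

#' @export
print.nucleus_crop <- function(x, ...) {
  cat(sprintf("<nucleus_crop> %s/#%d: %d x %d px, %d mask px\n",
              x$tissue_id, x$label, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Rescale an image linearly to [0, 1]
#'
#' The brightest pixel maps to 1 and the dimmest to 0; intermediate values
#' are rescaled linearly. A constant image has no defined rescaling and is
#' rejected.
#'
#' @param img a `gray_image`.
#' @return A `gray_image` with intensities in [0, 1].
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  rng <- range(img$pixels)
  if (rng[2] <= rng[1])
    stop("normalize_image: constant image has zero intensity range")
  gray_image((img$pixels - rng[1]) / (rng[2] - rng[1]), img$pixel_size_um)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Multi-channel images are reduced to the requested channel.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um micrometres per pixel of the stored image.
#' @param channel channel index for multi-channel inputs (default 1).
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path, pixel_size_um = 1, channel = 1L) {
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im)
  if (length(dim(px)) == 3L) px <- px[, , channel]
  # EBImage stores x in dim 1; transpose to rows = y
  gray_image(t(px), pixel_size_um)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask a `label_mask`.
#' @param path output path.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L)
    stop("write_label_mask: more than 65535 instances")
  im <- EBImage::Image(t(mask$labels) / 65535)
  EBImage::writeImage(im, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()] or a third-party tool
#'
#' Accepts any single-channel TIFF/PNG whose integer pixel values are
#' instance labels. This is the import path for externally produced
#' segmentations (for example CNN-based instance masks): downstream
#' processing is identical regardless of the mask's origin.
#'
#' @param path file path.
#' @param pixel_size_um micrometres per pixel.
#' @return A `label_mask`.
#' @export
read_label_mask <- function(path, pixel_size_um = 1) {
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lab <- round(t(px) * 65535)
  label_mask(lab, pixel_size_um)
}
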