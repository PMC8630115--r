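#' Extract the full single-nucleus feature vector
#'
#' Concatenates the four feature families (global morphology, boundary,
#' intensity, intensity distribution + GLCM texture) in a fixed, deterministic
#' order. Degenerate crops (mask under `min_pixels`) yield an all-NA vector
#' with the `degenerate` flag set; family-level failures are recorded as NA
#' for that family, never silently dropped.
#'
#' @param n a `nucleus_crop`.
#' @param glcm_distances,glcm_levels passed to [glcm_features()].
#' @param smooth_sigma passed to [boundary_features()].
#' @param min_pixels smallest non-degenerate mask size (default 3).
#' @return Named numeric vector with attribute `degenerate` (logical).
#' @export
extract_all <- function(n, glcm_distances = c(1, 3, 5, 11, 21),
                        glcm_levels = 64L, smooth_sigma = 5,
                        min_pixels = 3L) {
  stopifnot(inherits(n, "nucleus_crop"))
  fam <- function(expr, names_fallback) {
    tryCatch(expr, error = function(e)
      stats::setNames(rep(NA_real_, length(names_fallback)), names_fallback))
  }
  glcm_names <- as.vector(outer(glcm_stat_names(), glcm_distances,
                                function(s, d) paste0("glcm_", s, "_", d)))
  if (sum(n$mask) < min_pixels) {
    nm <- c(names(morphology_features_names()), names(boundary_features_names()),
            names(intensity_features_names()), names(distribution_features_names()),
            glcm_names)
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- c(
    fam(morphology_features(n), names(morphology_features_names())),
    fam(boundary_features(n, smooth_sigma = smooth_sigma),
        names(boundary_features_names())),
    fam(intensity_features(n), names(intensity_features_names())),
    fam(distribution_features(n), names(distribution_features_names())),
    fam(glcm_features(n, distances = glcm_distances, levels = glcm_levels),
        glcm_names))
  attr(out, "degenerate") <- FALSE
  out
}

morphology_features_names <- function()
  stats::setNames(numeric(6), c("area_um2", "perimeter_um", "aspect_ratio",
                                "eccentricity", "min_caliper_um", "max_caliper_um"))
boundary_features_names <- function()
  stats::setNames(numeric(4), c("frac_perimeter_positive_curved",
                                "frac_perimeter_negative_curved",
                                "sd_negative_curvature", "relative_concavity"))
intensity_features_names <- function()
  stats::setNames(numeric(6), c("mean_intensity", "median_intensity",
                                "sd_intensity", "mode_intensity",
                                "intensity_entropy", "hc_ec_ratio"))
distribution_features_names <- function()
  stats::setNames(numeric(9), c("pdi", "com_centroid_separation_um",
                                paste0("hu_moment_", 1:7)))

#' Build a per-nucleus feature table from a list of crops
#'
#' One row per nucleus: provenance metadata (tissue_id, label, stage,
#' centroid, axial orientation, border flag, degenerate flag, qc_pass
#' placeholder) followed by the full feature vector.
#'
#' @param crops list of `nucleus_crop` objects.
#' @param stage stage label applied to every crop (nuclei inherit their
#'   tissue's clinical annotation), or a vector of length(crops).
#' @param ... passed to [extract_all()].
#' @return A data.frame (one row per nucleus).
#' @export
feature_table <- function(crops, stage = NA_character_, ...) {
  stopifnot(length(crops) >= 1L)
  stage <- rep_len(stage, length(crops))
  rows <- lapply(seq_along(crops), function(i) {
    n <- crops[[i]]
    fv <- extract_all(n, ...)
    data.frame(tissue_id = n$tissue_id, label = n$label, stage = stage[i],
               centroid_x = n$centroid_xy[1], centroid_y = n$centroid_xy[2],
               orientation_deg = nucleus_orientation(n$mask),
               touches_border = n$touches_border,
               degenerate = isTRUE(attr(fv, "degenerate")),
               qc_pass = NA, t(fv), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metadata column names of a feature table
#' @param t a feature table.
#' @return Character vector of non-feature column names present in `t`.
#' @export
metadata_columns <- function(t) {
  intersect(c("tissue_id", "label", "stage", "centroid_x", "centroid_y",
              "orientation_deg", "touches_border", "degenerate", "qc_pass",
              "cluster_id", "elongated", "mgs", "health", "region"), names(t))
}

#' Feature column names of a feature table
#' @param t a feature table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(t) setdiff(names(t), metadata_columns(t))

#' Quality-control filter on the feature table
#'
#' Keeps interphase, in-focus nuclei: area between `area_min` and `area_max`
#' square micrometres, median intensity at least `median_min` and intensity
#' standard deviation at least `sd_min` (both on the 0-255 per-nucleus
#' scale). Defaults follow the filter used for tissue nuclei: 2-300 um^2,
#' median >= 10, sd >= 2.
#'
#' @param t feature table with `area_um2`, `median_intensity`,
#'   `sd_intensity` columns.
#' @param area_min,area_max area bounds in um^2.
#' @param median_min minimum median intensity (0-255 scale).
#' @param sd_min minimum intensity standard deviation.
#' @param keep_all if TRUE, return all rows with `qc_pass` set instead of
#'   dropping failures.
#' @return Filtered feature table (or full table with `qc_pass` flags).
#' @export
qc_filter <- function(t, area_min = 2, area_max = 300, median_min = 10,
                      sd_min = 2, keep_all = FALSE) {
  need <- c("area_um2", "median_intensity", "sd_intensity")
  miss <- setdiff(need, names(t))
  if (length(miss))
    stop("qc_filter: missing required columns: ", paste(miss, collapse = ", "))
  pass <- !is.na(t$area_um2) & !is.na(t$median_intensity) & !is.na(t$sd_intensity) &
    t$area_um2 >= area_min & t$area_um2 <= area_max &
    t$median_intensity >= median_min & t$sd_intensity >= sd_min
  t$qc_pass <- pass
  if (keep_all) t else t[pass, , drop = FALSE]
}

#' Write a feature table as tidy CSV with a JSON column dictionary
#'
#' @param t feature table.
#' @param path output CSV path; a `.json` sidecar with the column dictionary
#'   is written next to it.
#' @export
write_feature_table <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, na = "NA")
  dict <- list(metadata = metadata_columns(t), features = feature_columns(t))
  jsonlite::write_json(dict, sub("\\.csv$", ".columns.json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
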