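# Orientationally coupled neighbourhoods, local density features, nuclear
# expansion for biomarker calling, and the tissue-level architecture
# classifier.

#' Axial angle difference
#'
#' Difference between two axial orientations (period 180 degrees), in
#' [0, 90]: ellipse axes have no head or tail, so 10 and 170 degrees are 20
#' degrees apart.
#'
#' @param a,b angles in degrees.
#' @return Difference in degrees in [0, 90].
#' @export
axial_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Keep only elongated nuclei
#'
#' @param t feature table (or any data.frame) with an `aspect_ratio` column.
#' @param ar_min minimum aspect ratio (default 1.5).
#' @return Subset of `t`; empty result triggers a warning.
#' @export
filter_elongated <- function(t, ar_min = 1.5) {
  stopifnot("aspect_ratio" %in% names(t))
  keep <- !is.na(t$aspect_ratio) & t$aspect_ratio >= ar_min
  if (!any(keep)) warning("filter_elongated: no elongated nuclei")
  out <- t[keep, , drop = FALSE]
  out$elongated <- rep(TRUE, nrow(out))
  out
}

# Core DBSCAN on a precomputed distance matrix. Returns labels: -1 noise,
# clusters numbered 1.. in order of discovery.
dbscan_core <- function(D, eps, min_pts) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # includes self
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      new <- frontier[is.na(labels[frontier])]
      labels[new] <- cl
      frontier <- unique(unlist(nb[new[core[new]]]))
      frontier <- frontier[is.na(labels[frontier])]
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Orientation-coupled clustering of elongated nuclei (DBSCAN)
#'
#' DBSCAN on the combined position-orientation metric
#' d^2 = dx^2 + dy^2 + (w * dtheta_ax)^2, where dtheta_ax is the axial
#' angle difference in [0, 90] degrees and w converts degrees to pixels.
#' The default w = eps/90 makes fully orthogonal orientations unreachable
#' even at zero spatial separation; w = 0 recovers position-only clustering.
#'
#' @param x,y centroid coordinates in pixels.
#' @param theta axial orientations in degrees.
#' @param eps neighbourhood radius in pixels (default 400).
#' @param min_pts minimum cluster size (default 15).
#' @param angle_weight w in px/degree (default eps/90).
#' @return Integer cluster labels, -1 = noise.
#' @export
orientation_clusters <- function(x, y, theta, eps = 400, min_pts = 15L,
                                 angle_weight = eps / 90) {
  if (eps <= 0) stop("orientation_clusters: eps must be > 0")
  if (min_pts < 2L) stop("orientation_clusters: min_pts must be >= 2")
  n <- length(x)
  stopifnot(length(y) == n, length(theta) == n)
  if (n == 0L) return(integer(0))
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dth <- outer(theta, theta, axial_angle_diff)
  D <- sqrt(dx^2 + dy^2 + (angle_weight * dth)^2)
  dbscan_core(D, eps, min_pts)
}

#' Summary of orientation clusters in a tissue
#'
#' @param labels cluster labels from [orientation_clusters()] (-1 = noise).
#' @param x,y centroid coordinates (same units as desired outputs).
#' @return List: `n_clusters`, `fraction_clustered`, `cluster_sizes`,
#'   `cluster_areas` (convex hull of member centroids), `centroid_distances`
#'   (pairwise distances between cluster centroids).
#' @export
cluster_summary <- function(labels, x, y) {
  n <- length(labels)
  ids <- sort(unique(labels[labels > 0]))
  frac <- if (n) sum(labels > 0) / n else 0
  areas <- vapply(ids, function(k) {
    pts <- cbind(x[labels == k], y[labels == k])
    if (nrow(pts) < 3L) return(0)
    polygon_area(pts[grDevices::chull(pts), , drop = FALSE])
  }, numeric(1))
  cents <- t(vapply(ids, function(k)
    c(mean(x[labels == k]), mean(y[labels == k])), numeric(2)))
  cd <- if (length(ids) >= 2L) as.matrix(stats::dist(cents)) else
    matrix(0, length(ids), length(ids))
  list(n_clusters = length(ids), fraction_clustered = frac,
       cluster_sizes = vapply(ids, function(k) sum(labels == k), integer(1)),
       cluster_areas = areas, centroid_distances = cd)
}

#' Neighbourhood-scale diagnostics for the clustering parameters
#'
#' Curves of the median distance to, and the median axial-angle difference
#' with, the kth nearest neighbour as functions of k, and the number of
#' DBSCAN clusters over a grid of neighbourhood radii. The elbow report
#' gives the first k whose increment falls below `elbow_tol` times the
#' first increment, and the radius with the most clusters.
#'
#' @param x,y,theta point pattern with axial orientations.
#' @param ks neighbour indices to scan (default 1..30).
#' @param eps_grid radii for the cluster-count scan (default
#'   seq(100, 1000, by = 100)).
#' @param min_pts DBSCAN minimum cluster size (default 15).
#' @param angle_weight_of function mapping eps to w (default eps/90).
#' @param elbow_tol relative increment defining the elbow (default 0.1).
#' @return List: `knn` (data.frame k, median_dist, median_angle_diff),
#'   `eps_scan` (data.frame eps, n_clusters), `k_elbow`, `eps_best`.
#' @export
parameter_scan <- function(x, y, theta, ks = 1:30,
                           eps_grid = seq(100, 1000, by = 100),
                           min_pts = 15L,
                           angle_weight_of = function(eps) eps / 90,
                           elbow_tol = 0.1) {
  n <- length(x)
  if (n < 30L) stop("parameter_scan: need at least 30 points")
  ks <- ks[ks < n]
  D <- as.matrix(stats::dist(cbind(x, y)))
  dth <- outer(theta, theta, axial_angle_diff)
  ordD <- t(apply(D, 1, order))
  med_d <- med_a <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    idx <- cbind(seq_len(n), ordD[, k + 1L])
    med_d[j] <- stats::median(D[idx])
    med_a[j] <- stats::median(dth[idx])
  }
  ncl <- vapply(eps_grid, function(e) {
    lab <- orientation_clusters(x, y, theta, eps = e, min_pts = min_pts,
                                angle_weight = angle_weight_of(e))
    length(unique(lab[lab > 0]))
  }, integer(1))
  inc <- diff(med_d)
  k_elbow <- if (length(inc) > 1L && inc[1] > 0) {
    w <- which(inc < elbow_tol * inc[1])
    if (length(w)) ks[w[1] + 1L] else ks[length(ks)]
  } else ks[length(ks)]
  list(knn = data.frame(k = ks, median_dist = med_d, median_angle_diff = med_a),
       eps_scan = data.frame(eps = eps_grid, n_clusters = ncl),
       k_elbow = k_elbow, eps_best = eps_grid[which.max(ncl)])
}

# ---- Voronoi tessellation by half-plane clipping ------------------------

# Clip a convex polygon (counter-clockwise n x 2 matrix) with the half-plane
# {p : a . p <= b} (Sutherland-Hodgman, single edge).
clip_halfplane <- function(poly, a, b) {
  if (is.null(poly) || nrow(poly) == 0L) return(poly)
  v <- poly[, 1] * a[1] + poly[, 2] * a[2] - b
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- v[i] <= 1e-12; pj_in <- v[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      tt <- v[i] / (v[i] - v[j])
      out <- rbind(out, poly[i, ] + tt * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1, ])
  sum(sqrt(diff(p2[, 1])^2 + diff(p2[, 2])^2))
}

# Eccentricity of a uniform polygon via its area moments (Green's theorem).
polygon_eccentricity <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(NA_real_)
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12 - A * cy^2
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12 - A * cx^2
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24 - A * cx * cy
  co <- matrix(c(iyy, ixy, ixy, ixx), 2) / A
  ev <- eigen(co, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(NA_real_)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Voronoi tessellation clipped to a frame polygon
#'
#' Exact Voronoi cells computed per point by intersecting the frame with
#' the bisector half-planes against every other point. By default the frame
#' is the convex hull of the points dilated outward by the median
#' nearest-neighbour distance; cells that touch the frame boundary are
#' flagged `clipped`.
#'
#' @param x,y point coordinates.
#' @param frame optional convex frame polygon (counter-clockwise n x 2
#'   matrix); NULL = dilated hull of the points.
#' @return data.frame: `voronoi_area`, `voronoi_perimeter`,
#'   `voronoi_eccentricity`, `voronoi_clipped` per point.
#' @export
voronoi_features <- function(x, y, frame = NULL) {
  n <- length(x)
  pts <- cbind(x, y)
  if (is.null(frame)) frame <- default_frame(pts)
  out <- data.frame(voronoi_area = numeric(n), voronoi_perimeter = numeric(n),
                    voronoi_eccentricity = numeric(n),
                    voronoi_clipped = logical(n))
  for (i in seq_len(n)) {
    poly <- frame
    for (j in seq_len(n)) {
      if (j == i) next
      mid <- (pts[i, ] + pts[j, ]) / 2
      a <- pts[j, ] - pts[i, ]
      poly <- clip_halfplane(poly, a, sum(a * mid))
      if (is.null(poly) || nrow(poly) < 3L) break
    }
    if (is.null(poly) || nrow(poly) < 3L) {
      out[i, ] <- list(NA_real_, NA_real_, NA_real_, TRUE)
      next
    }
    # clipped if any vertex lies on the frame boundary
    clipped <- any(apply(poly, 1, function(p) on_frame_boundary(p, frame)))
    out$voronoi_area[i] <- polygon_area(poly)
    out$voronoi_perimeter[i] <- polygon_perimeter(poly)
    out$voronoi_eccentricity[i] <- polygon_eccentricity(poly)
    out$voronoi_clipped[i] <- clipped
  }
  out
}

default_frame <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  med_nn <- stats::median(apply(D, 1, min))
  h <- pts[rev(grDevices::chull(pts)), , drop = FALSE]   # counter-clockwise
  ctr <- colMeans(h)
  # dilate: push each edge outward by med_nn, keep as half-plane intersection
  big <- max(apply(pts, 2, function(v) diff(range(v)))) * 3 + 10 * med_nn
  frame <- rbind(ctr + c(-big, -big), ctr + c(big, -big),
                 ctr + c(big, big), ctr + c(-big, big))
  nh <- nrow(h)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(e[2], -e[1]) / len          # outward normal for CCW polygon
    frame <- clip_halfplane(frame, nrm, sum(nrm * h[i, ]) + med_nn)
  }
  frame
}

on_frame_boundary <- function(p, frame, tol = 1e-6) {
  n <- nrow(frame)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- frame[j, ] - frame[i, ]
    len2 <- sum(e^2)
    if (len2 < 1e-24) next
    tt <- sum((p - frame[i, ]) * e) / len2
    if (tt < -tol || tt > 1 + tol) next
    d <- p - frame[i, ] - tt * e
    if (sqrt(sum(d^2)) < tol) return(TRUE)
  }
  FALSE
}

#' Local density features of a tissue point pattern
#'
#' Per nucleus: the number of neighbours within each radius (self
#' excluded), the Euclidean distance to the kth nearest neighbour for each
#' k, and Voronoi cell area / perimeter / eccentricity with cells clipped
#' to the tissue frame.
#'
#' @param x,y centroid coordinates in micrometres.
#' @param radii neighbour-count radii in micrometres
#'   (default c(5, 15, 25, 40, 50)).
#' @param ks nearest-neighbour indices (default c(1, 3, 5, 10, 20)).
#' @param frame optional convex frame polygon for the Voronoi clipping.
#' @return data.frame with columns `n_neighbors_r<r>`, `knn_dist_k<k>` and
#'   the [voronoi_features()] block.
#' @export
density_features <- function(x, y, radii = c(5, 15, 25, 40, 50),
                             ks = c(1, 3, 5, 10, 20), frame = NULL) {
  n <- length(x)
  if (n < max(ks) + 1L)
    stop("density_features: need at least max(ks) + 1 nuclei")
  D <- as.matrix(stats::dist(cbind(x, y)))
  diag(D) <- Inf
  out <- data.frame(row.names = seq_len(n))
  for (r in radii)
    out[[paste0("n_neighbors_r", r)]] <- apply(D, 1, function(d) sum(d <= r))
  sorted <- t(apply(D, 1, sort))
  for (k in ks)
    out[[paste0("knn_dist_k", k)]] <- sorted[, k]
  cbind(out, voronoi_features(x, y, frame = frame))
}

# ---- nuclear expansion and biomarker calling ----------------------------

#' Expand nuclei into cell regions
#'
#' Each background pixel within `max_um` micrometres of a nucleus is
#' assigned to its nearest nucleus (Euclidean distance to the nucleus
#' boundary; ties go to the lower label). Expansion stops where two
#' expansions meet, so cells never overlap and each cell is a superset of
#' its nucleus.
#'
#' @param mask a `label_mask`.
#' @param max_um expansion distance in micrometres (default 5).
#' @return A `label_mask` of cell regions with the same labels.
#' @export
expand_nuclei_to_cells <- function(mask, max_um = 5) {
  stopifnot(inherits(mask, "label_mask"))
  labs <- mask$labels
  K <- max(labs)
  if (K == 0L) return(mask)
  max_px <- max_um / mask$pixel_size_um
  best_d <- matrix(Inf, nrow(labs), ncol(labs))
  best_l <- matrix(0L, nrow(labs), ncol(labs))
  for (k in seq_len(K)) {                  # ascending => ties to lower label
    fg <- labs == k
    if (!any(fg)) next
    dm <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(1 - fg)))))
    upd <- dm < best_d - 1e-9
    best_d[upd] <- dm[upd]
    best_l[upd] <- k
  }
  cell <- ifelse(best_d <= max_px, best_l, 0L)
  cell[labs > 0L] <- labs[labs > 0L]
  label_mask(cell, mask$pixel_size_um, relabel = FALSE)
}

#' Flag nuclei inside biomarker-positive (cancer) regions
#'
#' Computes the mean biomarker intensity over each expanded cell region and
#' flags cells whose mean exceeds the threshold. Without an explicit
#' threshold, a global Otsu split of the per-cell means is used.
#'
#' @param cells cell-region `label_mask` (see [expand_nuclei_to_cells()]).
#' @param marker biomarker `gray_image` aligned to `cells`.
#' @param threshold numeric threshold on the cell mean, or NULL for Otsu.
#' @return data.frame: `label`, `marker_mean`, `in_region` (logical),
#'   `threshold` (the value used).
#' @export
biomarker_region_call <- function(cells, marker, threshold = NULL) {
  stopifnot(inherits(cells, "label_mask"), inherits(marker, "gray_image"))
  if (!identical(dim(cells$labels), dim(marker$pixels)))
    stop("biomarker_region_call: marker not aligned to cells")
  K <- max(cells$labels)
  labs <- cells$labels
  means <- vapply(seq_len(K), function(k) {
    px <- marker$pixels[labs == k]
    if (!length(px)) NA_real_ else mean(px)
  }, numeric(1))
  if (is.null(threshold)) {
    threshold <- otsu_threshold_values(means[is.finite(means)])
    if (is.na(threshold)) threshold <- Inf    # constant means: nothing called
  }
  data.frame(label = seq_len(K), marker_mean = means,
             in_region = is.finite(means) & means > threshold,
             threshold = threshold)
}

# ---- tissue-level architecture classifier -------------------------------

#' Classify tissues from architecture-feature distributions
#'
#' Summarizes each tissue by the mean, standard deviation, skewness and
#' kurtosis of every architecture feature (optionally including the MGS
#' column), then fits tissue-stratified LDA on standardized summaries and
#' reports held-out balanced accuracy.
#'
#' @param t per-nucleus data.frame with `tissue_id`, `stage` and the
#'   architecture feature columns.
#' @param feature_cols architecture feature column names.
#' @param include_mgs also summarize the `mgs` column (default FALSE).
#' @param frac_tissues training fraction of tissues per class (default 0.8).
#' @param seed RNG seed for the tissue split.
#' @return List: `balanced_accuracy`, `predictions` (per held-out tissue),
#'   `summary_table` (per-tissue feature summaries).
#' @export
tissue_architecture_classifier <- function(t, feature_cols,
                                           include_mgs = FALSE,
                                           frac_tissues = 0.8, seed = 1L) {
  cols <- feature_cols
  if (include_mgs) {
    if (!"mgs" %in% names(t))
      stop("tissue_architecture_classifier: no mgs column")
    cols <- c(cols, "mgs")
  }
  summ <- tissue_summary_stats(t, cols)
  classes <- sort(unique(summ$stage))
  if (any(vapply(classes, function(cl) sum(summ$stage == cl), integer(1)) < 2L))
    stop("tissue_architecture_classifier: need >= 2 tissues per class")
  set.seed(seed)
  train_t <- unlist(lapply(classes, function(cl) {
    tis <- summ$tissue_id[summ$stage == cl]
    ntr <- min(max(1L, round(frac_tissues * length(tis))), length(tis) - 1L)
    sample(tis, ntr)
  }))
  tr <- summ[summ$tissue_id %in% train_t, , drop = FALSE]
  te <- summ[!summ$tissue_id %in% train_t, , drop = FALSE]
  fc <- setdiff(names(summ), c("tissue_id", "stage"))
  Xtr <- as.matrix(tr[, fc, drop = FALSE])
  keep <- apply(Xtr, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  Xtr <- Xtr[, keep, drop = FALSE]
  mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  # project onto leading PCs when summaries outnumber training tissues
  m <- min(ncol(Ztr), nrow(Ztr) - length(classes))
  rot <- stats::prcomp(Ztr, center = FALSE)$rotation[, seq_len(m), drop = FALSE]
  fit <- fit_lda_safe(Ztr %*% rot, factor(tr$stage))
  Xte <- as.matrix(te[, fc, drop = FALSE])[, keep, drop = FALSE]
  Xte[!is.finite(Xte)] <- 0
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  pred <- as.character(stats::predict(fit, Zte %*% rot)$class)
  list(balanced_accuracy = balanced_accuracy(te$stage, pred),
       predictions = data.frame(tissue_id = te$tissue_id, stage = te$stage,
                                pred = pred, stringsAsFactors = FALSE),
       summary_table = summ)
}

# Per-tissue distribution summaries (mean, sd, skewness, kurtosis) of the
# given columns.
tissue_summary_stats <- function(t, cols) {
  tis <- sort(unique(t$tissue_id))
  rows <- lapply(tis, function(ti) {
    sub <- t[t$tissue_id == ti, , drop = FALSE]
    stats_v <- unlist(lapply(cols, function(cl) {
      v <- sub[[cl]]
      v <- v[is.finite(v)]
      if (length(v) < 3L || stats::sd(v) == 0)
        out <- c(mean = if (length(v)) mean(v) else NA_real_, sd = 0,
                 skewness = 0, kurtosis = 0)
      else
        out <- c(mean = mean(v), sd = stats::sd(v),
                 skewness = e1071::skewness(v), kurtosis = e1071::kurtosis(v))
      stats::setNames(out, paste0(cl, "_", names(out)))
    }))
    cbind(data.frame(tissue_id = ti, stage = sub$stage[1],
                     stringsAsFactors = FALSE),
          as.data.frame(t(stats_v)))
  })
  do.call(rbind, rows)
}
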