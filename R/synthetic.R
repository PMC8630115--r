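# Synthetic DNA-stained tissue emulation with full ground truth: perturbed
# elliptical nuclei with heterochromatin-like texture foci, tissue fields
# with planted orientation-aligned neighbourhoods, and feature-level
# cohorts with a planted health axis.

#' Specification of one synthetic nucleus
#'
#' @param center_xy centre in image pixel coordinates (x = column, 0-based).
#' @param a,b semi-axes in pixels (a >= b > 0).
#' @param theta_deg axial orientation of the major axis, degrees CCW from +x.
#' @param irregularity amplitude of the low-order Fourier radial boundary
#'   perturbation, as a fraction of the local radius (< b/a to avoid
#'   self-intersection; 0 = smooth ellipse).
#' @param n_foci number of heterochromatin-like texture foci.
#' @param focus_contrast peak amplitude of each focus above background.
#' @param focus_sd Gaussian radius of each focus in pixels (NULL = b/5).
#' @param background interior background intensity in (0, 1].
#' @param noise_sd Gaussian noise scale; per-pixel sd is
#'   noise_sd * sqrt(intensity / background) (Poisson-like).
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(center_xy = c(0, 0), a = 12, b = 8, theta_deg = 0,
                         irregularity = 0, n_foci = 6L, focus_contrast = 0.3,
                         background = 0.5, noise_sd = 0.02, focus_sd = NULL) {
  stopifnot(a >= b, b > 0, background > 0, irregularity >= 0)
  structure(list(center_xy = as.numeric(center_xy), a = a, b = b,
                 theta_deg = theta_deg, irregularity = irregularity,
                 n_foci = as.integer(n_foci), focus_contrast = focus_contrast,
                 background = background, noise_sd = noise_sd,
                 focus_sd = focus_sd),
            class = "nucleus_spec")
}

# Radial boundary function r(phi) of a spec (phi absolute, degrees CCW from
# +x), with seeded Fourier perturbation orders 3-8.
spec_radius_fun <- function(spec, seed) {
  set.seed(seed)
  orders <- 3:8
  amps <- if (spec$irregularity > 0) {
    a0 <- abs(stats::rnorm(length(orders)))
    a0 / sum(a0) * spec$irregularity
  } else rep(0, length(orders))
  phases <- stats::runif(length(orders), 0, 2 * pi)
  th0 <- spec$theta_deg * pi / 180
  function(phi) {
    psi <- phi - th0
    re <- spec$a * spec$b /
      sqrt((spec$b * cos(psi))^2 + (spec$a * sin(psi))^2)
    pert <- rep(1, length(phi))
    for (i in seq_along(orders))
      pert <- pert + amps[i] * cos(orders[i] * phi + phases[i])
    re * pert
  }
}

# Rasterize spec into local matrices (pixels, mask) of side 2*rad+1, and
# return with the local centre offset. Used by render_nucleus/render_tissue.
rasterize_spec <- function(spec, seed) {
  rfun <- spec_radius_fun(spec, seed)
  rmax <- ceiling(spec$a * (1 + spec$irregularity)) + 2L
  side <- 2L * rmax + 1L
  dx <- matrix(rep(-rmax:rmax, each = side), side, side)   # x varies by col
  dy <- matrix(rep(rmax:-rmax, side), side, side)          # y up, rows down
  phi <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  mask <- rho <= rfun(phi)
  set.seed(seed + 1L)
  img <- matrix(0, side, side)
  img[mask] <- spec$background
  if (spec$n_foci > 0L && spec$focus_contrast > 0) {
    inpts <- which(mask & rho <= 0.7 * spec$b)
    if (length(inpts)) {
      pick <- inpts[sample.int(length(inpts), min(spec$n_foci, length(inpts)))]
      fsd <- if (!is.null(spec$focus_sd)) spec$focus_sd else max(1.2, spec$b / 5)
      for (p in pick) {
        fr <- ((p - 1L) %% side) + 1L
        fc <- ((p - 1L) %/% side) + 1L
        g <- exp(-((dx - dx[fr, fc])^2 + (dy - dy[fr, fc])^2) / (2 * fsd^2))
        img <- img + spec$focus_contrast * g
      }
    }
  }
  if (spec$noise_sd > 0) {
    sdpx <- spec$noise_sd * sqrt(pmax(img, 0) / spec$background)
    img <- img + stats::rnorm(length(img), sd = 1) * sdpx
  }
  img[!mask] <- 0
  img <- pmin(pmax(img, 0), 1)
  list(pixels = img, mask = mask, rmax = rmax)
}

#' Render one synthetic nucleus
#'
#' Rasterizes the perturbed ellipse of a [nucleus_spec()]: interior =
#' background + Gaussian heterochromatin-like foci + Poisson-like noise.
#' Bit-identical for identical (spec, seed).
#'
#' @param spec a `nucleus_spec`.
#' @param seed RNG seed.
#' @param pixel_size_um micrometres per pixel (default 1).
#' @return List: `crop` (a `nucleus_crop`), `truth` (planted parameters:
#'   aspect_ratio, theta_deg, irregularity, focus_contrast, ...).
#' @export
render_nucleus <- function(spec, seed = 1L, pixel_size_um = 1) {
  stopifnot(inherits(spec, "nucleus_spec"))
  ras <- rasterize_spec(spec, seed)
  crop <- nucleus_crop(gray_image(ras$pixels, pixel_size_um), ras$mask,
                       centroid_xy = spec$center_xy, tissue_id = "synthetic",
                       label = 1L)
  truth <- data.frame(aspect_ratio = spec$a / spec$b,
                      theta_deg = spec$theta_deg %% 180,
                      area_px = sum(ras$mask),
                      irregularity = spec$irregularity,
                      n_foci = spec$n_foci,
                      focus_contrast = spec$focus_contrast,
                      background = spec$background,
                      noise_sd = spec$noise_sd, seed = seed)
  list(crop = crop, truth = truth)
}

#' Chromatin texture-contrast knob
#'
#' Maps a scalar contrast knob in (0, 1] to heterochromatin-focus
#' parameters: higher contrast means more and sharper foci at fixed
#' amplitude. Because downstream intensity features are computed on a
#' per-nucleus rescaled intensity scale, a pure amplitude knob would
#' largely cancel; granularity is what moves the co-occurrence statistics,
#' raising GLCM contrast and lowering homogeneity as the knob grows.
#'
#' @param contrast knob value in (0, 1].
#' @param b nucleus minor semi-axis in pixels (sets the focus width scale).
#' @return List: `n_foci`, `focus_contrast`, `focus_sd`, spliceable into
#'   [nucleus_spec()].
#' @export
chromatin_texture_knobs <- function(contrast, b = 8) {
  stopifnot(contrast > 0, contrast <= 1)
  list(n_foci = as.integer(round(3 + 17 * contrast)),
       focus_contrast = 0.4,
       focus_sd = b / (2 + 4 * contrast))
}

#' Random non-overlapping tissue layout
#'
#' Uniformly random nucleus centres with rejection sampling to keep bounding
#' circles from overlapping, random axial orientations and aspect ratios.
#'
#' @param n number of nuclei.
#' @param width,height field size in pixels.
#' @param a,b mean semi-axes (px); per-nucleus values jittered by 10%.
#' @param margin minimal gap between bounding circles, px (default 2).
#' @param max_tries placement attempts per nucleus before erroring.
#' @param seed RNG seed.
#' @param ... further arguments stored on every [nucleus_spec()].
#' @return data.frame of per-nucleus spec parameters with planted truth
#'   columns (`cluster_id` = -1: unplanted).
#' @export
tissue_layout_random <- function(n, width = 512L, height = 512L, a = 10, b = 7,
                                 margin = 2, max_tries = 2000L, seed = 1L, ...) {
  set.seed(seed)
  extra <- list(...)
  rows <- list()
  placed <- matrix(numeric(0), 0, 3)   # x, y, radius
  for (i in seq_len(n)) {
    ai <- a * stats::runif(1, 0.9, 1.1)
    bi <- min(b * stats::runif(1, 0.9, 1.1), ai)
    irr <- if (!is.null(extra$irregularity)) extra$irregularity else 0
    rad <- ai * (1 + irr) + 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, rad, width - rad)
      cy <- stats::runif(1, rad, height - rad)
      if (!nrow(placed) ||
          all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
              (placed[, 3] + rad + margin)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("tissue_layout_random: could not place nucleus ", i,
                  " after ", max_tries, " tries (field too dense)")
    placed <- rbind(placed, c(cx, cy, rad))
    rows[[i]] <- data.frame(x = cx, y = cy, a = ai, b = bi,
                            theta_deg = stats::runif(1, 0, 180),
                            cluster_id = -1L)
  }
  out <- do.call(rbind, rows)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Tissue layout with planted orientation-aligned neighbourhoods
#'
#' Each planted cluster is a group of elongated, co-oriented nuclei around a
#' centre; optional sparse random-orientation noise nuclei fill the rest of
#' the field.
#'
#' @param clusters data.frame with columns `cx`, `cy`, `n`, `theta_deg`,
#'   `spread` (cluster radius, px).
#' @param n_noise number of noise nuclei.
#' @param width,height field size, px.
#' @param a,b semi-axes of the elongated nuclei (default 14 x 6).
#' @param theta_jitter sd of the orientation jitter within a cluster
#'   (degrees, default 5).
#' @param margin,max_tries,seed as in [tissue_layout_random()].
#' @return data.frame of spec parameters; `cluster_id` gives the planted
#'   cluster (1-based) or -1 for noise nuclei.
#' @export
tissue_layout_clusters <- function(clusters, n_noise = 0L, width = 2048L,
                                   height = 2048L, a = 14, b = 6,
                                   theta_jitter = 5, margin = 2,
                                   max_tries = 2000L, seed = 1L) {
  set.seed(seed)
  placed <- matrix(numeric(0), 0, 3)
  rows <- list()
  place_one <- function(gen_xy, rad) {
    for (try in seq_len(max_tries)) {
      p <- gen_xy()
      if (p[1] < rad || p[1] > width - rad || p[2] < rad || p[2] > height - rad)
        next
      if (!nrow(placed) ||
          all((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2 >
              (placed[, 3] + rad + margin)^2))
        return(p)
    }
    stop("tissue_layout_clusters: placement failed (field too dense)")
  }
  for (ci in seq_len(nrow(clusters))) {
    cl <- clusters[ci, ]
    for (i in seq_len(cl$n)) {
      rad <- a + 2
      p <- place_one(function()
        c(cl$cx + stats::rnorm(1, sd = cl$spread / 2),
          cl$cy + stats::rnorm(1, sd = cl$spread / 2)), rad)
      placed <- rbind(placed, c(p, rad))
      rows[[length(rows) + 1L]] <- data.frame(
        x = p[1], y = p[2], a = a, b = b,
        theta_deg = (cl$theta_deg + stats::rnorm(1, sd = theta_jitter)) %% 180,
        cluster_id = ci)
    }
  }
  for (i in seq_len(n_noise)) {
    rad <- a + 2
    p <- place_one(function()
      c(stats::runif(1, rad, width - rad), stats::runif(1, rad, height - rad)),
      rad)
    placed <- rbind(placed, c(p, rad))
    rows[[length(rows) + 1L]] <- data.frame(
      x = p[1], y = p[2], a = a, b = b,
      theta_deg = stats::runif(1, 0, 180), cluster_id = -1L)
  }
  do.call(rbind, rows)
}

#' Render a synthetic tissue field
#'
#' Composites the nuclei of a layout into one grayscale image plus the
#' ground-truth instance label mask and per-nucleus truth table.
#'
#' @param layout data.frame from [tissue_layout_random()] /
#'   [tissue_layout_clusters()] (columns x, y, a, b, theta_deg, cluster_id,
#'   optional irregularity, n_foci, focus_contrast, background, noise_sd,
#'   stage).
#' @param width,height field size in pixels.
#' @param pixel_size_um micrometres per pixel (default 1).
#' @param seed RNG seed; nucleus i uses seed + i.
#' @param tissue_id provenance id.
#' @return List: `image` (`gray_image`), `mask` (truth `label_mask`),
#'   `truth` (data.frame, one row per nucleus).
#' @export
render_tissue <- function(layout, width = 512L, height = 512L,
                          pixel_size_um = 1, seed = 1L,
                          tissue_id = "synthetic") {
  img <- matrix(0, height, width)
  labs <- matrix(0L, height, width)
  truth <- list()
  defaults <- nucleus_spec()
  getcol <- function(i, nm) if (nm %in% names(layout)) layout[[nm]][i]
                            else defaults[[nm]]
  for (i in seq_len(nrow(layout))) {
    spec <- nucleus_spec(center_xy = c(layout$x[i], layout$y[i]),
                         a = layout$a[i], b = layout$b[i],
                         theta_deg = layout$theta_deg[i],
                         irregularity = getcol(i, "irregularity"),
                         n_foci = getcol(i, "n_foci"),
                         focus_contrast = getcol(i, "focus_contrast"),
                         background = getcol(i, "background"),
                         noise_sd = getcol(i, "noise_sd"))
    ras <- rasterize_spec(spec, seed + i)
    side <- 2L * ras$rmax + 1L
    r0 <- round(layout$y[i]) - ras$rmax    # top row (y = row index here)
    c0 <- round(layout$x[i]) - ras$rmax
    rr <- (r0:(r0 + side - 1L))
    cc <- (c0:(c0 + side - 1L))
    keep_r <- rr >= 1L & rr <= height
    keep_c <- cc >= 1L & cc <= width
    sub_m <- ras$mask[keep_r, keep_c, drop = FALSE]
    sub_p <- ras$pixels[keep_r, keep_c, drop = FALSE]
    tgt_r <- rr[keep_r]; tgt_c <- cc[keep_c]
    blk_i <- img[tgt_r, tgt_c, drop = FALSE]
    blk_l <- labs[tgt_r, tgt_c, drop = FALSE]
    blk_i[sub_m] <- pmax(blk_i[sub_m], sub_p[sub_m])
    blk_l[sub_m] <- i
    img[tgt_r, tgt_c] <- blk_i
    labs[tgt_r, tgt_c] <- blk_l
    truth[[i]] <- data.frame(
      label = i, x = layout$x[i], y = layout$y[i],
      theta_deg = layout$theta_deg[i] %% 180,
      aspect_ratio = layout$a[i] / layout$b[i],
      cluster_id = if ("cluster_id" %in% names(layout)) layout$cluster_id[i] else -1L,
      stage = if ("stage" %in% names(layout)) layout$stage[i] else NA_character_)
  }
  list(image = gray_image(img, pixel_size_um),
       mask = label_mask(labs, pixel_size_um, relabel = FALSE),
       truth = do.call(rbind, truth))
}

# Map a malignancy level m in [0, 1] to generator texture/shape knobs along
# the cancer axis: malignant nuclei have more irregular (concave)
# boundaries, dimmer chromatin, and smoother texture (fewer/weaker foci =
# lower GLCM entropy/dissimilarity, higher homogeneity).
malignancy_knobs <- function(m) {
  list(irregularity = 0.04 + 0.22 * m,
       background = 0.72 - 0.35 * m,
       focus_contrast = 0.45 - 0.33 * m,
       n_foci = 7L,
       noise_sd = 0.02)
}

#' Generate an image-based synthetic cohort with ground truth
#'
#' Renders `n_tissues` tissue fields per stage; each stage's nuclei carry
#' generator knobs shifted along the cancer axis according to the stage's
#' malignancy level. Images, truth masks, truth tables and a JSON manifest
#' recording every seed and parameter are written to `out_dir`; the
#' manifest suffices to regenerate the cohort.
#'
#' @param stages character vector of stage names.
#' @param malignancy numeric per-stage malignancy in [0, 1], aligned with
#'   `stages`.
#' @param n_tissues tissues per stage (default 4).
#' @param n_nuclei nuclei per tissue (default 60).
#' @param width,height field size (default 512).
#' @param pixel_size_um micrometres per pixel (default 1).
#' @param seed master seed; every tissue's seed is derived from it and
#'   recorded in the manifest.
#' @param out_dir output directory, or NULL to return everything in memory.
#' @return Invisibly (or visibly when `out_dir` is NULL): list of tissues,
#'   each with `image`, `mask`, `truth`, `tissue_id`, `stage`, plus the
#'   `manifest`.
#' @export
generate_cohort <- function(stages = c("normal", "invasive"),
                            malignancy = seq(0, 1, length.out = length(stages)),
                            n_tissues = 4L, n_nuclei = 60L,
                            width = 512L, height = 512L, pixel_size_um = 1,
                            seed = 1L, out_dir = NULL) {
  stopifnot(length(stages) >= 2L, length(malignancy) == length(stages))
  tissues <- list()
  manifest <- list(seed = seed, stages = as.list(stats::setNames(malignancy, stages)),
                   n_tissues = n_tissues, n_nuclei = n_nuclei,
                   width = width, height = height,
                   pixel_size_um = pixel_size_um, tissues = list())
  idx <- 0L
  for (si in seq_along(stages)) {
    kn <- malignancy_knobs(malignancy[si])
    for (ti in seq_len(n_tissues)) {
      idx <- idx + 1L
      tseed <- seed + 1000L * idx
      tid <- sprintf("%s_t%02d", stages[si], ti)
      layout <- tissue_layout_random(n_nuclei, width = width, height = height,
                                     seed = tseed,
                                     irregularity = kn$irregularity,
                                     background = kn$background,
                                     focus_contrast = kn$focus_contrast,
                                     n_foci = kn$n_foci, noise_sd = kn$noise_sd)
      layout$stage <- stages[si]
      rt <- render_tissue(layout, width = width, height = height,
                          pixel_size_um = pixel_size_um, seed = tseed + 1L,
                          tissue_id = tid)
      rt$tissue_id <- tid
      rt$stage <- stages[si]
      tissues[[tid]] <- rt
      manifest$tissues[[tid]] <- list(stage = stages[si], seed = tseed,
                                      malignancy = malignancy[si])
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        EBImage::writeImage(EBImage::Image(t(rt$image$pixels)),
                            file.path(out_dir, paste0(tid, ".tif")),
                            type = "tiff", bits.per.sample = 16L)
        write_label_mask(rt$mask, file.path(out_dir, paste0(tid, "_mask.tif")))
        utils::write.csv(rt$truth, file.path(out_dir, paste0(tid, "_truth.csv")),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- list(tissues = tissues, manifest = manifest)
  if (is.null(out_dir)) out else invisible(out)
}

#' Feature-level synthetic cohort with a planted health axis
#'
#' Draws per-nucleus feature vectors directly (no images): six named
#' cancer-axis features are shifted along the documented directions
#' (cancer-like nuclei: higher relative concavity and sd of negative
#' curvature, lower median intensity, lower GLCM entropy and dissimilarity,
#' higher GLCM homogeneity) in proportion to a per-nucleus severity, plus
#' independent noise features. The planted health axis is minus the
#' severity.
#'
#' @param stages stage names.
#' @param severities per-stage mean severity (0 = healthy), aligned.
#' @param n_per_stage nuclei per stage.
#' @param n_tissues_per_stage tissues per stage (nuclei split evenly).
#' @param delta effect size: feature shift per unit severity, in units of
#'   the within-stage feature sd (default 4).
#' @param severity_jitter within-stage sd of the per-nucleus severity
#'   (default 0.15; 0 = binary populations).
#' @param n_noise_features uninformative N(0,1) features (default 10).
#' @param seed RNG seed.
#' @return Feature table with metadata columns plus a `health` column (the
#'   planted axis; not a feature column).
#' @export
synthetic_feature_cohort <- function(stages = c("normal", "cancer"),
                                     severities = seq(0, 1, length.out = length(stages)),
                                     n_per_stage = 500L,
                                     n_tissues_per_stage = 5L,
                                     delta = 4, severity_jitter = 0.15,
                                     n_noise_features = 10L, seed = 1L) {
  set.seed(seed)
  axis_features <- c(relative_concavity = 1, sd_negative_curvature = 1,
                     median_intensity = -1, glcm_entropy_3 = -1,
                     glcm_dissimilarity_3 = -1, glcm_homogeneity_3 = 1)
  rows <- list()
  for (si in seq_along(stages)) {
    n <- n_per_stage
    sev <- severities[si] + stats::rnorm(n, sd = severity_jitter)
    X <- matrix(stats::rnorm(n * length(axis_features)), n)
    X <- X + outer(sev, unname(axis_features) * delta)
    colnames(X) <- names(axis_features)
    Nz <- matrix(stats::rnorm(n * n_noise_features), n)
    colnames(Nz) <- paste0("noise_feature_", seq_len(n_noise_features))
    tid <- sprintf("%s_t%02d", stages[si],
                   rep_len(seq_len(n_tissues_per_stage), n))
    rows[[si]] <- data.frame(tissue_id = sort(tid), stage = stages[si],
                             health = -sev, X, Nz, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noisy one-dimensional curve embedded in d dimensions
#'
#' Points along a smooth curve parameterized by arc length, with isotropic
#' Gaussian noise; the latent parameter is returned for trajectory
#' recovery tests.
#'
#' @param n number of points (default 200).
#' @param d ambient dimension (default 5).
#' @param noise_sd isotropic noise sd (default 0.05).
#' @param seed RNG seed.
#' @return List: `X` (n x d matrix), `latent` (arc-length parameter).
#' @export
synthetic_curve_points <- function(n = 200L, d = 5L, noise_sd = 0.05,
                                   seed = 1L) {
  set.seed(seed)
  s <- sort(stats::runif(n))
  X <- cbind(cos(1.5 * pi * s), sin(1.5 * pi * s), s, s^2, sqrt(s + 0.1))
  X <- X[, seq_len(min(d, ncol(X))), drop = FALSE]
  if (d > ncol(X)) X <- cbind(X, matrix(0, n, d - ncol(X)))
  X <- X + matrix(stats::rnorm(n * d, sd = noise_sd), n)
  list(X = X, latent = s)
}

#' Three-armed star point cloud
#'
#' Three line-segment arms radiating from the origin at 120-degree spacing,
#' with Gaussian noise; arm labels are returned for branch-recovery tests.
#'
#' @param n_per_arm points per arm (default 70).
#' @param arm_length arm length (default 4).
#' @param noise_sd noise sd (default 0.08).
#' @param seed RNG seed.
#' @return List: `X` (n x 2 matrix), `arm` (integer labels 1..3).
#' @export
synthetic_star_points <- function(n_per_arm = 70L, arm_length = 4,
                                  noise_sd = 0.08, seed = 1L) {
  set.seed(seed)
  ang <- c(90, 210, 330) * pi / 180
  rows <- lapply(1:3, function(k) {
    r <- stats::runif(n_per_arm, 0.05, arm_length)
    cbind(r * cos(ang[k]), r * sin(ang[k])) +
      matrix(stats::rnorm(2 * n_per_arm, sd = noise_sd), n_per_arm)
  })
  list(X = do.call(rbind, rows), arm = rep(1:3, each = n_per_arm))
}

#' Per-nucleus architecture-feature cohort with planted stage effects
#'
#' Draws per-nucleus tissue-architecture observations directly from
#' per-stage distributions: the probability that a nucleus sits in an
#' orientation-coupled cluster, a log-normal Voronoi area whose scale
#' shrinks as crowding grows, matching neighbour counts and
#' nearest-neighbour distances, plus a per-nucleus MGS drawn around the
#' stage mean. Used to test the tissue-level classifier: the architecture
#' effect sizes overlap between stages while the MGS effect is strong, so
#' adding MGS summaries should help.
#'
#' @param stages stage names.
#' @param frac_clustered per-stage probability of a nucleus being
#'   orientation-clustered.
#' @param mgs_mean per-stage mean MGS.
#' @param density per-stage relative crowding (scales neighbour counts up
#'   and Voronoi areas / NN distances down).
#' @param n_tissues tissues per stage.
#' @param n_nuclei nuclei per tissue.
#' @param seed RNG seed.
#' @return data.frame: tissue_id, stage, clustered, voronoi_area,
#'   n_neighbors_r40, knn_dist_k1, mgs.
#' @export
synthetic_architecture_cohort <- function(stages = c("normal", "dcis"),
                                          frac_clustered = c(0.15, 0.55),
                                          mgs_mean = c(2, -2),
                                          density = c(1, 1.3),
                                          n_tissues = 10L, n_nuclei = 80L,
                                          seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (si in seq_along(stages)) {
    for (ti in seq_len(n_tissues)) {
      # tissue-level wobble keeps stages overlapping in architecture
      fc <- stats::plogis(stats::qlogis(frac_clustered[si]) + stats::rnorm(1, sd = 0.5))
      dens <- density[si] * exp(stats::rnorm(1, sd = 0.15))
      n <- n_nuclei
      rows[[length(rows) + 1L]] <- data.frame(
        tissue_id = sprintf("%s_t%02d", stages[si], ti),
        stage = stages[si],
        clustered = as.numeric(stats::runif(n) < fc),
        voronoi_area = stats::rlnorm(n, log(120 / dens), 0.4),
        n_neighbors_r40 = stats::rpois(n, 6 * dens),
        knn_dist_k1 = stats::rlnorm(n, log(12 / sqrt(dens)), 0.3),
        mgs = stats::rnorm(n, mgs_mean[si], 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planted DCIS-like tissue point pattern
#'
#' A dense duct core of randomly oriented, low-MGS nuclei surrounded by a
#' ring of tangentially co-oriented, high-MGS stromal nuclei, the
#' configuration in which orientationally clustered nuclei are the
#' healthier ones.
#'
#' @param n_core,n_ring nuclei in the core / ring (defaults 40 / 160: the
#'   ring is dense along its circumference, where orientation varies
#'   slowly, while the randomly oriented core stays below the DBSCAN
#'   density threshold in the combined position-orientation metric).
#' @param ring_radius ring radius in pixels (default 600).
#' @param mgs_core,mgs_ring mean MGS of core / ring nuclei (defaults -2, 2).
#' @param seed RNG seed.
#' @return data.frame: x, y, theta_deg, aspect_ratio, mgs, region
#'   ("core"/"ring").
#' @export
synthetic_dcis_layout <- function(n_core = 40L, n_ring = 160L,
                                  ring_radius = 600, mgs_core = -2,
                                  mgs_ring = 2, seed = 1L) {
  set.seed(seed)
  r_core <- sqrt(stats::runif(n_core)) * ring_radius * 0.6
  a_core <- stats::runif(n_core, 0, 2 * pi)
  core <- data.frame(x = r_core * cos(a_core), y = r_core * sin(a_core),
                     theta_deg = stats::runif(n_core, 0, 180),
                     aspect_ratio = stats::runif(n_core, 1.5, 2.5),
                     mgs = stats::rnorm(n_core, mgs_core, 0.5),
                     region = "core", stringsAsFactors = FALSE)
  a_ring <- stats::runif(n_ring, 0, 2 * pi)
  r_ring <- ring_radius * stats::runif(n_ring, 0.95, 1.05)
  # tangential orientation: perpendicular to the radius
  th <- ((a_ring * 180 / pi) + 90) %% 180 + stats::rnorm(n_ring, sd = 4)
  ring <- data.frame(x = r_ring * cos(a_ring), y = r_ring * sin(a_ring),
                     theta_deg = th %% 180,
                     aspect_ratio = stats::runif(n_ring, 1.8, 3),
                     mgs = stats::rnorm(n_ring, mgs_ring, 0.5),
                     region = "ring", stringsAsFactors = FALSE)
  rbind(core, ring)
}
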