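test_that("axial angle difference respects the 180-degree period", {
  expect_equal(axial_angle_diff(10, 170), 20)
  expect_equal(axial_angle_diff(0, 90), 90)
  expect_equal(axial_angle_diff(179, 1), 2)
  expect_equal(axial_angle_diff(45, 225), 0)
})

test_that("elongation filter keeps aspect ratios at or above the cut", {
  t <- data.frame(aspect_ratio = c(1.0, 1.4, 1.6, 2.2))
  expect_equal(nrow(filter_elongated(t, 1.5)), 2L)
  expect_equal(nrow(filter_elongated(t, 1.0)), 4L)
  expect_warning(out <- filter_elongated(t, 5), "no elongated")
  expect_equal(nrow(out), 0L)
})

test_that("DBSCAN equals the reachability-closure oracle on random patterns", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(40:100, 1)
    x <- runif(n, 0, 1500); y <- runif(n, 0, 1500); th <- runif(n, 0, 180)
    eps <- sample(c(150, 250, 400), 1)
    mp <- sample(3:8, 1)
    w <- eps / 90
    got <- orientation_clusters(x, y, th, eps, mp, w)
    D <- orientation_distance_matrix(x, y, th, w)
    want <- dbscan_oracle(D, eps, mp)
    expect_identical(got > 0, want > 0)
    expect_equal(ari(got[got > 0], want[got > 0]), 1)
  }
})

test_that("planted orientation clusters are recovered from sparse noise", {
  lay <- planted_orientation_layout(seed = 1)
  lab <- orientation_clusters(lay$x, lay$y, lay$theta_deg,
                              eps = 400, min_pts = 15)
  expect_equal(length(unique(lab[lab > 0])), 2L)
  expect_gt(ari(lab, lay$cluster_id), 0.9)
  cs <- cluster_summary(lab, lay$x, lay$y)
  expect_equal(cs$n_clusters, 2L)
  expect_equal(cs$centroid_distances[1, 2], 2000, tolerance = 0.05)
  expect_true(all(cs$cluster_sizes >= 15))
})

test_that("minimum cluster size and orthogonal orientations gate membership", {
  # 14 co-located co-oriented nuclei cannot form a 15-minimum cluster
  set.seed(62)
  x <- runif(14, 0, 50); y <- runif(14, 0, 50); th <- rnorm(14, 40, 2)
  expect_equal(unique(orientation_clusters(x, y, th, 400, 15)), -1L)
  # orthogonal alternating orientations are not mutually reachable at w = eps/90
  n <- 30
  x2 <- runif(n, 0, 10); y2 <- runif(n, 0, 10)
  th2 <- rep(c(0, 90), length.out = n)
  got <- orientation_clusters(x2, y2, th2, eps = 100, min_pts = 15,
                              angle_weight = 100 / 90)
  D <- orientation_distance_matrix(x2, y2, th2, 100 / 90)
  expect_identical(got, dbscan_oracle(D, 100, 15))
  # each parity forms its own cluster; the two never merge
  expect_equal(length(unique(got[got > 0])), 2L)
  expect_true(all(table(th2, got)[, "1"] %in% c(0L, 15L)))
})

test_that("cluster summaries handle the all-noise and single-cluster cases", {
  cs0 <- cluster_summary(rep(-1L, 10), runif(10), runif(10))
  expect_equal(cs0$n_clusters, 0L)
  expect_equal(cs0$fraction_clustered, 0)
  cs1 <- cluster_summary(rep(1L, 20), runif(20), runif(20))
  expect_equal(cs1$fraction_clustered, 1)
})

test_that("fraction clustered is monotone in min_pts and eps", {
  set.seed(63)
  lay <- planted_orientation_layout(seed = 2)
  frac <- function(eps, mp) {
    lab <- orientation_clusters(lay$x, lay$y, lay$theta_deg, eps, mp)
    mean(lab > 0)
  }
  expect_true(all(diff(sapply(c(5, 15, 25, 40), function(mp)
    frac(400, mp))) <= 0))
  expect_true(all(diff(sapply(c(200, 400, 800), function(e)
    frac(e, 15))) >= 0))
})

test_that("parameter scan produces increasing kNN distances and an eps peak", {
  set.seed(64)
  n <- 80
  x <- runif(n, 0, 2000); y <- runif(n, 0, 2000); th <- runif(n, 0, 180)
  ps <- parameter_scan(x, y, th, ks = 1:20,
                       eps_grid = seq(100, 800, by = 100), min_pts = 5)
  expect_true(all(diff(ps$knn$median_dist) > 0))
  # axial-angle differences of random orientations approach the 45-degree
  # expectation for large k
  expect_equal(mean(tail(ps$knn$median_angle_diff, 5)), 45, tolerance = 0.25)
  # planted two-cluster layout: cluster count peaks then merges
  lay <- planted_orientation_layout(seed = 3)
  ps2 <- parameter_scan(lay$x, lay$y, lay$theta_deg, ks = 1:10,
                        eps_grid = c(100, 400, 3000, 8000), min_pts = 15)
  expect_equal(max(ps2$eps_scan$n_clusters), 2L)
  expect_equal(ps2$eps_scan$n_clusters[4], 1L)
  expect_equal(ps2$eps_best, 400)
})

test_that("lattice density features match closed forms", {
  g <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  d <- density_features(g$x, g$y, radii = c(5, 15), ks = c(1, 3))
  interior <- g$x %in% seq(20, 70, 10) & g$y %in% seq(20, 70, 10)
  expect_true(all(d$knn_dist_k1 == 10))
  expect_true(all(d$n_neighbors_r5 == 0))
  # within 15 um: 4 axial neighbours at 10 + 4 diagonal at 14.14
  expect_true(all(d$n_neighbors_r15[interior] == 8))
  expect_true(all(abs(d$voronoi_area[interior] - 100) < 1e-6))
  expect_true(all(abs(d$voronoi_perimeter[interior] - 40) < 1e-6))
})

test_that("kth-NN distances are non-decreasing in k and pairs count right", {
  d2 <- density_features(c(0, 7), c(0, 0), radii = c(5, 15), ks = 1)
  expect_equal(d2$n_neighbors_r5, c(0L, 0L))
  expect_equal(d2$n_neighbors_r15, c(1L, 1L))
  set.seed(65)
  n <- 40
  d3 <- density_features(runif(n, 0, 100), runif(n, 0, 100),
                         radii = 10, ks = c(1, 3, 5, 10))
  expect_true(all(d3$knn_dist_k1 <= d3$knn_dist_k3))
  expect_true(all(d3$knn_dist_k3 <= d3$knn_dist_k5))
  expect_true(all(d3$knn_dist_k5 <= d3$knn_dist_k10))
})

test_that("Voronoi areas tile an interior window", {
  set.seed(66)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  frame <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  vf <- voronoi_features(x, y, frame = frame)
  expect_equal(sum(vf$voronoi_area), 100 * 100, tolerance = 0.01)
  expect_true(all(vf$voronoi_eccentricity >= 0 &
                    vf$voronoi_eccentricity < 1, na.rm = TRUE))
})

test_that("nuclear expansion matches the per-pixel nearest-nucleus brute force", {
  m <- matrix(0L, 40, 80)
  for (r in 1:40) for (cc in 1:80) {
    if ((r - 20)^2 + (cc - 20)^2 <= 16) m[r, cc] <- 1L
    if ((r - 20)^2 + (cc - 50)^2 <= 16) m[r, cc] <- 2L
  }
  lm <- label_mask(m, pixel_size_um = 1)
  cells <- expand_nuclei_to_cells(lm, max_um = 5)
  co <- function(idx) cbind((idx - 1) %% 40 + 1, (idx - 1) %/% 40 + 1)
  c1 <- co(which(m == 1L)); c2 <- co(which(m == 2L))
  for (p in which(m == 0L)) {
    pr <- (p - 1) %% 40 + 1; pc <- (p - 1) %/% 40 + 1
    d1 <- sqrt(min((c1[, 1] - pr)^2 + (c1[, 2] - pc)^2))
    d2 <- sqrt(min((c2[, 1] - pr)^2 + (c2[, 2] - pc)^2))
    want <- if (min(d1, d2) > 5) 0L else if (d1 < d2) 1L
            else if (d2 < d1) 2L else 1L      # tie to the lower label
    expect_identical(cells$labels[p], want)
  }
  # cells are supersets of their nuclei and never overlap
  expect_true(all(cells$labels[m > 0L] == m[m > 0L]))
})

test_that("an isolated 5-um nucleus expands to about four times its area", {
  m <- matrix(0L, 90, 90)
  for (r in 1:90) for (cc in 1:90) if ((r - 45)^2 + (cc - 45)^2 <= 100)
    m[r, cc] <- 1L
  lm <- label_mask(m, pixel_size_um = 0.5)   # r = 10 px = 5 um
  cells <- expand_nuclei_to_cells(lm, max_um = 5)
  expect_equal(sum(cells$labels == 1L) / sum(m == 1L), 4, tolerance = 0.05)
  # expansion clips at the frame edge
  m2 <- matrix(0L, 30, 30)
  for (r in 1:30) for (cc in 1:30) if ((r - 3)^2 + (cc - 15)^2 <= 25)
    m2[r, cc] <- 1L
  cells2 <- expand_nuclei_to_cells(label_mask(m2, 1), max_um = 5)
  expect_true(sum(cells2$labels == 1L) < sum(m2 == 1L) + pi * (10^2 - 5^2))
})

test_that("biomarker region calling thresholds cell means", {
  m <- matrix(0L, 40, 90)
  centers <- c(15, 45, 75)
  for (k in 1:3) for (r in 1:40) for (cc in 1:90)
    if ((r - 20)^2 + (cc - centers[k])^2 <= 36) m[r, cc] <- k
  cells <- label_mask(m, 1)
  marker <- matrix(0.05, 40, 90)
  marker[, 1:30] <- 0.9                 # cell 1 in a biomarker-high region
  g <- gray_image(marker)
  fixed <- biomarker_region_call(cells, g, threshold = 0.5)
  expect_equal(fixed$in_region, c(TRUE, FALSE, FALSE))
  auto <- biomarker_region_call(cells, g)  # Otsu on the three cell means
  expect_equal(auto$in_region, c(TRUE, FALSE, FALSE))
  dark <- biomarker_region_call(cells, gray_image(matrix(0, 40, 90) + 1e-9),
                                threshold = 0.5)
  expect_false(any(dark$in_region))
})

test_that("clustering is invariant under translation and 90-degree rotation", {
  lay <- planted_orientation_layout(seed = 4)
  lab0 <- orientation_clusters(lay$x, lay$y, lay$theta_deg, 400, 15)
  lab_t <- orientation_clusters(lay$x + 1234, lay$y - 987, lay$theta_deg,
                                400, 15)
  expect_equal(ari(lab0, lab_t), 1)
  # rotate the pattern by 90 degrees: (x, y) -> (-y, x), theta -> theta + 90
  lab_r <- orientation_clusters(-lay$y, lay$x, (lay$theta_deg + 90) %% 180,
                                400, 15)
  expect_equal(ari(lab0, lab_r), 1)
})

test_that("DCIS-like layouts show higher MGS among clustered nuclei", {
  d <- synthetic_dcis_layout(seed = 1)
  el <- filter_elongated(d, 1.5)
  lab <- orientation_clusters(el$x, el$y, el$theta_deg, eps = 200,
                              min_pts = 15)
  expect_gt(sum(lab > 0), 20)
  expect_gt(mean(el$mgs[lab > 0]), mean(el$mgs[lab <= 0]))
})

test_that("adding an informative MGS never hurts the tissue classifier", {
  arch_cols <- c("clustered", "voronoi_area", "n_neighbors_r40", "knn_dist_k1")
  co <- synthetic_architecture_cohort(seed = 2)
  without <- tissue_architecture_classifier(co, arch_cols,
                                            include_mgs = FALSE, seed = 12)
  with_mgs <- tissue_architecture_classifier(co, arch_cols,
                                             include_mgs = TRUE, seed = 12)
  expect_gte(with_mgs$balanced_accuracy, without$balanced_accuracy)
  expect_gt(with_mgs$balanced_accuracy, 0.5)
  # planted architecture effect alone beats chance across several cohorts
  accs <- sapply(3:6, function(s) {
    tissue_architecture_classifier(synthetic_architecture_cohort(seed = s),
                                   arch_cols, include_mgs = FALSE,
                                   seed = s)$balanced_accuracy
  })
  expect_gt(mean(accs), 0.6)
  one_each <- co[co$tissue_id %in% c("normal_t01", "dcis_t01"), ]
  expect_error(tissue_architecture_classifier(one_each, arch_cols),
               ">= 2 tissues")
})
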