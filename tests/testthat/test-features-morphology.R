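test_that("disk morphology matches analytic values", {
  cr <- flat_crop(disk_mask(20), 0.8)
  f <- morphology_features(cr)
  expect_equal(f[["area_um2"]], pi * 400, tolerance = 0.02)
  expect_equal(f[["aspect_ratio"]], 1, tolerance = 0.02)
  expect_equal(f[["perimeter_um"]], 2 * pi * 20, tolerance = 0.05)
})

test_that("ellipse aspect ratio and max caliper are recovered", {
  cr <- flat_crop(ellipse_mask(20, 10), 0.7)
  f <- morphology_features(cr)
  expect_equal(f[["aspect_ratio"]], 2, tolerance = 0.05)
  expect_equal(f[["max_caliper_um"]], 40, tolerance = 0.05)
})

test_that("a 10 px square has diagonal max Feret and side-length min Feret", {
  m <- matrix(FALSE, 18, 18)
  m[5:14, 5:14] <- TRUE
  f <- morphology_features(flat_crop(m, 1))
  expect_equal(f[["max_caliper_um"]], 10 * sqrt(2), tolerance = 1e-6)
  expect_equal(f[["min_caliper_um"]], 10, tolerance = 1e-6)
})

test_that("morphology scales correctly with pixel size", {
  m <- ellipse_mask(15, 9)
  f1 <- morphology_features(flat_crop(m, 1, pixel_size_um = 1))
  f2 <- morphology_features(flat_crop(m, 1, pixel_size_um = 2))
  expect_equal(f2[["area_um2"]], 4 * f1[["area_um2"]])
  expect_equal(f2[["perimeter_um"]], 2 * f1[["perimeter_um"]])
  expect_equal(f2[["max_caliper_um"]], 2 * f1[["max_caliper_um"]])
  expect_equal(f2[["aspect_ratio"]], f1[["aspect_ratio"]])
})

test_that("degenerate masks are flagged with NA features", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  f <- morphology_features(nucleus_crop(gray_image(matrix(0.5, 5, 5)), m))
  expect_true(all(is.na(f)))
})

test_that("circle curvature is 1/r and convex shapes have no negative fraction", {
  for (r in c(20, 30)) {
    cr <- flat_crop(disk_mask(r), 1)
    b <- boundary_features(cr)
    expect_equal(b[["frac_perimeter_negative_curved"]], 0)
    expect_equal(b[["sd_negative_curvature"]], 0)
    expect_lt(b[["relative_concavity"]], 0.01)
  }
  # mean curvature of the smoothed contour approximates 1/r
  m30 <- disk_mask(30)
  xy <- chromatinMGS:::smooth_closed(
    chromatinMGS:::resample_closed(chromatinMGS:::mask_contour(m30), 200), 5)
  expect_equal(mean(chromatinMGS:::closed_curvature(xy)), 1 / 30,
               tolerance = 0.05)
})

test_that("a convex ellipse has zero negative-curvature fraction", {
  b <- boundary_features(flat_crop(ellipse_mask(22, 11), 1))
  expect_equal(b[["frac_perimeter_negative_curved"]], 0)
  expect_lt(b[["relative_concavity"]], 0.01)
})

test_that("a wedge bite creates concavity matching the hull-area oracle", {
  m <- disk_mask(25)
  ct <- (nrow(m) + 1) / 2
  # remove a 70-degree wedge
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    ang <- atan2(-(r - ct), cc - ct) * 180 / pi
    if (ang > 10 && ang < 80) m[r, cc] <- FALSE
  }
  b <- boundary_features(flat_crop(m, 1))
  expect_gt(b[["frac_perimeter_negative_curved"]], 0)
  expect_gt(b[["sd_negative_curvature"]], 0)
  # oracle: count pixels inside the gift-wrapped hull of pixel centres
  xy <- chromatinMGS:::mask_xy(m)
  hull_px <- chromatinMGS:::pixels_in_hull(m)
  expect_equal(b[["relative_concavity"]], (hull_px - sum(m)) / hull_px)
  # hull area from the independent gift-wrapping oracle agrees closely
  expect_equal(hull_area_oracle(xy), hull_px, tolerance = 0.02)
  expect_gt(b[["relative_concavity"]], 0.05)
})

test_that("nucleus orientation recovers planted axial angles", {
  for (th in c(0, 45, 90, 135)) {
    rn <- render_nucleus(nucleus_spec(a = 20, b = 8, theta_deg = th,
                                      noise_sd = 0, n_foci = 0L), seed = 11)
    got <- nucleus_orientation(rn$crop$mask)
    d <- min(abs(got - th), 180 - abs(got - th))
    expect_lt(d, 1)
  }
  # axial symmetry: rotating the mask 180 degrees leaves theta unchanged
  rn <- render_nucleus(nucleus_spec(a = 18, b = 9, theta_deg = 30,
                                    noise_sd = 0, n_foci = 0L), seed = 12)
  m <- rn$crop$mask
  rot180 <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  expect_equal(nucleus_orientation(m), nucleus_orientation(rot180),
               tolerance = 1e-6)
  # near-circular masks have undefined orientation
  expect_true(is.na(nucleus_orientation(disk_mask(15))))
})

test_that("features are rotation-robust under exact 90-degree rotations", {
  rn <- render_nucleus(nucleus_spec(a = 16, b = 10, theta_deg = 25,
                                    irregularity = 0.08), seed = 13)
  cr <- rn$crop
  rot <- nucleus_crop(gray_image(t(cr$crop$pixels)[ncol(cr$crop$pixels):1, ],
                                 cr$crop$pixel_size_um),
                      t(cr$mask)[ncol(cr$mask):1, ])
  f1 <- morphology_features(cr); f2 <- morphology_features(rot)
  for (nm in names(f1))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 0.01, label = nm)
  b1 <- boundary_features(cr); b2 <- boundary_features(rot)
  # curvature fractions are discrete over 200 contour points: allow a
  # couple of points of slack
  for (nm in names(b1))
    expect_lt(abs(b2[[nm]] - b1[[nm]]), 0.02, label = nm)
})
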