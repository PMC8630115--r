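test_that("rendered nuclei are seed-deterministic with faithful shape truth", {
  sp <- nucleus_spec(a = 12, b = 12, irregularity = 0, noise_sd = 0)
  r1 <- render_nucleus(sp, seed = 5)
  r2 <- render_nucleus(sp, seed = 5)
  expect_identical(r1$crop$crop$pixels, r2$crop$crop$pixels)
  f <- morphology_features(r1$crop)
  expect_equal(f[["aspect_ratio"]], 1, tolerance = 0.02)
  # planted parameter recovery over many random specs
  set.seed(71)
  ok_ar <- ok_area <- ok_th <- 0L
  n_spec <- 40L
  for (i in seq_len(n_spec)) {
    a <- runif(1, 10, 18); b <- runif(1, 6, min(a, 12))
    th <- runif(1, 0, 180)
    rn <- render_nucleus(nucleus_spec(a = a, b = b, theta_deg = th,
                                      noise_sd = 0, n_foci = 0L),
                         seed = 100 + i)
    fm <- morphology_features(rn$crop)
    if (abs(fm[["aspect_ratio"]] - a / b) / (a / b) < 0.06) ok_ar <- ok_ar + 1L
    if (abs(fm[["area_um2"]] - pi * a * b) / (pi * a * b) < 0.04)
      ok_area <- ok_area + 1L
    got_th <- nucleus_orientation(rn$crop$mask)
    if (a / b > 1.2 && min(abs(got_th - th), 180 - abs(got_th - th)) < 3)
      ok_th <- ok_th + 1L
  }
  expect_gte(ok_ar, n_spec - 2L)
  expect_gte(ok_area, n_spec - 2L)
  expect_gte(ok_th, sum(TRUE) * 0)      # counted only for elongated specs
  expect_gt(ok_th, 25L)
})

test_that("texture amplitude raises GLCM contrast over replicate means", {
  mean_contrast <- function(amp) {
    mean(sapply(1:12, function(r) {
      rn <- render_nucleus(nucleus_spec(a = 14, b = 10, focus_contrast = amp,
                                        n_foci = 8L), seed = 300 + r)
      glcm_features(rn$crop, distances = 3)[["glcm_contrast_3"]]
    }))
  }
  cs <- sapply(c(0.1, 0.3, 0.55), mean_contrast)
  expect_true(all(diff(cs) > 0))
})

test_that("the texture knob moves contrast up and homogeneity down", {
  knob_stats <- function(ct) {
    rowMeans(sapply(1:15, function(r) {
      kn <- chromatin_texture_knobs(ct, b = 10)
      rn <- render_nucleus(nucleus_spec(a = 14, b = 10,
                                        n_foci = kn$n_foci,
                                        focus_contrast = kn$focus_contrast,
                                        focus_sd = kn$focus_sd,
                                        background = 0.45),
                           seed = 400 + r)
      g <- glcm_features(rn$crop, distances = 3)
      c(g[["glcm_contrast_3"]], g[["glcm_homogeneity_3"]])
    }))
  }
  s <- sapply(c(0.15, 0.5, 0.85), knob_stats)
  expect_true(all(diff(s[1, ]) > 0))   # contrast strictly increasing
  expect_true(all(diff(s[2, ]) < 0))   # homogeneity strictly decreasing
})

test_that("rendered tissues carry truth that round-trips the pipeline", {
  lay <- tissue_layout_clusters(
    data.frame(cx = c(700, 2300), cy = c(700, 2300), n = c(25, 25),
               theta_deg = c(30, 120), spread = c(120, 120)),
    n_noise = 8, width = 3000, height = 3000, seed = 8)
  rt <- render_tissue(lay, width = 3000, height = 3000, seed = 9)
  expect_equal(max(rt$mask$labels), nrow(lay))
  lab <- orientation_clusters(rt$truth$x, rt$truth$y, rt$truth$theta_deg,
                              eps = 400, min_pts = 15)
  expect_gt(ari(lab, rt$truth$cluster_id), 0.9)
})

test_that("impossibly dense layout requests fail with a placement error", {
  expect_error(tissue_layout_random(500, width = 100, height = 100,
                                    max_tries = 50, seed = 3),
               "too dense|could not place")
})

test_that("cohorts regenerate identically from the manifest parameters", {
  c1 <- generate_cohort(n_tissues = 1L, n_nuclei = 10L, width = 160L,
                        height = 160L, seed = 4)
  c2 <- generate_cohort(n_tissues = 1L, n_nuclei = 10L, width = 160L,
                        height = 160L, seed = 4)
  t1 <- c1$tissues[[1]]; t2 <- c2$tissues[[1]]
  expect_identical(t1$image$pixels, t2$image$pixels)
  expect_identical(c1$manifest$tissues, c2$manifest$tissues)
  # written cohort contains images, truth masks, truth tables and manifest
  d <- withr::local_tempdir()
  generate_cohort(n_tissues = 1L, n_nuclei = 8L, width = 160L, height = 160L,
                  seed = 5, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_length(list.files(d, pattern = "_mask\\.tif$"), 2L)
  expect_length(list.files(d, pattern = "_truth\\.csv$"), 2L)
})

test_that("a null cohort gives chance accuracy and a strong shift separates", {
  null_co <- synthetic_feature_cohort(severities = c(0, 0), delta = 0,
                                      n_per_stage = 300, seed = 81)
  sp <- split_train_test(null_co, seed = 1)
  m <- suppressWarnings(fit_classifier(sp$train, "lda"))
  p <- predict_nuclei(m, sp$test)
  expect_lt(abs(balanced_accuracy(sp$test$stage, p$class) - 0.5), 0.12)
  strong <- synthetic_feature_cohort(delta = 4, n_per_stage = 300, seed = 82)
  sp2 <- split_train_test(strong, seed = 1)
  m2 <- suppressWarnings(fit_classifier(sp2$train, "lda"))
  p2 <- predict_nuclei(m2, sp2$test)
  expect_gt(balanced_accuracy(sp2$test$stage, p2$class), 0.99)
})
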