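cohort <- synthetic_feature_cohort(seed = 101)

test_that("train/test split is by tissue, balanced, and seed-reproducible", {
  s1 <- split_train_test(cohort, seed = 3, per_class_n = 200)
  s2 <- split_train_test(cohort, seed = 3, per_class_n = 200)
  expect_identical(s1$train$tissue_id, s2$train$tissue_id)
  expect_length(intersect(unique(s1$train$tissue_id),
                          unique(s1$test$tissue_id)), 0)
  expect_equal(unname(table(s1$train$stage)), c(200L, 200L),
               ignore_attr = TRUE)
  # 5 tissues per class at frac 0.8 -> 4 train, 1 test per class
  expect_equal(length(unique(s1$train$tissue_id)), 8L)
})

test_that("well-separated classes reach near-perfect balanced accuracy", {
  sp <- split_train_test(cohort, seed = 5)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  pred <- predict_nuclei(model, sp$test)
  expect_gt(balanced_accuracy(sp$test$stage, pred$class), 0.99)
  # stored training accuracy is reproduced on the training data
  pred_tr <- predict_nuclei(model, sp$train)
  expect_equal(balanced_accuracy(sp$train$stage, pred_tr$class),
               model$training_accuracy)
})

test_that("identical class distributions score at chance", {
  null_cohort <- synthetic_feature_cohort(severities = c(0, 0), delta = 0,
                                          n_per_stage = 400, seed = 77)
  sp <- split_train_test(null_cohort, seed = 2)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  pred <- predict_nuclei(model, sp$test)
  expect_equal(balanced_accuracy(sp$test$stage, pred$class), 0.5,
               tolerance = 0.1)
})

test_that("requesting more components than the rank stores the bound", {
  expect_warning(model <- fit_classifier(cohort, "lda", n_components = 50),
                 "components")
  expect_lte(ncol(model$rotation), 16L)
})

test_that("standardize-PCA-project is invertible bookkeeping", {
  sp <- split_train_test(cohort, seed = 4)
  model <- suppressWarnings(fit_classifier(sp$train, "lda",
                                           n_components = 16))
  X <- as.matrix(sp$train[, model$feature_names])
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  S <- Z %*% model$rotation
  back <- S %*% t(model$rotation)
  expect_lt(max(abs(back - Z)), 1e-8)
})

test_that("rf and ann agree with lda on a linearly separable cohort", {
  sp <- split_train_test(cohort, seed = 6)
  pl <- suppressWarnings(predict_nuclei(fit_classifier(sp$train, "lda"), sp$test))
  pr <- suppressWarnings(predict_nuclei(fit_classifier(sp$train, "rf", seed = 2), sp$test))
  pa <- suppressWarnings(predict_nuclei(fit_classifier(sp$train, "ann", seed = 2), sp$test))
  expect_gt(mean(pl$class == pr$class), 0.95)
  expect_gt(mean(pl$class == pa$class), 0.95)
})

test_that("cross-validation is seed-deterministic and near-chance under permutation", {
  cv1 <- suppressWarnings(crossvalidate(cohort, "lda", k = 5, seed = 11))
  cv2 <- suppressWarnings(crossvalidate(cohort, "lda", k = 5, seed = 11))
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$mean_balanced_accuracy, 0.99)
  expect_true(all(rowSums(cv1$confusion) ==
                    table(cohort$stage)[rownames(cv1$confusion)]))
  set.seed(13)
  perm <- cohort
  perm$stage <- sample(perm$stage)
  # permuted labels follow tissues no longer, so re-tie them to tissues
  perm$stage <- ave(perm$stage, perm$tissue_id, FUN = function(s) s[1])
  cvp <- suppressWarnings(crossvalidate(perm, "lda", k = 5, seed = 11))
  se <- max(cvp$se_balanced_accuracy, 0.02)
  expect_lt(abs(cvp$mean_balanced_accuracy - 0.5), 3 * se + 0.1)
  expect_error(crossvalidate(cohort, "lda", k = 7), "fewer than k")
})

test_that("tissue majority vote follows the modal class with tie logging", {
  expect_equal(tissue_majority_vote(rep("t1", 3), c("N", "N", "C"))$class, "N")
  expect_equal(tissue_majority_vote(rep("t1", 10),
                                    c(rep("N", 9), "C"))$class, "N")
  sc <- matrix(c(0.4, 0.45, 0.6, 0.55), 2,
               dimnames = list(NULL, c("N", "C")))
  expect_message(v <- tissue_majority_vote(rep("t1", 2), c("N", "C"), sc),
                 "tie")
  expect_equal(v$class, "C")
  expect_true(v$tie)
})

test_that("MGS separates populations in the documented direction", {
  sp <- split_train_test(cohort, seed = 8)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  mgs <- compute_mgs(model, cohort, normal_class = "normal")
  expect_gt(mean(mgs[cohort$stage == "normal"]),
            mean(mgs[cohort$stage == "cancer"]))
  # planted health axis is recovered
  expect_gt(abs(cor(mgs, cohort$health, method = "spearman")), 0.9)
  expect_gt(cor(mgs, cohort$health, method = "spearman"), 0)
  # rank-sum separation at n = 200/arm with a 3-sigma effect
  co3 <- synthetic_feature_cohort(n_per_stage = 200, delta = 3, seed = 55)
  m3 <- suppressWarnings(
    fit_classifier(split_train_test(co3, seed = 1)$train, "lda"))
  mg3 <- compute_mgs(m3, co3, normal_class = "normal")
  w <- wilcox.test(mg3[co3$stage == "normal"], mg3[co3$stage == "cancer"])
  expect_lt(w$p.value, 0.001)
})

test_that("MGS is invariant to affine rescaling of a raw feature", {
  sp <- split_train_test(cohort, seed = 9)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  mgs <- compute_mgs(model, cohort, normal_class = "normal")
  scaled <- cohort
  scaled$median_intensity <- scaled$median_intensity * 1000 - 77
  sp2 <- split_train_test(scaled, seed = 9)
  model2 <- suppressWarnings(fit_classifier(sp2$train, "lda"))
  mgs2 <- compute_mgs(model2, scaled, normal_class = "normal")
  expect_equal(mgs2, mgs, tolerance = 1e-6)
})

test_that("feature correlations with MGS rank as planted", {
  sp <- split_train_test(cohort, seed = 10)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  mgs <- compute_mgs(model, cohort, normal_class = "normal")
  rr <- mgs_feature_correlations(cohort, mgs)
  r_of <- function(f) rr$pearson_r[rr$feature == f]
  # cancer-axis directions: healthy = low concavity, high median intensity
  expect_lt(r_of("relative_concavity"), -0.5)
  expect_lt(r_of("sd_negative_curvature"), -0.5)
  expect_gt(r_of("median_intensity"), 0.5)
  expect_gt(r_of("glcm_entropy_3"), 0.5)
  expect_lt(r_of("glcm_homogeneity_3"), -0.5)
  expect_lt(max(abs(rr$pearson_r[grepl("noise", rr$feature)])), 0.2)
  # perfect linear features hit +-1
  fake <- cohort
  fake$noise_feature_1 <- mgs
  fake$noise_feature_2 <- -mgs
  rr2 <- mgs_feature_correlations(fake, mgs)
  expect_equal(rr2$pearson_r[rr2$feature == "noise_feature_1"], 1)
  expect_equal(rr2$pearson_r[rr2$feature == "noise_feature_2"], -1)
})

test_that("LDA scoring models serialize to JSON + CSV text", {
  d <- withr::local_tempdir()
  sp <- split_train_test(cohort, seed = 12)
  model <- suppressWarnings(fit_classifier(sp$train, "lda"))
  p <- file.path(d, "model")
  write_scoring_model(model, p)
  meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(meta$classes, model$classes)
  arr <- utils::read.csv(paste0(p, "_arrays.csv"))
  rot <- matrix(arr$value[arr$block == "rotation"],
                nrow = length(model$mu))
  expect_equal(rot, unname(model$rotation))
})
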