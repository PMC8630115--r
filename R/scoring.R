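#' Tissue-stratified train/test split with per-class balanced sampling
#'
#' Splits by tissue so no tissue contributes nuclei to both sets: for each
#' class, `frac_tissues` of its tissues are assigned to training. Training
#' nuclei are then sampled equally per class (`per_class_n`, or all
#' available with a warning when fewer).
#'
#' @param t feature table with `tissue_id` and `stage` columns.
#' @param frac_tissues fraction of tissues per class used for training
#'   (default 0.8).
#' @param per_class_n training nuclei sampled per class (NULL = all).
#' @param seed RNG seed; the split is reproducible given the seed.
#' @return List with elements `train` and `test` (feature tables).
#' @export
split_train_test <- function(t, frac_tissues = 0.8, per_class_n = NULL,
                             seed = 1L) {
  stopifnot(all(c("tissue_id", "stage") %in% names(t)))
  set.seed(seed)
  train_tissues <- character(0)
  for (cl in sort(unique(t$stage))) {
    tis <- sort(unique(t$tissue_id[t$stage == cl]))
    if (length(tis) < 2L)
      stop("split_train_test: need >= 2 tissues for class ", cl)
    ntr <- max(1L, round(frac_tissues * length(tis)))
    ntr <- min(ntr, length(tis) - 1L)     # keep at least one test tissue
    train_tissues <- c(train_tissues, sample(tis, ntr))
  }
  tr <- t[t$tissue_id %in% train_tissues, , drop = FALSE]
  te <- t[!t$tissue_id %in% train_tissues, , drop = FALSE]
  if (!is.null(per_class_n)) {
    keep <- unlist(lapply(sort(unique(tr$stage)), function(cl) {
      idx <- which(tr$stage == cl)
      if (length(idx) < per_class_n) {
        warning(sprintf("split_train_test: class %s has %d < %d nuclei, taking all",
                        cl, length(idx), per_class_n))
        idx
      } else sample(idx, per_class_n)
    }))
    tr <- tr[sort(keep), , drop = FALSE]
  }
  list(train = tr, test = te)
}

#' Fit a nucleus-stage classifier on standardized PCA scores
#'
#' Standardizes the features, projects onto the leading principal
#' components (at most `n_components`, capped at the rank bound), and fits
#' the requested classifier on the component scores: `"lda"` (linear
#' discriminant analysis; ridge-regularized on a singular within-class
#' covariance), `"rf"` (random forest, 2000 trees of maximum depth 7) or
#' `"ann"` (a two-hidden-layer neural network).
#'
#' @param train feature table with a `stage` column; rows should be
#'   QC-passed.
#' @param kind one of "lda", "rf", "ann".
#' @param n_components principal components to retain (default 50).
#' @param seed RNG seed for the stochastic classifiers.
#' @param hidden hidden-layer sizes for the ANN (default c(64, 32)).
#' @return A `scoring_model`: standardization vectors, PCA rotation,
#'   achieved explained-variance fraction, the fitted classifier, class
#'   levels and training accuracy.
#' @export
fit_classifier <- function(train, kind = c("lda", "rf", "ann"),
                           n_components = 50L, seed = 1L,
                           hidden = c(64L, 32L)) {
  kind <- match.arg(kind)
  fc <- feature_columns(train)
  X <- as.matrix(train[, fc, drop = FALSE])
  keep <- colSums(!is.finite(X)) == 0 & apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  y <- factor(train$stage)
  if (nlevels(y) < 2L) stop("fit_classifier: need >= 2 classes")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  max_rank <- min(ncol(Z), nrow(Z) - 1L)
  m <- min(n_components, max_rank)
  if (m < n_components)
    warning(sprintf("fit_classifier: %d components requested, %d available",
                    n_components, m))
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  S <- Z %*% rot
  expl_var <- sum(pc$sdev[seq_len(m)]^2) / sum(pc$sdev^2)
  set.seed(seed)
  clf <- switch(kind,
    lda = fit_lda_safe(S, y),
    rf = ranger::ranger(y = y, x = as.data.frame(S), num.trees = 2000L,
                        max.depth = 7L, probability = TRUE, seed = seed),
    ann = mlp_fit(S, y, hidden = hidden, seed = seed))
  model <- structure(list(kind = kind, feature_names = colnames(X),
                          mu = mu, sd = sdv, rotation = rot,
                          explained_variance = expl_var, classifier = clf,
                          classes = levels(y), seed = seed),
                     class = "scoring_model")
  pr <- predict_nuclei(model, train)
  model$training_accuracy <- balanced_accuracy(y, pr$class)
  model
}

# LDA with a small ridge fallback when the within-class covariance is
# (near-)singular.
fit_lda_safe <- function(S, y, ridge = 1e-4) {
  tryCatch(MASS::lda(S, grouping = y),
           error = function(e) {
             warning("fit_classifier: singular covariance, ridge-regularized LDA")
             Sr <- S + matrix(stats::rnorm(length(S), sd = sqrt(ridge)),
                              nrow(S), ncol(S))
             MASS::lda(Sr, grouping = y)
           })
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model> %s on %d PCs (%.1f%% variance), classes: %s\n",
              toupper(x$kind), ncol(x$rotation), 100 * x$explained_variance,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Project a feature table onto the model's standardized PC space.
model_scores <- function(model, t) {
  X <- as.matrix(t[, model$feature_names, drop = FALSE])
  X[!is.finite(X)] <- 0
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  Z %*% model$rotation
}

#' Predict nucleus classes (and class probabilities) with a fitted model
#'
#' @param model a `scoring_model`.
#' @param t feature table with the model's feature columns.
#' @return data.frame: `class` (predicted label), one probability column per
#'   class, and for LDA models the discriminant coordinates `LD1..`.
#' @export
predict_nuclei <- function(model, t) {
  S <- model_scores(model, t)
  if (model$kind == "lda") {
    p <- stats::predict(model$classifier, S)
    out <- data.frame(class = as.character(p$class), p$posterior,
                      check.names = FALSE, stringsAsFactors = FALSE)
    ld <- as.data.frame(p$x)
    names(ld) <- paste0("LD", seq_len(ncol(ld)))
    cbind(out, ld)
  } else if (model$kind == "rf") {
    p <- stats::predict(model$classifier, data = as.data.frame(S))$predictions
    cls <- colnames(p)[max.col(p, ties.method = "first")]
    data.frame(class = cls, p, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    p <- mlp_predict_prob(model$classifier, S)
    cls <- colnames(p)[max.col(p, ties.method = "first")]
    data.frame(class = cls, p, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Class-averaged balanced accuracy
#'
#' Mean of the per-class recalls over the classes present in `truth`.
#'
#' @param truth,pred vectors of true and predicted labels.
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

# Macro-averaged one-vs-rest ROC AUC from a probability matrix.
macro_auc <- function(truth, prob) {
  classes <- colnames(prob)
  present <- intersect(classes, unique(as.character(truth)))
  aucs <- vapply(present, function(cl) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Tissue-stratified k-fold cross-validation
#'
#' Folds are formed over tissues (stratified by class) so a tissue's nuclei
#' never straddle a fold boundary. Reports per-fold balanced accuracy and
#' macro ROC AUC with their mean and standard error.
#'
#' @param t feature table.
#' @param kind classifier kind, see [fit_classifier()].
#' @param k number of folds (default 5).
#' @param n_components,seed,... passed to [fit_classifier()].
#' @return List: `folds` (per-fold data.frame), `mean_balanced_accuracy`,
#'   `se_balanced_accuracy`, `mean_auc`, `confusion` (pooled confusion
#'   matrix), `predictions` (pooled out-of-fold predictions with fold ids).
#' @export
crossvalidate <- function(t, kind = "lda", k = 5L, n_components = 50L,
                          seed = 1L, ...) {
  set.seed(seed)
  classes <- sort(unique(t$stage))
  tis_by_class <- lapply(classes, function(cl) sort(unique(t$tissue_id[t$stage == cl])))
  if (any(vapply(tis_by_class, length, integer(1)) < k))
    stop("crossvalidate: fewer than k tissues in some class")
  fold_of <- integer(0)
  for (tis in tis_by_class) {
    f <- rep_len(seq_len(k), length(tis))[sample(length(tis))]
    names(f) <- tis
    fold_of <- c(fold_of, f)
  }
  fold_id <- fold_of[t$tissue_id]
  acc <- auc <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- t[fold_id != f, , drop = FALSE]
    te <- t[fold_id == f, , drop = FALSE]
    model <- fit_classifier(tr, kind = kind, n_components = n_components,
                            seed = seed + f, ...)
    p <- predict_nuclei(model, te)
    acc[f] <- balanced_accuracy(te$stage, p$class)
    prob <- as.matrix(p[, model$classes, drop = FALSE])
    auc[f] <- macro_auc(te$stage, prob)
    preds[[f]] <- data.frame(tissue_id = te$tissue_id, stage = te$stage,
                             pred = p$class, fold = f,
                             stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, preds)
  list(folds = data.frame(fold = seq_len(k), balanced_accuracy = acc, auc = auc),
       mean_balanced_accuracy = mean(acc),
       se_balanced_accuracy = stats::sd(acc) / sqrt(k),
       mean_auc = mean(auc),
       confusion = table(truth = pooled$stage, pred = pooled$pred),
       predictions = pooled)
}

#' Tissue-level prediction by majority vote over nuclei
#'
#' Each tissue receives the modal predicted nuclear class. Ties are broken
#' in favour of the tied class with the higher mean score (class
#' probability), and flagged.
#'
#' @param tissue_id per-nucleus tissue identifiers.
#' @param pred_class per-nucleus predicted classes.
#' @param score optional per-nucleus numeric matrix/data.frame of class
#'   scores (columns named by class) used for tie-breaking.
#' @return data.frame: `tissue_id`, `class`, `tie` flag.
#' @export
tissue_majority_vote <- function(tissue_id, pred_class, score = NULL) {
  stopifnot(length(tissue_id) == length(pred_class))
  out <- lapply(unique(tissue_id), function(ti) {
    idx <- which(tissue_id == ti)
    if (!length(idx)) stop("tissue_majority_vote: empty tissue ", ti)
    tab <- table(pred_class[idx])
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1L
    cls <- if (!tie) top else if (!is.null(score)) {
      ms <- vapply(top, function(cl) mean(score[idx, cl]), numeric(1))
      message(sprintf("tissue_majority_vote: tie in %s broken by mean score", ti))
      top[which.max(ms)]
    } else sort(top)[1]
    data.frame(tissue_id = ti, class = cls, tie = tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mechano-Genomic Score (MGS) of nuclei
#'
#' The MGS is the signed projection of a nucleus onto the linear
#' discriminant of the binary normal-versus-cancer LDA model, with the sign
#' fixed at scoring time so that the model's normal-like class mean projects
#' higher: a high MGS corresponds to a healthy, normal-like nucleus and low
#' values to cancer-like nuclei.
#'
#' @param model a binary `scoring_model` of kind "lda".
#' @param t feature table.
#' @param normal_class label of the normal-like class (default: first class
#'   level).
#' @return Numeric vector of per-nucleus scores.
#' @export
compute_mgs <- function(model, t, normal_class = model$classes[1]) {
  stopifnot(inherits(model, "scoring_model"))
  if (model$kind != "lda")
    stop("compute_mgs: MGS is defined on the LDA discriminant")
  if (length(model$classes) != 2L)
    stop("compute_mgs: model must be binary")
  if (!normal_class %in% model$classes)
    stop("compute_mgs: unknown normal_class")
  S <- model_scores(model, t)
  ld <- drop(stats::predict(model$classifier, S)$x[, 1])
  centers <- stats::predict(model$classifier,
                            model$classifier$means)$x[, 1]
  sgn <- if (centers[normal_class] >= centers[setdiff(model$classes, normal_class)])
    1 else -1
  sgn * ld
}

#' Pearson correlation of every feature with the MGS
#'
#' @param t feature table (>= 3 rows).
#' @param scores per-nucleus MGS values aligned to `t`.
#' @return data.frame `feature`, `pearson_r`, ranked by decreasing r;
#'   constant features get NA.
#' @export
mgs_feature_correlations <- function(t, scores) {
  stopifnot(nrow(t) >= 3L, length(scores) == nrow(t))
  fc <- feature_columns(t)
  r <- vapply(fc, function(f) {
    v <- t[[f]]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) return(NA_real_)
    suppressWarnings(stats::cor(v, scores, use = "complete.obs"))
  }, numeric(1))
  out <- data.frame(feature = fc, pearson_r = r, stringsAsFactors = FALSE)
  out[order(-out$pearson_r, na.last = TRUE), ]
}

#' Serialize / restore a scoring model
#'
#' Writes the model as JSON metadata plus a flat CSV of the numeric arrays,
#' both plain text, so models survive text-only archival.
#'
#' @param model a `scoring_model` of kind "lda".
#' @param path base path (without extension); writes `<path>.json` and
#'   `<path>_arrays.csv`.
#' @export
write_scoring_model <- function(model, path) {
  if (model$kind != "lda")
    stop("write_scoring_model: only LDA models serialize to text")
  meta <- list(kind = model$kind, classes = model$classes,
               feature_names = model$feature_names, seed = model$seed,
               explained_variance = model$explained_variance,
               training_accuracy = model$training_accuracy,
               n_components = ncol(model$rotation),
               prior = as.numeric(model$classifier$prior))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  arr <- rbind(
    data.frame(block = "mu", i = seq_along(model$mu), j = 1L, value = model$mu),
    data.frame(block = "sd", i = seq_along(model$sd), j = 1L, value = model$sd),
    data.frame(block = "rotation",
               i = rep(seq_len(nrow(model$rotation)), ncol(model$rotation)),
               j = rep(seq_len(ncol(model$rotation)), each = nrow(model$rotation)),
               value = as.numeric(model$rotation)),
    data.frame(block = "lda_scaling",
               i = rep(seq_len(nrow(model$classifier$scaling)),
                       ncol(model$classifier$scaling)),
               j = rep(seq_len(ncol(model$classifier$scaling)),
                       each = nrow(model$classifier$scaling)),
               value = as.numeric(model$classifier$scaling)),
    data.frame(block = "lda_means",
               i = rep(seq_len(nrow(model$classifier$means)),
                       ncol(model$classifier$means)),
               j = rep(seq_len(ncol(model$classifier$means)),
                       each = nrow(model$classifier$means)),
               value = as.numeric(model$classifier$means)))
  utils::write.csv(arr, paste0(path, "_arrays.csv"), row.names = FALSE)
  invisible(path)
}
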