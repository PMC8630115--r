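#' Diffusion map of per-nucleus coordinates
#'
#' Builds the Gaussian-kernel Markov transition matrix on Euclidean
#' distances, K_ij = exp(-d_ij^2 / (2 sigma^2)), applies anisotropic density
#' normalization (alpha = 1: K / (q_i q_j)), row-normalizes, and returns the
#' right eigenvectors 2..m+1 scaled by their eigenvalues as diffusion
#' components. The eigensolver is deterministic; each eigenvector's sign is
#' fixed so its largest-magnitude entry is positive.
#'
#' @param X numeric matrix (rows = nuclei), e.g. linear discriminants.
#' @param sigma Gaussian kernel width (default 0.8); `sigma = "heuristic"`
#'   uses the median distance to the `knn_sigma`-th nearest neighbour.
#' @param m number of diffusion components (default 2).
#' @param knn_sigma neighbour index for the heuristic width (default 5).
#' @return A `diffusion_embedding`: `dc` (n x m matrix DC1..DCm),
#'   `eigenvalues`, `sigma`, the input `X`, and `transition` (the Markov
#'   matrix).
#' @export
diffusion_map <- function(X, sigma = 0.8, m = 2L, knn_sigma = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < m + 2L) stop("diffusion_map: need at least m + 2 points")
  D <- as.matrix(stats::dist(X))
  if (identical(sigma, "heuristic")) {
    kd <- apply(D, 1, function(r) sort(r)[knn_sigma + 1L])
    sigma <- stats::median(kd)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("diffusion_map: sigma must be > 0")
  K <- exp(-D^2 / (2 * sigma^2))
  q <- rowSums(K)
  Kt <- K / (q %o% q)                     # alpha = 1 density normalization
  d <- rowSums(Kt)
  if (any(d < 1e-300)) warning("diffusion_map: near-isolated points")
  # symmetric conjugate S = D^{-1/2} Kt D^{-1/2}; right eigvecs of P are
  # D^{-1/2} * eigvecs(S)
  dinv <- 1 / sqrt(d)
  S <- Kt * (dinv %o% dinv)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  if (m + 1L <= n && lam[2] > 1 - 1e-12)
    warning("diffusion_map: zero spectral gap (duplicate points?)")
  psi <- eg$vectors * dinv
  dc <- matrix(0, n, m)
  for (j in seq_len(m)) {
    v <- psi[, j + 1L]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    dc[, j] <- lam[j + 1L] * v
  }
  colnames(dc) <- paste0("DC", seq_len(m))
  structure(list(dc = dc, eigenvalues = lam[seq_len(m + 1L)], sigma = sigma,
                 X = X, transition = Kt / d),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("<diffusion_embedding> n = %d, %d components, sigma = %.3g\n",
              nrow(x$dc), ncol(x$dc), x$sigma))
  invisible(x)
}

#' Sample correctly predicted nuclei for the trajectory
#'
#' Keeps only nuclei whose predicted class equals their stage label and
#' draws at most `n_per_stage` per stage (all available, with a warning,
#' when fewer). Stages with no correctly predicted nucleus are absent from
#' the result (logged).
#'
#' @param t feature table with a `stage` column.
#' @param pred_class per-nucleus predicted classes aligned to `t`.
#' @param n_per_stage per-stage sample size (default 200).
#' @param seed RNG seed.
#' @return Integer row indices into `t`.
#' @export
sample_for_trajectory <- function(t, pred_class, n_per_stage = 200L, seed = 1L) {
  stopifnot(length(pred_class) == nrow(t))
  set.seed(seed)
  correct <- which(as.character(pred_class) == as.character(t$stage))
  idx <- integer(0)
  for (st in sort(unique(t$stage))) {
    pool <- correct[t$stage[correct] == st]
    if (!length(pool)) {
      message("sample_for_trajectory: no correctly predicted nuclei in stage ", st)
      next
    }
    if (length(pool) < n_per_stage) {
      warning(sprintf("sample_for_trajectory: stage %s has %d < %d correct nuclei",
                      st, length(pool), n_per_stage))
      idx <- c(idx, pool)
    } else idx <- c(idx, sample(pool, n_per_stage))
  }
  sort(idx)
}

#' Assign trajectory branches from a diffusion embedding
#'
#' Works on the weighted k-nearest-neighbour graph of the input
#' coordinates. Detects `n_branches` tip points as mutual extrema of the
#' graph geodesic distance (first tip: farthest from the graph medoid;
#' each further tip maximizes its minimum geodesic distance to the
#' existing tips), then assigns every nucleus to the branch of the tip it
#' reaches by the shortest weighted path. Geodesic distances follow the
#' data manifold, so branch structure survives even where the spectral
#' embedding compresses a branch. Disconnected graph components are
#' assigned per component with a warning.
#'
#' @param e a `diffusion_embedding`.
#' @param n_branches number of branches (default 3).
#' @param knn_k neighbours in the k-NN graph (default 10).
#' @param stages optional per-nucleus stage labels; when given, branches
#'   are named by their dominant stage composition, otherwise "branch_1"...
#' @return List: `branch` (per-nucleus labels), `tips` (tip indices),
#'   `names` (branch name per tip).
#' @export
assign_branches <- function(e, n_branches = 3L, knn_k = 10L, stages = NULL) {
  stopifnot(inherits(e, "diffusion_embedding"))
  n <- nrow(e$dc)
  # k-NN graph on the input coordinates, symmetrized, weights = distances
  DX <- as.matrix(stats::dist(e$X))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(DX[i, ])[2:(knn_k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(ij, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- DX[ij]
  G <- igraph::distances(g)                   # geodesic distances
  finite_sum <- function(v) sum(v[is.finite(v)])
  med <- which.min(apply(G, 1, finite_sum))
  if (n_branches == 1L) {
    gmed <- G[med, ]
    gmed[!is.finite(gmed)] <- -Inf
    return(list(branch = rep("branch_1", n), tips = which.max(gmed),
                names = "branch_1"))
  }
  gmed <- G[med, ]; gmed[!is.finite(gmed)] <- -1
  tips <- which.max(gmed)
  while (length(tips) < n_branches) {
    mind <- apply(G[, tips, drop = FALSE], 1, function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) -1 else min(v)
    })
    tips <- c(tips, which.max(mind))
  }
  gd <- G[tips, , drop = FALSE]
  if (any(!is.finite(gd))) {
    warning("assign_branches: k-NN graph disconnected; assigning per component")
    gd[!is.finite(gd)] <- NA
  }
  # nearest tip by graph distance; fall back to Euclidean where unreachable
  branch_idx <- vapply(seq_len(n), function(i) {
    col <- gd[, i]
    if (all(is.na(col))) which.min(DX[tips, i]) else which.min(col)
  }, integer(1))
  nm <- if (!is.null(stages)) {
    vapply(seq_along(tips), function(b) {
      s <- stages[branch_idx == b]
      if (!length(s)) paste0("branch_", b)
      else names(sort(table(s), decreasing = TRUE))[1]
    }, character(1))
  } else paste0("branch_", seq_along(tips))
  # deduplicate names (two branches can share a dominant stage)
  nm <- make.unique(nm, sep = "_")
  list(branch = nm[branch_idx], tips = tips, names = nm)
}

#' Branch composition and per-branch feature summary
#'
#' @param branch per-nucleus branch labels.
#' @param stages per-nucleus stage labels, aligned.
#' @param t optional feature table aligned to `branch`; when given,
#'   per-branch means of z-scored features are returned for heat-map export.
#' @return List: `composition` (branch x stage fractions, rows sum to 1),
#'   `feature_means` (branch x feature matrix of z-scored means, or NULL).
#' @export
branch_composition <- function(branch, stages, t = NULL) {
  stopifnot(length(branch) == length(stages))
  tab <- table(branch, stages)
  comp <- tab / rowSums(tab)
  fm <- NULL
  if (!is.null(t)) {
    fc <- feature_columns(t)
    X <- as.matrix(t[, fc, drop = FALSE])
    keep <- apply(X, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
    Z <- scale(X[, keep, drop = FALSE])
    fm <- do.call(rbind, lapply(sort(unique(branch)), function(b)
      colMeans(Z[branch == b, , drop = FALSE])))
    rownames(fm) <- sort(unique(branch))
  }
  list(composition = comp, feature_means = fm)
}
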