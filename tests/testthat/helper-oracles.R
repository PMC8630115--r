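# Shared fixtures and independent oracles used across the suite.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  den <- (si + sj) / 2 - ex
  if (abs(den) < 1e-12) return(1)  # both partitions trivial and identical
  (sij - ex) / den
}

# binary disk mask of radius r (pixel centres within r of the centre)
disk_mask <- function(r, pad = 4L) {
  w <- 2L * ceiling(r) + 2L * pad + 1L
  ct <- (w + 1) / 2
  outer(1:w, 1:w, function(i, j) (i - ct)^2 + (j - ct)^2 <= r^2)
}

# filled axis-aligned ellipse mask, semi-axes (a, b); a along columns (x)
ellipse_mask <- function(a, b, pad = 4L) {
  w <- 2L * ceiling(a) + 2L * pad + 1L
  h <- 2L * ceiling(b) + 2L * pad + 1L
  ctr <- (h + 1) / 2; ctc <- (w + 1) / 2
  outer(1:h, 1:w, function(i, j) ((j - ctc) / a)^2 + ((i - ctr) / b)^2 <= 1)
}

# crop with constant intensity over a mask
flat_crop <- function(mask, value = 0.5, pixel_size_um = 1) {
  px <- matrix(0, nrow(mask), ncol(mask))
  px[mask] <- value
  nucleus_crop(gray_image(px, pixel_size_um), mask)
}

# brute-force GLCM statistics: explicit double loop over pixel pairs of a
# quantized crop, both pixels in-mask, symmetric, pooled over angles
glcm_oracle <- function(px, mask, d, levels, angles = c(0, 45, 90, 135)) {
  v <- px[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(px), ncol(px))
  vq <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) * 255 else rep(0, length(v))
  q[mask] <- pmin(floor(vq / 256 * levels), levels - 1L)
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
  cnt <- matrix(0, levels, levels)
  nr <- nrow(px); nc <- ncol(px)
  for (a in as.character(angles)) {
    o <- offs[[a]]
    for (r in 1:nr) for (cc in 1:nc) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(q[r, cc]) || is.na(q[r2, c2])) next
      i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
  }
  if (sum(cnt) == 0) return(NULL)
  P <- cnt / sum(cnt)
  lev <- 0:(levels - 1)
  iM <- matrix(lev, levels, levels); jM <- t(iM)
  pnz <- P[P > 0]
  mu_i <- sum(iM * P); mu_j <- sum(jM * P)
  v_i <- sum((iM - mu_i)^2 * P); v_j <- sum((jM - mu_j)^2 * P)
  corr <- if (v_i <= 1e-15 || v_j <= 1e-15) 1 else
    sum((iM - mu_i) * (jM - mu_j) * P) / sqrt(v_i * v_j)
  c(contrast = sum(P * (iM - jM)^2),
    homogeneity = sum(P / (1 + (iM - jM)^2)),
    dissimilarity = sum(P * abs(iM - jM)),
    entropy = -sum(pnz * log2(pnz)),
    asm = sum(P^2),
    correlation = corr)
}

# exhaustive-threshold Otsu oracle: the threshold t in 0..254 minimizing
# the weighted intra-class variance of the 256-bin histogram, computed
# naively per candidate threshold
otsu_oracle <- function(v) {
  b <- pmin(floor(v), 255)
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    lo <- b[b <= t]; hi <- b[b > t]
    if (!length(lo) || !length(hi)) next
    tot <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (tot < best_w - 1e-9) { best_w <- tot; best_t <- t }
  }
  best_t
}

# brute-force DBSCAN by reachability closure on a precomputed distance
# matrix: grow each unclaimed core point's cluster to its full closure
dbscan_oracle <- function(D, eps, min_pts) {
  n <- nrow(D)
  nbs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbs, length, integer(1)) >= min_pts
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != -1L) next
    cl <- cl + 1L
    memb <- i
    repeat {
      grow <- unique(unlist(nbs[memb[core[memb]]]))
      grow <- setdiff(grow, memb)
      grow <- grow[lab[grow] == -1L]
      if (!length(grow)) break
      memb <- c(memb, grow)
    }
    lab[memb] <- cl
  }
  lab
}

# combined position + axial-angle DBSCAN distance matrix
orientation_distance_matrix <- function(x, y, theta, w) {
  dth <- outer(theta, theta, axial_angle_diff)
  sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2 + (w * dth)^2)
}

# gift-wrapping convex hull area over arbitrary points (independent of
# grDevices::chull used in the implementation)
hull_area_oracle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    nxt <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
        (pts[nxt, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      if (cr < 0 || (abs(cr) < 1e-12 &&
            sum((pts[q, ] - pts[p, ])^2) > sum((pts[nxt, ] - pts[p, ])^2)))
        nxt <- q
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("hull oracle failed")
  }
  h <- pts[hull, , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# standard two-cluster + sparse-noise orientation layout used by the
# architecture recovery tests (two co-oriented groups 2000 px apart in a
# sparse 6000 px field)
planted_orientation_layout <- function(seed = 1L) {
  tissue_layout_clusters(
    data.frame(cx = c(2000, 4000), cy = c(3000, 3000), n = c(30, 30),
               theta_deg = c(20, 110), spread = c(200, 200)),
    n_noise = 50, width = 6000, height = 6000, seed = seed)
}
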