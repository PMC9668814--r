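# Independent oracles and small fixture builders.  Everything here is
# deliberately naive (loops, enumeration) and shares no code with the
# package's fast paths.

# Brute-force GLCM of a window: explicit loop over every voxel and offset.
oracle_glcm_counts <- function(window, offsets, G) {
  d <- dim(window)
  counts <- matrix(0L, G, G)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      g1 <- window[x, y, z]; g2 <- window[x2, y2, z2]
      if (g1 > 0 && g2 > 0) {
        counts[g1, g2] <- counts[g1, g2] + 1L
        counts[g2, g1] <- counts[g2, g1] + 1L
      }
    }
  }
  counts
}

# Straight-from-formula texture features of a probability matrix.
oracle_features <- function(p) {
  G <- nrow(p)
  energy <- 0; contrast <- 0; homog <- 0; entropy <- 0
  qsum <- numeric(2 * G); qdiff <- numeric(G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    pr <- p[i, j]
    energy <- energy + pr^2
    contrast <- contrast + (i - j)^2 * pr
    homog <- homog + pr / (1 + abs(i - j))
    if (pr > 0) entropy <- entropy - pr * log2(pr)
    qsum[i + j] <- qsum[i + j] + pr
    qdiff[abs(i - j) + 1] <- qdiff[abs(i - j) + 1] + pr
  }
  se <- -sum(qsum[qsum > 0] * log2(qsum[qsum > 0]))
  de <- -sum(qdiff[qdiff > 0] * log2(qdiff[qdiff > 0]))
  c(entropy = entropy, sum_entropy = se, difference_entropy = de,
    energy = energy, contrast = contrast, homogeneity = homog)
}

# Per-voxel texture map via the window oracle (independent of the C++ path).
oracle_texture_map <- function(qvol, feature, cube, G, offsets = glcm_offsets()) {
  d <- dim(qvol)
  h <- (cube - 1) / 2
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1, x - h):min(d[1], x + h)
    ys <- max(1, y - h):min(d[2], y + h)
    zs <- max(1, z - h):min(d[3], z + h)
    win <- array(qvol[xs, ys, zs], dim = c(length(xs), length(ys), length(zs)))
    counts <- oracle_glcm_counts(win, offsets, G)
    tot <- sum(counts)
    if (tot > 0) out[x, y, z] <- oracle_features(counts / tot)[[feature]]
  }
  out
}

# Direct (non-separable) truncated-Gaussian convolution with zero padding
# and local-mass renormalization, matching the smooth_3d contract.
oracle_smooth_3d <- function(img, sigma, support) {
  h <- (support - 1) / 2
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  d <- dim(img)
  out <- array(0, d); w <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    acc <- 0; wacc <- 0
    for (dz in -h:h) for (dy in -h:h) for (dx in -h:h) {
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      kv <- k3[dx + h + 1, dy + h + 1, dz + h + 1]
      if (x2 >= 1 && x2 <= d[1] && y2 >= 1 && y2 <= d[2] &&
          z2 >= 1 && z2 <= d[3]) {
        acc <- acc + kv * img[x2, y2, z2]
        wacc <- wacc + kv
      }
    }
    out[x, y, z] <- acc / wacc
  }
  out
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

# Exhaustive best exemplar set for small similarity matrices: the net
# similarity of a candidate set assigns every point to its best exemplar
# and charges each exemplar its preference.
oracle_best_net_similarity <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (m in 1:(2^n - 1)) {
    ex <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    net <- 0
    for (i in seq_len(n)) {
      net <- net + if (i %in% ex) S[i, i] else max(S[i, ex])
    }
    best <- max(best, net)
  }
  best
}

# Small helper: fraction of positive-relevance mass inside a mask.
pr_mass_fraction <- function(map, roi, brain) {
  p <- pmax(map, 0)
  sum(p[roi]) / max(sum(p[brain]), 1e-12)
}

# Tiny planted-effect cohort spec used across tests.
tiny_effect_spec <- function(magnitude, n_per_group = 8L, grid = 20L,
                             seed = 42L, groups = c("FEP", "HC")) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  cohort_spec(group_sizes = sizes, grid_shape = rep(grid, 3L),
              effect = texture_effect(magnitude = magnitude,
                                      affected_groups = "FEP"),
              seed = seed)
}

# Gaussian point clouds rendered as small maps, with ground-truth labels.
cloud_maps <- function(centers, n_each, sd = 0.05, d = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  maps <- list(); truth <- integer(0)
  for (c_i in seq_along(centers)) {
    for (j in seq_len(n_each)) {
      maps[[length(maps) + 1L]] <-
        array(centers[[c_i]] + rnorm(prod(d), sd = sd), d)
      truth <- c(truth, c_i)
    }
  }
  names(maps) <- sprintf("s%02d", seq_along(maps))
  list(maps = maps, truth = truth)
}

# Welch t with a zero-variance guard (returns 0 for two constant equal
# groups), used for the volume-independence checks.
guarded_t <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / length(a) + vb / length(b)
  if (se2 <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}
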