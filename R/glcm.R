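# 3D gray-level co-occurrence matrices and the six texture features:
# entropy, sum entropy, difference entropy, energy, contrast, homogeneity.
# Entropies are in bits (log base 2); 0*log(0) is taken as 0.

#' Names of the supported GLCM texture features
#' @export
GLCM_FEATURES <- c("entropy", "sum_entropy", "difference_entropy",
                   "energy", "contrast", "homogeneity")

#' Unique 3D co-occurrence offsets
#'
#' The 13 unique distance-`d` 3D directions (of the 26 neighbours, one per
#' +-pair; reverses are handled by symmetrized accumulation).  Uniqueness is
#' by the first non-zero component being positive.
#'
#' @param distance Chebyshev distance (default 1).
#' @return Integer matrix with 13 rows and columns `dx, dy, dz`.
#' @export
glcm_offsets <- function(distance = 1L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    length(nz) > 0 && nz[1] > 0
  })
  out <- g[keep, , drop = FALSE] * as.integer(distance)
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

validate_offsets <- function(offsets) {
  if (!is.matrix(offsets) || ncol(offsets) != 3L)
    stop("offsets must be a matrix with 3 columns")
  if (any(rowSums(offsets != 0) == 0)) stop("zero offset is not allowed")
  key <- apply(offsets, 1, paste, collapse = ",")
  neg <- apply(-offsets, 1, paste, collapse = ",")
  if (any(neg %in% key)) stop("offset set contains an offset and its negation")
  storage.mode(offsets) <- "integer"
  offsets
}

#' GLCM of a single window
#'
#' Accumulates co-occurrence counts over all voxel pairs `(v, v + offset)`
#' with both members foreground (level >= 1), over all offsets, symmetrizes,
#' and normalizes by the total count.
#'
#' @param window Integer 3D array of gray levels; 0 marks background.
#' @param offsets Offset matrix as from [glcm_offsets()].
#' @param n_levels Number of gray levels G; defaults to `max(window)`.
#' @return An object of class `glcm`: list with `p` (G x G probability
#'   matrix) and `pair_count` (number of unordered contributing pairs).
#' @export
glcm_from_window <- function(window, offsets = glcm_offsets(), n_levels = NULL) {
  d <- dim(window)
  if (is.null(d) || length(d) != 3L) stop("window must be a 3D array")
  if (min(d) < 1L || max(d) < 2L) stop("window edge must be >= 2 on some axis")
  offsets <- validate_offsets(offsets)
  G <- if (is.null(n_levels)) max(window, 1L) else as.integer(n_levels)
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    from <- pmax(1L, 1L - o)
    to <- pmin(d, d - o)
    if (any(from > to)) next
    i1 <- lapply(1:3, function(a) from[a]:to[a])
    i2 <- lapply(1:3, function(a) (from[a] + o[a]):(to[a] + o[a]))
    g1 <- window[i1[[1]], i1[[2]], i1[[3]]]
    g2 <- window[i2[[1]], i2[[2]], i2[[3]]]
    ok <- g1 > 0 & g2 > 0
    if (!any(ok)) next
    t1 <- g1[ok]; t2 <- g2[ok]
    for (k in seq_along(t1)) {
      counts[t1[k], t2[k]] <- counts[t1[k], t2[k]] + 1
      counts[t2[k], t1[k]] <- counts[t2[k], t1[k]] + 1
    }
  }
  pair_count <- sum(counts) / 2
  p <- if (pair_count > 0) counts / sum(counts) else counts
  structure(list(p = p, pair_count = pair_count, n_levels = G), class = "glcm")
}

#' Scalar texture feature of a GLCM
#'
#' With `p` the normalized co-occurrence probabilities over levels `1..G`:
#' `energy = sum p^2`; `contrast = sum (g1-g2)^2 p`;
#' `homogeneity = sum p / (1 + |g1-g2|)` (inverse difference);
#' `entropy = -sum p log2 p`; sum/difference entropies are the entropies of
#' the distributions of `g1+g2` and `|g1-g2|`.
#'
#' @param glcm A `glcm` object (or a bare probability matrix).
#' @param feature_name One of [GLCM_FEATURES].
#' @return Scalar; `NA` when the GLCM had no contributing pair.
#' @export
feature_from_glcm <- function(glcm, feature_name) {
  feature_name <- match.arg(feature_name, GLCM_FEATURES)
  if (inherits(glcm, "glcm")) {
    if (glcm$pair_count == 0) return(NA_real_)
    p <- glcm$p
  } else p <- glcm
  G <- nrow(p)
  g1 <- row(p); g2 <- col(p)
  xlogx <- function(q) ifelse(q > 0, q * log2(q), 0)
  switch(feature_name,
    energy = sum(p^2),
    contrast = sum((g1 - g2)^2 * p),
    homogeneity = sum(p / (1 + abs(g1 - g2))),
    entropy = -sum(xlogx(p)),
    sum_entropy = {
      q <- tapply(p, g1 + g2, sum)
      -sum(xlogx(q))
    },
    difference_entropy = {
      q <- tapply(p, abs(g1 - g2), sum)
      -sum(xlogx(q))
    })
}

#' Voxel-wise sliding-cube texture feature maps
#'
#' For every voxel, the GLCM of the centred `cube_size`^3 window (cropped at
#' volume boundaries) is computed and the requested features are evaluated
#' and mapped to the window centre.  Windows contributing no foreground pair
#' yield 0.
#'
#' @param qvol Integer 3D array of gray levels (0 = background), e.g. from
#'   [quantize_volume()].
#' @param features Character vector of feature names (default all six).
#' @param cube_size Odd window edge, >= 3 (default 7).
#' @param offsets Offset matrix (default the 13 unique distance-1
#'   directions).
#' @param n_levels Number of gray levels; defaults to the `n_bins` attribute
#'   or `max(qvol)`.
#' @return A named list of 3D numeric arrays, one per requested feature.
#' @export
texture_maps <- function(qvol, features = GLCM_FEATURES, cube_size = 7L,
                         offsets = glcm_offsets(), n_levels = NULL) {
  d <- dim(qvol)
  if (is.null(d) || length(d) != 3L) stop("qvol must be a 3D array")
  cube_size <- as.integer(cube_size)
  if (cube_size < 3L || cube_size %% 2L == 0L)
    stop("cube_size must be odd and >= 3")
  if (any(cube_size > d)) stop("cube larger than volume")
  features <- vapply(features, match.arg, "", choices = GLCM_FEATURES)
  offsets <- validate_offsets(offsets)
  G <- if (!is.null(n_levels)) as.integer(n_levels)
       else if (!is.null(attr(qvol, "n_bins"))) attr(qvol, "n_bins")
       else max(qvol, 1L)
  vol <- as.integer(qvol)
  if (min(vol) < 0L || max(vol) > G) stop("gray levels must lie in 0..n_levels")
  res <- .texture_maps_cpp(vol, d, G, offsets, cube_size)
  out <- lapply(res[features], function(v) array(v, dim = d))
  names(out) <- features
  out
}

#' Single texture feature map
#'
#' Convenience wrapper around [texture_maps()] for one feature.
#'
#' @inheritParams texture_maps
#' @param feature_name One of [GLCM_FEATURES].
#' @return A 3D numeric array with attribute `feature_name`.
#' @export
texture_map <- function(qvol, feature_name, cube_size = 7L,
                        offsets = glcm_offsets(), n_levels = NULL) {
  m <- texture_maps(qvol, features = feature_name, cube_size = cube_size,
                    offsets = offsets, n_levels = n_levels)[[1]]
  attr(m, "feature_name") <- feature_name
  m
}

#' Smooth a texture feature map
#'
#' Gaussian smoothing truncated to a cubic support (default the 7x7x7
#' smoother applied to feature maps), with the background re-zeroed after
#' smoothing.
#'
#' @param map 3D numeric array.
#' @param mask Foreground mask; voxels outside are reset to 0 (default: the
#'   non-zero voxels of `map` itself).
#' @param support Odd cubic support edge (default 7).
#' @param sigma Gaussian sigma in voxels (default 1.0).
#' @return Smoothed 3D array.
#' @export
smooth_map <- function(map, mask = NULL, support = 7L, sigma = 1.0) {
  if (is.null(mask)) mask <- map != 0
  smooth_3d(map, sigma = sigma, support = support, mask = mask)
}
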