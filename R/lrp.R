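# Layer-wise relevance propagation (epsilon rule) through the trained tanh
# MLP, and assembly of per-subject relevance heatmaps.  Relevance starts at
# the output score and is redistributed layer by layer to each unit's inputs
# in proportion to their signed pre-activation contributions
# z_ij = w_ij * a_i, stabilized by epsilon * sign(z_j).  The bias term's
# share is absorbed (dropped), which is the documented conservation leak.

#' LRP propagation rule
#'
#' @param epsilon Positive stabilizer added (sign-matched) to each unit's
#'   pre-activation denominator.
#' @param relative If `TRUE`, the stabilizer is `epsilon * |z_j|` — i.e.
#'   epsilon is expressed on the scale of each denominator, which keeps the
#'   conservation leak at about `n_layers * epsilon` relative regardless of
#'   the score magnitude.  Default `FALSE` (absolute epsilon).
#' @return An object of class `lrp_rule`.
#' @export
lrp_rule <- function(epsilon = 1e-6, relative = FALSE) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(variant = "epsilon", epsilon = epsilon,
                 relative = isTRUE(relative)), class = "lrp_rule")
}

#' Input relevances of a prediction
#'
#' Runs the forward pass for one subject (applying the model's stored
#' feature selection and standardization) and propagates the output score
#' back to the model's input features with the epsilon rule.
#'
#' @param model A `braintex_mlp`.
#' @param x Feature vector on the design-matrix columns the model was fit
#'   in (pre-selection when the model stores `selected_features`).
#' @param rule An [lrp_rule()].
#' @return Numeric vector of relevances over the model's input features
#'   (length `layer_sizes[1]`), with attribute `score` (the output score).
#' @export
lrp <- function(model, x, rule = lrp_rule()) {
  if (!inherits(model, "braintex_mlp")) stop("model must be a braintex_mlp")
  x <- as.numeric(x)
  if (!is.null(model$selected_features)) {
    if (max(model$selected_features) > length(x))
      stop("x is shorter than the model's feature indices")
    x <- x[model$selected_features]
  }
  if (length(x) != model$layer_sizes[1L])
    stop("x dimension does not match the model input")
  if (!is.null(model$center)) x <- (x - model$center) / model$scale
  A <- mlp_forward(model$weights, model$biases, matrix(x, nrow = 1L))
  L <- length(model$weights)
  R <- as.numeric(A[[L + 1L]])                    # relevance starts at the score
  score <- R
  eps <- rule$epsilon
  for (l in rev(seq_len(L))) {
    a <- as.numeric(A[[l]])                       # inputs of layer l
    W <- model$weights[[l]]
    Z <- W * a                                    # z_ij = w_ij * a_i
    zj <- colSums(Z) + model$biases[[l]]
    eps_j <- if (isTRUE(rule$relative)) eps * abs(zj) else eps
    denom <- zj + eps_j * ifelse(zj >= 0, 1, -1)
    denom[denom == 0] <- 1               # dead unit: no relevance to pass
    R <- as.numeric(Z %*% (R / denom))
    if (!all(is.finite(R)))
      stop("non-finite relevance while propagating through layer ", l)
  }
  attr(R, "score") <- score
  R
}

#' Scatter a relevance vector onto the volume grid
#'
#' @param rel Relevance vector over selected features.
#' @param voxel_index Linear voxel index per relevance entry (the design
#'   matrix `voxel_index` subset by the model's `selected_features`).
#' @param grid Length-3 grid dimensions.
#' @return 3D array, 0 outside the selected-feature support.
#' @export
relevance_to_map <- function(rel, voxel_index, grid) {
  if (length(rel) != length(voxel_index))
    stop("rel and voxel_index lengths differ")
  if (any(voxel_index < 1 | voxel_index > prod(grid)))
    stop("voxel index outside the grid")
  map <- array(0, dim = grid)
  map[voxel_index] <- rel
  map
}

#' Positive part of a relevance map
#'
#' @param map 3D numeric array (or vector).
#' @return Same shape with negative values clipped to 0.
#' @export
positive_relevance <- function(map) pmax(map, 0)

#' Smooth a relevance map
#'
#' Either a fixed cubic support (default the 7x7x7 figure-stage kernel,
#' sigma 1 voxel) or a stated FWHM in mm (sigma = FWHM / 2.3548 / voxel).
#'
#' @param map 3D numeric array.
#' @param support Odd cubic support edge; ignored when `fwhm_mm` is given.
#' @param fwhm_mm Optional full width at half maximum in mm.
#' @param voxel_size_mm Voxel edge in mm (used with `fwhm_mm`).
#' @param mask Optional foreground mask re-zeroed after smoothing.
#' @return Smoothed 3D array.
#' @export
smooth_relevance <- function(map, support = 7L, fwhm_mm = NULL,
                             voxel_size_mm = 1, mask = NULL) {
  if (!is.null(fwhm_mm)) {
    sigma <- fwhm_to_sigma(fwhm_mm, voxel_size_mm)
    support <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                   2L * (min(dim(map)) %/% 2L) - 1L)
  } else sigma <- 1.0
  smooth_3d(map, sigma = sigma, support = support, mask = mask)
}

#' Per-subject relevance heatmaps from a nested-CV result
#'
#' For every outer model, scores the subjects it held out; for the subjects
#' it classified correctly, computes input relevances and scatters them onto
#' the grid.  A subject's heatmap is the average over all models that held
#' it out and classified it correctly (mirroring "correctly classified
#' hold-out subjects").
#'
#' @param result A `braintex_cv` from [nested_cv()].
#' @param design A design-matrix object from [build_design_matrix()].
#' @param y Labels in `{+1, -1}` aligned with `design$X` rows.
#' @param rule An [lrp_rule()].
#' @return A list with `maps` (named list of 3D arrays, only subjects
#'   correctly classified at least once) and `n_contributions` (named
#'   integer vector).
#' @export
subject_relevance_maps <- function(result, design, y, rule = lrp_rule()) {
  n <- nrow(design$X)
  acc <- vector("list", n)
  cnt <- integer(n)
  for (model in result$models) {
    held <- model$held_out
    pred <- predict(model, design$X[held, , drop = FALSE])
    for (j in seq_along(held)) {
      i <- held[j]
      if (pred$labels[j] != y[i]) next
      rel <- lrp(model, design$X[i, ], rule)
      map <- relevance_to_map(rel, design$voxel_index[model$selected_features],
                              design$grid)
      acc[[i]] <- if (is.null(acc[[i]])) map else acc[[i]] + map
      cnt[i] <- cnt[i] + 1L
    }
  }
  keep <- which(cnt > 0L)
  maps <- lapply(keep, function(i) acc[[i]] / cnt[i])
  names(maps) <- rownames(design$X)[keep]
  list(maps = maps, n_contributions = stats::setNames(cnt[keep],
                                                      rownames(design$X)[keep]))
}
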