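# Synthetic phantom cohorts with planted, texture-only group differences.
#
# Phantoms are brain-shaped three-compartment volumes (CSF-like < GM-like <
# WM-like nested bands) plus spatially correlated subject noise.  Group
# effects are planted inside known ROI masks by operations that alter local
# co-occurrence structure while leaving first-order ROI statistics (voxel
# count, histogram, mean) untouched -- the texture-only contract that lets
# downstream classification be attributed to texture rather than volume.

GROUP_LEVELS <- c("FEP", "CHR_NT", "CHR_T", "HC")

#' Describe a planted texture effect
#'
#' @param kind Effect family: `"pair-shuffle"` permutes intensities within
#'   small blocks inside the ROI (exactly histogram-preserving);
#'   `"correlation-length-shift"` rank-remaps a fraction of ROI voxels onto a
#'   white-noise ordering (also a permutation); `"checker-mix"` adds a
#'   zero-sum high-frequency checkerboard component (mean-preserving, not
#'   histogram-preserving).
#' @param magnitude Effect size in `[0, 1]`; 0 is the exact identity.
#' @param affected_groups Character vector of group labels that receive the
#'   effect.
#' @param block_size Edge of the shuffle blocks for `"pair-shuffle"` (voxels).
#' @return An object of class `texture_effect`.
#' @export
texture_effect <- function(kind = c("pair-shuffle", "correlation-length-shift",
                                    "checker-mix"),
                           magnitude = 0.8,
                           affected_groups = c("FEP", "CHR_T"),
                           block_size = 6L) {
  kind <- match.arg(kind)
  if (magnitude < 0 || magnitude > 1) stop("magnitude must lie in [0, 1]")
  if (block_size < 2) stop("block_size must be >= 2")
  structure(list(kind = kind, magnitude = magnitude,
                 affected_groups = affected_groups,
                 block_size = as.integer(block_size)),
            class = "texture_effect")
}

#' Specify a synthetic phantom cohort
#'
#' Defaults mirror the study design this generator emulates: group sizes
#' FEP = 77, CHR_NT = 58, CHR_T = 15, HC = 44 (194 subjects), isotropic 1 mm
#' voxels.  The default grid is a desk-scale 48^3; ROI masks default to one
#' ellipsoidal region placed in the gray-matter band, strictly inside the
#' brain mask.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param grid_shape Length-3 integer vector of voxels per axis.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param roi_masks Named list of logical 3D arrays (effect-planting ROIs);
#'   `NULL` builds the default single ROI for the grid.
#' @param effect A [texture_effect()].
#' @param noise_sd Standard deviation of the correlated subject noise, on the
#'   intensity scale of the compartments (which span about 0.3-0.8).
#' @param seed Master integer seed; per-subject streams are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(FEP = 77, CHR_NT = 58, CHR_T = 15, HC = 44),
                        grid_shape = c(48L, 48L, 48L),
                        voxel_size_mm = 1.0,
                        roi_masks = NULL,
                        effect = texture_effect(),
                        noise_sd = 0.05,
                        seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 0)) stop("all group counts must be >= 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("grid_shape must be three positive integers")
  if (!inherits(effect, "texture_effect")) stop("effect must be a texture_effect")
  spec <- structure(list(group_sizes = group_sizes, grid_shape = grid_shape,
                         voxel_size_mm = voxel_size_mm, roi_masks = roi_masks,
                         effect = effect, noise_sd = noise_sd,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  if (is.null(spec$roi_masks))
    spec$roi_masks <- list(planted = default_roi_mask(grid_shape))
  bm <- brain_mask(grid_shape)
  if (!any(bm)) stop("configuration error: empty brain mask")
  for (nm in names(spec$roi_masks)) {
    m <- spec$roi_masks[[nm]] > 0
    if (!all(dim(m) == grid_shape)) stop("ROI '", nm, "' does not match grid_shape")
    if (any(m & !bm)) stop("ROI '", nm, "' extends outside the brain mask")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      sprintf("(n=%d)\n", sum(x$group_sizes)))
  cat(sprintf("  grid %s, voxel %.2f mm, noise sd %.3f, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              x$noise_sd, x$seed))
  cat(sprintf("  effect: %s, magnitude %.2f, groups {%s}, ROIs {%s}\n",
              x$effect$kind, x$effect$magnitude,
              paste(x$effect$affected_groups, collapse = ", "),
              paste(names(x$roi_masks), collapse = ", ")))
  invisible(x)
}

# squared normalized ellipsoidal radius of every voxel
ellipsoid_r2 <- function(grid_shape, center, semi_axes) {
  x <- (seq_len(grid_shape[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(grid_shape[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(grid_shape[3]) - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Brain mask of the phantom geometry
#'
#' @param grid_shape Length-3 integer vector.
#' @return Logical 3D array, TRUE inside the outer ellipsoid.
#' @export
brain_mask <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  ellipsoid_r2(grid_shape, c0, 0.44 * grid_shape) <= 1
}

default_roi_mask <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  center <- c0 + c(round(grid_shape[1] / 6), 0, 0)
  r <- pmax(2, round(grid_shape / 6))
  mask <- ellipsoid_r2(grid_shape, center, r) <= 1
  mask & brain_mask(grid_shape)
}

# Deterministic per-subject seed stream: a fixed-multiplier counter scheme on
# the master seed, folded into the 31-bit range R accepts.
subject_seed <- function(master_seed, subject_index, stream = 0L) {
  val <- (as.double(master_seed) * 48271 + subject_index * 7919 + stream * 104729)
  as.integer(val %% 2147483647)
}

cohort_table <- function(spec) {
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  within <- unlist(lapply(spec$group_sizes, seq_len), use.names = FALSE)
  data.frame(subject_id = sprintf("%s_%03d", groups, within),
             group = groups, stringsAsFactors = FALSE)
}

phantom_base <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  r2 <- ellipsoid_r2(grid_shape, c0, 0.44 * grid_shape)
  img <- array(0, dim = grid_shape)
  img[r2 <= 1] <- 0.30                     # CSF-like rim
  img[r2 <= 0.80] <- 0.55                  # GM-like band
  img[r2 <= 0.35] <- 0.80                  # WM-like core
  # smooth the steps so compartments have soft borders, then re-zero outside
  smooth_3d(img, sigma = 1.0, support = 5L, mask = r2 <= 1)
}

#' Generate one phantom volume
#'
#' Deterministic in `(spec$seed, subject_index)`.  The subject's group
#' determines whether the cohort's texture effect is applied inside the ROI
#' masks.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Integer in `1..sum(group_sizes)`.
#' @return 3D numeric array with attributes `subject_id` and `group`.
#' @export
make_phantom <- function(spec, subject_index) {
  tab <- cohort_table(spec)
  if (subject_index < 1 || subject_index > nrow(tab))
    stop("subject_index out of range (cohort has ", nrow(tab), " subjects)")
  base <- phantom_base(spec$grid_shape)
  mask <- base > 0
  rng <- subject_seed(spec$seed, subject_index)
  set.seed(rng)
  noise <- smooth_3d(array(stats::rnorm(prod(spec$grid_shape)), spec$grid_shape),
                     sigma = 1.0, support = 5L, renormalize = FALSE)
  noise <- noise / stats::sd(noise) * spec$noise_sd
  vol <- base
  vol[mask] <- vol[mask] + noise[mask]
  group <- tab$group[subject_index]
  if (group %in% spec$effect$affected_groups && spec$effect$magnitude > 0) {
    for (m in spec$roi_masks)
      vol <- plant_texture_effect(vol, m, spec$effect)
  }
  attr(vol, "subject_id") <- tab$subject_id[subject_index]
  attr(vol, "group") <- group
  attr(vol, "voxel_size") <- rep(spec$voxel_size_mm, 3)
  vol
}

#' Plant a texture effect inside an ROI
#'
#' Rearranges or perturbs voxel values inside `mask` so that local spatial
#' autocorrelation changes monotonically with `effect$magnitude`, while the
#' ROI histogram (hence mean intensity and voxel count) is exactly preserved
#' for the permutation-based kinds.  Uses the current RNG state; seed before
#' calling for reproducibility (cohort generators do this per subject).
#'
#' @param vol 3D numeric array.
#' @param mask Logical/0-1 array of the same shape.
#' @param effect A [texture_effect()].
#' @return The modified volume (attributes preserved).
#' @export
plant_texture_effect <- function(vol, mask, effect) {
  if (!all(dim(vol) == dim(mask))) stop("mask must match volume dimensions")
  mask <- mask > 0
  if (!any(mask)) {
    warning("empty ROI mask: effect is a no-op")
    return(vol)
  }
  if (effect$magnitude == 0) return(vol)
  out <- vol
  idx <- which(mask)
  coords <- arrayInd(idx, dim(vol))
  if (effect$kind == "pair-shuffle") {
    block <- effect$block_size
    key <- paste(ceiling(coords[, 1] / block),
                 ceiling(coords[, 2] / block),
                 ceiling(coords[, 3] / block))
    for (b in split(idx, key)) {
      if (length(b) >= 2 && stats::runif(1) < effect$magnitude)
        out[b] <- out[b][sample.int(length(b))]
    }
  } else if (effect$kind == "correlation-length-shift") {
    take <- stats::runif(length(idx)) < effect$magnitude
    sub <- idx[take]
    if (length(sub) >= 2) {
      w <- stats::rnorm(length(sub))
      out[sub] <- sort(out[sub])[rank(w, ties.method = "first")]
    }
  } else if (effect$kind == "checker-mix") {
    checker <- (-1)^(coords[, 1] + coords[, 2] + coords[, 3])
    amp <- stats::sd(vol[idx])
    comp <- effect$magnitude * amp * checker
    comp <- comp - mean(comp)            # exact ROI-mean preservation
    out[idx] <- vol[idx] + comp
  }
  out
}

#' Generate a whole cohort in memory
#'
#' @param spec A [cohort_spec()].
#' @return A list with `volumes` (named list of 3D arrays) and `table`
#'   (data.frame `subject_id`, `group`).
#' @export
simulate_cohort <- function(spec) {
  tab <- cohort_table(spec)
  vols <- lapply(seq_len(nrow(tab)), function(i) make_phantom(spec, i))
  names(vols) <- tab$subject_id
  list(volumes = vols, table = tab)
}

#' Write a cohort to disk as NIfTI + TSV
#'
#' Writes one `.nii.gz` per subject, a subject table
#' (`subjects.tsv`: `subject_id<TAB>group`) and a JSON manifest with the
#' generating parameters, seed and per-file MD5 checksums.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the subject table with a `volume_path` column, in
#'   table order.
#' @export
write_cohort <- function(spec, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  tab <- cohort_table(spec)
  tab$volume_path <- file.path(out_dir, paste0(tab$subject_id, ".nii.gz"))
  for (i in seq_len(nrow(tab))) {
    vol <- make_phantom(spec, i)
    write_nifti(vol, tab$volume_path[i], voxel_size = spec$voxel_size_mm)
  }
  utils::write.table(tab[, c("subject_id", "group")],
                     file.path(out_dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    group_sizes = as.list(spec$group_sizes),
    grid_shape = spec$grid_shape,
    voxel_size_mm = spec$voxel_size_mm,
    noise_sd = spec$noise_sd,
    seed = spec$seed,
    effect = spec$effect[c("kind", "magnitude", "affected_groups", "block_size")],
    rois = names(spec$roi_masks),
    checksums = as.list(tools::md5sum(tab$volume_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tab)
}
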