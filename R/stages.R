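# Stage-wise disk interface: each stage reads the previous stage's on-disk
# outputs and writes its own, so any stage can be re-run in isolation.  The
# in-memory path (run_pipeline) is the primary engine; these wrappers share
# its building blocks.

read_stage_json <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p)) stop("missing stage metadata: ", p)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

copy_subject_table <- function(in_dir, out_dir) {
  file.copy(file.path(in_dir, "subjects.tsv"),
            file.path(out_dir, "subjects.tsv"), overwrite = TRUE)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  dir
}

#' Equalize and quantize a cohort directory
#'
#' Reads raw volumes, histogram-equalizes, quantizes to `n_bins` gray
#' levels, and writes per-subject quantized volumes (int16 NIfTI) plus the
#' 256-entry equalization LUTs (CSV) for audit.
#'
#' @param in_dir Cohort directory (`subjects.tsv` + NIfTI volumes).
#' @param out_dir Output directory.
#' @param n_bins Even integer in `[2, 256]`.
#' @return `out_dir`, invisibly.
#' @export
stage_prep <- function(in_dir, out_dir, n_bins = 16L) {
  cohort <- load_cohort(in_dir)
  ensure_dir(out_dir)
  for (id in cohort$table$subject_id) {
    eq <- equalize(cohort$volumes[[id]])
    q <- quantize_volume(eq$volume, n_bins)
    write_nifti(q, file.path(out_dir, paste0(id, ".nii.gz")),
                datatype = "int16")
    write_equalization_lut(eq$transform,
                           file.path(out_dir, paste0(id, "_lut.csv")))
  }
  copy_subject_table(in_dir, out_dir)
  jsonlite::write_json(list(n_bins = as.integer(n_bins)),
                       file.path(out_dir, "prep.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Compute texture feature maps for a prepared cohort directory
#'
#' @param in_dir Output of [stage_prep()].
#' @param out_dir Output directory; one NIfTI per (subject, feature), named
#'   `{subject}_{feature}.nii.gz`.
#' @param features Feature names (default all six).
#' @param cube_size Sliding-cube edge (default 7).
#' @param smooth Apply the 7x7x7 Gaussian map smoother (default TRUE).
#' @return `out_dir`, invisibly.
#' @export
stage_texture <- function(in_dir, out_dir, features = GLCM_FEATURES,
                          cube_size = 7L, smooth = TRUE) {
  meta <- read_stage_json(in_dir, "prep.json")
  cohort <- load_cohort(in_dir)
  ensure_dir(out_dir)
  for (id in cohort$table$subject_id) {
    q <- array(as.integer(round(cohort$volumes[[id]])),
               dim = dim(cohort$volumes[[id]]))
    maps <- texture_maps(q, features = features, cube_size = cube_size,
                         n_levels = meta$n_bins)
    for (feat in names(maps)) {
      m <- if (smooth) smooth_map(maps[[feat]], mask = q > 0) else maps[[feat]]
      write_nifti(m, file.path(out_dir, sprintf("%s_%s.nii.gz", id, feat)))
    }
  }
  copy_subject_table(in_dir, out_dir)
  jsonlite::write_json(list(n_bins = meta$n_bins, cube_size = cube_size,
                            features = features, smoothed = smooth,
                            offsets = glcm_offsets()),
                       file.path(out_dir, "texture.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

serialize_mlp <- function(model) {
  list(layer_sizes = model$layer_sizes,
       weights = lapply(model$weights, function(w)
         list(dim = dim(w), data = as.numeric(w))),
       biases = model$biases,
       l2_lambda = model$l2_lambda,
       selected_features = model$selected_features,
       center = model$center, scale = model$scale,
       held_out = model$held_out)
}

deserialize_mlp <- function(obj) {
  structure(list(
    weights = lapply(obj$weights, function(w) {
      d <- as.integer(unlist(w$dim))
      matrix(as.numeric(unlist(w$data)), d[1], d[2])
    }),
    biases = lapply(obj$biases, function(b) as.numeric(unlist(b))),
    layer_sizes = as.integer(unlist(obj$layer_sizes)),
    l2_lambda = obj$l2_lambda,
    losses = NA_real_, epochs = NA_integer_,
    selected_features = as.integer(unlist(obj$selected_features)),
    center = as.numeric(unlist(obj$center)),
    scale = as.numeric(unlist(obj$scale)),
    held_out = as.integer(unlist(obj$held_out))), class = "braintex_mlp")
}

load_feature_maps <- function(dir, feature, ids) {
  maps <- lapply(ids, function(id)
    read_nifti(file.path(dir, sprintf("%s_%s.nii.gz", id, feature))))
  names(maps) <- ids
  maps
}

#' Train nested-CV classifiers from a texture-map directory
#'
#' One independent nested cross-validation per feature; writes per-feature
#' fold metrics (`{feature}_cv.json`), the outer-model registry
#' (`{feature}_models.json`, versioned schema) and a combined `metrics.tsv`
#' mirroring the per-feature metrics-table layout.
#'
#' @param in_dir Output of [stage_texture()].
#' @param out_dir Output directory.
#' @param schema `"a"` (FEP vs HC) or `"b"` (FEP vs CHR_NT).
#' @param cv A [cv_config()].
#' @return `out_dir`, invisibly.
#' @export
stage_train <- function(in_dir, out_dir, schema = c("a", "b"),
                        cv = cv_config()) {
  schema <- match.arg(schema)
  meta <- read_stage_json(in_dir, "texture.json")
  tab <- utils::read.delim(file.path(in_dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
  y_all <- schema_labels(tab$group, schema)
  in_schema <- !is.na(y_all)
  ensure_dir(out_dir)
  rows <- list()
  for (feat in meta$features) {
    maps <- load_feature_maps(in_dir, feat, tab$subject_id)
    design <- build_design_matrix(maps)
    res <- nested_cv(design$X[in_schema, , drop = FALSE], y_all[in_schema], cv)
    agg <- res$aggregate
    rows[[feat]] <- data.frame(feature = feat,
                               balanced_accuracy = agg[["balanced_accuracy"]],
                               sensitivity = agg[["sensitivity"]],
                               specificity = agg[["specificity"]])
    jsonlite::write_json(list(schema = schema, feature = feat,
                              folds = res$folds,
                              aggregate = as.list(agg),
                              n_models = res$n_models,
                              config = unclass(res$config)),
                         file.path(out_dir, sprintf("%s_cv.json", feat)),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(format_version = 1L, feature = feat,
                              schema = schema,
                              voxel_index = design$voxel_index,
                              grid = design$grid,
                              models = lapply(res$models, serialize_mlp)),
                         file.path(out_dir, sprintf("%s_models.json", feat)),
                         auto_unbox = TRUE, digits = NA)
  }
  metrics <- do.call(rbind, rows)
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  copy_subject_table(in_dir, out_dir)
  jsonlite::write_json(list(schema = schema, features = meta$features),
                       file.path(out_dir, "train.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Compute relevance heatmaps from trained models
#'
#' Loads the model registry and texture maps, computes epsilon-rule LRP
#' heatmaps for correctly classified hold-out subjects, clips to positive
#' relevance, smooths, and writes `{subject}_{feature}_PR.nii.gz` plus an
#' index linking subjects to contributing models.
#'
#' @param train_dir Output of [stage_train()].
#' @param texture_dir Output of [stage_texture()].
#' @param out_dir Output directory.
#' @param rule An [lrp_rule()].
#' @param fwhm_mm Relevance smoothing FWHM in mm (default 10).
#' @return `out_dir`, invisibly.
#' @export
stage_explain <- function(train_dir, texture_dir, out_dir,
                          rule = lrp_rule(), fwhm_mm = 10) {
  meta <- read_stage_json(train_dir, "train.json")
  tab <- utils::read.delim(file.path(train_dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
  y_all <- schema_labels(tab$group, meta$schema)
  in_schema <- !is.na(y_all)
  ensure_dir(out_dir)
  index <- list()
  for (feat in meta$features) {
    reg <- jsonlite::read_json(file.path(train_dir,
                                         sprintf("%s_models.json", feat)),
                               simplifyVector = FALSE)
    maps <- load_feature_maps(texture_dir, feat, tab$subject_id)
    voxel_index <- as.integer(unlist(reg$voxel_index))
    grid <- as.integer(unlist(reg$grid))
    X <- t(vapply(maps, function(m) m[voxel_index],
                  numeric(length(voxel_index))))
    rownames(X) <- tab$subject_id
    design <- list(X = X[in_schema, , drop = FALSE],
                   voxel_index = voxel_index, grid = grid)
    result <- list(models = lapply(reg$models, deserialize_mlp))
    rel <- subject_relevance_maps(result, design, y_all[in_schema], rule)
    for (id in names(rel$maps)) {
      pr <- smooth_relevance(positive_relevance(rel$maps[[id]]),
                             fwhm_mm = fwhm_mm)
      write_nifti(pr, file.path(out_dir, sprintf("%s_%s_PR.nii.gz", id, feat)))
    }
    index[[feat]] <- as.list(rel$n_contributions)
  }
  copy_subject_table(train_dir, out_dir)
  jsonlite::write_json(list(features = meta$features, fwhm_mm = fwhm_mm,
                            epsilon = rule$epsilon,
                            n_correct_models = index),
                       file.path(out_dir, "explain.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Cluster positive-relevance heatmaps
#'
#' Affinity propagation on the `{subject}_{feature}_PR.nii.gz` maps of a
#' directory; writes per-feature membership tables
#' (`subject_id  cluster  exemplar_id`) and cluster-average mean maps.
#'
#' @param in_dir Output of [stage_explain()].
#' @param out_dir Output directory.
#' @param damping,max_iter,stable_iter Affinity-propagation parameters.
#' @return `out_dir`, invisibly.
#' @export
stage_cluster <- function(in_dir, out_dir, damping = 0.9, max_iter = 1000L,
                          stable_iter = 100L) {
  meta <- read_stage_json(in_dir, "explain.json")
  ensure_dir(out_dir)
  run_meta <- list()
  for (feat in meta$features) {
    files <- list.files(in_dir, pattern = sprintf("_%s_PR\\.nii\\.gz$", feat),
                        full.names = TRUE)
    if (length(files) == 0L) next
    ids <- sub(sprintf("_%s_PR\\.nii\\.gz$", feat), "", basename(files))
    maps <- lapply(files, read_nifti)
    names(maps) <- ids
    S <- similarity_matrix(maps)
    ap <- affinity_propagation(S, damping = damping, max_iter = max_iter,
                               stable_iter = stable_iter)
    rep <- cluster_report(maps, ap)
    utils::write.table(rep$membership,
                       file.path(out_dir, sprintf("%s_membership.tsv", feat)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cl in names(rep$mean_maps))
      write_nifti(rep$mean_maps[[cl]],
                  file.path(out_dir, sprintf("%s_%s_mean.nii.gz", feat, cl)))
    run_meta[[feat]] <- list(n_clusters = length(rep$mean_maps),
                             converged = ap$converged,
                             iterations = ap$iterations)
  }
  jsonlite::write_json(list(damping = damping, max_iter = max_iter,
                            stable_iter = stable_iter, results = run_meta),
                       file.path(out_dir, "cluster.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
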