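# End-to-end orchestration: equalize -> quantize -> texture maps -> nested
# CV per feature -> LRP on correctly classified hold-out subjects ->
# positive-relevance clustering -> external validation of the held-out
# clinical-high-risk group.  Features are always analyzed one at a time and
# never concatenated.

SCHEMA_GROUPS <- list(a = c(positive = "FEP", negative = "HC"),
                      b = c(positive = "FEP", negative = "CHR_NT"))
EXTERNAL_GROUP <- "CHR_T"

#' Pipeline run configuration
#'
#' @param cohort Either a [cohort_spec()] (synthetic cohort, generated in
#'   memory) or a directory containing per-subject NIfTI volumes and a
#'   `subjects.tsv` table.
#' @param n_bins Gray levels after quantization (default 16).
#' @param cube_size GLCM sliding-cube edge (default 7).
#' @param features Texture features to analyze (default all six).
#' @param schema `"a"` (FEP vs HC) or `"b"` (FEP vs CHR_NT); the CHR_T group
#'   is externally validated in both when present.
#' @param cv A [cv_config()].
#' @param lrp An [lrp_rule()].
#' @param relevance_fwhm_mm FWHM of the final relevance smoothing (mm).
#' @param ap_damping,ap_max_iter,ap_stable_iter Affinity-propagation
#'   parameters.
#' @param out_dir Optional output directory for reports and maps.
#' @param write_maps Write per-subject relevance and cluster-mean NIfTIs
#'   when `out_dir` is set.
#' @param seed Master seed (overrides `cv$seed` and the cohort seed is left
#'   untouched).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), n_bins = 16L, cube_size = 7L,
                       features = GLCM_FEATURES, schema = c("a", "b"),
                       cv = cv_config(), lrp = lrp_rule(),
                       relevance_fwhm_mm = 10,
                       ap_damping = 0.9, ap_max_iter = 1000L,
                       ap_stable_iter = 100L,
                       out_dir = NULL, write_maps = FALSE, seed = 1L) {
  schema <- match.arg(schema)
  features <- vapply(features, match.arg, "", choices = GLCM_FEATURES)
  if (is.character(cohort) && !dir.exists(cohort))
    stop("cohort directory does not exist: ", cohort)
  structure(list(cohort = cohort, n_bins = as.integer(n_bins),
                 cube_size = as.integer(cube_size), features = features,
                 schema = schema, cv = cv, lrp = lrp,
                 relevance_fwhm_mm = relevance_fwhm_mm,
                 ap_damping = ap_damping, ap_max_iter = as.integer(ap_max_iter),
                 ap_stable_iter = as.integer(ap_stable_iter),
                 out_dir = out_dir, write_maps = isTRUE(write_maps),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a cohort directory (NIfTI volumes + subjects.tsv)
#'
#' @param dir Directory with `subjects.tsv` (`subject_id`, `group`) and one
#'   `<subject_id>.nii[.gz]` per row.
#' @return List with `volumes` and `table`, as [simulate_cohort()].
#' @export
load_cohort <- function(dir) {
  tsv <- file.path(dir, "subjects.tsv")
  if (!file.exists(tsv)) stop("missing subject table: ", tsv)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(tab)))
    stop("subjects.tsv must have columns subject_id, group")
  vols <- lapply(tab$subject_id, function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(id, ".nii"))
    read_nifti(p)
  })
  names(vols) <- tab$subject_id
  list(volumes = vols, table = tab)
}

#' Validate a cohort directory
#'
#' Checks NIfTI readability, a shared grid across subjects, subject-table
#' consistency and that group labels are in the allowed set.  Never throws
#' for content problems; failures are listed in the returned report.
#'
#' @param dir Cohort directory.
#' @return A data.frame with columns `check`, `subject`, `message`; zero
#'   rows means the cohort is well-formed.
#' @export
validate_inputs <- function(dir) {
  fail <- function(check, subject, message)
    data.frame(check = check, subject = subject, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  tsv <- file.path(dir, "subjects.tsv")
  if (!file.exists(tsv))
    return(fail("table", NA, paste("missing subjects.tsv in", dir)))
  tab <- tryCatch(utils::read.delim(tsv, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || !all(c("subject_id", "group") %in% names(tab)))
    return(fail("table", NA, "subjects.tsv lacks subject_id/group columns"))
  if (anyDuplicated(tab$subject_id))
    out[[length(out) + 1L]] <- fail("table", NA, "duplicate subject_id values")
  allowed <- c(names(unlist(SCHEMA_GROUPS)), GROUP_LEVELS)
  bad_groups <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad_groups) > 0L)
    out[[length(out) + 1L]] <- fail("groups", NA,
      paste("group labels outside the allowed set:",
            paste(bad_groups, collapse = ", ")))
  ref_dim <- NULL
  for (i in seq_len(nrow(tab))) {
    id <- tab$subject_id[i]
    p <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(id, ".nii"))
    vol <- tryCatch(read_nifti(p), error = function(e) e)
    if (inherits(vol, "error")) {
      out[[length(out) + 1L]] <- fail("readable", id, conditionMessage(vol))
      next
    }
    if (is.null(ref_dim)) ref_dim <- dim(vol)
    else if (!all(dim(vol) == ref_dim))
      out[[length(out) + 1L]] <- fail("grid", id,
        sprintf("grid %s differs from %s", paste(dim(vol), collapse = "x"),
                paste(ref_dim, collapse = "x")))
  }
  if (length(out) == 0L)
    data.frame(check = character(), subject = character(),
               message = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

schema_labels <- function(groups, schema) {
  map <- SCHEMA_GROUPS[[schema]]
  y <- rep(NA_real_, length(groups))
  y[groups == map[["positive"]]] <- 1
  y[groups == map[["negative"]]] <- -1
  y
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic or on-disk cohort and returns a run
#' report: a per-feature metrics table (balanced accuracy, sensitivity,
#' specificity on outer hold-out sets), per-feature clustering of
#' positive-relevance heatmaps, external validation counts for CHR_T, and a
#' provenance manifest.  When `config$out_dir` is set, the metrics table
#' (TSV), the report (JSON) and optionally the maps (NIfTI) are written
#' under it.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stage <- "cohort"
  report <- tryCatch({
    cohort <- if (inherits(config$cohort, "cohort_spec"))
      simulate_cohort(config$cohort) else load_cohort(config$cohort)
    tab <- cohort$table
    map <- SCHEMA_GROUPS[[config$schema]]
    for (g in map)
      if (!any(tab$group == g))
        stop("schema ", config$schema, " needs group ", g, " in the cohort")
    y_all <- schema_labels(tab$group, config$schema)
    in_schema <- !is.na(y_all)
    external <- tab$group == EXTERNAL_GROUP

    stage <- "prep"
    qvols <- lapply(cohort$volumes,
                    function(v) quantize_volume(equalize(v)$volume,
                                                config$n_bins))
    stage <- "texture"
    maps_by_subject <- lapply(qvols, function(q) {
      m <- texture_maps(q, features = config$features,
                        cube_size = config$cube_size,
                        n_levels = config$n_bins)
      lapply(m, smooth_map, mask = q > 0)
    })

    voxel_mask <- Reduce(`|`, lapply(qvols, function(q) q > 0))
    feature_results <- list()
    metrics_rows <- list()
    for (feat in config$features) {
      stage <- paste0("train:", feat)
      maps <- lapply(maps_by_subject, `[[`, feat)
      design <- build_design_matrix(maps, mask = voxel_mask)
      cv <- config$cv
      cv$seed <- subject_seed(config$seed, match(feat, GLCM_FEATURES),
                              stream = 23L)
      res <- nested_cv(design$X[in_schema, , drop = FALSE],
                       y_all[in_schema], cv)
      agg <- res$aggregate
      metrics_rows[[feat]] <- data.frame(
        feature = feat,
        balanced_accuracy = agg[["balanced_accuracy"]],
        sensitivity = agg[["sensitivity"]],
        specificity = agg[["specificity"]])

      stage <- paste0("explain:", feat)
      sub_design <- list(X = design$X[in_schema, , drop = FALSE],
                         voxel_index = design$voxel_index, grid = design$grid)
      rel <- subject_relevance_maps(res, sub_design, y_all[in_schema],
                                    config$lrp)
      pr <- lapply(rel$maps, function(m)
        smooth_relevance(positive_relevance(m),
                         fwhm_mm = config$relevance_fwhm_mm))
      stage <- paste0("cluster:", feat)
      clustering <- NULL
      if (length(pr) >= 1L) {
        S <- similarity_matrix(pr, mask = voxel_mask)
        ap <- affinity_propagation(S, damping = config$ap_damping,
                                   max_iter = config$ap_max_iter,
                                   stable_iter = config$ap_stable_iter)
        clustering <- cluster_report(pr, ap)
        clustering$converged <- ap$converged
      }
      stage <- paste0("external:", feat)
      ext <- NULL
      if (any(external)) {
        ext <- external_validate(res, design$X[external, , drop = FALSE])
        ext$votes$subject <- tab$subject_id[external]
      }
      feature_results[[feat]] <- list(cv = res, relevance = rel,
                                      positive_relevance = pr,
                                      clustering = clustering,
                                      external = ext)
    }
    metrics <- do.call(rbind, metrics_rows)
    rownames(metrics) <- NULL
    structure(list(metrics = metrics, features = feature_results,
                   table = tab, schema = config$schema, config = config,
                   grid = dim(cohort$volumes[[1L]])),
              class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run, schema", x$schema, "\n")
  m <- x$metrics
  m[, -1] <- round(m[, -1] * 100, 2)
  names(m) <- c("feature", "balanced_accuracy_pct", "sensitivity_pct",
                "specificity_pct")
  print(m, row.names = FALSE)
  for (feat in names(x$features)) {
    ext <- x$features[[feat]]$external
    if (!is.null(ext))
      cat(sprintf("  %s: external subjects classified as positive: %d of %d\n",
                  feat, ext$counts[["positive"]], sum(ext$counts)))
  }
  invisible(x)
}

write_run_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  utils::write.table(report$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  config <- report$config
  json <- list(
    schema = report$schema,
    n_bins = config$n_bins, cube_size = config$cube_size,
    seed = config$seed,
    cv = unclass(config$cv), lrp = unclass(config$lrp),
    metrics = report$metrics,
    folds = lapply(report$features, function(f) f$cv$folds),
    n_models = lapply(report$features, function(f) f$cv$n_models),
    external = lapply(report$features, function(f)
      if (is.null(f$external)) NULL else as.list(f$external$counts)),
    clusters = lapply(report$features, function(f)
      if (is.null(f$clustering)) NULL else f$clustering$membership)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (feat in names(report$features)) {
    f <- report$features[[feat]]
    if (!is.null(f$clustering)) {
      utils::write.table(f$clustering$membership,
                         file.path(out_dir, sprintf("%s_membership.tsv", feat)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (config$write_maps) {
      for (id in names(f$positive_relevance))
        write_nifti(f$positive_relevance[[id]],
                    file.path(out_dir, sprintf("%s_%s_PR.nii.gz", id, feat)))
      if (!is.null(f$clustering))
        for (cl in names(f$clustering$mean_maps))
          write_nifti(f$clustering$mean_maps[[cl]],
                      file.path(out_dir, sprintf("%s_%s_mean.nii.gz", feat, cl)))
    }
  }
  invisible(out_dir)
}
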