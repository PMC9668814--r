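# Intensity normalization front end: histogram equalization over foreground
# voxels (a single monotone 256-entry transform per image, for audit), then
# discretization to G gray levels.  Background (exactly-zero) voxels are
# never touched by either step, so the zero-voxel set is invariant.

#' Histogram-equalize a volume
#'
#' Computes the CDF-based equalization mapping over foreground (non-zero)
#' voxels on a 256-level discretization of the input range and applies it.
#' Output foreground intensities lie in `(0, 1]` (level `l` maps to
#' `(l+1)/256`), so no foreground voxel can collide with the 0 background.
#'
#' @param vol 3D numeric array; 0 marks background.
#' @return A list with `volume` (equalized array, attributes preserved) and
#'   `transform` (class `equalization_transform`: 256-entry integer LUT of
#'   output levels 0..255, `source_range`, `mask_rule`).
#' @export
equalize <- function(vol) {
  fg <- which(vol != 0)
  vals <- vol[fg]
  rng <- range(vals)
  if (length(fg) == 0L || rng[1] == rng[2])
    stop("degenerate histogram: fewer than 2 distinct foreground intensities")
  lvl <- pmin(255L, as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * 256)))
  h <- tabulate(lvl + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(vals)
  cdf_min <- cdf[which(h > 0)[1]]
  lut <- as.integer(round((cdf - cdf_min) / (1 - cdf_min + 1e-12) * 255))
  lut <- cummax(pmax(0L, pmin(255L, lut)))
  out <- vol
  out[fg] <- (lut[lvl + 1L] + 1) / 256
  transform <- structure(list(lut = lut, source_range = rng,
                              mask_rule = "foreground (non-zero) voxels"),
                         class = "equalization_transform")
  list(volume = out, transform = transform)
}

#' Write an equalization LUT as CSV
#'
#' Dumps the 256-entry transform for audit: columns `input_level`,
#' `output_level`.
#'
#' @param transform An `equalization_transform`.
#' @param path Output CSV path.
#' @export
write_equalization_lut <- function(transform, path) {
  utils::write.csv(data.frame(input_level = 0:255,
                              output_level = transform$lut),
                   path, row.names = FALSE)
  invisible(path)
}

#' Quantize a volume to G gray levels
#'
#' Equal-width binning of the foreground intensities over their min-max into
#' levels `1..n_bins`; background stays 0.  Intended to run after
#' [equalize()], whose flattened histogram makes equal-width binning behave
#' like equal-frequency binning.
#'
#' @param vol 3D numeric array; 0 marks background.
#' @param n_bins Even integer in `[2, 256]`.
#' @return Integer 3D array of class `quantized_volume` with attribute
#'   `n_bins`; foreground levels in `1..n_bins`.
#' @export
quantize_volume <- function(vol, n_bins = 16L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L || n_bins > 256L || n_bins %% 2L != 0L)
    stop("n_bins must be an even integer in [2, 256]")
  fg <- which(vol != 0)
  vals <- vol[fg]
  rng <- range(vals)
  if (length(fg) == 0L || rng[1] == rng[2])
    stop("degenerate histogram: fewer than 2 distinct foreground intensities")
  lev <- 1L + as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins))
  lev <- pmin(lev, n_bins)
  out <- array(0L, dim = dim(vol))
  out[fg] <- lev
  attr(out, "n_bins") <- n_bins
  for (a in c("subject_id", "group", "voxel_size"))
    attr(out, a) <- attr(vol, a)
  class(out) <- c("quantized_volume", class(out))
  out
}

#' Default bin-count search grid
#'
#' The exhaustive grid of candidate gray-level counts: 2 to 256 in steps
#' of 2 (128 candidates).
#'
#' @return Integer vector.
#' @export
default_bin_grid <- function() seq(2L, 256L, by = 2L)

#' Sweep gray-level counts against a downstream evaluator
#'
#' Equalizes every cohort volume once, then for each candidate bin count
#' quantizes the cohort and calls `evaluator(qvols, table)`, which must
#' return a scalar score (by convention a hold-out balanced accuracy).  The
#' argmax is selected; ties break toward fewer bins.
#'
#' @param cohort A list with `volumes` (named list of arrays) and `table`
#'   (data.frame with `subject_id`, `group`), as from [simulate_cohort()].
#' @param bins Integer vector of candidate bin counts (subset of the 2-256
#'   step-2 grid).
#' @param evaluator `function(qvols, table) -> numeric(1)`.
#' @return A data.frame `(n_bins, score)` with attribute `best_n_bins`.
#' @export
sweep_bins <- function(cohort, bins = default_bin_grid(), evaluator) {
  if (length(bins) == 0L) stop("bins must be non-empty")
  if (!all(bins %in% default_bin_grid()))
    stop("bins must be even values in [2, 256]")
  if (!is.function(evaluator)) stop("evaluator must be a function")
  bins <- sort(as.integer(bins))
  eq <- lapply(cohort$volumes, function(v) equalize(v)$volume)
  score <- vapply(bins, function(b) {
    qv <- lapply(eq, quantize_volume, n_bins = b)
    as.numeric(evaluator(qv, cohort$table))
  }, numeric(1))
  out <- data.frame(n_bins = bins, score = score)
  attr(out, "best_n_bins") <- bins[which.max(score)]
  out
}
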