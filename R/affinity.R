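# Affinity-propagation clustering of positive-relevance heatmaps
# (Frey & Dueck message passing: responsibilities and availabilities with
# damping), plus similarity construction and cluster-average reporting.

#' Pairwise similarity matrix of relevance maps
#'
#' `s(i, k) = -||PR_i - PR_k||^2` over foreground voxels; the diagonal
#' (preference) is set to the median off-diagonal similarity, the standard
#' choice yielding a moderate number of clusters.
#'
#' @param maps List of 3D arrays (or numeric vectors) on a shared grid.
#' @param mask Optional logical array restricting the voxels used.
#' @param preference Optional scalar overriding the median-preference rule.
#' @return An N x N similarity matrix of class `similarity_matrix`.
#' @export
similarity_matrix <- function(maps, mask = NULL, preference = NULL) {
  n <- length(maps)
  if (n < 1L) stop("need at least one map")
  d1 <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) identical(dim(m), d1), TRUE)))
    stop("maps do not share a grid")
  V <- vapply(maps, function(m) {
    v <- as.numeric(m)
    if (!is.null(mask)) v <- v[as.logical(mask)]
    v
  }, numeric(if (is.null(mask)) prod(if (is.null(d1)) length(maps[[1L]]) else d1)
             else sum(mask > 0)))
  V <- matrix(V, ncol = n)
  sq <- colSums(V^2)
  S <- -(outer(sq, sq, `+`) - 2 * crossprod(V))
  S <- (S + t(S)) / 2                      # exact symmetry
  if (n > 1L) {
    pref <- if (is.null(preference)) stats::median(S[row(S) != col(S)]) else preference
  } else pref <- if (is.null(preference)) 0 else preference
  diag(S) <- pref
  dimnames(S) <- list(names(maps), names(maps))
  structure(S, class = c("similarity_matrix", "matrix"))
}

net_similarity <- function(S, exemplar_of) {
  sum(S[cbind(seq_len(nrow(S)), exemplar_of)])
}

assign_to_exemplars <- function(S, exemplars) {
  ex <- vapply(seq_len(nrow(S)), function(i) {
    if (i %in% exemplars) return(i)
    exemplars[which.max(S[i, exemplars])]
  }, integer(1))
  ex
}

#' Affinity propagation
#'
#' Iterates damped responsibility and availability updates until the
#' exemplar set is stable for `stable_iter` sweeps or `max_iter` is
#' reached.  Cluster labels are reindexed `1..C` by descending cluster
#' size (ties by ascending exemplar index), so cluster 1 is always the
#' largest.  If the messages never stabilize, the best exemplar set seen
#' (by net similarity) is returned with `converged = FALSE` and a warning.
#'
#' @param S Similarity matrix (preferences on the diagonal), e.g. from
#'   [similarity_matrix()].
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum sweeps.
#' @param stable_iter Sweeps of unchanged exemplar set required for
#'   convergence.
#' @param degeneracy_jitter Add a deterministic perturbation of relative
#'   magnitude ~1e-14 to the similarities before message passing (default
#'   TRUE).  Exactly symmetric similarity matrices make the message updates
#'   degenerate and prone to poor fixed points; breaking ties at machine
#'   precision is standard practice and does not perturb non-degenerate
#'   solutions.
#' @return An object of class `ap_result`: `exemplar` (index per subject),
#'   `cluster` (size-ranked labels `1..C`), `exemplars`, `iterations`,
#'   `converged`, `net_similarity`.
#' @export
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000L,
                                 stable_iter = 100L, degeneracy_jitter = TRUE) {
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  S <- unclass(S)
  n <- nrow(S)
  if (n < 1L) stop("empty similarity matrix")
  if (n == 1L) {
    return(structure(list(exemplar = 1L, cluster = 1L, exemplars = 1L,
                          iterations = 0L, converged = TRUE,
                          net_similarity = S[1, 1]), class = "ap_result"))
  }
  S_orig <- S
  if (isTRUE(degeneracy_jitter)) {
    # fixed-seed jitter; the caller's RNG stream is left untouched
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(20231123L)
    noise <- matrix(stats::rnorm(n * n), n, n)
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
    S <- S + (.Machine$double.eps * abs(S) + 1e-300) * 100 * noise
  }
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  idx <- seq_len(n)
  prev_ex <- integer(0)
  stable <- 0L
  best <- list(net = -Inf, exemplars = NULL)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(idx, which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(idx, which1)] <- S[cbind(idx, which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- 0
    cs <- colSums(Rp)
    Anew <- matrix(rep(diag(R) + cs, each = n), n, n) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- cs
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex) > 0L) {
      net <- net_similarity(S_orig, assign_to_exemplars(S_orig, ex))
      if (net > best$net) best <- list(net = net, exemplars = ex)
      if (identical(ex, prev_ex)) stable <- stable + 1L else stable <- 0L
      prev_ex <- ex
      if (stable >= stable_iter) { converged <- TRUE; break }
    } else stable <- 0L
  }
  exemplars <- if (converged) prev_ex else best$exemplars
  if (is.null(exemplars) || length(exemplars) == 0L) {
    exemplars <- which.max(diag(A) + diag(R))
  }
  if (!converged)
    warning("affinity propagation did not converge; returning best exemplar set seen")
  exemplar_of <- assign_to_exemplars(S_orig, exemplars)
  sizes <- table(factor(exemplar_of, levels = sort(unique(exemplar_of))))
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  label_of <- stats::setNames(seq_along(ord), names(sizes)[ord])
  cluster <- as.integer(label_of[as.character(exemplar_of)])
  structure(list(exemplar = exemplar_of, cluster = cluster,
                 exemplars = sort(unique(exemplar_of)), iterations = it,
                 converged = converged,
                 net_similarity = net_similarity(S_orig, exemplar_of)),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("Affinity propagation: %d clusters, %d iterations, %s\n",
              length(x$exemplars), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Cluster-average heatmaps and membership table
#'
#' @param maps Named list of 3D arrays (one per subject).
#' @param assignment An `ap_result` over the same subjects, in order.
#' @return A list with `mean_maps` (list of 3D arrays indexed by size-ranked
#'   cluster label) and `membership` (data.frame `subject_id`, `cluster`,
#'   `exemplar_id`).
#' @export
cluster_report <- function(maps, assignment) {
  n <- length(maps)
  if (length(assignment$cluster) != n)
    stop("assignment does not cover all maps")
  ids <- if (is.null(names(maps))) as.character(seq_len(n)) else names(maps)
  membership <- data.frame(subject_id = ids,
                           cluster = assignment$cluster,
                           exemplar_id = ids[assignment$exemplar],
                           stringsAsFactors = FALSE)
  labels <- sort(unique(assignment$cluster))
  mean_maps <- lapply(labels, function(cl) {
    members <- which(assignment$cluster == cl)
    Reduce(`+`, maps[members]) / length(members)
  })
  names(mean_maps) <- paste0("cluster", labels)
  list(mean_maps = mean_maps, membership = membership)
}
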