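# Two-class discrimination from voxel-wise feature maps:
# Welch t-test feature ranking, a small tanh MLP (5 hidden layers of 2
# units, linear output) batch-trained by Levenberg-Marquardt with an L2
# penalty, evaluated in repeated stratified nested cross-validation.
# Labels are coded +1 / -1; the decision threshold is sign(score) with
# score 0 calling the positive class.

#' Nested cross-validation configuration
#'
#' The full-scale profile is 10 outer folds x 10 repetitions with a
#' 10-fold x 10-repetition inner cycle (10,000 inner model fits), top-200
#' feature selection, and up to 1000 training epochs.  Tests use smaller
#' profiles; the semantics are identical.
#'
#' @param outer_folds,inner_folds Stratified fold counts (>= 2).
#' @param outer_reps,inner_reps Repetitions of each cycle.
#' @param k_features Number of columns kept by univariate selection.
#' @param epochs_max Cap on accepted Levenberg-Marquardt iterations.
#' @param l2_lambda L2 penalty weight on connection weights.
#' @param seed Master seed; all split and init randomness derives from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 10L,
                      outer_reps = 10L, inner_reps = 10L,
                      k_features = 200L, epochs_max = 1000L,
                      l2_lambda = 0.01, seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) stop("fold counts must be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 outer_reps = as.integer(outer_reps),
                 inner_reps = as.integer(inner_reps),
                 k_features = as.integer(k_features),
                 epochs_max = as.integer(epochs_max),
                 l2_lambda = l2_lambda, seed = as.integer(seed)),
            class = "cv_config")
}

#' Rank columns by two-sample t statistic and keep the top k
#'
#' Welch t statistics per column between the +1 and -1 classes, ranked by
#' absolute value (descending), ties broken by ascending column index.
#' Columns with zero variance in both classes get t = 0 and rank last.
#'
#' @param X Numeric matrix, rows = samples.
#' @param y Labels in `{+1, -1}`.
#' @param k Number of columns to return (`k <= ncol(X)`).
#' @return Integer vector of `k` column indices, best first.
#' @export
select_features <- function(X, y, k) {
  if (k > ncol(X)) stop("k exceeds the number of columns")
  i1 <- y > 0; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  t_abs <- abs(welch_t(X, i1, i2, n1, n2))
  order(-t_abs, seq_len(ncol(X)))[seq_len(k)]
}

welch_t <- function(X, i1, i2, n1, n2) {
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- (colSums(X[i1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X[i2, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  t[se2 <= 0] <- 0          # zero variance in both classes
  t
}

mlp_init <- function(n_in, hidden = rep(2L, 5L)) {
  sizes <- c(n_in, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1L], -0.5, 0.5) / sqrt(fan_in),
                     fan_in, sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L))
    A[[l + 1L]] <- tanh(sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`))
  A[[L + 1L]] <- sweep(A[[L]] %*% W[[L]], 2L, b[[L]], `+`)
  A
}

flatten_params <- function(W, b) c(unlist(W), unlist(b))

unflatten_params <- function(theta, sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    n <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(theta[pos + seq_len(n)], sizes[l], sizes[l + 1L])
    pos <- pos + n
  }
  for (l in seq_len(L)) {
    n <- sizes[l + 1L]
    b[[l]] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  list(W = W, b = b)
}

# Jacobian d f(x_n) / d theta, N x P, by per-layer backward sensitivities.
mlp_jacobian <- function(W, b, A) {
  L <- length(W)
  N <- nrow(A[[1L]])
  D <- vector("list", L)                      # d y / d z_l, N x sizes[l+1]
  D[[L]] <- matrix(1, N, 1L)
  for (l in rev(seq_len(L - 1L)))
    D[[l]] <- (D[[l + 1L]] %*% t(W[[l + 1L]])) * (1 - A[[l + 1L]]^2)
  Jw <- vector("list", L); Jb <- vector("list", L)
  for (l in seq_len(L)) {
    p <- ncol(A[[l]]); q <- ncol(D[[l]])
    Jw[[l]] <- A[[l]][, rep(seq_len(p), times = q), drop = FALSE] *
               D[[l]][, rep(seq_len(q), each = p), drop = FALSE]
    Jb[[l]] <- D[[l]]
  }
  cbind(do.call(cbind, Jw), do.call(cbind, Jb))
}

#' Train the tanh MLP by Levenberg-Marquardt
#'
#' Full-batch damped Gauss-Newton on the squared-error loss with an L2
#' penalty on connection weights (biases unpenalized): steps solve the
#' Jacobian normal equations with adaptive damping (x10 on rejection, /10 on
#' acceptance, abort above 1e10).  The sequence of accepted regularized
#' losses is non-increasing by construction.  Columns of `X` are expected to
#' be standardized by the caller.
#'
#' @param X Numeric matrix, rows = samples (standardized columns).
#' @param y Targets in `{+1, -1}`.
#' @param epochs_max Cap on accepted iterations (default 1000).
#' @param l2_lambda L2 penalty weight (default 0.01).
#' @param hidden Hidden layer widths (default five layers of 2).
#' @param tol Relative loss-decrease convergence tolerance.
#' @return An object of class `braintex_mlp`: weights, biases, layer sizes,
#'   the accepted-loss trace, and bookkeeping slots (`selected_features`,
#'   `center`, `scale`) filled by the cross-validation driver.
#' @export
train_mlp <- function(X, y, epochs_max = 1000L, l2_lambda = 0.01,
                      hidden = rep(2L, 5L), tol = 1e-10) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  net <- mlp_init(ncol(X), hidden)
  sizes <- net$sizes
  n_w <- sum(sizes[-length(sizes)] * sizes[-1L])      # weight entries
  theta <- flatten_params(net$W, net$b)
  P <- length(theta)
  w_idx <- seq_len(n_w)
  loss_of <- function(th) {
    pr <- unflatten_params(th, sizes)
    f <- mlp_forward(pr$W, pr$b, X)[[length(sizes)]]
    r <- y - as.numeric(f)
    sum(r^2) + l2_lambda * sum(th[w_idx]^2)
  }
  lambda_lm <- 1e-3
  losses <- loss_of(theta)
  if (!is.finite(losses)) stop("non-finite initial loss")
  epoch <- 0L
  while (epoch < epochs_max) {
    pr <- unflatten_params(theta, sizes)
    A <- mlp_forward(pr$W, pr$b, X)
    r <- y - as.numeric(A[[length(sizes)]])
    Jf <- mlp_jacobian(pr$W, pr$b, A)
    # residuals: model part (d r / d theta = -Jf) + penalty part sqrt(l2)*w
    g <- -crossprod(Jf, r)                       # gradient of sum(r^2)/2 part
    g[w_idx] <- g[w_idx] + l2_lambda * theta[w_idx]
    H <- crossprod(Jf)
    diag(H)[w_idx] <- diag(H)[w_idx] + l2_lambda
    if (sqrt(sum(g^2)) < 1e-8) break
    current <- utils::tail(losses, 1L)
    accepted <- FALSE
    while (lambda_lm <= 1e10) {
      step <- tryCatch(solve(H + diag(lambda_lm, P), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        new_loss <- loss_of(cand)
        if (is.finite(new_loss) && new_loss < current) {
          theta <- cand
          losses <- c(losses, new_loss)
          lambda_lm <- max(lambda_lm / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda_lm <- lambda_lm * 10
    }
    if (!accepted) break                          # damping overflow
    epoch <- epoch + 1L
    if ((current - utils::tail(losses, 1L)) < tol * max(current, 1e-12)) break
  }
  pr <- unflatten_params(theta, sizes)
  structure(list(weights = pr$W, biases = pr$b, layer_sizes = sizes,
                 l2_lambda = l2_lambda, losses = losses, epochs = epoch,
                 selected_features = NULL, center = NULL, scale = NULL),
            class = "braintex_mlp")
}

#' @export
print.braintex_mlp <- function(x, ...) {
  cat(sprintf("tanh MLP [%s], %d accepted LM epochs, final loss %.4g\n",
              paste(x$layer_sizes, collapse = "-"), x$epochs,
              utils::tail(x$losses, 1L)))
  invisible(x)
}

#' Predict with a trained MLP
#'
#' Applies the model's stored feature selection and train-fold
#' standardization, then the forward pass.  The label is `sign(score)` with
#' score 0 assigned to the positive class.
#'
#' @param object A `braintex_mlp`.
#' @param newdata Numeric matrix whose columns match the design matrix the
#'   model was fit in (pre-selection if the model stores
#'   `selected_features`).
#' @param ... Unused.
#' @return A list with `scores` (numeric) and `labels` (+1/-1).
#' @export
predict.braintex_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$selected_features)) {
    if (max(object$selected_features) > ncol(X))
      stop("newdata has fewer columns than the model's feature indices")
    X <- X[, object$selected_features, drop = FALSE]
  }
  if (ncol(X) != object$layer_sizes[1L])
    stop("dimension mismatch: model expects ", object$layer_sizes[1L],
         " inputs, got ", ncol(X))
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center, `-`), 2L, object$scale, `/`)
  scores <- as.numeric(mlp_forward(object$weights, object$biases,
                                   X)[[length(object$layer_sizes)]])
  labels <- ifelse(scores >= 0, 1, -1)
  list(scores = scores, labels = labels)
}

#' Confusion-count metrics
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `balanced_accuracy` their mean.  A rate whose class is absent is `NA`
#' and propagates into the balanced accuracy.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return Named numeric vector
#'   `(balanced_accuracy, sensitivity, specificity)`.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  if (tp + fn + tn + fp == 0) stop("no observations")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(balanced_accuracy = (sens + spec) / 2, sensitivity = sens,
    specificity = spec)
}

stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("stratification error: class ", cls, " has fewer samples (",
           length(idx), ") than folds (", k, ")")
    idx <- sample(idx)
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale,
       X = sweep(sweep(X, 2L, center, `-`), 2L, scale, `/`))
}

fit_fold_model <- function(X_train, y_train, selected, config) {
  std <- standardize_fit(X_train[, selected, drop = FALSE])
  model <- train_mlp(std$X, y_train, epochs_max = config$epochs_max,
                     l2_lambda = config$l2_lambda)
  model$selected_features <- selected
  model$center <- std$center
  model$scale <- std$scale
  model
}

#' Repeated stratified nested cross-validation
#'
#' Outer folds estimate hold-out performance; the inner cycle (folds x
#' repetitions within each outer-training set) performs t-test feature
#' selection and one model fit per inner split.  The outer-fold model is
#' refit on the full outer-training set using the inner-cycle consensus
#' feature set: columns ordered by inner-selection vote count (descending),
#' then mean selection rank (ascending), then column index, truncated to
#' exactly `k_features`.  Metrics come from outer hold-out predictions only;
#' all randomness derives from `config$seed`.
#'
#' @param X Numeric design matrix (rows = subjects).
#' @param y Labels in `{+1, -1}`.
#' @param config A [cv_config()].
#' @return An object of class `braintex_cv`: per-fold confusion counts and
#'   metrics (`$folds`), aggregate metrics (`$aggregate`, with
#'   `balanced_accuracy = (sensitivity + specificity) / 2` exactly), the
#'   outer-model registry (`$models`), and `n_models`, the number of inner
#'   fits (10,000 under the full-scale profile).
#' @export
nested_cv <- function(X, y, config = cv_config()) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (min(table(y)) < config$outer_folds)
    stop("stratification error: smallest class has fewer samples than outer folds")
  k <- min(config$k_features, ncol(X))
  fold_rows <- list()
  models <- list()
  n_inner_fits <- 0L
  for (rep_o in seq_len(config$outer_reps)) {
    set.seed(subject_seed(config$seed, rep_o, stream = 11L))
    outer_folds <- stratified_folds(y, config$outer_folds)
    for (f in seq_along(outer_folds)) {
      test_idx <- outer_folds[[f]]
      train_idx <- setdiff(seq_along(y), test_idx)
      X_tr <- X[train_idx, , drop = FALSE]
      y_tr <- y[train_idx]
      votes <- integer(ncol(X))
      rank_sum <- numeric(ncol(X))
      set.seed(subject_seed(config$seed, rep_o * 1000L + f, stream = 13L))
      for (rep_i in seq_len(config$inner_reps)) {
        inner_folds <- stratified_folds(y_tr, config$inner_folds)
        for (g in seq_along(inner_folds)) {
          it <- setdiff(seq_along(y_tr), inner_folds[[g]])
          sel <- select_features(X_tr[it, , drop = FALSE], y_tr[it], k)
          votes[sel] <- votes[sel] + 1L
          rank_sum[sel] <- rank_sum[sel] + seq_len(k)
          fit_fold_model(X_tr[it, , drop = FALSE], y_tr[it], sel, config)
          n_inner_fits <- n_inner_fits + 1L
        }
      }
      mean_rank <- ifelse(votes > 0, rank_sum / votes, Inf)
      consensus <- order(-votes, mean_rank, seq_len(ncol(X)))[seq_len(k)]
      set.seed(subject_seed(config$seed, rep_o * 1000L + f, stream = 17L))
      model <- fit_fold_model(X_tr, y_tr, consensus, config)
      pred <- predict(model, X[test_idx, , drop = FALSE])
      y_te <- y[test_idx]
      tp <- sum(pred$labels > 0 & y_te > 0); fn <- sum(pred$labels < 0 & y_te > 0)
      tn <- sum(pred$labels < 0 & y_te < 0); fp <- sum(pred$labels > 0 & y_te < 0)
      m <- classification_metrics(tp, fn, tn, fp)
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(rep = rep_o, fold = f, tp = tp, fn = fn, tn = tn, fp = fp,
                   balanced_accuracy = m[["balanced_accuracy"]],
                   sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]])
      model$held_out <- test_idx
      models[[sprintf("rep%02d_fold%02d", rep_o, f)]] <- model
    }
  }
  folds <- do.call(rbind, fold_rows)
  sens <- mean(folds$sensitivity, na.rm = TRUE)
  spec <- mean(folds$specificity, na.rm = TRUE)
  structure(list(folds = folds,
                 aggregate = c(balanced_accuracy = (sens + spec) / 2,
                               sensitivity = sens, specificity = spec),
                 models = models,
                 n_models = n_inner_fits,
                 config = config),
            class = "braintex_cv")
}

#' @export
print.braintex_cv <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "Nested CV (%dx%d outer, %dx%d inner, %d inner fits):\n",
    x$config$outer_reps, x$config$outer_folds,
    x$config$inner_reps, x$config$inner_folds, x$n_models))
  cat(sprintf("  balanced accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              a[["balanced_accuracy"]], a[["sensitivity"]], a[["specificity"]]))
  invisible(x)
}

#' External validation of a third group against stored outer models
#'
#' Every outer model in the registry scores every external subject; a
#' subject's call is the majority vote across models (ties to the positive
#' class).
#'
#' @param result A `braintex_cv` from [nested_cv()].
#' @param X_ext Design matrix of external subjects on the same columns as
#'   the training design matrix.
#' @return A list with `counts` (named vector: subjects called positive /
#'   negative) and `votes` (data.frame `subject`, `frac_positive`, `call`).
#' @export
external_validate <- function(result, X_ext) {
  X_ext <- as.matrix(X_ext)
  calls <- vapply(result$models, function(m) predict(m, X_ext)$labels,
                  numeric(nrow(X_ext)))
  calls <- matrix(calls, nrow = nrow(X_ext))
  frac_pos <- rowMeans(calls > 0)
  call <- ifelse(frac_pos >= 0.5, 1, -1)
  list(counts = c(positive = sum(call > 0), negative = sum(call < 0)),
       votes = data.frame(subject = seq_len(nrow(X_ext)),
                          frac_positive = frac_pos, call = call))
}

#' Build a design matrix from registered feature maps
#'
#' Flattens the foreground voxels of one feature-map type across subjects
#' into a subjects x voxels matrix; the column-to-voxel mapping is kept for
#' scattering relevances back onto the grid.
#'
#' @param maps Named list of 3D arrays (one per subject, shared grid).
#' @param mask Logical array of voxels to use (default: voxels that are
#'   non-zero in at least one map).
#' @return A list with `X` (matrix), `voxel_index` (column -> linear voxel
#'   index), `grid` (dim of the maps).
#' @export
build_design_matrix <- function(maps, mask = NULL) {
  d <- dim(maps[[1L]])
  if (!all(vapply(maps, function(m) all(dim(m) == d), TRUE)))
    stop("all maps must share one grid")
  if (is.null(mask)) {
    mask <- Reduce(`+`, lapply(maps, function(m) (m != 0) + 0)) > 0
  }
  cols <- which(mask > 0)
  X <- t(vapply(maps, function(m) m[cols], numeric(length(cols))))
  bad <- !apply(is.finite(X), 2L, all)
  if (any(bad)) {
    X <- X[, !bad, drop = FALSE]
    cols <- cols[!bad]
  }
  rownames(X) <- names(maps)
  list(X = X, voxel_index = cols, grid = d)
}
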