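make_toy <- function(n = 20, p = 6, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + sep * y
  list(X = X, y = y)
}

test_that("feature selection matches a per-column t-test oracle", {
  set.seed(20)
  X <- matrix(rnorm(30 * 40), 30, 40)
  y <- rep(c(1, -1), each = 15)
  X[, 5] <- X[, 5] + 3 * y
  sel <- select_features(X, y, 10)
  expect_equal(sel[1], 5)                    # dominant column first
  t_oracle <- apply(X, 2, function(col)
    abs(stats::t.test(col[y > 0], col[y < 0])$statistic))
  expect_setequal(sel, order(-t_oracle)[1:10])
  # k = n returns a permutation of all columns
  expect_setequal(select_features(X, y, 40), 1:40)
  expect_error(select_features(X, y, 41), "exceeds")
  expect_error(select_features(X[1:3, ], y[c(1, 2, 16)], 2), ">= 2 samples")
})

test_that("zero-variance columns rank last", {
  X <- cbind(const = rep(1, 10), sig = rep(c(1, -1), each = 5) * 2 + rnorm(10, sd = 0.1))
  y <- rep(c(1, -1), each = 5)
  expect_equal(select_features(X, y, 2), c(2, 1))
})

test_that("confusion metrics follow their definitions", {
  expect_equal(unname(classification_metrics(7, 3, 9, 1)), c(0.8, 0.7, 0.9))
  expect_equal(classification_metrics(5, 5, 5, 5)[["balanced_accuracy"]], 0.5)
  expect_equal(classification_metrics(10, 0, 8, 0)[["balanced_accuracy"]], 1)
  m <- classification_metrics(0, 0, 5, 1)
  expect_true(is.na(m[["sensitivity"]]) && is.na(m[["balanced_accuracy"]]))
  expect_error(classification_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("LM training separates toy data and descends monotonically", {
  toy <- make_toy()
  set.seed(2)
  model <- train_mlp(scale(toy$X), toy$y, epochs_max = 100)
  pred <- predict(model, scale(toy$X))
  expect_equal(pred$labels, toy$y)           # capacity check
  expect_true(all(diff(model$losses) <= 0))  # accepted losses non-increasing
  expect_lte(model$epochs, 100)
  expect_equal(length(model$layer_sizes), 7) # 5 hidden layers + in/out
  expect_true(all(model$layer_sizes[2:6] == 2))
})

test_that("epoch cap is honored", {
  toy <- make_toy(n = 12, sep = 1)
  set.seed(3)
  model <- train_mlp(scale(toy$X), toy$y, epochs_max = 5)
  expect_lte(model$epochs, 5)
  expect_lte(length(model$losses), 6)
})

test_that("prediction applies the documented tie rule and validations", {
  model <- structure(list(
    weights = list(matrix(0, 3, 1)), biases = list(0),
    layer_sizes = c(3L, 1L), l2_lambda = 0, losses = 0, epochs = 0L,
    selected_features = NULL, center = NULL, scale = NULL),
    class = "braintex_mlp")
  pred <- predict(model, matrix(rnorm(12), 4, 3))
  expect_true(all(pred$scores == 0))
  expect_true(all(pred$labels == 1))         # score 0 -> positive class
  expect_error(predict(model, matrix(1, 2, 5)), "dimension mismatch")
})

test_that("small-weight single layer behaves linearly", {
  w <- c(0.01, -0.02, 0.015)
  model <- structure(list(
    weights = list(matrix(w, 3, 1)), biases = list(0),
    layer_sizes = c(3L, 1L), l2_lambda = 0, losses = 0, epochs = 0L,
    selected_features = NULL, center = NULL, scale = NULL),
    class = "braintex_mlp")
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(predict(model, X)$scores, as.numeric(X %*% w), tolerance = 1e-12)
})

test_that("nested CV is deterministic and counts its models", {
  toy <- make_toy(n = 24, p = 15, sep = 3, seed = 4)
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, outer_reps = 2,
                   inner_reps = 2, k_features = 5, epochs_max = 15, seed = 7)
  r1 <- nested_cv(toy$X, toy$y, cfg)
  expect_equal(r1$n_models,
               cfg$outer_reps * cfg$outer_folds * cfg$inner_reps * cfg$inner_folds)
  expect_equal(nrow(r1$folds), cfg$outer_reps * cfg$outer_folds)
  # balanced accuracy identity per fold and in aggregate
  expect_equal(r1$folds$balanced_accuracy,
               (r1$folds$sensitivity + r1$folds$specificity) / 2)
  a <- r1$aggregate
  expect_equal(a[["balanced_accuracy"]],
               (a[["sensitivity"]] + a[["specificity"]]) / 2)
  r2 <- nested_cv(toy$X, toy$y, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(lapply(r1$models, `[[`, "weights"),
                   lapply(r2$models, `[[`, "weights"))
  # every stored model carries provenance of its own training partition
  for (m in r1$models) {
    expect_length(m$selected_features, 5)
    expect_length(m$held_out, 24 / 3)
  }
  expect_gte(a[["balanced_accuracy"]], 0.9)  # separable toy
  expect_error(nested_cv(toy$X, toy$y,
                         cv_config(outer_folds = 15, inner_folds = 2)),
               "stratification error")
})

test_that("permuted labels drive CV accuracy to chance", {
  set.seed(30)
  n <- 30
  X <- matrix(rnorm(n * 12), n, 12)
  y <- rep(c(1, -1), each = n / 2)
  cfg <- cv_config(outer_folds = 2, inner_folds = 2, outer_reps = 1,
                   inner_reps = 1, k_features = 4, epochs_max = 10, seed = 5)
  bas <- vapply(1:10, function(i) {
    set.seed(100 + i)
    yp <- sample(y)
    cfg$seed <- i
    nested_cv(X, yp, cfg)$aggregate[["balanced_accuracy"]]
  }, numeric(1))
  se <- sqrt(0.25 / n)                       # binomial SE of one CV estimate
  expect_lt(abs(mean(bas) - 0.5), 3 * se)
})

test_that("external validation votes across the model registry", {
  toy <- make_toy(n = 24, p = 10, sep = 4, seed = 6)
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, outer_reps = 1,
                   inner_reps = 1, k_features = 4, epochs_max = 20, seed = 9)
  res <- nested_cv(toy$X, toy$y, cfg)
  set.seed(7)
  X_ext <- matrix(rnorm(5 * 10), 5, 10)
  X_ext[, 1] <- X_ext[, 1] + 4               # positive-class distribution
  ev <- external_validate(res, X_ext)
  expect_equal(sum(ev$counts), 5)            # counts sum to the external n
  expect_gte(ev$counts[["positive"]], 4)     # majority classified positive
  expect_equal(nrow(ev$votes), 5)
  # single model, single subject: one vote, one call
  one <- list(models = res$models[1])
  ev1 <- external_validate(one, X_ext[1, , drop = FALSE])
  expect_equal(sum(ev1$counts), 1)
  expect_true(ev1$votes$frac_positive %in% c(0, 1))
})
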