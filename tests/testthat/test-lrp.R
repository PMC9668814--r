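random_mlp <- function(n_in, hidden = rep(2L, 5L), zero_bias = TRUE, seed = 1) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  W <- lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1L], sd = 0.8), sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(length(sizes) - 1L), function(l)
    if (zero_bias) rep(0, sizes[l + 1L]) else rnorm(sizes[l + 1L], sd = 0.2))
  structure(list(weights = W, biases = b, layer_sizes = sizes,
                 l2_lambda = 0, losses = 0, epochs = 0L,
                 selected_features = NULL, center = NULL, scale = NULL),
            class = "braintex_mlp")
}

test_that("zero input with zero biases yields zero relevance", {
  model <- random_mlp(4)
  rel <- lrp(model, rep(0, 4))
  expect_true(all(rel == 0))
  expect_equal(attr(rel, "score"), 0)
})

test_that("single linear unit recovers the closed form as epsilon -> 0", {
  w <- c(0.5, -1.2, 2.0)
  model <- structure(list(weights = list(matrix(w, 3, 1)), biases = list(0),
                          layer_sizes = c(3L, 1L), l2_lambda = 0, losses = 0,
                          epochs = 0L, selected_features = NULL,
                          center = NULL, scale = NULL),
                     class = "braintex_mlp")
  x <- c(1, 2, -0.5)
  f <- sum(w * x)
  for (eps in c(1e-2, 1e-6)) {
    rel <- lrp(model, x, lrp_rule(eps))
    want <- w * x * f / (f + eps * sign(f))
    expect_equal(as.numeric(rel), want, tolerance = 1e-12)
  }
  rel <- lrp(model, x, lrp_rule(1e-12))
  expect_equal(as.numeric(rel), w * x, tolerance = 1e-8)
})

test_that("relevance is conserved up to the epsilon leak on zero-bias nets", {
  for (s in 1:10) {
    model <- random_mlp(6, seed = s)
    set.seed(100 + s)
    x <- rnorm(6)
    rel <- lrp(model, x, lrp_rule(1e-9, relative = TRUE))
    score <- attr(rel, "score")
    expect_lte(abs(sum(rel) - score), 1e-6 * abs(score) + 1e-12)
  }
})

test_that("scaling the input in the linear regime scales single-layer relevance", {
  w <- c(0.3, 0.7)
  model <- structure(list(weights = list(matrix(w, 2, 1)), biases = list(0),
                          layer_sizes = c(2L, 1L), l2_lambda = 0, losses = 0,
                          epochs = 0L, selected_features = NULL,
                          center = NULL, scale = NULL),
                     class = "braintex_mlp")
  x <- c(0.02, -0.01)
  r1 <- lrp(model, x, lrp_rule(1e-12))
  r2 <- lrp(model, 3 * x, lrp_rule(1e-12))
  expect_equal(as.numeric(r2), 3 * as.numeric(r1), tolerance = 1e-6)
})

test_that("relevance vectors scatter onto the grid faithfully", {
  rel <- c(1.5, -2, 0.25)
  idx <- c(4L, 10L, 17L)
  map <- relevance_to_map(rel, idx, c(3, 3, 3))
  expect_equal(sum(map != 0), 3)             # k relevances -> k non-zero voxels
  expect_equal(sum(map), sum(rel))           # conservation of scatter
  perm <- c(3, 1, 2)
  expect_identical(relevance_to_map(rel[perm], idx[perm], c(3, 3, 3)), map)
  expect_error(relevance_to_map(rel, c(1L, 2L, 99L), c(3, 3, 3)),
               "outside the grid")
  expect_error(relevance_to_map(rel, idx[1:2], c(3, 3, 3)), "lengths differ")
})

test_that("positive relevance clips negatives and is idempotent", {
  m <- array(c(-1, 0, 2, -3, 4, 0), c(1, 2, 3))
  pm <- positive_relevance(m)
  expect_true(all(pm >= 0))
  expect_equal(pm[pm > 0], c(2, 4))
  expect_identical(positive_relevance(pm), pm)
  expect_true(all(positive_relevance(array(-abs(rnorm(8)), c(2, 2, 2))) == 0))
})

test_that("FWHM converts to sigma by the standard identity", {
  expect_equal(fwhm_to_sigma(10, 1), 10 / (2 * sqrt(2 * log(2))))
  expect_equal(fwhm_to_sigma(10, 1), 10 / 2.3548, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(10, 2), fwhm_to_sigma(10, 1) / 2)
})

test_that("relevance smoothing honors support and FWHM arguments", {
  img <- array(0, c(15, 15, 15)); img[8, 8, 8] <- 1
  sm <- smooth_relevance(img, support = 7)
  expect_equal(dim(sm), dim(img))
  expect_gt(sm[8, 8, 8], sm[8, 8, 10])
  sm2 <- smooth_relevance(img, fwhm_mm = 4, voxel_size_mm = 1)
  expect_gt(sm2[8, 8, 12], 0)                # wider kernel spreads further
})

test_that("lrp applies stored selection and standardization", {
  model <- random_mlp(3, seed = 3)
  model$selected_features <- c(2L, 5L, 9L)
  model$center <- c(1, 1, 1); model$scale <- c(2, 2, 2)
  x_full <- rnorm(10)
  rel <- lrp(model, x_full)
  expect_length(rel, 3)
  expect_error(lrp(model, rnorm(5)), "shorter")
})
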