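test_that("offset set holds the 13 unique distance-1 directions", {
  off <- glcm_offsets()
  expect_equal(nrow(off), 13)
  expect_true(all(rowSums(off != 0) > 0))
  key <- apply(off, 1, paste, collapse = ",")
  neg <- apply(-off, 1, paste, collapse = ",")
  expect_false(any(neg %in% key))
  expect_error(validate_offsets(rbind(off, c(0L, 0L, 0L))), "zero offset")
  expect_error(validate_offsets(rbind(off, -off[1, ])), "negation")
})

test_that("window GLCM matches brute-force pair enumeration exactly", {
  set.seed(10)
  for (trial in 1:5) {
    w <- array(sample(0:5, 7^3, replace = TRUE), c(7, 7, 7))
    g <- glcm_from_window(w, n_levels = 5)
    counts <- oracle_glcm_counts(w, glcm_offsets(), 5)
    expect_identical(g$pair_count, sum(counts) / 2)
    expect_equal(g$p, matrix(counts / sum(counts), 5, 5), tolerance = 1e-15)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, t(g$p))
  }
})

test_that("degenerate and two-level windows give the analytic GLCMs", {
  w <- array(3L, c(3, 3, 3))
  g <- glcm_from_window(w, n_levels = 4)
  expect_equal(g$p[3, 3], 1)
  expect_equal(sum(g$p), 1)
  w2 <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  g2 <- glcm_from_window(w2, offsets = matrix(c(1L, 0L, 0L), 1), n_levels = 2)
  expect_equal(g2$p[1, 2], 0.5)
  expect_equal(g2$p[2, 1], 0.5)
  empty <- glcm_from_window(array(0L, c(3, 3, 3)), n_levels = 2)
  expect_equal(empty$pair_count, 0)
  expect_true(is.na(feature_from_glcm(empty, "entropy")))
})

test_that("feature formulas match the straight-formula oracle", {
  # analytic degenerate case
  g <- glcm_from_window(array(3L, c(3, 3, 3)), n_levels = 4)
  vals <- vapply(GLCM_FEATURES, function(f) feature_from_glcm(g, f), 0)
  expect_equal(unname(vals), c(0, 0, 0, 1, 0, 1))   # ent, se, de, energy, contrast, homog
  # analytic alternating case: energy .5, entropy 1 bit, contrast 1, homog .5
  g2 <- glcm_from_window(array(rep(c(1L, 2L), 4), c(8, 1, 1)),
                         offsets = matrix(c(1L, 0L, 0L), 1), n_levels = 2)
  expect_equal(feature_from_glcm(g2, "energy"), 0.5)
  expect_equal(feature_from_glcm(g2, "entropy"), 1)
  expect_equal(feature_from_glcm(g2, "contrast"), 1)
  expect_equal(feature_from_glcm(g2, "homogeneity"), 0.5)
  expect_equal(feature_from_glcm(g2, "sum_entropy"), 0)
  expect_equal(feature_from_glcm(g2, "difference_entropy"), 0)
  # random distributions
  set.seed(11)
  for (trial in 1:20) {
    G <- sample(2:8, 1)
    p <- matrix(rexp(G * G), G, G); p <- (p + t(p)); p <- p / sum(p)
    want <- oracle_features(p)
    for (f in GLCM_FEATURES)
      expect_equal(feature_from_glcm(p, f), want[[f]], tolerance = 1e-12)
  }
  expect_error(feature_from_glcm(g, "correlation"), "arg")
})

test_that("feature ranges hold on random GLCMs", {
  set.seed(12)
  for (trial in 1:10) {
    G <- sample(2:10, 1)
    p <- matrix(rexp(G * G), G, G); p <- p + t(p); p <- p / sum(p)
    expect_gte(feature_from_glcm(p, "energy"), 0)
    expect_lte(feature_from_glcm(p, "energy"), 1)
    expect_lte(feature_from_glcm(p, "contrast"), (G - 1)^2)
    h <- feature_from_glcm(p, "homogeneity")
    expect_gt(h, 0); expect_lte(h, 1)
    expect_gte(feature_from_glcm(p, "entropy"), 0)
  }
})

test_that("texture maps equal the naive per-voxel oracle", {
  set.seed(13)
  q <- array(sample(0:4, 10 * 9 * 8, replace = TRUE), c(10, 9, 8))
  maps <- texture_maps(q, cube_size = 5, n_levels = 4)
  for (f in c("contrast", "difference_entropy", "homogeneity")) {
    want <- oracle_texture_map(q, f, cube = 5, G = 4)
    expect_lt(max(abs(maps[[f]] - want)), 1e-12)
  }
})

test_that("uniform foreground gives entropy 0 / energy 1 maps", {
  q <- array(0L, c(9, 9, 9))
  q[3:7, 3:7, 3:7] <- 2L
  maps <- texture_maps(q, cube_size = 3, n_levels = 3)
  fg <- q > 0
  expect_true(all(maps$entropy[fg] == 0))
  expect_true(all(maps$energy[fg] == 1))
})

test_that("axis permutation commutes with map computation", {
  set.seed(14)
  q <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
  maps <- texture_maps(q, cube_size = 5, n_levels = 3)
  qp <- aperm(q, c(2, 3, 1))
  mapsp <- texture_maps(qp, cube_size = 5, n_levels = 3)
  for (f in c("contrast", "entropy"))
    expect_equal(mapsp[[f]], aperm(maps[[f]], c(2, 3, 1)), tolerance = 1e-12)
})

test_that("map computation validates its inputs", {
  q <- array(1L, c(6, 6, 6))
  expect_error(texture_maps(q, cube_size = 4), "odd")
  expect_error(texture_maps(q, cube_size = 7), "larger than volume")
  expect_error(texture_maps(q, features = "banana"), "arg")
})

test_that("planted shuffle raises ROI contrast monotonically in magnitude", {
  mags <- c(0, 0.2, 0.4, 0.6, 0.8)
  mean_contrast <- vapply(mags, function(m) {
    spec <- tiny_effect_spec(m, n_per_group = 2, grid = 18, seed = 21)
    co <- simulate_cohort(spec)
    roi <- spec$roi_masks$planted
    vals <- vapply(co$volumes[co$table$group == "FEP"], function(v) {
      q <- quantize_volume(equalize(v)$volume, 16)
      mean(texture_maps(q, "contrast")$contrast[roi])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  rho <- cor(mags, mean_contrast, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("map smoothing matches a direct 3D convolution oracle", {
  set.seed(15)
  img <- array(rnorm(9 * 8 * 7), c(9, 8, 7))
  got <- smooth_3d(img, sigma = 1.0, support = 5)
  want <- oracle_smooth_3d(img, sigma = 1.0, support = 5)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("smoothing has unit impulse response and DC invariance", {
  img <- array(0, c(11, 11, 11)); img[6, 6, 6] <- 1
  sm <- smooth_3d(img, sigma = 1, support = 7, renormalize = FALSE)
  k <- gaussian_kernel_1d(1, 7)
  expect_equal(sm[3:9, 3:9, 3:9], outer(outer(k, k), k), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  const <- array(3.7, c(10, 10, 10))
  expect_equal(smooth_map(const, mask = array(TRUE, dim(const))), const,
               tolerance = 1e-12)
  # background re-zeroed
  m <- array(1, c(8, 8, 8)); mask <- array(FALSE, dim(m)); mask[3:6, 3:6, 3:6] <- TRUE
  sm2 <- smooth_map(m, mask = mask)
  expect_true(all(sm2[!mask] == 0))
})
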