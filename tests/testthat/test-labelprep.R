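test_that("mask building thresholds exactly on bimodal images", {
  img <- matrix(1, 12, 12); img[4:9, 5:10] <- 10
  m <- build_mask(img, threshold = "otsu", min_object_px = 1)
  expect_identical(m == 1, img == 10)

  # small-object removal
  img2 <- matrix(0, 10, 10); img2[2, 2:4] <- 5  # 3-pixel object
  expect_true(all(build_mask(img2, threshold = 1, min_object_px = 5) == 0))
  expect_equal(sum(build_mask(img2, threshold = 1, min_object_px = 3)), 3)

  expect_error(build_mask(matrix(2, 5, 5)), class = "flimglia_error_value")
  expect_error(build_mask(matrix(-1, 5, 5), threshold = 1),
               class = "flimglia_error_value")
})

test_that("mask from a phantom label channel matches the ground truth footprint", {
  p <- tiny_phantom(seed = 8, size = 64)
  # label channel: cells bright at 10x background, Poisson noise
  label_img <- withr::with_seed(80, {
    matrix(rpois(64 * 64, ifelse(p$class_map == 1, 50, 5)), 64, 64)
  })
  m <- build_mask(label_img, threshold = "otsu", min_object_px = 5)
  disagree <- mean(m != (p$class_map == 1))
  expect_lt(disagree, 0.01)
})

test_that("FBM block means match exhaustive enumeration", {
  cfg <- run_config(block_size = 8, block_stride = 1)
  maps <- constant_param_maps(3.3, 10, 10)
  mask <- matrix(0L, 10, 10)
  tbl <- extract_fbm_blocks(maps, mask, cfg)
  expect_equal(nrow(tbl), 9)  # 3 x 3 positions
  for (nm in c("t1", "t2", "tm", "a1", "a2", "a1pct", "chi2")) {
    expect_equal(tbl[[nm]], rep(3.3, 9), tolerance = 1e-12)
  }

  # random maps with invalid pixels vs brute force
  withr::with_seed(5, {
    m <- matrix(rnorm(144), 12, 12)
    valid <- matrix(runif(144) > 0.2, 12, 12)
  })
  m[!valid] <- NaN
  maps2 <- constant_param_maps(1, 12, 12)
  for (nm in names(maps2$maps)) maps2$maps[[nm]] <- m
  maps2 <- param_maps(maps2$maps, valid = valid)
  tbl2 <- extract_fbm_blocks(maps2, matrix(0L, 12, 12),
                             run_config(block_size = 4, block_stride = 1))
  ref <- brute_block_means(m, valid, 4, 1)
  ref <- ref[ref$n_valid >= 8, ]  # >= 50% of 16 pixels
  expect_equal(nrow(tbl2), nrow(ref))
  merged <- merge(as.data.frame(tbl2[, c("x", "y", "t1")]), ref,
                  by = c("x", "y"))
  expect_equal(merged$t1, merged$mean, tolerance = 1e-12)
})

test_that("block labels come from the block's center pixel", {
  maps <- constant_param_maps(1, 10, 10)
  mask <- matrix(0L, 10, 10)
  mask[5, 5] <- 1L  # 0-based (4,4): center of the block at top-left (0,0)
  tbl <- extract_fbm_blocks(maps, mask, run_config(block_size = 8))
  lab <- tbl$label[tbl$x == 4 & tbl$y == 4]
  expect_equal(lab, 1L)
  expect_equal(sum(tbl$label), 1L)
})

test_that("a 256x256 image yields (256-8+1)^2 overlapping block positions", {
  maps <- constant_param_maps(1, 256, 256)
  tbl <- extract_fbm_blocks(maps, matrix(0L, 256, 256), run_config())
  expect_equal(nrow(tbl), 249^2)
})

test_that("DBM vectors are area-normalized block histogram sums", {
  cube <- small_cube(6, 6, 8, seed = 12, lambda = 6)
  cfg <- run_config(block_size = 3, block_stride = 1)
  tbl <- extract_dbm_vectors(cube, matrix(0L, 6, 6), cfg)
  fn <- feature_names(tbl)
  expect_equal(unname(rowSums(as.matrix(tbl[fn]))), rep(1, nrow(tbl)),
               tolerance = 1e-9)

  # brute-force accumulation oracle
  for (row in sample(seq_len(nrow(tbl)), 5)) {
    r0 <- tbl$y[row] - 1; c0 <- tbl$x[row] - 1  # top-left, 0-based
    block <- cube$counts[r0 + (1:3), c0 + (1:3), , drop = FALSE]
    ref <- apply(block, 3, sum)
    expect_equal(as.numeric(tbl[row, fn]), ref / sum(ref), tolerance = 1e-12)
  }

  # uniform cube: every vector identical
  u <- decay_cube(array(2, dim = c(5, 5, 6)), bin_width = DT)
  tu <- extract_dbm_vectors(u, matrix(0L, 5, 5),
                            run_config(block_size = 2, block_stride = 1))
  fu <- as.matrix(tu[feature_names(tu)])
  expect_equal(max(apply(fu, 2, function(col) diff(range(col)))), 0)

  # zero-photon blocks are dropped
  z <- decay_cube(array(0, dim = c(6, 6, 4)), bin_width = DT)
  z$counts[1, 1, 1] <- 5
  tz <- extract_dbm_vectors(z, matrix(0L, 6, 6),
                            run_config(block_size = 2, block_stride = 2))
  expect_equal(nrow(tz), 1)
})

test_that("FBM and DBM tables share row keys when the same blocks survive", {
  p <- tiny_phantom(seed = 19, size = 32)
  cfg <- run_config(photon_threshold = 0)
  maps <- fit_cube(p$cube, p$irf, cfg)
  fbm <- extract_fbm_blocks(maps, p$mask, cfg, fov = 3L)
  dbm <- extract_dbm_vectors(p$cube, p$mask, cfg, fov = 3L)
  expect_identical(fbm$fov, dbm$fov)
  expect_identical(fbm$x, dbm$x)
  expect_identical(fbm$y, dbm$y)
  expect_identical(fbm$label, dbm$label)
})

test_that("feature-table label rate tracks the mask area fraction", {
  p <- tiny_phantom(seed = 23, size = 64)
  cfg <- run_config(photon_threshold = 0)
  dbm <- extract_dbm_vectors(p$cube, p$mask, cfg)
  expect_lt(abs(mean(dbm$label) - mean(p$mask)), 0.02)
})

test_that("splits are stratified, exhaustive and deterministic", {
  tbl <- make_feature_table(matrix(rnorm(200), 100, 2),
                            rep(c(0, 1), c(60, 40)))
  s <- split_dataset(tbl, c(0.7, 0.15, 0.15), seed = 2)
  expect_equal(as.vector(table(s$split)), c(70, 15, 15))
  expect_identical(s, split_dataset(tbl, c(0.7, 0.15, 0.15), seed = 2))

  # imbalanced table: per-class train fraction within one row of 70%
  withr::with_seed(6, {
    y <- c(rep(1, 80), rep(0, 920))
  })
  big <- make_feature_table(matrix(rnorm(2000), 1000, 2), y)
  sb <- split_dataset(big, seed = 3)
  for (cl in c(0, 1)) {
    idx <- which(big$label == cl)
    n_tr <- sum(sb$split[idx] == "train")
    expect_lte(abs(n_tr - 0.7 * length(idx)), 1)
  }

  tiny <- make_feature_table(matrix(rnorm(8), 4, 2), c(0, 0, 0, 1))
  expect_error(split_dataset(tiny), class = "flimglia_error_value")
})

test_that("normalization is invertible and reuses training statistics", {
  X <- matrix(rnorm(300, mean = 5, sd = 3), 100, 3)
  tbl <- make_feature_table(X, rep(0:1, 50))
  out <- normalize_features(tbl)
  fn <- feature_names(tbl)
  norm_X <- as.matrix(out$table[fn])
  expect_equal(unname(colMeans(norm_X)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(norm_X, 2, sd)), rep(1, 3), tolerance = 1e-9)

  # invert with the stored stats
  inv <- sweep(sweep(norm_X, 2, out$stats$sd, `*`), 2, -out$stats$mean, `-`)
  expect_equal(unname(inv), unname(X), tolerance = 1e-9)

  # a shifted test table normalized with train stats keeps its offset
  test_tbl <- make_feature_table(X + 2, rep(0:1, 50))
  test_norm <- normalize_features(test_tbl, stats = out$stats)$table
  expect_true(all(abs(colMeans(as.matrix(test_norm[fn]))) > 0.5))

  # zero-variance feature is centered with a warning
  Xz <- cbind(X[, 1:2], 7)
  expect_warning(normalize_features(make_feature_table(Xz, rep(0:1, 50))),
                 "zero-variance")
})
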