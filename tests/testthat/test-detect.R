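make_prob_image <- function(m) {
  structure(m, class = "flim_prob_image", centre_offset = 4L, stride = 1L,
            block_size = 8L, image_dim = dim(m) + 7L)
}

test_that("probability images propagate NaN and are deterministic", {
  maps <- constant_param_maps(NaN, 12, 12)
  maps$valid[] <- FALSE
  for (nm in names(maps$maps)) maps$maps[[nm]][] <- NaN
  net <- init_network(7, 5, seed = 1)
  net$mode <- NULL  # raw network, no stats required
  pi1 <- predict_image(net, maps, run_config(block_size = 4))
  expect_true(all(is.na(pi1)))

  maps2 <- constant_param_maps(1, 12, 12)
  p1 <- predict_image(net, maps2, run_config(block_size = 4))
  p2 <- predict_image(net, maps2, run_config(block_size = 4))
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(9, 9))
})

test_that("scores concentrate on microglia footprints in a phantom", {
  p <- tiny_phantom(seed = 51, size = 48)
  cfg <- run_config(photon_threshold = 0)
  maps <- fit_cube(p$cube, p$irf, cfg)
  tbl <- extract_fbm_blocks(maps, p$mask, cfg)
  nrm <- normalize_features(tbl)
  fit <- train_network(init_network(7, 10, seed = 52), nrm$table,
                       split_dataset(nrm$table, seed = 52),
                       stats = nrm$stats, max_epochs = 30, seed = 52)
  prob <- predict_image(fit, maps, cfg)
  gt <- block_grid_mask(p$mask, cfg)
  expect_gt(mean(prob[gt == 1], na.rm = TRUE),
            mean(prob[gt == 0], na.rm = TRUE))
})

test_that("threshold calibration honors its tie-break contract", {
  mask <- matrix(0L, 30, 30); mask[5:25, 5:25] <- 1L  # 441 px >= 100
  prob <- make_prob_image(matrix(as.numeric(mask), 30, 30))
  th <- calibrate_thresholds(list(prob), list(mask))
  expect_equal(th$cutoff, 0.95)  # every cutoff ties at Dice 1
  expect_equal(th$overlap, 1)

  expect_error(calibrate_thresholds(list(make_prob_image(matrix(0, 10, 10))),
                                    list(matrix(0L, 10, 10))),
               class = "flimglia_error_value")
  zero_prob <- make_prob_image(matrix(0, 30, 30))
  expect_error(calibrate_thresholds(list(zero_prob), list(mask)),
               class = "flimglia_error_value")
})

test_that("calibration separates signal from noise levels and matches brute force", {
  mask <- matrix(0L, 20, 20); mask[3:12, 3:12] <- 1L
  prob <- matrix(0.3, 20, 20); prob[mask == 1] <- 0.7
  pim <- make_prob_image(prob)
  th <- calibrate_thresholds(list(pim), list(mask))
  expect_true(th$cutoff > 0.3 && th$cutoff <= 0.7)

  # independent re-computation of the whole Dice grid
  cutoffs <- seq(0.05, 0.95, by = 0.05)
  sizes <- c(5, 10, 25, 50, 100)
  ref <- expand.grid(cutoff = cutoffs, min_size = sizes)
  ref$overlap <- mapply(function(ct, ms) {
    bin <- matrix(as.integer(prob >= ct), 20, 20)
    lab <- label_components(bin)
    if (max(lab) > 0) {
      keep <- which(tabulate(lab[lab > 0]) >= ms)
      bin <- matrix(as.integer(lab %in% keep & lab > 0), 20, 20)
    }
    den <- sum(bin) + sum(mask)
    if (den == 0) NaN else 2 * sum(bin & mask) / den
  }, ref$cutoff, ref$min_size)
  got <- merge(as.data.frame(th$grid), ref, by = c("cutoff", "min_size"))
  expect_equal(got$overlap.x, got$overlap.y, tolerance = 1e-12)
})

test_that("binarize_and_clean enforces the minimum region size exactly", {
  prob <- matrix(0, 15, 15)
  prob[2:3, 2:3] <- 0.9            # 4-pixel blob
  prob[8:12, 8:12] <- 0.8          # 25-pixel blob
  pim <- make_prob_image(prob)

  pure <- binarize_and_clean(pim, list(cutoff = 0.5, min_size = 1))
  expect_equal(sum(pure), 29)

  cleaned <- binarize_and_clean(pim, list(cutoff = 0.5, min_size = 5))
  expect_equal(sum(cleaned), 25)
  expect_true(all(cleaned[2:3, 2:3] == 0))

  # property: every surviving component is at least min_size pixels
  rp <- withr::with_seed(61, matrix(runif(900), 30, 30))
  out <- binarize_and_clean(make_prob_image(rp), list(cutoff = 0.6, min_size = 4))
  lab <- label_components(out)
  if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 4))
})

test_that("detection matching follows the any-overlap cell rule", {
  gt <- matrix(0L, 10, 10); gt[2:4, 2:4] <- 1L; gt[7:9, 7:9] <- 1L
  expect_equal(match_detections(gt, gt),
               tibble::tibble(tp = 2, fn = 0, fp = 0))
  expect_equal(match_detections(matrix(0L, 10, 10), gt),
               tibble::tibble(tp = 0, fn = 2, fp = 0))

  # one predicted blob bridging two cells detects both, no false positive
  bridge <- matrix(0L, 10, 10); bridge[3, 2:8] <- 1L; bridge[3:8, 8] <- 1L
  res <- match_detections(bridge, gt)
  expect_equal(res$tp, 2)
  expect_equal(res$fp, 0)
})

test_that("the 16x16 toy layout counts TP=2, FN=1, FP=2", {
  gt <- matrix(0L, 16, 16)
  gt[2:4, 2:4] <- 1L      # cell A
  gt[2:4, 12:14] <- 1L    # cell B
  gt[12:14, 2:4] <- 1L    # cell C
  pred <- matrix(0L, 16, 16)
  pred[3:5, 3:5] <- 1L    # touches A
  pred[1:2, 13] <- 1L     # touches B
  pred[9:10, 9:10] <- 1L  # touches nothing
  pred[14:15, 12:13] <- 1L  # touches nothing

  res <- match_detections(pred, gt)
  expect_equal(unlist(res[c("tp", "fn", "fp")], use.names = FALSE), c(2, 1, 2))

  # brute-force verification by exhaustive pixel-overlap enumeration
  lg <- label_components(gt); lp <- label_components(pred)
  overlap <- table(gt_cell = lg[lg > 0 & lp > 0])
  expect_equal(res$tp, length(overlap))
  hit_pred <- unique(lp[lg > 0 & lp > 0])
  expect_equal(res$fp, max(lp) - length(hit_pred))
})

test_that("metric identities hold exactly and the pooled rates are correct", {
  withr::with_seed(71, {
    counts <- tibble::tibble(tp = rpois(1000, 5), fn = rpois(1000, 2),
                             fp = rpois(1000, 3))
  })
  m <- compute_metrics(counts)
  def <- !is.nan(m$tpr)
  expect_equal(m$tpr[def] + m$fnr[def], rep(1, sum(def)))
  defp <- !is.nan(m$ppv)
  expect_equal(m$ppv[defp] + m$fdr[defp], rep(1, sum(defp)))

  perfect <- compute_metrics(tibble::tibble(tp = 4, fn = 0, fp = 0))
  expect_equal(glance(perfect)$fdr, 0)
  expect_equal(glance(perfect)$ppv, 1)

  # zero denominators give NaN, not errors
  nand <- compute_metrics(tibble::tibble(tp = 0, fn = 0, fp = 0))
  expect_true(is.nan(glance(nand)$tpr))
})

test_that("raising the cutoff never increases the false-positive count", {
  # smooth, blob-shaped score field (the realistic shape of network output:
  # unimodal bumps whose superlevel sets shrink without splitting)
  grid <- expand.grid(r = 1:50, c = 1:50)
  bump <- function(r0, c0, h, s) h * exp(-((grid$r - r0)^2 + (grid$c - c0)^2) / (2 * s^2))
  p <- matrix(bump(15, 15, 0.95, 4) + bump(35, 40, 0.7, 3) +
                bump(40, 12, 0.5, 3) + bump(8, 40, 0.35, 2), 50, 50)
  gt <- matrix(0L, 50, 50); gt[12:18, 12:18] <- 1L
  fps <- vapply(seq(0.1, 0.9, by = 0.1), function(ct) {
    pm <- binarize_and_clean(make_prob_image(p), list(cutoff = ct, min_size = 1))
    match_detections(pm, gt)$fp
  }, numeric(1))
  expect_true(all(diff(fps) <= 0))
  expect_gt(fps[1], 0)  # the sweep actually exercises false positives
})
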