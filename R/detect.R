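# From block scores to cell-level detection metrics.
#
# Scores live on the block-center grid (one value per block position).
# Thresholds — a probability cutoff and a minimum region size — are
# calibrated on training FOVs by maximizing mean pixel-wise Dice overlap
# with the ground truth, then frozen and applied to held-out FOVs.
# Detection counting is per cell: a ground-truth cell touched by any
# predicted region (soma or process) is a true positive; a predicted
# region touching no cell is one false positive. True negatives are
# undefined in this scheme and never reported.

#' Predict a microglia probability image
#'
#' Runs the same feature pipeline as training (same block geometry, same
#' normalization statistics stored in the model) over a parameter-map stack
#' (FBM) or a decay cube (DBM) and reshapes the scores to the block-center
#' grid. Blocks dropped by the feature filters are `NaN`.
#'
#' @param object a trained `flim_ann` or `flim_ann_fit`.
#' @param input a `flim_param_maps` (FBM model) or `flim_decay_cube`
#'   (DBM model).
#' @param config the [run_config()] used for training.
#' @return a `flim_prob_image`: numeric matrix in `[0, 1]` (block grid)
#'   with geometry attributes for mapping back to image space.
#' @export
predict_image <- function(object, input, config = run_config()) {
  net <- if (inherits(object, "flim_ann_fit")) object$net else object
  if (inherits(input, "flim_param_maps")) {
    if (!is.null(net$mode) && net$mode != "fbm") {
      stop_value("model was trained on decay vectors (DBM); supply a decay cube")
    }
    tbl <- extract_fbm_blocks(input, mask = NULL, config = config)
  } else if (inherits(input, "flim_decay_cube")) {
    if (!is.null(net$mode) && net$mode != "dbm") {
      stop_value("model was trained on fitted parameters (FBM); supply parameter maps")
    }
    tbl <- extract_dbm_vectors(input, mask = NULL, config = config)
  } else {
    stop_value("input must be flim_param_maps or flim_decay_cube")
  }
  if (is.null(net$stats) && !is.null(net$mode)) {
    stop_value("model carries no normalization statistics")
  }
  gd <- attr(tbl, "grid_dim")
  off <- attr(tbl, "centre_offset")
  s <- attr(tbl, "block_stride")
  img <- matrix(NaN, gd[1], gd[2])
  if (nrow(tbl) > 0) {
    scores <- predict(net, tbl)
    gi <- (tbl$y - off) %/% s + 1L
    gj <- (tbl$x - off) %/% s + 1L
    img[cbind(gi, gj)] <- scores
  }
  structure(img, class = "flim_prob_image",
            centre_offset = off, stride = s,
            block_size = attr(tbl, "block_size"),
            image_dim = attr(tbl, "image_dim"))
}

#' Resample a full-resolution mask onto the block-center grid
#'
#' @param mask 0/1 matrix at image resolution.
#' @param config the [run_config()] defining the block geometry.
#' @return 0/1 matrix with one entry per block position.
#' @export
block_grid_mask <- function(mask, config = run_config()) {
  geom <- block_grid_geometry(dim(mask), config$block_size, config$block_stride)
  mask[geom$r0 + geom$centre_off + 1L, geom$c0 + geom$centre_off + 1L,
       drop = FALSE]
}

dice_overlap <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NaN)
  2 * sum(a & b) / (sa + sb)
}

iou_overlap <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NaN)
  sum(a & b) / u
}

#' Calibrate detection thresholds on training FOVs
#'
#' Exhaustive grid search over probability cutoffs and minimum region
#' sizes, maximizing the mean pixel-wise overlap (Dice by default) between
#' the cleaned prediction and ground truth across the training FOVs. Ties
#' are broken toward the higher cutoff, then the larger minimum size (the
#' more conservative detector).
#'
#' @param prob_images list of `flim_prob_image`s.
#' @param gt_masks list of matching ground-truth masks, either at image
#'   resolution (resampled automatically) or already on the block grid.
#' @param cutoffs candidate probability cutoffs.
#' @param min_sizes candidate minimum region sizes in pixels.
#' @param config [run_config()] used to resample full-resolution masks.
#' @param overlap `"dice"` or `"iou"`.
#' @return object of class `flim_thresholds`: chosen `cutoff`, `min_size`,
#'   achieved `overlap`, and the full search `grid` tibble.
#' @export
calibrate_thresholds <- function(prob_images, gt_masks,
                                 cutoffs = seq(0.05, 0.95, by = 0.05),
                                 min_sizes = c(5, 10, 25, 50, 100),
                                 config = run_config(),
                                 overlap = c("dice", "iou")) {
  overlap <- match.arg(overlap)
  ofun <- if (overlap == "dice") dice_overlap else iou_overlap
  if (length(prob_images) != length(gt_masks) || length(prob_images) == 0) {
    stop_value("need matching, non-empty lists of probability images and masks")
  }
  masks <- purrr::map2(gt_masks, prob_images, function(m, p) {
    if (identical(dim(m), dim(p))) m else block_grid_mask(m, config)
  })
  if (all(vapply(masks, sum, numeric(1)) == 0)) {
    stop_value("all ground-truth masks are empty; cannot calibrate")
  }

  # label each thresholded image once per cutoff, then filter by size
  grid <- vector("list", length(cutoffs) * length(min_sizes))
  gi <- 0
  for (ct in cutoffs) {
    labs <- lapply(prob_images, function(p) {
      bin <- matrix(as.integer(!is.na(p) & p >= ct), nrow(p), ncol(p))
      label_components(bin)
    })
    for (ms in min_sizes) {
      ov <- purrr::map2_dbl(labs, masks, function(lab, m) {
        pred <- clean_labels(lab, ms)
        ofun(pred > 0, m > 0)
      })
      gi <- gi + 1
      grid[[gi]] <- tibble::tibble(cutoff = ct, min_size = ms,
                                   overlap = mean(ov, na.rm = TRUE))
    }
  }
  grid <- dplyr::bind_rows(grid)
  if (all(!is.finite(grid$overlap)) || max(grid$overlap, na.rm = TRUE) <= 0) {
    stop_value("no threshold setting produced any overlap with the ground truth")
  }
  best <- grid |>
    dplyr::filter(is.finite(.data$overlap)) |>
    dplyr::arrange(dplyr::desc(.data$overlap), dplyr::desc(.data$cutoff),
                   dplyr::desc(.data$min_size)) |>
    dplyr::slice(1)
  structure(list(cutoff = best$cutoff, min_size = best$min_size,
                 overlap = best$overlap, measure = overlap, grid = grid),
            class = "flim_thresholds")
}

#' @export
print.flim_thresholds <- function(x, ...) {
  cat(sprintf("<flim_thresholds> cutoff %.2f, min size %d px (%s %.3f)\n",
              x$cutoff, x$min_size, x$measure, x$overlap))
  invisible(x)
}

clean_labels <- function(lab, min_size) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0])
  out <- lab
  out[lab > 0 & sizes[pmax(lab, 1)] < min_size] <- 0L
  out
}

#' Threshold and clean a probability image
#'
#' Keeps pixels with probability at or above the cutoff, then removes
#' 8-connected regions smaller than the minimum size.
#'
#' @param prob_image a `flim_prob_image` (or plain matrix of scores).
#' @param thresholds a `flim_thresholds` (or list with `cutoff` and
#'   `min_size`).
#' @return 0/1 predicted mask on the same grid.
#' @export
binarize_and_clean <- function(prob_image, thresholds) {
  bin <- matrix(as.integer(!is.na(prob_image) & prob_image >= thresholds$cutoff),
                nrow(prob_image), ncol(prob_image))
  if (thresholds$min_size > 1) {
    lab <- label_components(bin)
    bin <- matrix(as.integer(clean_labels(lab, thresholds$min_size) > 0),
                  nrow(bin), ncol(bin))
  }
  bin
}

#' Match predicted regions against ground-truth cells
#'
#' Both masks are decomposed into 8-connected components. A ground-truth
#' cell counts as detected (TP) if any predicted region shares at least one
#' pixel with it — soma or process — otherwise it is a miss (FN). A
#' predicted region that touches no cell is one false positive; a region
#' touching several cells detects all of them and contributes no FP.
#'
#' @param pred_mask 0/1 predicted mask.
#' @param gt_mask 0/1 ground-truth mask of the same size.
#' @return tibble with columns `tp`, `fn`, `fp`.
#' @export
match_detections <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop_value("mask dimensions differ")
  }
  lp <- label_components(pred_mask)
  lg <- label_components(gt_mask)
  np <- max(lp); ng <- max(lg)
  both <- lp > 0 & lg > 0
  touched_gt <- unique(lg[both])
  touching_pred <- unique(lp[both])
  tibble::tibble(
    tp = length(touched_gt),
    fn = ng - length(touched_gt),
    fp = np - length(touching_pred))
}

#' Detection metrics from per-FOV counts
#'
#' Computes TPR = TP/(TP+FN), PPV = TP/(TP+FP), FNR = 1 - TPR and
#' FDR = 1 - PPV per field of view, pooled over all FOVs, and as an
#' across-FOV mean and standard deviation. Rates with zero denominators
#' are `NaN`. True negatives are not defined for this counting scheme and
#' no accuracy is reported.
#'
#' @param counts tibble with columns `tp`, `fn`, `fp` (one row per FOV;
#'   an optional `fov` column is preserved), or a list of
#'   [match_detections()] results.
#' @return object of class `flim_detection`: tibble of per-FOV metrics,
#'   with `pooled` (one-row tibble) and `summary` (mean/sd tibble)
#'   attributes, also accessible via [glance()].
#' @export
compute_metrics <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- dplyr::bind_rows(counts, .id = "fov")
  }
  if (!all(c("tp", "fn", "fp") %in% names(counts))) {
    stop_value("counts need tp, fn and fp columns")
  }
  if (any(counts$tp < 0 | counts$fn < 0 | counts$fp < 0)) {
    stop_value("counts must be non-negative")
  }
  if (!"fov" %in% names(counts)) counts$fov <- seq_len(nrow(counts))

  rate <- function(num, den) ifelse(den > 0, num / den, NaN)
  per_fov <- counts |>
    dplyr::mutate(
      tpr = rate(.data$tp, .data$tp + .data$fn),
      ppv = rate(.data$tp, .data$tp + .data$fp),
      fnr = 1 - rate(.data$tp, .data$tp + .data$fn),
      fdr = 1 - rate(.data$tp, .data$tp + .data$fp)) |>
    dplyr::relocate("fov")

  pooled <- tibble::tibble(
    tp = sum(counts$tp), fn = sum(counts$fn), fp = sum(counts$fp)) |>
    dplyr::mutate(
      tpr = rate(.data$tp, .data$tp + .data$fn),
      ppv = rate(.data$tp, .data$tp + .data$fp),
      fnr = 1 - .data$tpr, fdr = 1 - .data$ppv)

  summary <- per_fov |>
    tidyr::pivot_longer(c("tpr", "ppv", "fnr", "fdr"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")

  structure(per_fov, class = c("flim_detection", class(per_fov)),
            pooled = pooled, summary = summary)
}

#' @export
print.flim_detection <- function(x, ...) {
  p <- attr(x, "pooled")
  cat(sprintf("<flim_detection> %d FOV(s); pooled TP %d / FN %d / FP %d\n",
              nrow(x), p$tp, p$fn, p$fp))
  cat(sprintf("  pooled TPR %.3f, PPV %.3f, FNR %.3f, FDR %.3f\n",
              p$tpr, p$ppv, p$fnr, p$fdr))
  NextMethod()
}
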