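# Ground-truth masks and labeled training instances.
#
# Instances are built from overlapping square blocks slid over the field of
# view. For the fitting-based method (FBM) the feature vector is the mean of
# each of the seven fitted parameters over the block's valid pixels; for the
# decay-based method (DBM) it is the block-summed photon histogram,
# normalized to unit area so that only decay shape (not brightness) reaches
# the classifier. A block's label is the ground-truth mask value at its
# center pixel.

#' Threshold an intensity image into a ground-truth mask
#'
#' `mask = intensity >= threshold`, followed by removal of 8-connected
#' objects smaller than `min_object_px`. The threshold is either an explicit
#' value or Otsu's method on the intensity histogram (the usual choice for
#' the bright, sparse label channels — GFP or immunostains — used to mark
#' cells).
#'
#' @param intensity non-negative numeric matrix.
#' @param threshold `"otsu"` or an explicit numeric cutoff.
#' @param min_object_px minimum surviving object size in pixels.
#' @return 0/1 integer mask.
#' @export
build_mask <- function(intensity, threshold = "otsu", min_object_px = 5) {
  if (any(intensity < 0)) stop_value("intensity must be non-negative")
  if (identical(threshold, "otsu")) {
    if (max(intensity) == min(intensity)) {
      stop_value("constant image: automatic thresholding is undefined, supply an explicit threshold")
    }
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_value("EBImage is required for Otsu thresholding; supply an explicit threshold instead")
    }
    mx <- max(intensity)
    threshold <- EBImage::otsu(EBImage::Image(intensity / mx),
                               range = c(0, 1), levels = 256) * mx
  }
  mask <- matrix(as.integer(intensity >= threshold),
                 nrow(intensity), ncol(intensity))
  if (min_object_px > 1 && any(mask > 0)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    mask[lab > 0 & sizes[pmax(lab, 1)] < min_object_px] <- 0L
  }
  mask
}

#' 8-connected component labeling
#'
#' Deterministic row-major labeling of a binary mask; diagonal neighbors
#' are connected by default, which is the convention used by the detection
#' metrics in this package.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_value("connectivity must be 4 or 8")
  storage.mode(mask) <- "integer"
  label_components_cpp(mask, as.integer(connectivity))
}

block_grid_geometry <- function(image_dim, block_size, stride) {
  b <- block_size
  if (b > min(image_dim)) stop_value("block_size exceeds image side")
  list(
    r0 = seq(0L, image_dim[1] - b, by = stride),  # 0-based top-left rows
    c0 = seq(0L, image_dim[2] - b, by = stride),
    centre_off = b %/% 2L
  )
}

finish_feature_table <- function(tbl, mode, feature_names, config,
                                 image_dim, geom, fov) {
  structure(
    tbl,
    class = c("flim_feature_table", class(tibble::tibble())),
    mode = mode, feature_names = feature_names,
    block_size = config$block_size, block_stride = config$block_stride,
    centre_offset = geom$centre_off, image_dim = image_dim,
    grid_dim = c(length(geom$r0), length(geom$c0)), fov = fov
  )
}

#' Feature columns of a feature table
#' @param table a `flim_feature_table`.
#' @return character vector of feature column names.
#' @export
feature_names <- function(table) attr(table, "feature_names")

#' Build FBM training instances from parameter maps
#'
#' Slides `block_size` x `block_size` windows (stride `block_stride`) over
#' the maps and averages each of the seven fitted parameters over the
#' block's valid pixels. Blocks with fewer than 50% valid pixels are
#' dropped. The label is the mask value at the block's center pixel
#' (offset `floor(block_size/2)` from the top-left corner, 0-based).
#'
#' @param maps a `flim_param_maps`.
#' @param mask 0/1 ground-truth mask of the same size, or `NULL` when
#'   extracting features for prediction (labels become `NA`).
#' @param config a [run_config()].
#' @param fov integer tag identifying the field of view in the output.
#' @return a `flim_feature_table` tibble with columns `fov`, `x`, `y`
#'   (0-based center pixel), the seven parameter means (`t1` ... `chi2`)
#'   and `label`.
#' @export
extract_fbm_blocks <- function(maps, mask = NULL, config = run_config(),
                               fov = 1L) {
  stopifnot(inherits(maps, "flim_param_maps"))
  d <- dim(maps)
  if (!is.null(mask) && !identical(dim(mask), d)) {
    stop_value("maps and mask dimensions differ")
  }
  geom <- block_grid_geometry(d, config$block_size, config$block_stride)
  s <- config$block_stride

  nvalid <- block_sums(matrix(as.numeric(maps$valid), d[1], d[2]),
                       config$block_size, s)
  feats <- lapply(maps$maps, function(m) {
    m0 <- m
    m0[!maps$valid | is.na(m0)] <- 0
    block_sums(m0, config$block_size, s) / pmax(nvalid, 1)
  })

  keep <- nvalid >= 0.5 * config$block_size^2
  centres_r <- geom$r0 + geom$centre_off   # 0-based
  centres_c <- geom$c0 + geom$centre_off
  grid_r <- matrix(centres_r, length(geom$r0), length(geom$c0))
  grid_c <- matrix(centres_c, length(geom$r0), length(geom$c0), byrow = TRUE)

  label <- if (is.null(mask)) {
    matrix(NA_integer_, length(geom$r0), length(geom$c0))
  } else {
    matrix(mask[cbind(as.vector(grid_r) + 1L, as.vector(grid_c) + 1L)],
           length(geom$r0), length(geom$c0))
  }

  tbl <- tibble::tibble(
    fov = as.integer(fov),
    x = as.vector(grid_c)[as.vector(keep)],
    y = as.vector(grid_r)[as.vector(keep)],
    !!!stats::setNames(lapply(feats, function(f) as.vector(f)[as.vector(keep)]),
                       PARAM_NAMES),
    label = as.vector(label)[as.vector(keep)]
  )
  finish_feature_table(tbl, "fbm", PARAM_NAMES, config, d, geom, fov)
}

#' Build DBM training instances from a decay cube
#'
#' For each block position the 256-bin histograms of all block pixels are
#' summed and normalized to unit area; blocks containing no photons are
#' dropped. Labeling follows the same center-pixel rule as
#' [extract_fbm_blocks()].
#'
#' @param cube a `flim_decay_cube`.
#' @inheritParams extract_fbm_blocks
#' @return a `flim_feature_table` with feature columns `b001` ... `b<n>`.
#' @export
extract_dbm_vectors <- function(cube, mask = NULL, config = run_config(),
                                fov = 1L) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  d <- dim(cube$counts)[1:2]
  if (!is.null(mask) && !identical(dim(mask), d)) {
    stop_value("cube and mask dimensions differ")
  }
  geom <- block_grid_geometry(d, config$block_size, config$block_stride)
  s <- config$block_stride
  nb <- cube$n_bins

  nblocks <- length(geom$r0) * length(geom$c0)
  feat <- matrix(0, nblocks, nb)
  for (k in seq_len(nb)) {
    feat[, k] <- as.vector(block_sums(cube$counts[, , k], config$block_size, s))
  }
  tot <- rowSums(feat)
  keep <- tot > 0
  feat <- feat / pmax(tot, 1e-300)

  centres_r <- geom$r0 + geom$centre_off
  centres_c <- geom$c0 + geom$centre_off
  grid_r <- matrix(centres_r, length(geom$r0), length(geom$c0))
  grid_c <- matrix(centres_c, length(geom$r0), length(geom$c0), byrow = TRUE)
  label <- if (is.null(mask)) {
    rep(NA_integer_, nblocks)
  } else {
    mask[cbind(as.vector(grid_r) + 1L, as.vector(grid_c) + 1L)]
  }

  fnames <- sprintf("b%03d", seq_len(nb))
  tbl <- tibble::tibble(
    fov = as.integer(fov),
    x = as.vector(grid_c)[keep],
    y = as.vector(grid_r)[keep]
  )
  feat_df <- tibble::as_tibble(feat[keep, , drop = FALSE], .name_repair = "minimal")
  names(feat_df) <- fnames
  tbl <- dplyr::bind_cols(tbl, feat_df)
  tbl$label <- label[keep]
  finish_feature_table(tbl, "dbm", fnames, config, d, geom, fov)
}

#' Stratified train/validation/test split
#'
#' Rows are assigned at random within each label class so that the class
#' balance of every partition matches the table (within one row per class).
#' Deterministic under `seed`.
#'
#' @param table a feature table with a binary `label` column.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return tibble with columns `row` and `split`
#'   (factor train/validation/test).
#' @export
split_dataset <- function(table, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop_value("fractions must sum to 1")
  if (length(fractions) != 3) stop_value("need train/validation/test fractions")
  lev <- c("train", "validation", "test")
  n <- nrow(table)
  assign <- character(n)
  withr::with_seed(seed, {
    for (cl in unique(table$label)) {
      idx <- which(table$label == cl)
      if (length(idx) < 3) {
        stop_value(sprintf("class %s has %d rows, fewer than the number of partitions",
                           format(cl), length(idx)))
      }
      idx <- sample(idx)
      n_tr <- round(fractions[1] * length(idx))
      n_va <- round(fractions[2] * length(idx))
      n_tr <- max(1L, min(n_tr, length(idx) - 2L))
      n_va <- max(1L, min(n_va, length(idx) - n_tr - 1L))
      assign[idx[seq_len(n_tr)]] <- "train"
      assign[idx[n_tr + seq_len(n_va)]] <- "validation"
      assign[idx[(n_tr + n_va + 1):length(idx)]] <- "test"
    }
  })
  tibble::tibble(row = seq_len(n), split = factor(assign, levels = lev))
}

#' Z-score feature normalization
#'
#' Standardizes each feature column. At training time the statistics are
#' computed from the table itself; at test time the training statistics
#' must be passed back in so that test rows are scaled exactly like the
#' training rows. Zero-variance features are centered only (with a
#' warning).
#'
#' @param table a `flim_feature_table`.
#' @param stats optional tibble with columns `feature`, `mean`, `sd`
#'   (from a previous call).
#' @return list with elements `table` (normalized) and `stats`.
#' @export
normalize_features <- function(table, stats = NULL) {
  if (nrow(table) == 0) stop_value("empty feature table")
  fn <- feature_names(table)
  if (is.null(stats)) {
    mu <- vapply(table[fn], mean, numeric(1))
    sd <- vapply(table[fn], stats::sd, numeric(1))
    if (any(sd == 0 | is.na(sd))) {
      rlang::warn("zero-variance feature(s): centered only")
      sd[sd == 0 | is.na(sd)] <- 1
    }
    stats <- tibble::tibble(feature = fn, mean = unname(mu), sd = unname(sd))
  } else {
    if (!all(fn %in% stats$feature)) stop_value("stats do not cover all features")
    stats <- stats[match(fn, stats$feature), ]
  }
  at <- attributes(table)
  for (i in seq_along(fn)) {
    table[[fn[i]]] <- (table[[fn[i]]] - stats$mean[i]) / stats$sd[i]
  }
  attributes(table) <- at
  list(table = table, stats = stats)
}
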