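# End-to-end detection pipeline on phantom (or pre-fitted) fields of view.

#' Run the full detection workflow on a set of fields of view
#'
#' Convenience driver used by the command-line tool, the examples and the
#' validation suite: fit every cube (FBM) or take the raw decays (DBM),
#' build labeled block instances from the training FOVs, split, normalize
#' and train the network, calibrate the probability/size thresholds on the
#' training FOVs, then detect on the held-out FOVs and count TP/FN/FP per
#' FOV.
#'
#' @param train_fovs,test_fovs lists of FOVs; each element is either a
#'   `flim_phantom` or a list with elements `cube` (a `flim_decay_cube`),
#'   `mask` (0/1 ground truth) and, for FBM, optionally pre-fitted `maps`.
#' @param irf IRF vector used for fitting; defaults to the phantom's own.
#' @param mode `"fbm"` (fit lifetimes, classify parameter blocks) or
#'   `"dbm"` (classify area-normalized raw decay blocks).
#' @param config a [run_config()].
#' @param regularization,max_epochs,max_rows passed to [train_network()].
#' @param seed seed for the split, initialization and row subsampling.
#' @param verbose print stage progress.
#' @return list with `fit` (the `flim_ann_fit`), `thresholds`, `metrics`
#'   (a `flim_detection` over the test FOVs), `prob_images` (test-FOV
#'   probability images) and `pred_masks`.
#' @export
run_detection_pipeline <- function(train_fovs, test_fovs, mode = c("fbm", "dbm"),
                                   config = run_config(), irf = NULL,
                                   regularization = "bayes",
                                   max_epochs = 60, max_rows = 20000,
                                   seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))

  fov_input <- function(fov) {
    if (mode == "dbm") return(fov$cube)
    if (!is.null(fov$maps)) return(fov$maps)
    say("fitting cube (%d px)...", prod(dim(fov$cube$counts)[1:2]))
    fit_cube(fov$cube, irf %||% fov$irf, config)
  }
  train_inputs <- lapply(train_fovs, fov_input)
  test_inputs <- lapply(test_fovs, fov_input)

  say("extracting %s features...", mode)
  tables <- purrr::imap(train_inputs, function(inp, i) {
    if (mode == "fbm") {
      extract_fbm_blocks(inp, train_fovs[[i]]$mask, config, fov = i)
    } else {
      extract_dbm_vectors(inp, train_fovs[[i]]$mask, config, fov = i)
    }
  })
  table <- dplyr::bind_rows(tables)
  at <- attributes(tables[[1]])
  for (nm in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(table, nm) <- at[[nm]]
  }
  class(table) <- class(tables[[1]])

  norm <- normalize_features(table)
  spl <- split_dataset(norm$table, config$split_fractions, seed = seed)
  say("training network on %d instances...", nrow(table))
  fit <- train_network(init_network(length(feature_names(table)),
                                    config$n_hidden, seed = seed),
                       norm$table, spl, stats = norm$stats,
                       regularization = regularization,
                       max_epochs = max_epochs, max_rows = max_rows,
                       seed = seed)

  say("calibrating thresholds on %d training FOVs...", length(train_fovs))
  train_probs <- lapply(train_inputs, function(inp) predict_image(fit, inp, config))
  thresholds <- calibrate_thresholds(
    train_probs, lapply(train_fovs, `[[`, "mask"), config = config)

  say("evaluating on %d test FOVs...", length(test_fovs))
  ev <- evaluate_detection(fit, thresholds, test_inputs,
                           lapply(test_fovs, `[[`, "mask"), config)

  list(fit = fit, thresholds = thresholds, metrics = ev$metrics,
       prob_images = ev$prob_images, pred_masks = ev$pred_masks)
}

#' Score, clean and count detections on held-out fields of view
#'
#' Applies a trained model and frozen thresholds to new FOVs and returns
#' the cell-level detection metrics.
#'
#' @param fit trained `flim_ann_fit` (or `flim_ann`).
#' @param thresholds a `flim_thresholds` calibrated on training FOVs.
#' @param inputs list of `flim_param_maps` (FBM) or `flim_decay_cube`s
#'   (DBM).
#' @param gt_masks list of matching ground-truth masks at image resolution.
#' @param config the [run_config()] used during training.
#' @return list with `metrics` (a `flim_detection`), `prob_images` and
#'   `pred_masks`.
#' @export
evaluate_detection <- function(fit, thresholds, inputs, gt_masks,
                               config = run_config()) {
  probs <- lapply(inputs, function(inp) predict_image(fit, inp, config))
  pred_masks <- lapply(probs, binarize_and_clean, thresholds = thresholds)
  counts <- purrr::imap(pred_masks, function(pm, i) {
    gt <- block_grid_mask(gt_masks[[i]], config)
    dplyr::mutate(match_detections(pm, gt), fov = i)
  })
  list(metrics = compute_metrics(dplyr::bind_rows(counts)),
       prob_images = probs, pred_masks = pred_masks)
}
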