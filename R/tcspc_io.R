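# On-disk artifacts: decay cubes, IRF vectors, lifetime parameter maps,
# intensity images and masks.
#
# Conventions used throughout the package:
#   * decay cubes are arrays indexed [y, x, t] (row, column, time bin);
#   * pixel coordinates are 0-based and row-major when reported in tables;
#   * the native cube format is a multi-page 32-bit float TIFF (one page per
#     time bin) with a JSON sidecar `<path>.json` holding acquisition
#     metadata and the power-of-two count scale (float TIFF pages must stay
#     in [0, 1], so counts are stored divided by that scale; integer counts
#     below 2^24 round-trip exactly);
#   * lifetime maps are plain-text whitespace-separated matrices, one file
#     per parameter (t1, t2, tm, a1, a2, a1pct, chi2 with extension .asc),
#     C-locale decimals, NaN spelled "NaN".

PARAM_NAMES <- c("t1", "t2", "tm", "a1", "a2", "a1pct", "chi2")

#' Construct a TCSPC decay cube
#'
#' A decay cube is the raw product of time-correlated single photon counting
#' imaging: for every pixel a histogram of photon arrival times, here
#' `n_bins` bins spanning one laser repetition period.
#'
#' @param counts numeric array `[y, x, t]` of non-negative photon counts.
#' @param bin_width width of one time bin in nanoseconds. The default
#'   corresponds to a 12.5 ns repetition period (80 MHz Ti:Sapphire) split
#'   into 256 bins; real systems should supply their calibrated value.
#' @param shift_bins per-acquisition timing shift of the decay, in bins.
#' @param pixel_size optional pixel size in micrometers (metadata only).
#' @return an object of class `flim_decay_cube`.
#' @export
decay_cube <- function(counts, bin_width = 12.5 / 256, shift_bins = 0,
                       pixel_size = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3) {
    stop_format("`counts` must be a 3-D array [y, x, t]")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_format("decay cube counts must be non-negative and finite")
  }
  n_bins <- dim(counts)[3]
  if (n_bins < 4) stop_value("a decay cube needs at least 4 time bins")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_value("`bin_width` must be positive (nanoseconds)")
  }
  structure(
    list(counts = counts, n_bins = n_bins, bin_width = bin_width,
         shift_bins = shift_bins, pixel_size = pixel_size),
    class = "flim_decay_cube"
  )
}

#' @export
print.flim_decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_decay_cube> %d x %d pixels, %d time bins (%.4f ns/bin)\n",
              d[1], d[2], d[3], x$bin_width))
  cat(sprintf("  total photons: %.0f, shift: %g bins\n",
              sum(x$counts), x$shift_bins))
  invisible(x)
}

#' Total photons per pixel
#' @param cube a `flim_decay_cube`.
#' @return matrix of per-pixel total counts.
#' @export
total_counts <- function(cube) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  rowSums(cube$counts, dims = 2)
}

#' Write a decay cube to a multi-page TIFF with JSON sidecar
#'
#' @param cube a `flim_decay_cube`.
#' @param path output file; a sidecar `<path>.json` is written next to it.
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  if (!dir.exists(dirname(path))) {
    stop_not_found(sprintf("directory does not exist: %s", dirname(path)))
  }
  scale <- 2^ceiling(log2(max(1, max(cube$counts))))
  pages <- lapply(seq_len(cube$n_bins), function(k) cube$counts[, , k] / scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  # 32-bit TIFF samples quantize at ~2^-32 of full scale; flag integer cubes
  # so the reader can undo that quantization exactly
  integer_counts <- all(cube$counts == round(cube$counts))
  meta <- list(bin_width_ns = cube$bin_width, shift_bins = cube$shift_bins,
               count_scale = scale, n_bins = cube$n_bins,
               integer_counts = integer_counts)
  if (!is.null(cube$pixel_size)) meta$pixel_size_um <- cube$pixel_size
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay cube from a multi-page TIFF
#'
#' Pages are time bins in order. When a JSON sidecar written by
#' [write_decay_cube()] is present its metadata is applied; otherwise the
#' defaults (12.5/256 ns bins, zero shift, counts as stored) are used so
#' that third-party TIFF time stacks can be read directly.
#'
#' @param path TIFF file whose pages are the time bins.
#' @return a `flim_decay_cube`.
#' @export
read_decay_cube <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2) {
      stop_format(sprintf(
        "page %d is not a single-channel 2-D image; decay cubes need one grayscale page per time bin", i))
    }
  }
  if (length(pages) < 4) {
    stop_format(sprintf(
      "file has %d page(s); a decay cube needs one page per time bin (>= 4)",
      length(pages)))
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("TIFF pages differ in size")
  }
  counts <- array(unlist(pages, use.names = FALSE),
                  dim = c(dims[1, 1], dims[2, 1], length(pages)))
  bin_width <- 12.5 / 256
  shift <- 0
  pixel_size <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    counts <- counts * (meta$count_scale %||% 1)
    if (isTRUE(meta$integer_counts)) counts <- round(counts)
    bin_width <- meta$bin_width_ns %||% bin_width
    shift <- meta$shift_bins %||% 0
    pixel_size <- meta$pixel_size_um
  }
  if (any(counts < -1e-9)) stop_format("negative counts in decay cube")
  counts[counts < 0] <- 0
  decay_cube(counts, bin_width = bin_width, shift_bins = shift,
             pixel_size = pixel_size)
}

#' Lifetime parameter maps
#'
#' Per-pixel images of the fitted two-component decay parameters: short and
#' long lifetime (`t1`, `t2`, ns), amplitude-weighted mean lifetime (`tm`),
#' component amplitudes (`a1`, `a2`), free fraction in percent (`a1pct`) and
#' the reduced chi-square of the fit (`chi2`). Pixels failing the photon
#' threshold are `NaN` in every map and `FALSE` in the validity mask.
#'
#' @param maps named list of seven numeric matrices (names as above).
#' @param valid logical matrix marking fitted pixels; defaults to pixels
#'   that are non-`NA` in every map.
#' @param extra optional named list of additional per-pixel matrices
#'   (e.g. fitted offset or shift) carried along for diagnostics.
#' @return object of class `flim_param_maps`.
#' @export
param_maps <- function(maps, valid = NULL, extra = list()) {
  if (!all(PARAM_NAMES %in% names(maps))) {
    stop_format(sprintf("missing parameter map(s): %s",
                        paste(setdiff(PARAM_NAMES, names(maps)), collapse = ", ")))
  }
  maps <- maps[PARAM_NAMES]
  d <- dim(maps[[1]])
  for (nm in PARAM_NAMES) {
    if (!identical(dim(maps[[nm]]), d)) {
      stop_format(sprintf("map '%s' has different dimensions", nm))
    }
  }
  if (is.null(valid)) {
    valid <- Reduce(`&`, lapply(maps, function(m) !is.na(m)))
  }
  # invalid pixels are NaN everywhere
  for (nm in PARAM_NAMES) maps[[nm]][!valid] <- NaN
  structure(list(maps = maps, valid = valid, extra = extra),
            class = "flim_param_maps")
}

#' @export
print.flim_param_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("<flim_param_maps> %d x %d, %d/%d pixels fitted\n",
              d[1], d[2], sum(x$valid), prod(d)))
  invisible(x)
}

#' @export
dim.flim_param_maps <- function(x) dim(x$maps[[1]])

asc_file <- function(directory, name) file.path(directory, paste0(name, ".asc"))

#' Write parameter maps as ASC text matrices
#'
#' One whitespace-delimited text file per parameter (`t1.asc` ... `chi2.asc`),
#' one image row per line, `NaN` for unfitted pixels. This mirrors the plain
#' matrix export of commercial TCSPC fitting software.
#'
#' @param maps a `flim_param_maps`.
#' @param directory output directory (created if needed).
#' @export
write_param_maps <- function(maps, directory) {
  stopifnot(inherits(maps, "flim_param_maps"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in PARAM_NAMES) {
    m <- maps$maps[[nm]]
    lines <- apply(m, 1, function(row) {
      paste(ifelse(is.na(row), "NaN", formatC(row, format = "g", digits = 9)),
            collapse = " ")
    })
    writeLines(lines, asc_file(directory, nm))
  }
  invisible(directory)
}

#' Read parameter maps from ASC text matrices
#'
#' @param directory directory holding `t1.asc`, `t2.asc`, `tm.asc`, `a1.asc`,
#'   `a2.asc`, `a1pct.asc`, `chi2.asc`.
#' @param zero_as_na treat 0 as the unfitted-pixel sentinel (some exporters
#'   write 0 instead of NaN).
#' @return a `flim_param_maps`.
#' @export
read_param_maps <- function(directory, zero_as_na = FALSE) {
  if (!dir.exists(directory)) {
    stop_not_found(sprintf("no such directory: %s", directory))
  }
  maps <- list()
  for (nm in PARAM_NAMES) {
    f <- asc_file(directory, nm)
    if (!file.exists(f)) stop_format(sprintf("missing parameter file: %s", f))
    m <- as.matrix(utils::read.table(f, header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (zero_as_na) m[m == 0] <- NaN
    maps[[nm]] <- m
  }
  d <- dim(maps[[1]])
  for (nm in PARAM_NAMES) {
    if (!identical(dim(maps[[nm]]), d)) {
      stop_format(sprintf("dimension mismatch: %s.asc is %d x %d, t1.asc is %d x %d",
                          nm, nrow(maps[[nm]]), ncol(maps[[nm]]), d[1], d[2]))
    }
  }
  param_maps(maps)
}

#' Read a grayscale intensity image
#'
#' @param path single-page grayscale TIFF.
#' @return numeric matrix of non-negative intensities.
#' @export
read_intensity_image <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: %s", path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    stop_format(paste0("multi-channel TIFF: select one channel ",
                       "(e.g. img[ , , 1]) and save it as grayscale first"))
  }
  if (any(img < 0)) stop_format("negative intensity values")
  img
}

#' Write a grayscale image (values scaled to the unit range)
#' @param img numeric matrix.
#' @param path output TIFF.
#' @export
write_intensity_image <- function(img, path) {
  mx <- max(img, 1e-12)
  tiff::writeTIFF(img / mx, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary mask
#'
#' Accepts masks stored as 0/1 or 0/255 single-page TIFFs and returns a
#' strict 0/1 integer matrix.
#'
#' @param path mask TIFF.
#' @return integer matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: %s", path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    stop_format("multi-channel TIFF: masks must be single-channel; select one channel first")
  }
  u <- sort(unique(as.vector(img)))
  if (!all(u %in% c(0, 1)) && !all(u %in% c(0, 255))) {
    stop_format("mask values must be 0/1 or 0/255")
  }
  m <- matrix(as.integer(img > 0), nrow(img), ncol(img))
  m
}

#' Write a binary mask as an 8-bit TIFF
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop_value("mask values must be 0 or 1")
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read / write an IRF vector (plain text, one value per line)
#' @param path text file.
#' @return numeric IRF vector.
#' @export
read_irf <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: %s", path))
  v <- scan(path, quiet = TRUE)
  if (any(v < 0) || sum(v) <= 0) stop_format("IRF values must be non-negative with positive sum")
  v
}

#' @rdname read_irf
#' @param irf numeric vector of non-negative values.
#' @export
write_irf <- function(irf, path) {
  writeLines(formatC(irf, format = "g", digits = 17), path)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the knobs shared across the fitting, feature-extraction and
#' training stages.
#'
#' @param photon_threshold minimum per-pixel total photon count for a pixel
#'   to be fitted; dimmer pixels become `NaN` in every parameter map.
#' @param bin_radius spatial binning radius: each pixel's decay is summed
#'   over its (2r+1) x (2r+1) neighborhood before fitting.
#' @param block_size side of the square feature blocks (pixels).
#' @param block_stride stride between block positions; 1 = maximally
#'   overlapping blocks.
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param n_hidden hidden neurons in the classifier network.
#' @param seed RNG seed used for splitting and network initialization.
#' @return object of class `flim_run_config`.
#' @export
run_config <- function(photon_threshold = 100, bin_radius = 1,
                       block_size = 8, block_stride = 1,
                       split_fractions = c(0.70, 0.15, 0.15),
                       n_hidden = 10, seed = 1L) {
  if (photon_threshold < 0) stop_value("photon_threshold must be >= 0")
  if (bin_radius < 0) stop_value("bin_radius must be >= 0")
  if (block_size < 1 || block_stride < 1) {
    stop_value("block_size and block_stride must be positive")
  }
  if (length(split_fractions) != 3 ||
      any(split_fractions <= 0) || any(split_fractions >= 1) ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    stop_value("split_fractions must be three values in (0,1) summing to 1")
  }
  if (n_hidden < 1) stop_value("n_hidden must be positive")
  structure(
    list(photon_threshold = photon_threshold, bin_radius = bin_radius,
         block_size = as.integer(block_size),
         block_stride = as.integer(block_stride),
         split_fractions = split_fractions,
         n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
    class = "flim_run_config"
  )
}
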