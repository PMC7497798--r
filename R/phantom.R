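# Synthetic FLIM phantoms.
#
# A phantom is a simulated field of view: cell bodies with branching
# processes are painted onto a background, every pixel gets a true
# (tau1, tau2, a1%) triple, the expected decay is the IRF-convolved
# two-component exponential scaled to the pixel's photon budget, and the
# observed cube is a Poisson draw from it. Ground truth (microglia mask,
# class map, true parameter maps, per-cell manifest) is returned alongside,
# so every downstream stage can be validated without microscope data.

#' Describe one simulated cell class
#'
#' Lifetime parameters are drawn per cell (cells are internally coherent)
#' and then jittered per pixel at 20% of the class standard deviation.
#'
#' @param name class label, e.g. `"microglia"`.
#' @param tau1,tau1_sd short-lifetime mean and between-cell sd (ns).
#' @param tau2,tau2_sd long-lifetime mean and between-cell sd (ns).
#' @param a1_pct,a1_pct_sd free-fraction mean and sd (percent).
#' @param photons_per_pixel expected total photons per cell pixel.
#' @param soma_radius range of soma semi-axes in pixels.
#' @param n_processes range of branch processes per cell.
#' @param process_length range of branch lengths in pixels.
#' @param process_width branch width in pixels (1 or 2).
#' @return object of class `flim_cell_class`.
#' @export
cell_class_spec <- function(name, tau1 = 0.4, tau1_sd = 0.05,
                            tau2 = 2.4, tau2_sd = 0.2,
                            a1_pct = 78, a1_pct_sd = 4,
                            photons_per_pixel = 3000,
                            soma_radius = c(3, 6), n_processes = c(2, 5),
                            process_length = c(5, 15), process_width = 1) {
  if (tau1 <= 0 || tau2 <= tau1) stop_value("need 0 < tau1 < tau2")
  if (a1_pct <= 0 || a1_pct >= 100) stop_value("a1_pct must be in (0, 100)")
  if (min(tau1_sd, tau2_sd, a1_pct_sd) < 0) stop_value("sds must be >= 0")
  if (photons_per_pixel <= 0) stop_value("photons_per_pixel must be positive")
  structure(
    list(name = name, tau1 = tau1, tau1_sd = tau1_sd, tau2 = tau2,
         tau2_sd = tau2_sd, a1_pct = a1_pct, a1_pct_sd = a1_pct_sd,
         photons_per_pixel = photons_per_pixel, soma_radius = soma_radius,
         n_processes = n_processes, process_length = process_length,
         process_width = process_width),
    class = "flim_cell_class"
  )
}

#' Phantom configuration
#'
#' The default class parameters are modelling assumptions chosen to give a
#' separable but noisy problem in the plausible NAD(P)H range, not measured
#' values: microglia-like cells have a larger free fraction and shorter
#' bound lifetime than the other-glia class. All of them are configurable.
#'
#' @param size image side in pixels (square FOV).
#' @param n_microglia,n_other number of cells per class.
#' @param classes named list with elements `microglia` and `other`, each a
#'   [cell_class_spec()].
#' @param background list with `photons` (expected photons per background
#'   pixel), a (`tau1`, `tau2`, `a1_pct`) triple, and `tau1_sd`, `tau2_sd`,
#'   `a1_pct_sd` controlling per-pixel background variability.
#' @param n_bins,bin_width TCSPC histogram geometry.
#' @param irf_sigma_bins,irf_t0_bins Gaussian IRF width and position (bins).
#' @param shift_bins fixed decay shift applied to the FOV, in bins.
#' @param shift_jitter_sd sd of an additional per-FOV random shift (bins);
#'   emulates detector timing drift between acquisitions.
#' @param heterogeneity multiplier on all parameter sds; the `"tissue"`
#'   preset uses a larger value than `"culture"` to mimic the broader
#'   lifetime variation of intact tissue.
#' @param seed RNG seed; the same seed reproduces the phantom bit for bit.
#' @return object of class `flim_phantom_config`.
#' @export
phantom_config <- function(size = 128, n_microglia = 6, n_other = 6,
                           classes = list(
                             microglia = cell_class_spec(
                               "microglia", tau1 = 0.4, tau1_sd = 0.05,
                               tau2 = 2.4, tau2_sd = 0.15,
                               a1_pct = 78, a1_pct_sd = 3),
                             other = cell_class_spec(
                               "other", tau1 = 0.4, tau1_sd = 0.05,
                               tau2 = 3.0, tau2_sd = 0.15,
                               a1_pct = 68, a1_pct_sd = 3)),
                           background = list(photons = 150, tau1 = 0.4,
                                             tau2 = 2.8, a1_pct = 70,
                                             tau1_sd = 0.02, tau2_sd = 0.1,
                                             a1_pct_sd = 2),
                           n_bins = 256, bin_width = 12.5 / 256,
                           irf_sigma_bins = 2, irf_t0_bins = 10,
                           shift_bins = 0, shift_jitter_sd = 0,
                           heterogeneity = 1, seed = 1L) {
  max_r <- max(vapply(classes, function(cl) max(cl$soma_radius), numeric(1)))
  if (size < 4 * max_r) stop_value("image too small for the configured cells")
  if (background$photons < 0) stop_value("background photons must be >= 0")
  if (heterogeneity <= 0) stop_value("heterogeneity must be positive")
  structure(
    list(size = as.integer(size), n_microglia = as.integer(n_microglia),
         n_other = as.integer(n_other), classes = classes,
         background = background, n_bins = as.integer(n_bins),
         bin_width = bin_width, irf_sigma_bins = irf_sigma_bins,
         irf_t0_bins = irf_t0_bins, shift_bins = shift_bins,
         shift_jitter_sd = shift_jitter_sd, heterogeneity = heterogeneity,
         seed = as.integer(seed)),
    class = "flim_phantom_config"
  )
}

#' Preset phantom configurations
#'
#' `"culture"` mimics mixed glial cultures: moderate cell density, tight
#' within-class lifetime distributions. `"tissue"` raises the heterogeneity
#' multiplier and background fluorescence and packs in more non-microglia
#' cells, mimicking the broader lifetime variation of brain slices.
#'
#' @param preset `"culture"` or `"tissue"`.
#' @param ... overrides passed to [phantom_config()].
#' @export
phantom_preset <- function(preset = c("culture", "tissue"), ...) {
  preset <- match.arg(preset)
  defaults <- if (preset == "culture") {
    list(heterogeneity = 1)
  } else {
    list(heterogeneity = 2.5, n_other = 10,
         background = list(photons = 400, tau1 = 0.4, tau2 = 2.8,
                           a1_pct = 70, tau1_sd = 0.02,
                           tau2_sd = 0.1, a1_pct_sd = 2))
  }
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

#' Discretized Gaussian stand-in for a measured IRF
#'
#' @param n_bins histogram length.
#' @param sigma_bins Gaussian width in bins (> 0).
#' @param t0_bins center position in bins.
#' @return non-negative vector of length `n_bins` summing to 1, with its
#'   mode at `round(t0_bins)`.
#' @export
generate_irf <- function(n_bins = 256, sigma_bins = 2, t0_bins = 10) {
  if (sigma_bins <= 0) stop_value("sigma_bins must be positive")
  if (t0_bins < 0 || t0_bins >= n_bins) stop_value("t0_bins out of range")
  k <- seq_len(n_bins) - 1
  v <- exp(-0.5 * ((k - t0_bins) / sigma_bins)^2)
  v / sum(v)
}

#' Shift every decay in a cube by a fractional number of bins
#'
#' Circular linear interpolation along the time axis; total counts are
#' conserved up to interpolation (counts become reals — this operation is
#' meant for simulating detector timing drift, not for storage).
#'
#' @param cube a `flim_decay_cube`.
#' @param shift_bins shift in bins, `|shift| < n_bins / 2`.
#' @return shifted `flim_decay_cube` with updated `shift_bins` metadata.
#' @export
apply_decay_shift <- function(cube, shift_bins) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  if (abs(shift_bins) >= cube$n_bins / 2) {
    stop_value("|shift_bins| must be below n_bins / 2")
  }
  if (shift_bins == 0) return(cube)
  d <- dim(cube$counts)
  m <- matrix(cube$counts, d[1] * d[2], d[3])
  out <- pmax(shift_rows_circular(m, shift_bins), 0)  # clear interpolation round-off
  decay_cube(array(out, d), bin_width = cube$bin_width,
             shift_bins = cube$shift_bins + shift_bins,
             pixel_size = cube$pixel_size)
}

# circular fractional shift applied to every row of a pixels x bins matrix
shift_rows_circular <- function(m, shift) {
  n <- ncol(m)
  x <- (seq_len(n) - 1) - shift
  i0 <- floor(x)
  f <- x - i0
  lo <- (i0 %% n) + 1L
  hi <- ((i0 + 1L) %% n) + 1L
  sweep(m[, lo, drop = FALSE], 2, 1 - f, `*`) +
    sweep(m[, hi, drop = FALSE], 2, f, `*`)
}

# Paint one cell (soma ellipse + random-walk processes) onto a logical mask.
# Returns the updated mask; drawing consumes RNG, so placement is part of
# the seeded stream. Branch walks reflect at the `margin` box so that a
# cell's footprint stays connected after any border cropping downstream
# (block-feature grids drop a frame of block_size/2 pixels).
paint_cell <- function(mask, cx, cy, spec, margin = 6) {
  size <- nrow(mask)
  lo <- margin + 1; hi <- size - margin
  rx <- stats::runif(1, spec$soma_radius[1], spec$soma_radius[2])
  ry <- stats::runif(1, spec$soma_radius[1], spec$soma_radius[2])
  th <- stats::runif(1, 0, pi)
  r <- ceiling(max(rx, ry))
  rows <- max(1, cy - r):min(size, cy + r)
  cols <- max(1, cx - r):min(size, cx + r)
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(th) + dy * sin(th)) / rx
  v <- (-dx * sin(th) + dy * cos(th)) / ry
  mask[rows, cols] <- mask[rows, cols] | (u^2 + v^2 <= 1)

  n_proc <- sample(spec$n_processes[1]:spec$n_processes[2], 1)
  for (p in seq_len(n_proc)) {
    ang <- stats::runif(1, 0, 2 * pi)
    len <- sample(spec$process_length[1]:spec$process_length[2], 1)
    # start just inside the rotated soma boundary so the branch stays attached
    px <- cx + 0.9 * (rx * cos(ang) * cos(th) - ry * sin(ang) * sin(th))
    py <- cy + 0.9 * (rx * cos(ang) * sin(th) + ry * sin(ang) * cos(th))
    for (s in seq_len(len)) {
      ang <- ang + stats::rnorm(1, 0, 0.3)
      px <- px + cos(ang)
      py <- py + sin(ang)
      if (px < lo || px > hi) { px <- min(max(px, lo), hi); ang <- pi - ang }
      if (py < lo || py > hi) { py <- min(max(py, lo), hi); ang <- -ang }
      ix <- round(px); iy <- round(py)
      mask[iy, ix] <- TRUE
      if (spec$process_width > 1) {
        for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
          jy <- iy + d[1]; jx <- ix + d[2]
          if (jy >= lo && jy <= hi && jx >= lo && jx <= hi) mask[jy, jx] <- TRUE
        }
      }
    }
  }
  mask
}

#' Generate a synthetic FLIM field of view
#'
#' @param config a [phantom_config()] or [phantom_preset()].
#' @return object of class `flim_phantom`: a list with
#'   * `cube` — the Poisson photon-count `flim_decay_cube`,
#'   * `mask` — 0/1 ground-truth microglia mask (somas and processes),
#'   * `class_map` — 0 background / 1 microglia / 2 other,
#'   * `truth` — true per-pixel `t1`, `t2`, `a1pct`, `tm` matrices,
#'   * `irf` — the IRF used,
#'   * `manifest` — tibble of per-cell drawn parameters,
#'   * `shift_applied` — the realized decay shift in bins,
#'   * `config` — the configuration.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "flim_phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  size <- cfg$size
  het <- cfg$heterogeneity
  class_map <- matrix(0L, size, size)
  t1 <- matrix(NA_real_, size, size)
  t2 <- matrix(NA_real_, size, size)
  a1p <- matrix(NA_real_, size, size)
  photons <- matrix(cfg$background$photons, size, size)

  # background per-pixel parameter fields
  bg <- cfg$background
  t1[] <- stats::rnorm(size^2, bg$tau1, (bg$tau1_sd %||% 0) * het)
  t2[] <- stats::rnorm(size^2, bg$tau2, (bg$tau2_sd %||% 0) * het)
  a1p[] <- stats::rnorm(size^2, bg$a1_pct, (bg$a1_pct_sd %||% 0) * het)

  # place cells: "other" first, microglia last so that on overlap the
  # later-placed (microglia) cell deterministically wins
  plan <- c(rep("other", cfg$n_other), rep("microglia", cfg$n_microglia))
  manifest <- vector("list", length(plan))
  microglia_mask <- matrix(FALSE, size, size)
  edge <- 6L  # keep footprints clear of the border so block grids never cut them
  margin <- edge + ceiling(max(vapply(cfg$classes,
                                      function(cl) max(cl$soma_radius),
                                      numeric(1)))) + 1
  for (i in seq_along(plan)) {
    cl <- cfg$classes[[plan[i]]]
    cx <- sample(seq(margin + 1, size - margin), 1)
    cy <- sample(seq(margin + 1, size - margin), 1)
    cell_tau1 <- max(stats::rnorm(1, cl$tau1, cl$tau1_sd * het), 0.05)
    cell_tau2 <- max(stats::rnorm(1, cl$tau2, cl$tau2_sd * het), cell_tau1 + 0.1)
    cell_a1p <- min(max(stats::rnorm(1, cl$a1_pct, cl$a1_pct_sd * het), 1), 99)

    foot <- paint_cell(matrix(FALSE, size, size), cx, cy, cl, margin = edge)
    class_map[foot] <- if (plan[i] == "microglia") 1L else 2L
    if (plan[i] == "microglia") microglia_mask <- microglia_mask | foot

    npx <- sum(foot)
    t1[foot] <- pmax(cell_tau1 + stats::rnorm(npx, 0, 0.2 * cl$tau1_sd * het), 0.05)
    t2[foot] <- cell_tau2 + stats::rnorm(npx, 0, 0.2 * cl$tau2_sd * het)
    t2[foot] <- pmax(t2[foot], t1[foot] + 0.1)
    a1p[foot] <- pmin(pmax(cell_a1p + stats::rnorm(npx, 0, 0.2 * cl$a1_pct_sd * het), 1), 99)
    photons[foot] <- cl$photons_per_pixel

    manifest[[i]] <- tibble::tibble(
      cell = i, class = plan[i], x = cx - 1L, y = cy - 1L,
      tau1 = cell_tau1, tau2 = cell_tau2, a1_pct = cell_a1p,
      n_pixels = npx)
  }
  # cells painted later may have overwritten earlier footprints
  class_map[microglia_mask] <- 1L

  t1 <- pmax(t1, 0.05)
  t2 <- pmax(t2, t1 + 0.05)
  a1p <- pmin(pmax(a1p, 1), 99)

  irf <- generate_irf(cfg$n_bins, cfg$irf_sigma_bins, cfg$irf_t0_bins)
  tvec <- (seq_len(cfg$n_bins) - 1) * cfg$bin_width

  # expected decays: rows are pixels in R's column-major order
  a1f <- as.vector(a1p) / 100
  D <- a1f * exp(-outer(1 / as.vector(t1), tvec)) +
    (1 - a1f) * exp(-outer(1 / as.vector(t2), tvec))
  conv <- matrix(0, cfg$n_bins, cfg$n_bins)
  for (k in seq_len(cfg$n_bins)) conv[k, 1:k] <- irf[k:1]
  D <- D %*% t(conv)
  D <- D * (as.vector(photons) / rowSums(D))

  shift <- cfg$shift_bins +
    if (cfg$shift_jitter_sd > 0) stats::rnorm(1, 0, cfg$shift_jitter_sd) else 0
  if (shift != 0) D <- shift_rows_circular(D, shift)

  counts <- array(stats::rpois(length(D), as.vector(D)),
                  dim = c(size, size, cfg$n_bins))
  cube <- decay_cube(counts, bin_width = cfg$bin_width, shift_bins = shift)

  structure(
    list(cube = cube,
         mask = matrix(as.integer(microglia_mask), size, size),
         class_map = class_map,
         truth = list(t1 = t1, t2 = t2, a1pct = a1p,
                      tm = (a1p / 100) * t1 + (1 - a1p / 100) * t2),
         irf = irf,
         manifest = dplyr::bind_rows(manifest),
         shift_applied = shift,
         config = cfg),
    class = "flim_phantom"
  )
}

#' @export
print.flim_phantom <- function(x, ...) {
  cat(sprintf("<flim_phantom> %d x %d px, %d microglia + %d other cells, shift %.2f bins\n",
              x$config$size, x$config$size, x$config$n_microglia,
              x$config$n_other, x$shift_applied))
  invisible(x)
}
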