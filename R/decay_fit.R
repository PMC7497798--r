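# Two-component exponential decay modelling and per-pixel fitting.
#
# The measured TCSPC histogram is modelled as the discrete convolution of
# the instrument response function (IRF) with
#   d(t) = a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
# sampled at t_k = k * bin_width, plus a constant background offset. tau1 is
# the short (free NAD(P)H) component, tau2 the long (protein-bound) one.
# Fitting minimizes Poisson-weighted squared residuals (model-based
# variance) with a Levenberg-Marquardt routine (compiled; see src/fit.cpp).

#' Amplitude-weighted mean fluorescence lifetime
#'
#' `tau_m = (a1 * tau1 + a2 * tau2) / (a1 + a2)`, the standard summary of a
#' two-component NAD(P)H decay. Vectorized over all arguments.
#'
#' @param a1,a2 component amplitudes (non-negative).
#' @param tau1,tau2 component lifetimes in ns.
#' @return mean lifetime in ns.
#' @export
mean_lifetime <- function(a1, tau1, a2, tau2) {
  s <- a1 + a2
  if (any(s == 0)) stop_value("a1 + a2 must be positive")
  (a1 * tau1 + a2 * tau2) / s
}

#' Expected decay histogram for given parameters
#'
#' Convolves the (optionally shift-interpolated) IRF with the two-component
#' exponential and adds the offset. The convolution uses the exact O(n)
#' recursion `y_k = exp(-dt/tau) * y_{k-1} + irf_k`.
#'
#' @param tau1,tau2 lifetimes in ns (must be positive; set `a2 = 0` for a
#'   single-component decay).
#' @param a1,a2 amplitudes.
#' @param irf IRF vector of length `n_bins`.
#' @param n_bins number of time bins.
#' @param bin_width bin width in ns.
#' @param offset constant background counts per bin.
#' @param shift decay shift in bins (IRF is shifted by linear interpolation,
#'   zero-padded; positive = later).
#' @return numeric vector of expected counts per bin.
#' @export
model_decay <- function(tau1, tau2, a1, a2, irf, n_bins = length(irf),
                        bin_width = 12.5 / 256, offset = 0, shift = 0) {
  if (tau1 <= 0 || (a2 > 0 && tau2 <= 0)) stop_value("lifetimes must be positive")
  if (length(irf) != n_bins) stop_value("irf length must equal n_bins")
  irf_s <- shift_curve(irf, shift)
  y1 <- as.numeric(stats::filter(irf_s, exp(-bin_width / tau1), method = "recursive"))
  out <- a1 * y1
  if (a2 > 0) {
    y2 <- as.numeric(stats::filter(irf_s, exp(-bin_width / tau2), method = "recursive"))
    out <- out + a2 * y2
  }
  out + offset
}

#' Spatially bin a decay cube
#'
#' Replaces each pixel's histogram by the sum over its (2r+1) x (2r+1)
#' neighborhood (truncated at image edges), the usual trick to reach a
#' fittable photon count per pixel without losing the pixel grid.
#'
#' @param cube a `flim_decay_cube`.
#' @param radius binning radius r; `0` returns the cube unchanged.
#' @return a `flim_decay_cube` with binned counts.
#' @export
spatial_bin <- function(cube, radius) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  if (radius < 0) stop_value("radius must be >= 0")
  if (radius == 0) return(cube)
  d <- dim(cube$counts)
  out <- cube$counts
  # cumsum round-off on real-valued (e.g. shift-interpolated) cubes can
  # leave values a few ulp below zero; clamp them
  for (k in seq_len(d[3])) out[, , k] <- pmax(box_sum(cube$counts[, , k], radius), 0)
  decay_cube(out, bin_width = cube$bin_width, shift_bins = cube$shift_bins,
             pixel_size = cube$pixel_size)
}

#' Fit one decay histogram
#'
#' Levenberg-Marquardt fit of the IRF-convolved two-component model with
#' Poisson weights `1/max(model, 1)` (model-based variance, recomputed at
#' every step; data-based weights bias the long component low when tail
#' bins are photon-starved). Components are ordered so that
#' `tau1 <= tau2`; if the two lifetimes collapse (ratio < 1.5) the decay is
#' refitted with a single component and `a2` is set to 0. The timing shift
#' is a bounded nuisance parameter when `fit_shift = TRUE`.
#'
#' Starting values: tau1 = 0.5 ns, tau2 = 2.5 ns, offset from the bins
#' preceding the IRF rise, amplitudes matching the total count with a 70/30
#' split. The fit window runs from 2 bins before the IRF mode to the last
#' bin holding at least one photon.
#'
#' @param decay numeric vector of counts (must contain photons).
#' @param irf IRF vector of the same length.
#' @param bin_width bin width in ns.
#' @param fit_shift fit the timing shift as a free parameter.
#' @param shift_bound bound on the fitted shift in bins.
#' @param max_iter,tol LM iteration cap and relative convergence tolerance.
#' @return object of class `flim_decay_fit`: fitted parameters (`tau1`,
#'   `tau2`, `a1`, `a2`, `a1_pct`, `tau_m`, `chi2`, `offset`, `shift`),
#'   `converged` flag, and the data/fitted curves for inspection.
#' @export
fit_decay <- function(decay, irf, bin_width = 12.5 / 256, fit_shift = TRUE,
                      shift_bound = 3, max_iter = 200, tol = 1e-8) {
  if (sum(decay) <= 0) stop_value("cannot fit an all-zero decay")
  if (length(decay) != length(irf)) stop_value("decay and irf lengths differ")
  v <- fit_decay_cpp(as.numeric(decay), as.numeric(irf), bin_width,
                     fit_shift, shift_bound, max_iter, tol)
  fitted <- model_decay(v[["tau1"]], v[["tau2"]], v[["a1"]], v[["a2"]],
                        irf = irf, bin_width = bin_width,
                        offset = v[["offset"]], shift = v[["shift"]])
  structure(
    list(tau1 = v[["tau1"]], tau2 = v[["tau2"]], a1 = v[["a1"]],
         a2 = v[["a2"]], a1_pct = v[["a1_pct"]], tau_m = v[["tau_m"]],
         chi2 = v[["chi2"]], offset = v[["offset"]], shift = v[["shift"]],
         converged = v[["converged"]] > 0, iterations = v[["iterations"]],
         n_components = v[["n_components"]],
         decay = as.numeric(decay), irf = as.numeric(irf),
         bin_width = bin_width, fitted = fitted),
    class = "flim_decay_fit"
  )
}

#' @export
print.flim_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_decay_fit> tau1 %.3f ns, tau2 %.3f ns, a1 %.1f%%, tau_m %.3f ns, chi2 %.3f%s\n",
    x$tau1, x$tau2, x$a1_pct, x$tau_m, x$chi2,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit every pixel of a decay cube
#'
#' Applies the photon threshold, spatially bins the cube, fits each passing
#' pixel with [fit_decay()]'s compiled core and assembles the seven
#' parameter maps. Pixels below the threshold are `NaN` in every map.
#'
#' @param cube a `flim_decay_cube`.
#' @param irf IRF vector of length `cube$n_bins`.
#' @param config a [run_config()]; uses `photon_threshold` and `bin_radius`.
#' @param fit_shift,shift_bound,max_iter,tol as in [fit_decay()].
#' @return a `flim_param_maps`; `$extra` carries the fitted offset, shift
#'   and convergence maps.
#' @export
fit_cube <- function(cube, irf, config = run_config(), fit_shift = TRUE,
                     shift_bound = 3, max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(cube, "flim_decay_cube"))
  if (length(irf) != cube$n_bins) stop_value("irf length must equal n_bins")
  d <- dim(cube$counts)
  valid <- total_counts(cube) >= config$photon_threshold
  binned <- spatial_bin(cube, config$bin_radius)
  npix <- d[1] * d[2]
  decays <- matrix(binned$counts, npix, d[3])  # pixel-major (column order)
  idx <- which(as.vector(valid))

  blank <- matrix(NaN, d[1], d[2])
  maps <- stats::setNames(replicate(7, blank, simplify = FALSE), PARAM_NAMES)
  extra <- list(offset = blank, shift = blank, converged = blank)

  if (length(idx) > 0) {
    fits <- fit_decays_cpp(decays[idx, , drop = FALSE], as.numeric(irf),
                           cube$bin_width, fit_shift, shift_bound,
                           max_iter, tol)
    col_for <- c(t1 = "tau1", t2 = "tau2", tm = "tau_m", a1 = "a1",
                 a2 = "a2", a1pct = "a1_pct", chi2 = "chi2")
    for (nm in PARAM_NAMES) maps[[nm]][idx] <- fits[, col_for[[nm]]]
    extra$offset[idx] <- fits[, "offset"]
    extra$shift[idx] <- fits[, "shift"]
    extra$converged[idx] <- fits[, "converged"]
  }
  param_maps(maps, valid = valid & !is.na(maps$t1), extra = extra)
}
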