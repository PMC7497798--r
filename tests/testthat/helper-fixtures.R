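# Shared fixtures, all generated in code.

DT <- 12.5 / 256

small_cube <- function(ny = 4, nx = 4, nb = 8, seed = 1, lambda = 5) {
  withr::with_seed(seed, {
    decay_cube(array(rpois(ny * nx * nb, lambda), dim = c(ny, nx, nb)),
               bin_width = DT)
  })
}

# a feature table built directly from a matrix, for classifier tests
make_feature_table <- function(X, y, fnames = sprintf("f%d", seq_len(ncol(X)))) {
  tbl <- tibble::tibble(fov = 1L, x = seq_len(nrow(X)) - 1L, y = 0L)
  for (i in seq_along(fnames)) tbl[[fnames[i]]] <- X[, i]
  tbl$label <- y
  structure(tbl, class = c("flim_feature_table", class(tibble::tibble())),
            mode = "custom", feature_names = fnames)
}

constant_param_maps <- function(value = 1, nr = 6, nc = 6) {
  maps <- stats::setNames(
    replicate(7, matrix(value, nr, nc), simplify = FALSE),
    c("t1", "t2", "tm", "a1", "a2", "a1pct", "chi2"))
  param_maps(maps)
}

# tiny culture-like phantom, cheap enough for unit tests
tiny_phantom <- function(seed = 1, size = 48, n_microglia = 3, n_other = 3, ...) {
  generate_phantom(phantom_preset("culture", size = size,
                                  n_microglia = n_microglia,
                                  n_other = n_other, seed = seed, ...))
}

# tight class separation: classification margin is small, so decay-shape
# perturbations (timing shifts) can push blocks across the boundary
tight_phantom <- function(seed, size = 48, n_microglia = 3, n_other = 3) {
  generate_phantom(phantom_config(
    size = size, n_microglia = n_microglia, n_other = n_other, seed = seed,
    classes = list(
      microglia = cell_class_spec("microglia", tau2 = 2.4, tau2_sd = 0.1,
                                  a1_pct = 78, a1_pct_sd = 2),
      other = cell_class_spec("other", tau2 = 2.7, tau2_sd = 0.1,
                              a1_pct = 73, a1_pct_sd = 2))))
}

# brute-force reference for block means over valid pixels
brute_block_means <- function(m, valid, b, stride) {
  nr <- nrow(m) - b + 1
  nc <- ncol(m) - b + 1
  out <- list()
  for (r0 in seq(1, nr, by = stride)) {
    for (c0 in seq(1, nc, by = stride)) {
      vv <- valid[r0:(r0 + b - 1), c0:(c0 + b - 1)]
      mm <- m[r0:(r0 + b - 1), c0:(c0 + b - 1)]
      out[[length(out) + 1]] <- data.frame(
        y = r0 - 1 + b %/% 2, x = c0 - 1 + b %/% 2,
        n_valid = sum(vv),
        mean = if (sum(vv) > 0) mean(mm[vv]) else NA_real_)
    }
  }
  do.call(rbind, out)
}
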