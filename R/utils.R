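# Internal helpers: typed errors, shared numeric utilities.

stop_value <- function(msg, ...) {
  rlang::abort(msg, class = "flimglia_error_value", ...)
}

stop_format <- function(msg, ...) {
  rlang::abort(msg, class = "flimglia_error_format", ...)
}

stop_not_found <- function(msg, ...) {
  rlang::abort(msg, class = "flimglia_error_not_found", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a sampled curve by a fractional number of bins
#'
#' Linear interpolation of `v` at positions `k - shift`. With
#' `circular = TRUE` indices wrap around (used when simulating detector
#' timing shifts, where photons leaving one end of the TCSPC window
#' re-enter at the other); otherwise out-of-range samples are zero.
#' Positive shifts move the curve toward later bins.
#'
#' @param v numeric vector.
#' @param shift shift in bins; may be fractional.
#' @param circular wrap around instead of zero-padding.
#' @return numeric vector of the same length.
#' @keywords internal
shift_curve <- function(v, shift, circular = FALSE) {
  n <- length(v)
  if (shift == 0) return(v)
  x <- (seq_len(n) - 1) - shift
  i0 <- floor(x)
  f <- x - i0
  if (circular) {
    lo <- v[(i0 %% n) + 1L]
    hi <- v[((i0 + 1L) %% n) + 1L]
  } else {
    lo <- ifelse(i0 >= 0 & i0 < n, v[pmax(i0, 0) + 1L], 0)
    hi <- ifelse(i0 + 1L >= 0 & i0 + 1L < n, v[pmax(i0 + 1L, 0) + 1L], 0)
  }
  (1 - f) * lo + f * hi
}

# Edge-truncated (2r+1)x(2r+1) box sum of a matrix via integral images.
box_sum <- function(m, r) {
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ii <- rbind(0, apply(rbind(0, m), 2, cumsum)[-1, , drop = FALSE])
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  # ii is (nr+1) x (nc+1), ii[i+1, j+1] = sum m[1:i, 1:j]
  r1 <- pmax(seq_len(nr) - r, 1L); r2 <- pmin(seq_len(nr) + r, nr)
  c1 <- pmax(seq_len(nc) - r, 1L); c2 <- pmin(seq_len(nc) + r, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- ii[cbind(r2 + 1L, c2[j] + 1L)] - ii[cbind(r1, c2[j] + 1L)] -
      ii[cbind(r2 + 1L, c1[j])] + ii[cbind(r1, c1[j])]
  }
  out
}

# Sums over block_size x block_size tiles at the given stride.
# Returns a matrix with one entry per block position (row-major grid).
block_sums <- function(m, block_size, stride) {
  nr <- nrow(m); nc <- ncol(m)
  b <- block_size
  ii <- rbind(0, apply(rbind(0, m), 2, cumsum)[-1, , drop = FALSE])
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r0 <- seq(0L, nr - b, by = stride)   # 0-based top-left rows
  c0 <- seq(0L, nc - b, by = stride)
  ii[r0 + b + 1L, c0 + b + 1L, drop = FALSE] -
    ii[r0 + 1L, c0 + b + 1L, drop = FALSE] -
    ii[r0 + b + 1L, c0 + 1L, drop = FALSE] +
    ii[r0 + 1L, c0 + 1L, drop = FALSE]
}
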