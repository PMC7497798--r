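# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted decay
#'
#' @param x a `flim_decay_fit`.
#' @param ... unused.
#' @return one-row tibble of the fitted parameters.
#' @export
tidy.flim_decay_fit <- function(x, ...) {
  tibble::tibble(tau1 = x$tau1, tau2 = x$tau2, a1 = x$a1, a2 = x$a2,
                 a1_pct = x$a1_pct, tau_m = x$tau_m, chi2 = x$chi2,
                 offset = x$offset, shift = x$shift,
                 n_components = x$n_components, converged = x$converged)
}

#' @rdname tidy.flim_decay_fit
#' @export
glance.flim_decay_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, converged = x$converged,
                 iterations = x$iterations, n_components = x$n_components)
}

#' Tidy a trained network
#'
#' @param x a `flim_ann_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per weight with `layer`, `from`, `to` and
#'   `estimate`; `glance()`: the one-row training report (train,
#'   validation and held-out test MSE, regularization state, epochs).
#' @export
tidy.flim_ann_fit <- function(x, ...) {
  net <- x$net
  h <- net$n_hidden; d <- net$n_inputs
  dplyr::bind_rows(
    tibble::tibble(layer = "hidden",
                   from = rep(sprintf("x%d", seq_len(d)), each = h),
                   to = rep(sprintf("h%d", seq_len(h)), d),
                   estimate = as.vector(net$W1)),
    tibble::tibble(layer = "hidden", from = "bias",
                   to = sprintf("h%d", seq_len(h)), estimate = net$b1),
    tibble::tibble(layer = "output", from = sprintf("h%d", seq_len(h)),
                   to = "out", estimate = net$w2),
    tibble::tibble(layer = "output", from = "bias", to = "out",
                   estimate = net$b2))
}

#' @rdname tidy.flim_ann_fit
#' @export
glance.flim_ann_fit <- function(x, ...) x$report

#' Detection summaries
#'
#' @param x a `flim_detection` from [compute_metrics()].
#' @param ... unused.
#' @return `tidy()`: across-FOV mean and sd per metric; `glance()`: the
#'   pooled counts and rates as one row.
#' @export
tidy.flim_detection <- function(x, ...) attr(x, "summary")

#' @rdname tidy.flim_detection
#' @export
glance.flim_detection <- function(x, ...) attr(x, "pooled")
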