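# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(m) {
  tibble::tibble(
    x = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 1L, ncol(m)),
    value = as.vector(m))
}

#' Plot a fitted decay on a log scale
#'
#' @param object a `flim_decay_fit`.
#' @param ... unused.
#' @export
autoplot.flim_decay_fit <- function(object, ...) {
  t_ns <- (seq_along(object$decay) - 1) * object$bin_width
  df <- tibble::tibble(t = t_ns, observed = object$decay,
                       fitted = object$fitted) |>
    tidyr::pivot_longer(c("observed", "fitted"),
                        names_to = "curve", values_to = "counts")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = pmax(.data$counts, 0.5),
                                   color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photons / bin",
                  title = sprintf("tau_m = %.2f ns, a1 = %.0f%%, chi2 = %.2f",
                                  object$tau_m, object$a1_pct, object$chi2)) +
    ggplot2::theme_minimal()
}

#' Facet the seven lifetime parameter maps
#'
#' @param object a `flim_param_maps`.
#' @param parameters subset of map names to show.
#' @param ... unused.
#' @export
autoplot.flim_param_maps <- function(object,
                                     parameters = c("tm", "a1pct", "chi2"),
                                     ...) {
  df <- purrr::map_dfr(parameters, function(nm) {
    dplyr::mutate(raster_df(object$maps[[nm]]), parameter = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a detection probability image
#'
#' @param object a `flim_prob_image`.
#' @param ... unused.
#' @export
autoplot.flim_prob_image <- function(object, ...) {
  ggplot2::ggplot(raster_df(unclass(object)),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "P(microglia)", x = NULL, y = NULL)
}

#' Bar chart of detection metrics with across-FOV spread
#'
#' @param object a `flim_detection`.
#' @param ... unused.
#' @export
autoplot.flim_detection <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(s, ggplot2::aes(x = toupper(.data$metric), y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "rate (mean +- sd across FOVs)") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
}
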