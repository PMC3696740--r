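#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: peak-activity
#' traces for a ring simulation, a dominance-time histogram with the
#' fitted density for a [fit_exponential()] / [fit_gamma_3point()]
#' object, the finite-n inference trace, and the regime partition of
#' the parameter plane as a tile map.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name multistable-autoplot
NULL

#' @rdname multistable-autoplot
#' @export
autoplot.ring_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$peaks, c("peak_R", "peak_L"),
                            names_to = "side", values_to = "peak")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$peak,
                                   colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "t (model units)", y = "bump peak activity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname multistable-autoplot
#' @export
autoplot.dominance_fit <- function(object, ...) {
  d <- object$durations
  if (is.null(d)) stop("fit carries no sample durations to plot")
  df <- tibble::tibble(duration = d)
  xs <- seq(min(d), max(d), length.out = 256)
  dens <- tibble::tibble(duration = xs, density = object$density(xs))
  ggplot2::ggplot(df, ggplot2::aes(.data$duration)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey75", colour = "white") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density), colour = "red") +
    ggplot2::labs(x = "dominance time (model units)", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname multistable-autoplot
#' @export
autoplot.inference_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$n, .data$p_n)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$p_inf, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "cycles sampled (n)",
                  y = "p[I_R > I_L | T*(n)]") +
    ggplot2::theme_minimal()
}

#' @rdname multistable-autoplot
#' @export
autoplot.regime_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$beta, .data$I0,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(beta), y = expression(I[0]),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
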