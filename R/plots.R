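#' Plot a biexponential refolding fit
#'
#' Data points with the fitted curve and, dashed, the slow-phase plateau
#' `a1`.
#'
#' @param object A `biexp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biexp_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$t), max(object$t), length.out = 200))
  grid$p_nn <- biexp_pnn(grid$t, object$a0, object$k1, object$k2)
  ggplot2::ggplot(tibble(t = object$t, p_nn = object$p_nn),
                  ggplot2::aes(x = .data$t, y = .data$p_nn)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$a1, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = expression(P[NN](t)),
                  subtitle = sprintf("a1 = %.2f, k2 = %.3g /min (%s)",
                                     object$a1, object$k2, object$k2_flag)) +
    ggplot2::theme_minimal()
}

#' Plot a GroEL trajectory
#'
#' Species concentrations against time, one line per species.
#'
#' @param object A `groel_trajectory`.
#' @param species Species to show (default client states and ATP bundles).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.groel_trajectory <- function(object,
                                      species = c("U", "F", "M", "ATP7"),
                                      ...) {
  long <- tidyr::pivot_longer(object[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a contact trajectory with its bound/unbound threshold
#'
#' @param data Frame/contacts tibble (optionally classified).
#' @param threshold Threshold to draw (taken from the classification
#'   attribute when present).
#' @return A ggplot.
#' @export
plot_contact_trajectory <- function(data, threshold = attr(data, "threshold")) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$frame,
                                          y = .data$contacts)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "frame", y = "intermolecular contacts") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "black")
  }
  p
}

#' @export
ggplot2::autoplot
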