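#' Plot power curves
#'
#' Power against fold change, one line per normalization (or per method),
#' faceted by the DE fraction gamma.
#'
#' @param x A `power_grid` tibble.
#' @param colour Column mapped to colour, `"normalization"` (default) or
#'   `"method"`.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(x, colour = c("normalization", "method")) {
  colour <- match.arg(colour)
  facet_rows <- if (colour == "normalization") "method" else "normalization"
  ggplot2::ggplot(x, ggplot2::aes(x = .data$fc, y = .data$power,
                                  colour = .data[[colour]],
                                  group = .data[[colour]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data[[facet_rows]]),
      cols = ggplot2::vars(.data$gamma),
      labeller = ggplot2::label_both
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold change", y = "power") +
    ggplot2::theme_bw()
}

#' @rdname plot_power_curves
#' @param object,... Passed from the autoplot generic.
#' @export
autoplot.power_grid <- function(object, ...) plot_power_curves(object, ...)

#' Plot a Type I error grid
#'
#' Attained Type I error per test and normalization with the nominal level
#' as a dashed reference line.
#'
#' @param object A `type1_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.type1_grid <- function(object, ...) {
  alpha <- if ("alpha" %in% names(object)) object$alpha[1L] else 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$normalization, y = .data$type1,
                                       colour = .data$method,
                                       group = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    { if (all(c("N", "p") %in% names(object)))
        ggplot2::facet_grid(rows = ggplot2::vars(.data$N),
                            cols = ggplot2::vars(.data$p),
                            labeller = ggplot2::label_both) } +
    ggplot2::labs(x = "normalization", y = "attained Type I error") +
    ggplot2::theme_bw()
}

#' P-value histograms for a gene set analysis result
#'
#' @param object A `gsa_result` tibble.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsa_result <- function(object, bins = 20L, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p.value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = "permutation P-value", y = "gene sets") +
    ggplot2::theme_bw()
}

#' Plot the P-value transforms used by the combiners
#'
#' Draws `H(p)` for Fisher's method, Stouffer's method and the Gamma method
#' at a given soft truncation threshold, over a log-spaced grid of
#' P-values. The Gamma transform's collapse for all but the smallest
#' P-values is the visual signature of soft truncation.
#'
#' @param stt Soft truncation threshold for the Gamma transform.
#' @param p_min Smallest P-value drawn.
#' @return A ggplot object.
#' @export
plot_combiner_transforms <- function(stt = 0.05, p_min = 1e-5) {
  w <- stt_to_shape(stt)
  p <- 10^seq(log10(p_min), -0.0001, length.out = 500)
  tbl <- dplyr::bind_rows(
    tibble::tibble(p = p, H = -2 * log(p), transform = "Fisher"),
    tibble::tibble(p = p, H = qnorm(p, lower.tail = FALSE), transform = "Stouffer"),
    tibble::tibble(p = p, H = qgamma(p, shape = w, scale = 1, lower.tail = FALSE),
                   transform = sprintf("Gamma (STT = %g)", stt))
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$p, y = .data$H,
                                    colour = .data$transform)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gene-level P-value", y = "transformed value H(p)") +
    ggplot2::theme_bw()
}
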