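#' Plot a persistence barcode
#'
#' Horizontal bars (birth to death) stacked per dimension; infinite deaths
#' are drawn to just past the largest finite value and marked with an
#' arrowhead-like open end.
#'
#' @param object a `ph_barcode`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ph_barcode
#' @export
autoplot.ph_barcode <- function(object, ...) {
  df <- as_tibble(object)
  fin <- df$death[is.finite(df$death)]
  cap <- if (length(fin)) max(fin) * 1.1 else max(df$birth, 1) + 1
  df <- dplyr::arrange(df, .data$dimension, .data$birth, .data$death)
  df$bar <- seq_len(nrow(df))
  df$capped <- pmin(df$death, cap)
  df$infinite <- is.infinite(df$death)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$capped,
                                       y = .data$bar, yend = .data$bar,
                                       linetype = .data$infinite)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dimension),
                        scales = "free_y", space = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "filtration value (Å)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a persistent Betti number curve
#'
#' @param object a `pbn_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pbn_curve
#' @export
autoplot.pbn_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "filtration value (Å)",
                  y = sprintf("PBN (dim %d)", attr(object, "dimension"))) +
    ggplot2::theme_minimal()
}

#' Plot a persistent radial distribution function
#'
#' @param object a `prdf_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot prdf_curve
#' @export
autoplot.prdf_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "filtration value r (Å)", y = "PRDF") +
    ggplot2::theme_minimal()
}

#' @export
plot.ph_barcode <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.pbn_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.prdf_curve <- function(x, ...) print(autoplot(x, ...))
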