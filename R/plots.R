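#' Plot a recording
#'
#' Voltage (CC) or current (VC) traces against time, one facet per sweep,
#' coloured by trial.
#'
#' @param object A [new_recording()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recording <- function(object, ...) {
  ylab <- if (object$mode == "CC") "membrane voltage (mV)" else
    "membrane current (pA)"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time, y = .data$recorded,
                               group = .data$trial,
                               colour = factor(.data$trial))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "time (ms)", y = ylab, colour = "trial") +
    ggplot2::theme_minimal()
}

#' Plot an I-V curve
#'
#' @param object An `iv_curve` or `ramp_iv` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage,
                                       y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "test potential (mV)",
                  y = "current density (pA/pF)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.iv_curve
#' @export
autoplot.ramp_iv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage,
                                       y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "command voltage (mV)",
                  y = "current density (pA/pF)") +
    ggplot2::theme_minimal()
}

#' Plot a candidate ranking
#'
#' Glial expression against specificity ratio on log10 axes, labelling
#' the top candidates by combined rank.
#'
#' @param object A [specificity_and_rank()] result.
#' @param top_n Number of top candidates to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_ranking <- function(object, top_n = 4, ...) {
  lab <- utils::head(object, top_n)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sgc_cpm,
                                       y = .data$specificity_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "glial expression (CPM)",
                  y = "specificity ratio (glia / max other)") +
    ggplot2::theme_minimal()
}

#' Plot an up-down von Frey session
#'
#' @param object An `updown_session` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.updown_session <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial,
                                       y = .data$force_g,
                                       shape = .data$withdraw)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "trial", y = "filament force (g)",
                  shape = "withdraw") +
    ggplot2::theme_minimal()
}
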