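#' Plot a validation report
#'
#' Experimental versus estimated activity on log10 axes, colored by
#' activity-scale agreement, with the identity line.
#'
#' @param object A `validation_report` from [validate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$experimental_uM,
                               y = .data$estimated_uM,
                               colour = .data$scale_mismatch)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2c7fb8",
                                            `TRUE` = "#d95f02"),
                                 name = "scale mismatch") +
    ggplot2::labs(x = "experimental IC50 (uM)",
                  y = "estimated IC50 (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a Fischer randomization result
#'
#' Best total cost of each activity-scrambled regeneration against the
#' original model's cost (dashed line): a sound model sits below every
#' scrambled run.
#'
#' @param object A `fischer_result` from [fischer_randomization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fischer_result <- function(object, ...) {
  orig <- object$total_cost[object$run == 0]
  ggplot2::ggplot(dplyr::filter(object, .data$permuted),
                  ggplot2::aes(x = factor(.data$run), y = .data$total_cost)) +
    ggplot2::geom_col(fill = "#9ecae1") +
    ggplot2::geom_hline(yintercept = orig, linetype = 2, colour = "#d95f02") +
    ggplot2::labs(x = "scrambled run", y = "best total cost (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a screening funnel
#'
#' Survivor counts per funnel stage on a log scale.
#'
#' @param object A `screen_hits` tibble from [screen_library()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_hits <- function(object, ...) {
  f <- funnel_counts(object)
  f$stage <- factor(f$stage, levels = f$stage)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$stage, y = pmax(.data$n, 0.5))) +
    ggplot2::geom_col(fill = "#74c476") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "compounds surviving") +
    ggplot2::theme_minimal()
}

#' Plot a pharmacophore hypothesis
#'
#' 2D projection (x/y) of the feature centroids with tolerance radii.
#'
#' @param object A [pharmacophore].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pharmacophore <- function(object, ...) {
  f <- object$features
  ggplot2::ggplot(f, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$ftype)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$tolerance), alpha = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_size_area(max_size = 12, name = "tolerance (A)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)", colour = "feature") +
    ggplot2::theme_minimal()
}
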