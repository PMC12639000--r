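#' Plot per-position cleavage scores
#'
#' Signal profile along each reference, faceted by reference id; the default
#' score is NGC. Masked positions are greyed out.
#'
#' @param object An `oab_scores` tibble.
#' @param score Column to plot (`"ngc"`, `"stop_ratio"` or `"ncleavage"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oab_scores <- function(object, score = "ngc", ...) {
  stopifnot(score %in% names(object))
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data[[score]],
                                   fill = .data$masked)) +
    ggplot2::geom_col(width = 1, show.legend = any(df$masked)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#4477AA", `TRUE` = "grey70"),
                               name = "masked") +
    ggplot2::facet_wrap(~ref, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "position (nt)", y = score) +
    ggplot2::theme_minimal()
}

#' Plot a condition comparison
#'
#' log2-NGC scatter of the two conditions; points where both scores clear
#' the display threshold are highlighted, the rest shown in grey.
#'
#' @param object An `oab_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oab_comparison <- function(object, ...) {
  df <- filter(object$pairs, .data$ngc_a > 0, .data$ngc_b > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ngc_a), y = log2(.data$ngc_b),
                                   colour = .data$retained)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#CC3311"),
                                 name = "both above\nthreshold") +
    ggplot2::labs(x = "log2 NGC (condition A)", y = "log2 NGC (condition B)",
                  subtitle = sprintf("R^2 = %.3f over %d retained sites",
                                     object$r_squared, object$n_retained)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Standards with the fitted line; the slope is the relative response factor.
#'
#' @param object An `oab_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oab_calibration <- function(object, ...) {
  df <- tibble(level = object$fit$model$lv,
               response = object$fit$model$rs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$rrf, intercept = object$intercept,
                         colour = "#4477AA") +
    ggplot2::labs(x = "standard amount", y = "response",
                  subtitle = sprintf("rRF = %.4g, R^2 = %.4f",
                                     object$rrf, object$r_squared)) +
    ggplot2::theme_minimal()
}
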