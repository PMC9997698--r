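#' Plot collapsed contra/ipsi PLV time courses
#'
#' @param collapsed Output of [collapse_contra_ipsi()].
#' @param freq_average Average over frequencies before plotting.
#' @return A ggplot.
#' @export
plot_plv_timecourse <- function(collapsed, freq_average = TRUE) {
  df <- if (freq_average && "frequency" %in% names(collapsed)) {
    collapsed |>
      dplyr::group_by(.data$laterality, .data$time_ms) |>
      dplyr::summarise(plv = mean(.data$plv), .groups = "drop")
  } else {
    collapsed
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$plv,
                                   colour = .data$laterality)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "PLV", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lateralization-index summary
#'
#' @param object A `li_summary`.
#' @param ... Unused.
#' @return A ggplot of the condition-wise LI time course with SEM
#'   ribbons.
#' @export
autoplot.li_summary <- function(object, ...) {
  tc <- object$timecourse
  ggplot2::ggplot(tc, ggplot2::aes(.data$time_ms, .data$mean,
                                   colour = .data$attended_side,
                                   fill = .data$attended_side)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "lateralization index",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the SVM validation-accuracy landscape
#'
#' @param object Result of [optimize_rbf_svm()] (or a `decoding_report`'s
#'   landscape tibble).
#' @param ... Unused.
#' @return A ggplot heat map over cost x gamma.
#' @export
plot_svm_landscape <- function(object, ...) {
  land <- if (is.data.frame(object)) object else object$landscape
  ggplot2::ggplot(land, ggplot2::aes(log10(.data$cost), log10(.data$gamma),
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "log10 cost (margin)", y = "log10 gamma",
                  fill = "val. accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a decoding confusion matrix
#'
#' @param object A `decoding_report`.
#' @param ... Unused.
#' @return A ggplot tile plot (row percentages, counts overlaid).
#' @export
autoplot.decoding_report <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(.data$predicted, .data$truth,
                               fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%\n(%d)", .data$percent, .data$count))) +
    ggplot2::labs(x = "predicted", y = "ground truth",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
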