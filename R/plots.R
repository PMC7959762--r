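#' Plot an IHR series
#'
#' @param object an `ihr_series` from [compute_ihr()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ihr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$bpm)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "IHR (bpm)") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-subject normalized features by class
#'
#' The screening view: features z-scored within subject, one box per
#' feature and class.  Restrict `features` to one 16-column block
#' (e.g. columns starting `sl0_`) for a readable plot.
#'
#' @param features labeled feature tibble.
#' @param cols character vector of feature columns (default: all).
#' @return A ggplot object.
#' @export
plot_feature_boxes <- function(features, cols = NULL) {
  z <- zscore_by_subject(features, cols)
  meta <- c("subject_id", "epoch", "label", "end_time")
  if (is.null(cols)) cols <- setdiff(names(z), meta)
  long <- tidyr::pivot_longer(z[c("label", cols)], -"label",
                              names_to = "feature", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$z,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "within-subject z-score")
}
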