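#' Plot a cross-model accuracy report
#'
#' Point estimates with 95% bootstrap confidence intervals, one panel per
#' metric, benchmarks on the x axis, models as colors — the standard way
#' bias baselines are compared against scoring functions.
#'
#' @param object A `bias_report` from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_report <- function(object, ...) {
  df <- object[!object$insufficient, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$benchmark, y = .data$point, colour = .data$model
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.6), size = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "point estimate (95% CI)", colour = "model") +
    ggplot2::theme_bw()
}

#' Plot a pose set's RMSD ladder
#'
#' @param object A `pose_set`.
#' @param bins Optional bin edges (e.g. [default_rmsd_bins()]) drawn as
#'   horizontal guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pose_set <- function(object, bins = NULL, ...) {
  df <- object$poses
  df$pose_id <- factor(df$pose_id, levels = df$pose_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pose_id, y = .data$rmsd)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$provenance)) +
    ggplot2::labs(x = NULL, y = "RMSD to reference (Å)",
                  title = object$complex_id) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(bins)) {
    p <- p + ggplot2::geom_hline(yintercept = unique(c(bins$lo, bins$hi)),
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' Plot a benchmark split's pK distributions
#'
#' Overlaid train/test label distributions: benchmark splits designed to
#' defeat memorization should keep the test labels centered but spread.
#'
#' @param split A `benchmark_split`.
#' @param records The records tibble the split was built from.
#' @return A ggplot object.
#' @export
plot_split_pk <- function(split, records) {
  roles <- as_tibble(split)
  df <- dplyr::inner_join(roles,
                          records[, c("complex_id", "pk")], by = "complex_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pk, fill = .data$role)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "pK", y = "complexes", title = split$name) +
    ggplot2::theme_bw()
}
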