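#' Plot a constraint table
#'
#' Histogram of per-meta-position scores for powered positions, with the
#' nominal (`1`) and high-constraint (`0.8`) thresholds marked.
#'
#' @param object An `hmc_constraint`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmc_constraint <- function(object, ...) {
  df <- tidy(object) |> filter(.data$powered)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hmc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = c(0.8, 1), linetype = c("dashed",
                                                             "solid"),
                        colour = "firebrick") +
    ggplot2::labs(x = "constraint score (0.95 posterior quantile of O/E)",
                  y = "meta-positions") +
    ggplot2::theme_minimal()
}

#' Plot a precision-sensitivity curve
#'
#' @param object An `hmc_pr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmc_pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$sensitivity, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "sensitivity", y = "precision",
                  subtitle = sprintf("area = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a per-bin risk-ratio report
#'
#' Point estimates with confidence intervals per score bin, on a log scale,
#' with the null ratio of 1 marked.
#'
#' @param report Output of [bin_report()].
#' @return A ggplot object.
#' @export
plot_bin_report <- function(report) {
  df <- report |> filter(!is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bin,
                                              levels = unique(report$bin)),
                                   y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score bin", y = "risk ratio (95% CI)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
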