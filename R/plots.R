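#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of QTL counts per chromosome, filled by stress class
#'
#' @param qtls QTL tibble with `chromosome` and `stress`.
#' @return A ggplot object.
#' @export
plot_qtl_distribution <- function(qtls) {
  ggplot2::ggplot(tibble::as_tibble(qtls),
                  ggplot2::aes(x = .data$chromosome, fill = .data$stress)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "chromosome", y = "QTLs", fill = "stress") +
    ggplot2::theme_minimal()
}

#' Confidence-interval reduction plot
#'
#' Mean initial (projected) QTL CI width next to the mean MQTL CI width per
#' chromosome, the usual visual for the fold reduction a meta-analysis buys.
#'
#' @param summary_tbl `fold_reduction_by_chromosome` tibble from
#'   [summarize_mqtls()].
#' @return A ggplot object.
#' @export
plot_ci_reduction <- function(summary_tbl) {
  long <- tidyr::pivot_longer(summary_tbl,
                              c("mean_initial_ci_cm", "mean_mqtl_ci_cm"),
                              names_to = "which", values_to = "ci_cm")
  long$which <- ifelse(long$which == "mean_initial_ci_cm", "initial QTLs", "MQTLs")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chromosome, y = .data$ci_cm,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromosome", y = "mean 95% CI (cM)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot projected QTL peaks and MQTL positions per chromosome
#'
#' @param object An `mqtl_result` from [meta_qtl()].
#' @param ... Unused.
#' @return A ggplot object: projected peaks as points (jittered), MQTL
#'   positions as vertical lines with their 95% CI as a shaded band.
#' @export
autoplot.mqtl_result <- function(object, ...) {
  pq <- object$projected
  mq <- object$mqtls
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = mq,
                       ggplot2::aes(xmin = .data$ci_start_cm, xmax = .data$ci_end_cm,
                                    ymin = -Inf, ymax = Inf),
                       fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_vline(data = mq, ggplot2::aes(xintercept = .data$position_cm),
                        colour = "steelblue") +
    ggplot2::geom_jitter(data = pq,
                         ggplot2::aes(x = .data$peak_cm, y = .data$stress),
                         height = 0.2, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "consensus position (cM)", y = NULL) +
    ggplot2::theme_minimal()
}
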