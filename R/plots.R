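#' Plot mean MCC against cells per individual, faceted by individuals
#'
#' @param summary A tibble from [summarize_benchmark()].
#' @return A ggplot object.
#' @export
plot_mcc <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$n_cells_case, y = .data$mcc_mean, colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mcc_mean - .data$mcc_se,
      ymax = .data$mcc_mean + .data$mcc_se), width = 0) +
    ggplot2::facet_wrap(~ n_individuals, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "cells per individual", y = "mean MCC",
                  colour = "method") +
    ggplot2::theme_bw()
}

#' Plot pooled ROC curves from a ROC study
#'
#' @param study The list returned by [run_roc_study()].
#' @return A ggplot object, one panel per DE-gene proportion.
#' @export
plot_roc <- function(study) {
  rows <- list()
  for (lev in names(study$curves)) {
    for (m in names(study$curves[[lev]])) {
      cv <- study$curves[[lev]][[m]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        prop_de = lev, method = m, fpr = cv$fpr, tpr = cv$tpr)
    }
  }
  dat <- dplyr::bind_rows(rows)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::facet_wrap(~ prop_de, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "method") +
    ggplot2::theme_bw()
}
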