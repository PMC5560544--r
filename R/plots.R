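#' @exportS3Method
autoplot.calf_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC %.2f, 95%% CI %.2f-%.2f)",
                      object$auc, object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.calf_decile_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ri <- attr(object, "reference_interval")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$decile),
                                   y = 100 * .data$survival,
                                   fill = .data$reference)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$significant, "*", "")),
      vjust = -0.3, size = 6
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(
      x = sprintf("%s decile (reference interval %s-%s)",
                  attr(object, "variable"), format(ri[1]), format(ri[2])),
      y = "Survival rate (%)",
      title = sprintf(
        "Survival by %s decile (* P <= %.3f vs reference decile %d)",
        attr(object, "variable"), attr(object, "adjusted_alpha"),
        attr(object, "reference_decile")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.calf_pruning_path <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$cv_error)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$cv_error - .data$cv_se,
                   ymax = .data$cv_error + .data$cv_se)
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$resub_error),
                       linetype = "dotted", colour = "grey50") +
    ggplot2::labs(
      x = "Terminal nodes", y = "Misclassification error",
      title = "Cross-validated cost-complexity pruning path",
      subtitle = "dotted: resubstitution error"
    ) +
    ggplot2::theme_minimal()
}
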