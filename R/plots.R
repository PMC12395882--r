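#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_errorbar geom_point
#'   labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Train and validation loss per epoch, with the early-stopping epoch marked.
#'
#' @param object a `moetox_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.moetox_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    geom_point(data = dplyr::filter(h, .data$epoch == object$best_epoch,
                                    .data$set == "val_loss")) +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = sprintf("best epoch %d", object$best_epoch)) +
    theme_minimal()
}

#' Plot a gate-weight summary
#'
#' Mean gate weight per branch with its 95% t confidence interval.
#'
#' @param object a [gate_summary()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gate_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$branch, y = .data$mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean - .data$ci_half_width,
                      ymax = .data$mean + .data$ci_half_width), width = 0.2) +
    labs(x = "expert branch", y = "mean gate weight") +
    theme_minimal()
}

#' Sensitivity/specificity per task
#'
#' Dot plot of sensitivity and specificity per endpoint, visualising the
#' imbalance gap the balanced loss is meant to shrink.
#'
#' @param report tibble from [task_metrics()].
#' @return A ggplot.
#' @export
plot_sens_spec <- function(report) {
  h <- tidyr::pivot_longer(report, c("sensitivity", "specificity"),
                           names_to = "metric", values_to = "value")
  ggplot(h, aes(x = .data$value, y = .data$task, colour = .data$metric)) +
    geom_point(size = 2) +
    labs(x = NULL, y = NULL, colour = NULL) +
    theme_minimal()
}
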