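#' Plot the six kinematic channels of an event
#'
#' Linear acceleration (g) and angular velocity (deg/s) against time relative
#' to the trigger, with the trigger instant marked.
#'
#' @param event A one-row event tibble.
#' @return A ggplot object.
#' @export
plot_event <- function(event) {
  stopifnot(is.data.frame(event), nrow(event) == 1L)
  m <- event$samples[[1]]
  df <- tibble::tibble(
    t_ms = rep(event_time_ms(), each = 6L),
    channel = factor(rep(mg_channels(), mg_const$n_samples),
                     levels = mg_channels()),
    value = as.vector(m),
    family = rep(rep(c("linear acceleration [g]", "angular velocity [deg/s]"),
                     each = 3L), mg_const$n_samples))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$value,
                                   color = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~family, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time relative to trigger [ms]", y = NULL,
                  title = sprintf("%s (%s)", event$event_id, event$label)) +
    ggplot2::theme_minimal()
}

#' Training-history curves of a fitted network
#'
#' @param object A trained `mignet_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and accuracy for train and validation.
#' @method autoplot mignet_model
#' @export
autoplot.mignet_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = c("set", "metric"),
                              names_sep = "_", values_to = "value")
  ggplot2::ggplot(stats::na.omit(long),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s training history",
                                  object$config$architecture_id),
                  x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot
#'
#' @param object A `confusion_metrics` object.
#' @param ... Unused.
#' @return A ggplot tile rendering of the 2 x 2 confusion table.
#' @method autoplot confusion_metrics
#' @export
autoplot.confusion_metrics <- function(object, ...) {
  df <- tibble::tibble(
    truth = factor(c("impact", "impact", "non-impact", "non-impact"),
                   levels = c("impact", "non-impact")),
    predicted = factor(c("impact", "non-impact", "impact", "non-impact"),
                       levels = c("impact", "non-impact")),
    count = c(object$tp, object$fn, object$fp, object$tn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = format_metrics_line(object)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
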