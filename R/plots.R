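# ggplot2 visualisations: training-history curves, explanation bar charts,
# and the dependency-degree trace of a reduct search.

#' @importFrom ggplot2 autoplot
NULL

#' Plot the per-epoch training and validation error curves
#'
#' Mirrors the usual "model MSE" learning-curve panels: one line for the
#' training split, one for the held-out validation split, on the model's
#' (scaled) training loss.
#'
#' @param object A trained `cnn_regressor`.
#' @param metric `"mse"` is the recorded loss; plotted on a log10 y axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_regressor <- function(object, metric = "mse", ...) {
  h <- object$history
  if (is.null(h)) stop("Model has no training history.", call. = FALSE)
  long <- tidyr::pivot_longer(h, c("train_mse", "val_mse"),
                              names_to = "split", values_to = "value")
  long$split <- ifelse(long$split == "train_mse", "train", "validation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (scaled target)", colour = NULL,
                  title = "Model MSE") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cnn_regressor
#' @param model A trained `cnn_regressor`.
#' @export
plot_training_history <- function(model, ...) autoplot(model, ...)

#' Horizontal bar chart of a local surrogate explanation
#'
#' Green bars are features whose range condition supports (raises) the
#' predicted IC50, red bars oppose it — the conventional LIME tabular
#' rendering.
#'
#' @param object An `explanation`.
#' @param top_k Number of largest-magnitude weights shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.explanation <- function(object, top_k = 10L, ...) {
  w <- utils::head(object$weights, top_k)
  w$condition <- factor(w$condition, levels = rev(w$condition))
  w$direction <- ifelse(w$weight >= 0, "support", "oppose")
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight, y = .data$condition,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(support = "forestgreen",
                                          oppose = "firebrick")) +
    ggplot2::labs(x = "weight", y = NULL, fill = NULL,
                  title = paste0("Local explanation: ", object$instance_id)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.explanation
#' @param explanation An `explanation`.
#' @export
plot_explanation <- function(explanation, top_k = 10L, ...) {
  autoplot(explanation, top_k = top_k, ...)
}

#' Dependency-degree trace of a reduct search
#'
#' @param object A `reduct_result`.
#' @param ... Unused.
#' @return A ggplot object showing gamma after each greedy addition, with
#'   the full-set dependency as a dashed reference line.
#' @export
autoplot.reduct_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$gamma)) +
    ggplot2::geom_hline(yintercept = object$gamma_full, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$step, labels = d$feature) +
    ggplot2::labs(x = NULL, y = "dependency degree",
                  title = "QuickReduct dependency trace") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
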