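# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
NULL

#' Tidy a QuickReduct result
#'
#' One row per greedy step: the feature added and the dependency degree
#' reached after adding it.
#'
#' @param x A `reduct_result`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `feature`, `gamma`.
#' @export
tidy.reduct_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), feature = x$selected,
                 gamma = x$gamma_trace)
}

#' @rdname tidy.reduct_result
#' @export
glance.reduct_result <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    n_features = length(x$feature_universe),
    gamma_final = if (length(x$gamma_trace)) utils::tail(x$gamma_trace, 1) else 0,
    gamma_full = x$gamma_full,
    tolerance = x$tolerance
  )
}

#' Tidy a trained convolutional regressor
#'
#' `tidy()` returns the per-epoch training history in long-friendly wide
#' form; `glance()` a one-row fit summary.
#'
#' @param x A trained `cnn_regressor`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cnn_regressor <- function(x, ...) {
  if (is.null(x$history)) {
    stop("Model has no training history (untrained?).", call. = FALSE)
  }
  x$history
}

#' @rdname tidy.cnn_regressor
#' @export
glance.cnn_regressor <- function(x, ...) {
  n_params <- sum(vapply(x$params, length, integer(1)))
  h <- x$history
  tibble::tibble(
    n_features = x$n_features,
    n_parameters = n_params,
    epochs = x$config$epochs,
    final_train_mse = if (!is.null(h)) h$train_mse[nrow(h)] else NA_real_,
    final_val_mse = if (!is.null(h)) h$val_mse[nrow(h)] else NA_real_
  )
}

#' Tidy a local surrogate explanation
#'
#' @param x An `explanation`.
#' @param ... Unused.
#' @return `tidy()`: the per-feature weight table (`feature`, `condition`,
#'   `weight`, `direction`); `glance()`: a one-row summary with the
#'   surrogate's weighted R-squared.
#' @export
tidy.explanation <- function(x, ...) {
  dplyr::mutate(x$weights,
                direction = ifelse(.data$weight >= 0, "support", "oppose"))
}

#' @rdname tidy.explanation
#' @export
glance.explanation <- function(x, ...) {
  tibble::tibble(
    instance_id = x$instance_id,
    prediction = x$prediction,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_samples = x$n_samples,
    kernel_width = x$kernel_width
  )
}
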