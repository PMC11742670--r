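# Local surrogate explanations of single IC50 predictions.
#
# The black-box regressor is probed around one compound: each descriptor is
# quartile-binned on the training table, perturbed samples either keep the
# compound's bin or jump to a random other bin (drawing a concrete value
# uniformly inside the chosen bin), and a distance-weighted ridge regression
# of the black-box output on the binary keep/jump matrix yields one signed
# weight per descriptor. Positive weights support the prediction, negative
# weights oppose it, mirroring the green/red bars of LIME tabular reports.

#' Quartile-discretize descriptors for the explainer
#'
#' Computes per-feature quartile edges on a reference (training) table,
#' together with the observed minima/maxima that bound the outer bins, and a
#' labelling rule producing range conditions in the style
#' `"-0.10 < mZagreb2 <= 0.41"` (two decimals; outer bins render as
#' `"name <= q1"` and `"name > q3"`). A value exactly on an edge falls in
#' the lower bin. Constant features collapse to a single degenerate bin and
#' are flagged.
#'
#' @param data Reference tibble of compounds by descriptors (>= 4 rows).
#' @return A `feature_bins` object: per-feature `edges`, `min`, `max`,
#'   `constant`.
#' @export
discretize_features <- function(data) {
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  if (nrow(data) < 4) stop("Need at least 4 rows to discretize.", call. = FALSE)
  bins <- lapply(feats, function(f) {
    v <- data[[f]]
    if (!all(is.finite(v))) stop("Non-finite values in '", f, "'.", call. = FALSE)
    if (max(v) == min(v)) {
      list(edges = numeric(0), min = min(v), max = max(v), constant = TRUE)
    } else {
      q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
      list(edges = unique(q), min = min(v), max = max(v), constant = FALSE)
    }
  })
  names(bins) <- feats
  structure(bins, class = "feature_bins")
}

# Bin index of a value: 1 + number of edges strictly below it (values on an
# edge fall in the lower bin).
bin_of <- function(value, bin) {
  if (bin$constant) return(1L)
  1L + sum(value > bin$edges)
}

n_bins_of <- function(bin) if (bin$constant) 1L else length(bin$edges) + 1L

# (lo, hi) bounds of bin b, outer bins bounded by the observed min/max.
bin_bounds <- function(bin, b) {
  if (bin$constant) return(c(bin$min, bin$max))
  lo <- if (b == 1L) bin$min else bin$edges[b - 1L]
  hi <- if (b > length(bin$edges)) bin$max else bin$edges[b]
  c(lo, hi)
}

#' Human-readable range condition for a feature value
#'
#' @param bins A `feature_bins` object.
#' @param feature Feature name.
#' @param value The value whose bin is described.
#' @return A condition string such as `"0.12 < fMF <= 0.45"`.
#' @export
bin_label <- function(bins, feature, value) {
  bin <- bins[[feature]]
  if (is.null(bin)) stop("No bins for feature '", feature, "'.", call. = FALSE)
  if (bin$constant) return(sprintf("%s = %.2f", feature, bin$min))
  b <- bin_of(value, bin)
  ne <- length(bin$edges)
  if (b == 1L) {
    sprintf("%s <= %.2f", feature, bin$edges[1])
  } else if (b == ne + 1L) {
    sprintf("%s > %.2f", feature, bin$edges[ne])
  } else {
    sprintf("%.2f < %s <= %.2f", bin$edges[b - 1L], feature, bin$edges[b])
  }
}

#' Draw perturbed samples around one compound
#'
#' Row 1 is the unperturbed instance (interpretable vector all ones). Every
#' other row independently keeps each feature's bin with probability
#' `keep_prob` (interpretable 1) or jumps to a uniformly chosen *other* bin
#' (interpretable 0), then draws the concrete descriptor value uniformly
#' inside the chosen bin. Constant features always keep their value.
#'
#' @param instance Named numeric vector (or 1-row data frame) of the
#'   compound's descriptor values.
#' @param bins A `feature_bins` from [discretize_features()].
#' @param n Number of samples (>= 10), including the anchor row.
#' @param seed Integer seed.
#' @param keep_prob Probability of keeping the instance's bin.
#' @return List with `z` (n x p binary interpretable matrix) and `samples`
#'   (n x p tibble of reconstructed descriptor values).
#' @export
sample_perturbations <- function(instance, bins, n = 5000L, seed = 1L,
                                 keep_prob = 0.5) {
  if (is.data.frame(instance)) {
    stopifnot(nrow(instance) == 1)
    instance <- unlist(instance[feature_names_of(instance)])
  }
  stopifnot(n >= 10, keep_prob > 0, keep_prob < 1)
  feats <- names(instance)
  missing <- feats[!feats %in% names(bins)]
  if (length(missing)) {
    stop("No bins for feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- length(feats)
  z <- matrix(1L, n, p, dimnames = list(NULL, feats))
  vals <- matrix(rep(as.numeric(instance), each = n), n, p,
                 dimnames = list(NULL, feats))
  with_seed(seed, {
    for (j in seq_len(p)) {
      bin <- bins[[feats[j]]]
      nb <- n_bins_of(bin)
      if (nb == 1L) next                       # degenerate: always kept
      home <- bin_of(instance[[j]], bin)
      keep <- stats::runif(n - 1) < keep_prob
      z[-1, j] <- as.integer(keep)
      others <- setdiff(seq_len(nb), home)
      chosen <- ifelse(keep, home,
                       others[1L + floor(stats::runif(n - 1) * length(others))])
      u <- stats::runif(n - 1)
      bounds <- vapply(chosen, function(b) bin_bounds(bin, b), numeric(2))
      vals[-1, j] <- bounds[1, ] + u * (bounds[2, ] - bounds[1, ])
    }
  })
  list(z = z, samples = tibble::as_tibble(as.data.frame(vals)))
}

#' Fit a local linear surrogate around one prediction
#'
#' Weighted ridge regression of the black-box predictions on the binary
#' keep/jump matrix from [sample_perturbations()]. Sample weights are
#' `exp(-d^2 / kernel_width^2)` with `d` the normalized Hamming distance to
#' the anchor row, so samples close to the explained compound dominate.
#' The intercept is unpenalized.
#'
#' @param predict_fn Function mapping a tibble of descriptor values to a
#'   numeric prediction per row (the black box).
#' @param instance Named numeric vector (or 1-row data frame) to explain.
#' @param bins A `feature_bins` from [discretize_features()].
#' @param n Number of perturbation samples (default 5000).
#' @param seed Integer seed.
#' @param kernel_width Locality kernel width; default `0.75 * sqrt(p)`.
#' @param ridge Ridge penalty on the feature weights (default 1).
#' @param keep_prob Bin keep probability passed to the sampler.
#' @param instance_id Label stored in the explanation.
#' @return An `explanation`: tibble `weights` with columns `feature`,
#'   `condition`, `weight` sorted by decreasing `|weight|` (ties by name),
#'   plus `intercept`, `r_squared` (weighted), `prediction`, `n_samples`,
#'   `seed`, `kernel_width`.
#' @export
fit_local_surrogate <- function(predict_fn, instance, bins, n = 5000L,
                                seed = 1L, kernel_width = NULL, ridge = 1,
                                keep_prob = 0.5, instance_id = "instance") {
  if (is.data.frame(instance)) {
    id_cols <- setdiff(names(instance), feature_names_of(instance))
    if (identical(instance_id, "instance") && length(id_cols)) {
      instance_id <- as.character(instance[[id_cols[1]]][1])
    }
    instance <- unlist(instance[1, feature_names_of(instance)])
  }
  feats <- names(instance)
  p <- length(feats)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)
  pert <- sample_perturbations(instance, bins, n = n, seed = seed,
                               keep_prob = keep_prob)
  y <- as.numeric(predict_fn(pert$samples))
  if (length(y) != n || !all(is.finite(y))) {
    bad <- which(!is.finite(y))[1]
    stop("Black box returned a non-finite prediction",
         if (!is.na(bad)) paste0(" for sample ", bad), ".", call. = FALSE)
  }
  d <- rowMeans(pert$z == 0)                 # normalized Hamming distance
  w <- exp(-d^2 / kernel_width^2)

  a <- cbind(`(Intercept)` = 1, pert$z)
  pen <- diag(c(0, rep(ridge, p)))
  aw <- a * w
  beta <- solve(crossprod(a, aw) + pen, crossprod(aw, y))
  fitted <- drop(a %*% beta)
  ybar <- sum(w * y) / sum(w)
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  weights <- tibble::tibble(
    feature = feats,
    condition = unname(vapply(feats,
                              function(f) bin_label(bins, f, instance[[f]]),
                              character(1))),
    weight = as.numeric(beta[-1])
  )
  weights <- dplyr::arrange(weights, dplyr::desc(abs(.data$weight)),
                            .data$feature)
  structure(
    list(instance_id = instance_id, weights = weights,
         intercept = as.numeric(beta[1]), r_squared = r2,
         prediction = y[1], n_samples = as.integer(n),
         seed = as.integer(seed), kernel_width = kernel_width),
    class = "explanation"
  )
}

#' Explain one prediction of a trained regressor
#'
#' Convenience wrapper building the black-box function from a trained
#' [cnn_regressor][build_cnn_regressor()] and explaining one row of a
#' (normalized) descriptor table.
#'
#' @param model A trained `cnn_regressor`.
#' @param instance One-row tibble (or named vector) of normalized descriptor
#'   values, in the model's feature order.
#' @inheritParams fit_local_surrogate
#' @param ... Passed on to [fit_local_surrogate()].
#' @return An `explanation`.
#' @export
explain_prediction <- function(model, instance, bins, ...) {
  predict_fn <- function(samples) stats::predict(model, samples)
  fit_local_surrogate(predict_fn, instance, bins, ...)
}

#' @export
print.explanation <- function(x, top_k = 10L, ...) {
  cat("Local surrogate explanation for '", x$instance_id, "'\n", sep = "")
  cat("  black-box prediction: ", signif(x$prediction, 6),
      "   surrogate weighted R^2: ", signif(x$r_squared, 4), "\n", sep = "")
  cat(render_explanation(x, top_k = min(top_k, nrow(x$weights))), sep = "\n")
  invisible(x)
}

#' Render an explanation as text or JSON
#'
#' The text rendering lists the `top_k` largest-magnitude weights with a
#' support/oppose annotation (positive weights push the prediction up,
#' negative pull it down) and the binned range condition of each feature.
#' The JSON rendering round-trips losslessly through
#' [parse_explanation_json()].
#'
#' @param e An `explanation`.
#' @param top_k How many features to keep (capped at the total with a
#'   warning).
#' @param format `"text"` or `"json"`.
#' @return Character vector of report lines, or a JSON string.
#' @export
render_explanation <- function(e, top_k = 10L, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(e, "explanation"), top_k >= 1)
  if (format == "text" && top_k > nrow(e$weights)) {
    warning("top_k = ", top_k, " exceeds the ", nrow(e$weights),
            " available features; returning all.", call. = FALSE)
    top_k <- nrow(e$weights)
  }
  if (format == "json") {
    payload <- list(
      instance_id = e$instance_id,
      weights = e$weights,
      intercept = e$intercept, r_squared = e$r_squared,
      prediction = e$prediction, n_samples = e$n_samples,
      seed = e$seed, kernel_width = e$kernel_width
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = I(17))))
  }
  top <- e$weights[seq_len(top_k), ]
  sprintf("  %-8s %+.4f  %s",
          ifelse(top$weight >= 0, "support", "oppose"),
          top$weight, top$condition)
}

#' @rdname render_explanation
#' @param json A JSON string produced by `render_explanation(format = "json")`.
#' @export
parse_explanation_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(
    list(instance_id = payload$instance_id,
         weights = tibble::as_tibble(payload$weights),
         intercept = payload$intercept, r_squared = payload$r_squared,
         prediction = payload$prediction,
         n_samples = as.integer(payload$n_samples),
         seed = as.integer(payload$seed),
         kernel_width = payload$kernel_width),
    class = "explanation"
  )
}
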