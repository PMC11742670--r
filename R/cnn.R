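# One-dimensional convolutional IC50 regressor.
#
# Architecture: Conv1D(kernel 3, ReLU) -> MaxPool(2) -> Conv1D(kernel 3,
# ReLU) -> MaxPool(2) -> Flatten -> Dense(64, ReLU) -> Dense(1).  The
# descriptor vector enters as a length-n single-channel sequence.
# Convolutions are valid (no padding); pooling covers an odd remainder with
# a partial window so every input position keeps a path to the output.
# Training is plain mini-batch Adam on an MSE loss with targets min-max
# scaled to [0, 1]; every random draw goes through the config seed, so a
# fit is bit-reproducible.

#' Configuration of the convolutional IC50 regressor
#'
#' @param conv_filters Integer pair: filter counts of the two convolutional
#'   stages.
#' @param kernel_size Convolution kernel length (default 3).
#' @param pool_size Max-pooling window (default 2, non-overlapping; an
#'   odd remainder is pooled as a partial window so no input position is
#'   discarded).
#' @param dense_units Width of the penultimate dense layer (default 64).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param validation_split Fraction of rows held out (seeded) for the
#'   per-epoch validation curve.
#' @param seed Integer seed governing initialization, the train/validation
#'   split and batch shuffling.
#' @param target_scaling `"minmax"` (train on targets scaled to `[0, 1]`,
#'   predictions inverse-scaled back to micrograms per mL) or `"none"`.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_filters = c(32L, 64L), kernel_size = 3L,
                       pool_size = 2L, dense_units = 64L, epochs = 200L,
                       batch_size = 16L, learning_rate = 1e-3,
                       validation_split = 0.2, seed = 1L,
                       target_scaling = c("minmax", "none")) {
  target_scaling <- match.arg(target_scaling)
  cfg <- list(
    conv_filters = as.integer(conv_filters), kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size), dense_units = as.integer(dense_units),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, validation_split = validation_split,
    seed = as.integer(seed), target_scaling = target_scaling
  )
  stopifnot(length(cfg$conv_filters) == 2, all(cfg$conv_filters >= 1),
            cfg$kernel_size >= 1, cfg$pool_size >= 1, cfg$dense_units >= 1,
            cfg$epochs >= 1, cfg$batch_size >= 1, cfg$learning_rate > 0,
            cfg$validation_split >= 0, cfg$validation_split < 1)
  structure(cfg, class = "cnn_config")
}

# Layer lengths after each stage; NULL when the stack does not fit.
# Pooling covers an odd remainder with a partial window (ceiling length), so
# every input position keeps a path to the output.
cnn_dims <- function(n_features, config) {
  k <- config$kernel_size; p <- config$pool_size
  l1 <- n_features - k + 1L
  l2 <- (l1 + p - 1L) %/% p
  l3 <- l2 - k + 1L
  l4 <- (l3 + p - 1L) %/% p
  if (l1 < 1 || l2 < 1 || l3 < 1 || l4 < 1) return(NULL)
  list(l1 = l1, l2 = l2, l3 = l3, l4 = l4,
       flat = l4 * config$conv_filters[2])
}

# Smallest feature count the configured stack accepts.
min_cnn_features <- function(config = cnn_config()) {
  n <- config$kernel_size
  while (is.null(cnn_dims(n, config))) n <- n + 1L
  n
}

#' Build an untrained convolutional regressor
#'
#' Validates that `n_features` leaves at least one position after the two
#' convolution/pooling stages and initializes the weights (He-scaled normal
#' draws) under the config seed, so two builds with the same seed start from
#' identical parameters.
#'
#' @param n_features Length of the input descriptor vector.
#' @param config A [cnn_config()].
#' @return An untrained `cnn_regressor` object.
#' @export
build_cnn_regressor <- function(n_features, config = cnn_config()) {
  dims <- cnn_dims(n_features, config)
  if (is.null(dims)) {
    stop("n_features = ", n_features, " is too small for the ",
         "conv(", config$kernel_size, ")/pool(", config$pool_size,
         ") stack; minimum is ", min_cnn_features(config), ".", call. = FALSE)
  }
  k <- config$kernel_size
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  d <- config$dense_units
  params <- with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(k * f1, sd = sqrt(2 / k)), k, f1),
    b1 = rep(0, f1),
    W2 = matrix(stats::rnorm(k * f1 * f2, sd = sqrt(2 / (k * f1))), k * f1, f2),
    b2 = rep(0, f2),
    W3 = matrix(stats::rnorm(dims$flat * d, sd = sqrt(2 / dims$flat)), dims$flat, d),
    b3 = rep(0, d),
    W4 = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1),
    b4 = 0
  ))
  structure(
    list(config = config, n_features = n_features, dims = dims,
         params = params, trained = FALSE, feature_names = NULL,
         target_scale = NULL, history = NULL),
    class = "cnn_regressor"
  )
}

# Forward pass. x: B x n matrix. Returns cache when training.
cnn_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; dims <- model$dims; cfg <- model$config
  k <- cfg$kernel_size; ps <- cfg$pool_size
  b <- nrow(x)
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]

  z1 <- array(0, c(b, dims$l1, f1))
  for (pos in seq_len(dims$l1)) {
    z1[, pos, ] <- x[, pos:(pos + k - 1), drop = FALSE] %*% p$W1 +
      rep(p$b1, each = b)
  }
  h1 <- pmax(z1, 0)

  pool1 <- array(0, c(b, dims$l2, f1))
  win1 <- array(0L, c(b, dims$l2, f1))   # index of winning position in window
  for (q in seq_len(dims$l2)) {
    base <- (q - 1L) * ps
    w <- min(ps, dims$l1 - base)         # last window may be partial
    block <- h1[, base + seq_len(w), , drop = FALSE]
    best <- block[, 1, , drop = FALSE]; arg <- array(1L, c(b, 1, f1))
    if (w > 1) for (o in 2:w) {
      cand <- block[, o, , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      arg[better] <- o
    }
    pool1[, q, ] <- best
    win1[, q, ] <- arg
  }

  z2 <- array(0, c(b, dims$l3, f2))
  for (pos in seq_len(dims$l3)) {
    wmat <- matrix(pool1[, pos:(pos + k - 1), , drop = FALSE], nrow = b)
    # layout: columns ordered (offset, filter) with offset fastest in the
    # array's second dim -> matrix() flattens dims 2 then 3; W2 rows must
    # match: (position within window) x f1 blocks with position fastest.
    z2[, pos, ] <- wmat %*% p$W2 + rep(p$b2, each = b)
  }
  h2 <- pmax(z2, 0)

  pool2 <- array(0, c(b, dims$l4, f2))
  win2 <- array(0L, c(b, dims$l4, f2))
  for (q in seq_len(dims$l4)) {
    base <- (q - 1L) * ps
    w <- min(ps, dims$l3 - base)
    block <- h2[, base + seq_len(w), , drop = FALSE]
    best <- block[, 1, , drop = FALSE]; arg <- array(1L, c(b, 1, f2))
    if (w > 1) for (o in 2:w) {
      cand <- block[, o, , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      arg[better] <- o
    }
    pool2[, q, ] <- best
    win2[, q, ] <- arg
  }

  flat <- matrix(pool2, nrow = b)
  z3 <- flat %*% p$W3 + rep(p$b3, each = b)
  h3 <- pmax(z3, 0)
  yhat <- drop(h3 %*% p$W4 + p$b4)

  if (!keep_cache) return(yhat)
  list(yhat = yhat, x = x, z1 = z1, win1 = win1, pool1 = pool1,
       z2 = z2, win2 = win2, flat = flat, z3 = z3, h3 = h3)
}

# Backward pass for one batch; returns gradients with the params' shapes.
cnn_backward <- function(model, cache, y) {
  p <- model$params; dims <- model$dims; cfg <- model$config
  k <- cfg$kernel_size; ps <- cfg$pool_size
  b <- nrow(cache$x)
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]

  dyhat <- matrix(2 * (cache$yhat - y) / b, ncol = 1)

  gW4 <- t(cache$h3) %*% dyhat
  gb4 <- sum(dyhat)
  dh3 <- dyhat %*% t(p$W4)
  dz3 <- dh3 * (cache$z3 > 0)
  gW3 <- t(cache$flat) %*% dz3
  gb3 <- colSums(dz3)
  dflat <- dz3 %*% t(p$W3)

  dpool2 <- array(dflat, c(b, dims$l4, f2))
  dh2 <- array(0, c(b, dims$l3, f2))
  for (q in seq_len(dims$l4)) {
    base <- (q - 1L) * ps
    for (o in seq_len(min(ps, dims$l3 - base))) {
      sel <- cache$win2[, q, ] == o
      g <- dpool2[, q, ] * sel
      dh2[, base + o, ] <- dh2[, base + o, ] + g
    }
  }
  dz2 <- dh2 * (cache$z2 > 0)

  gW2 <- matrix(0, k * f1, f2)
  gb2 <- rep(0, f2)
  dpool1 <- array(0, c(b, dims$l2, f1))
  for (pos in seq_len(dims$l3)) {
    g <- matrix(dz2[, pos, ], nrow = b)
    wmat <- matrix(cache$pool1[, pos:(pos + k - 1), , drop = FALSE], nrow = b)
    gW2 <- gW2 + t(wmat) %*% g
    gb2 <- gb2 + colSums(g)
    dwin <- g %*% t(p$W2)                      # b x (k * f1)
    dwin_arr <- array(dwin, c(b, k, f1))
    for (o in seq_len(k)) {
      dpool1[, pos + o - 1L, ] <- dpool1[, pos + o - 1L, ] + dwin_arr[, o, ]
    }
  }

  dh1 <- array(0, c(b, dims$l1, f1))
  for (q in seq_len(dims$l2)) {
    base <- (q - 1L) * ps
    for (o in seq_len(min(ps, dims$l1 - base))) {
      sel <- cache$win1[, q, ] == o
      dh1[, base + o, ] <- dh1[, base + o, ] + dpool1[, q, ] * sel
    }
  }
  dz1 <- dh1 * (cache$z1 > 0)

  gW1 <- matrix(0, k, f1)
  gb1 <- rep(0, f1)
  for (pos in seq_len(dims$l1)) {
    g <- matrix(dz1[, pos, ], nrow = b)
    gW1 <- gW1 + t(cache$x[, pos:(pos + k - 1), drop = FALSE]) %*% g
    gb1 <- gb1 + colSums(g)
  }

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Train the convolutional regressor
#'
#' Minimizes mean squared error on (by default) min-max-scaled targets with
#' mini-batch Adam. An 80/20 train/validation split, the batch order of every
#' epoch, and the initial weights are all drawn under `config$seed`, so the
#' per-epoch history is reproducible to the bit.
#'
#' @param model An untrained model from [build_cnn_regressor()].
#' @param data Tibble of compounds by descriptors, already normalized to
#'   `[0, 1]`; its numeric columns must match the model's `n_features`.
#' @param targets Positive IC50 vector (micrograms per mL), one per row.
#' @return The trained `cnn_regressor` with `history` (tibble of per-epoch
#'   train/validation MSE on the training scale), `feature_names` and
#'   `target_scale`.
#' @export
train_regressor <- function(model, data, targets) {
  stopifnot(inherits(model, "cnn_regressor"))
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  x <- as.matrix(data[feats])
  assert_finite_matrix(x)
  if (ncol(x) != model$n_features) {
    stop("Model was built for ", model$n_features, " features but the table ",
         "has ", ncol(x), ".", call. = FALSE)
  }
  n <- nrow(x)
  if (n < 10) stop("Need at least 10 rows to train (got ", n, ").",
                   call. = FALSE)
  stopifnot(length(targets) == n, all(is.finite(targets)), all(targets > 0))
  cfg <- model$config

  if (cfg$target_scaling == "minmax") {
    lo <- min(targets); hi <- max(targets)
    if (hi == lo) hi <- lo + 1
    y <- (targets - lo) / (hi - lo)
    model$target_scale <- list(min = lo, max = hi)
  } else {
    y <- targets
    model$target_scale <- list(min = 0, max = 1)
  }

  adam <- list(m = lapply(model$params, function(w) w * 0),
               v = lapply(model$params, function(w) w * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  history <- matrix(NA_real_, cfg$epochs, 2,
                    dimnames = list(NULL, c("train_mse", "val_mse")))

  model <- with_seed(cfg$seed, {
    n_val <- floor(cfg$validation_split * n)
    val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    for (epoch in seq_len(cfg$epochs)) {
      order <- tr_idx[sample.int(length(tr_idx))]
      starts <- seq(1, length(order), by = cfg$batch_size)
      for (s in starts) {
        idx <- order[s:min(s + cfg$batch_size - 1, length(order))]
        cache <- cnn_forward(model, x[idx, , drop = FALSE], keep_cache = TRUE)
        grads <- cnn_backward(model, cache, y[idx])
        adam$t <- adam$t + 1
        for (nm in names(model$params)) {
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
          vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
          model$params[[nm]] <- model$params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      yhat_tr <- cnn_forward(model, x[tr_idx, , drop = FALSE])
      history[epoch, "train_mse"] <- mean((yhat_tr - y[tr_idx])^2)
      history[epoch, "val_mse"] <- if (length(val_idx)) {
        yhat_val <- cnn_forward(model, x[val_idx, , drop = FALSE])
        mean((yhat_val - y[val_idx])^2)
      } else {
        history[epoch, "train_mse"]
      }
    }
    model
  })

  model$trained <- TRUE
  model$feature_names <- feats
  model$history <- tibble::tibble(
    epoch = seq_len(cfg$epochs),
    train_mse = history[, "train_mse"],
    val_mse = history[, "val_mse"]
  )
  model
}

#' Predict IC50 for new compounds
#'
#' @param object A trained `cnn_regressor`.
#' @param newdata Tibble of compounds by descriptors, normalized with the
#'   training-set parameters; its numeric columns must match the model's
#'   `feature_names` exactly.
#' @param ... Unused.
#' @return Numeric vector of predicted IC50 values in the original
#'   (micrograms per mL) units, one per row.
#' @export
predict.cnn_regressor <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop("Model is not trained.", call. = FALSE)
  newdata <- tibble::as_tibble(newdata)
  feats <- feature_names_of(newdata)
  if (!identical(feats, object$feature_names)) {
    missing <- setdiff(object$feature_names, feats)
    extra <- setdiff(feats, object$feature_names)
    stop("Feature mismatch.",
         if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
         if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), "."),
         if (!length(missing) && !length(extra)) " Column order differs.",
         call. = FALSE)
  }
  if (nrow(newdata) == 0) return(numeric(0))
  x <- as.matrix(newdata[feats])
  assert_finite_matrix(x)
  yhat <- cnn_forward(object, x)
  sc <- object$target_scale
  yhat * (sc$max - sc$min) + sc$min
}

#' @export
print.cnn_regressor <- function(x, ...) {
  cfg <- x$config
  cat("1-D CNN regressor: Conv(", cfg$kernel_size, ") x", cfg$conv_filters[1],
      " -> Pool(", cfg$pool_size, ") -> Conv(", cfg$kernel_size, ") x",
      cfg$conv_filters[2], " -> Pool(", cfg$pool_size, ") -> Dense(",
      cfg$dense_units, ") -> Dense(1)\n", sep = "")
  cat("  input features:", x$n_features,
      if (isTRUE(x$trained)) "(trained)" else "(untrained)", "\n")
  if (isTRUE(x$trained)) {
    h <- x$history[nrow(x$history), ]
    cat("  final scaled MSE: train ", signif(h$train_mse, 4),
        ", validation ", signif(h$val_mse, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Regression error metrics
#'
#' Mean squared error `sum((y - yhat)^2) / m` and mean absolute error
#' `sum(|y - yhat|) / m`.
#'
#' @param y,yhat Equal-length numeric vectors of observed and predicted
#'   values.
#' @return A non-negative scalar.
#' @export
mse <- function(y, yhat) {
  check_metric_args(y, yhat)
  mean((y - yhat)^2)
}

#' @rdname mse
#' @export
mae <- function(y, yhat) {
  check_metric_args(y, yhat)
  mean(abs(y - yhat))
}

check_metric_args <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("Length mismatch: ", length(y), " vs ", length(yhat), ".",
         call. = FALSE)
  }
  if (length(y) == 0) stop("Empty vectors.", call. = FALSE)
  stopifnot(is.numeric(y), is.numeric(yhat))
  invisible(TRUE)
}

#' Evaluate a trained regressor on a labelled table
#'
#' @inheritParams predict.cnn_regressor
#' @param model A trained `cnn_regressor`.
#' @param data Normalized descriptor tibble.
#' @param targets Observed IC50 vector (micrograms per mL).
#' @param cell_line Optional label for the report row.
#' @param scale `"original"` computes the metrics in micrograms per mL;
#'   `"scaled"` on the model's min-max training scale (the scale on which
#'   per-epoch history is recorded).
#' @return A one-row tibble: `cell_line`, `mse`, `mae`.
#' @export
evaluate_regressor <- function(model, data, targets, cell_line = NA_character_,
                               scale = c("original", "scaled")) {
  scale <- match.arg(scale)
  yhat <- stats::predict(model, data)
  y <- targets
  if (scale == "scaled") {
    sc <- model$target_scale
    y <- (y - sc$min) / (sc$max - sc$min)
    yhat <- (yhat - sc$min) / (sc$max - sc$min)
  }
  tibble::tibble(cell_line = cell_line, mse = mse(y, yhat), mae = mae(y, yhat))
}

#' Write a metrics report as CSV
#'
#' Columns `CellLine`, `MSE`, `MAE` — one row per evaluated run.
#'
#' @param metrics Tibble from [evaluate_regressor()] (rows may be bound).
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- tibble::tibble(CellLine = metrics$cell_line, MSE = metrics$mse,
                        MAE = metrics$mae)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Save / load a trained regressor as JSON
#'
#' A plain-text checkpoint: architecture echo, learned parameters, feature
#' names and target-scaling parameters, at full double precision.
#'
#' @param model A `cnn_regressor`.
#' @param path JSON file path.
#' @return `read_regressor` returns the restored `cnn_regressor`.
#' @export
write_regressor <- function(model, path) {
  stopifnot(inherits(model, "cnn_regressor"))
  payload <- list(
    config = unclass(model$config),
    n_features = model$n_features,
    trained = isTRUE(model$trained),
    feature_names = model$feature_names,
    target_scale = model$target_scale,
    params = lapply(model$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.numeric(w))
      else list(dim = NULL, values = as.numeric(w))
    }),
    history = if (!is.null(model$history)) as.list(model$history)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(cnn_config, payload$config[setdiff(names(payload$config), character(0))])
  model <- build_cnn_regressor(payload$n_features, cfg)
  model$params <- lapply(payload$params, function(w) {
    if (!is.null(w$dim)) matrix(w$values, w$dim[1], w$dim[2]) else w$values
  })
  model$params$b4 <- as.numeric(model$params$b4)
  model$trained <- isTRUE(payload$trained)
  model$feature_names <- payload$feature_names
  model$target_scale <- payload$target_scale
  if (!is.null(payload$history)) {
    model$history <- tibble::as_tibble(payload$history)
  }
  model
}
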