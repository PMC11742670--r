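# Architecture shape, seeded initialization, gradient correctness, training,
# prediction, metrics, and the checkpoint round trip.

small_cnn <- function(seed = 1L, epochs = 5L) {
  cnn_config(conv_filters = c(2L, 3L), dense_units = 4L, epochs = epochs,
             batch_size = 8L, seed = seed)
}

test_that("the stack has the prescribed stage structure for 29 features", {
  model <- build_cnn_regressor(29L)
  d <- model$dims
  expect_equal(d$l1, 27L)   # conv, kernel 3, valid
  expect_equal(d$l2, 14L)   # pool 2 (partial final window)
  expect_equal(d$l3, 12L)   # conv
  expect_equal(d$l4, 6L)    # pool
  expect_equal(d$flat, 6L * 64L)
  # 7 computational stages: conv, pool, conv, pool, flatten, dense, dense
  expect_named(model$params, c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"))
  expect_equal(ncol(model$params$W4), 1L)      # scalar regression output
})

test_that("too-short descriptor vectors are rejected at build time", {
  expect_error(build_cnn_regressor(4L), "minimum is 7")
  expect_s3_class(build_cnn_regressor(7L), "cnn_regressor")
})

test_that("two builds with one seed start from identical parameters", {
  m1 <- build_cnn_regressor(12L, small_cnn(seed = 5L))
  m2 <- build_cnn_regressor(12L, small_cnn(seed = 5L))
  m3 <- build_cnn_regressor(12L, small_cnn(seed = 6L))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients match numerical differentiation", {
  # 13 features makes both pooling stages end on a partial window
  cfg <- small_cnn(seed = 3L)
  model <- build_cnn_regressor(13L, cfg)
  set.seed(42)
  # jitter all parameters (the zero-initialized biases in particular) so no
  # pre-activation sits exactly on the ReLU kink, where the one-sided
  # analytic subgradient and the central difference legitimately disagree
  model$params <- lapply(model$params,
                         function(w) w + rnorm(length(w), sd = 0.05))
  x <- matrix(runif(3 * 13), 3, 13)
  y <- runif(3)
  loss_of <- function(m) mean((frscreen:::cnn_forward(m, x) - y)^2)
  cache <- frscreen:::cnn_forward(model, x, keep_cache = TRUE)
  grads <- frscreen:::cnn_backward(model, cache, y)
  eps <- 1e-6
  worst <- 0
  for (nm in names(model$params)) {
    w <- model$params[[nm]]
    probe <- if (length(w) > 6) sample(seq_along(w), 6) else seq_along(w)
    for (i in probe) {
      up <- model; up$params[[nm]][i] <- w[i] + eps
      dn <- model; dn$params[[nm]][i] <- w[i] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      ana <- grads[[nm]][i]
      rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-8)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training descends on a linear target and is seed-reproducible", {
  set.seed(9)
  n <- 200
  data <- tibble::as_tibble(as.data.frame(matrix(runif(n * 10), n, 10)))
  names(data) <- sprintf("f%02d", 1:10)
  targets <- 5 + 40 * data$f02 + 25 * data$f07
  cfg <- small_cnn(seed = 2L, epochs = 30L)
  m1 <- train_regressor(build_cnn_regressor(10L, cfg), data, targets)
  expect_lt(m1$history$train_mse[30], m1$history$train_mse[1])
  expect_equal(nrow(m1$history), 30L)          # history length = epochs
  m2 <- train_regressor(build_cnn_regressor(10L, cfg), data, targets)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("fewer than 10 training rows is an error", {
  data <- tibble::as_tibble(as.data.frame(matrix(runif(9 * 8), 9, 8)))
  expect_error(
    train_regressor(build_cnn_regressor(8L, small_cnn()), data, runif(9, 1, 2)),
    "at least 10 rows")
})

test_that("predictions come back in original micrograms-per-mL units", {
  set.seed(10)
  data <- tibble::as_tibble(as.data.frame(matrix(runif(40 * 8), 40, 8)))
  names(data) <- sprintf("f%d", 1:8)
  targets <- runif(40, 20, 80)                 # far from the [0, 1] scale
  model <- train_regressor(build_cnn_regressor(8L, small_cnn(epochs = 20L)),
                           data, targets)
  preds <- predict(model, data)
  expect_length(preds, 40L)
  expect_true(all(is.finite(preds)))
  expect_gt(mean(preds), 5)                    # inverse-scaled, not in [0, 1]
  # duplicated input row -> identical prediction
  dup <- data[c(1, 1), ]
  expect_equal(predict(model, dup)[1], predict(model, dup)[2])
  # empty table -> empty prediction vector
  expect_identical(predict(model, data[0, ]), numeric(0))
})

test_that("feature mismatches are reported with the exact differences", {
  set.seed(10)
  data <- tibble::as_tibble(as.data.frame(matrix(runif(12 * 8), 12, 8)))
  names(data) <- sprintf("f%d", 1:8)
  model <- train_regressor(build_cnn_regressor(8L, small_cnn(epochs = 2L)),
                           data, runif(12, 1, 2))
  wrong <- data
  names(wrong)[3] <- "g3"
  err <- expect_error(predict(model, wrong))
  expect_match(conditionMessage(err), "Missing: f3")
  expect_match(conditionMessage(err), "Unexpected: g3")
  expect_error(predict(model, data[, c(2:8, 1)]), "order differs")
})

test_that("mse and mae satisfy their closed forms and identities", {
  expect_identical(mse(c(0, 0), c(1, 3)), 5)
  expect_identical(mae(c(0, 0), c(1, 3)), 2)
  expect_identical(mse(1:4, 1:4), 0)
  expect_identical(mae(1:4, 1:4), 0)
  expect_error(mse(1:3, 1:4), "Length mismatch")
  expect_error(mae(numeric(0), numeric(0)), "Empty")
  set.seed(13)
  for (k in 1:100) {
    y <- rnorm(7); yhat <- rnorm(7); c0 <- rnorm(1)
    expect_lte(mae(y, yhat), sqrt(mse(y, yhat)) + 1e-12)   # Jensen
    expect_equal(mse(y, yhat + c0), mean((y - yhat - c0)^2), tolerance = 1e-12)
  }
})

test_that("evaluation mirrors manual metric computation and serializes", {
  set.seed(14)
  data <- tibble::as_tibble(as.data.frame(matrix(runif(20 * 8), 20, 8)))
  names(data) <- sprintf("f%d", 1:8)
  targets <- runif(20, 1, 90)
  model <- train_regressor(build_cnn_regressor(8L, small_cnn(epochs = 3L)),
                           data, targets)
  preds <- predict(model, data)
  rep_orig <- evaluate_regressor(model, data, targets, cell_line = "HCT-116")
  expect_equal(rep_orig$mse, mse(targets, preds))
  expect_equal(rep_orig$mae, mae(targets, preds))
  sc <- model$target_scale
  rep_scaled <- evaluate_regressor(model, data, targets, scale = "scaled")
  expect_equal(rep_scaled$mse, mse(targets, preds) / (sc$max - sc$min)^2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep_orig, path)
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(got, c("CellLine", "MSE", "MAE"))
  expect_equal(got$CellLine, "HCT-116")
})

test_that("a checkpoint round-trips to identical predictions", {
  set.seed(15)
  data <- tibble::as_tibble(as.data.frame(matrix(runif(15 * 9), 15, 9)))
  names(data) <- sprintf("f%d", 1:9)
  model <- train_regressor(build_cnn_regressor(9L, small_cnn(epochs = 4L)),
                           data, runif(15, 1, 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_regressor(model, path)
  back <- read_regressor(path)
  expect_identical(predict(back, data), predict(model, data))
  expect_equal(back$history, model$history)
  expect_identical(back$feature_names, model$feature_names)
})
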