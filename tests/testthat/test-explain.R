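# Quartile discretization, perturbation sampling, the local ridge surrogate,
# and explanation rendering.

ref_table <- function(n = 200, p = 3, seed = 31) {
  set.seed(seed)
  out <- tibble::as_tibble(as.data.frame(matrix(runif(n * p), n, p)))
  names(out) <- sprintf("x%d", seq_len(p))
  out
}

test_that("discretization yields quartile bins with a constant-feature flag", {
  data <- ref_table()
  data$flat <- 2
  bins <- discretize_features(data)
  expect_s3_class(bins, "feature_bins")
  expect_length(bins$x1$edges, 3L)
  expect_false(bins$x1$constant)
  expect_true(bins$flat$constant)
  expect_error(discretize_features(data[1:3, ]), "at least 4 rows")
})

test_that("bin labels follow the range-condition format, edges fall low", {
  data <- tibble::tibble(v = c(0, 1, 2, 3, 4))
  bins <- discretize_features(data)        # edges 1, 2, 3
  expect_equal(bin_label(bins, "v", 0.5), "v <= 1.00")
  expect_equal(bin_label(bins, "v", 1),   "v <= 1.00")     # on-edge -> lower
  expect_equal(bin_label(bins, "v", 1.5), "1.00 < v <= 2.00")
  expect_equal(bin_label(bins, "v", 3.7), "v > 3.00")
  expect_error(bin_label(bins, "w", 1), "No bins")
})

test_that("perturbation sampling anchors row 1 and respects the chosen bins", {
  data <- ref_table()
  bins <- discretize_features(data)
  inst <- unlist(data[1, ])
  pert <- sample_perturbations(inst, bins, n = 400L, seed = 4L)
  expect_equal(dim(pert$z), c(400L, 3L))
  expect_true(all(pert$z %in% c(0L, 1L)))
  expect_equal(pert$z[1, ], c(x1 = 1L, x2 = 1L, x3 = 1L))
  expect_equal(unlist(pert$samples[1, ]), inst)
  # kept features stay inside the instance's bin; jumps leave it
  for (j in 1:3) {
    bin <- bins[[j]]
    home <- 1L + sum(inst[[j]] > bin$edges)
    sampled_bin <- vapply(pert$samples[[j]], function(v) 1L + sum(v > bin$edges),
                          integer(1))
    kept <- pert$z[, j] == 1L
    expect_true(all(sampled_bin[kept] == home))
    expect_true(all(sampled_bin[!kept] != home))
  }
  pert2 <- sample_perturbations(inst, bins, n = 400L, seed = 4L)
  expect_identical(pert, pert2)                     # seeded determinism
  expect_error(sample_perturbations(inst, bins, n = 5L), "n >= 10")
})

test_that("the surrogate recovers the signs of a linear black box", {
  data <- ref_table(p = 4)
  bins <- discretize_features(data)
  f <- function(samples) {
    2.5 * samples$x1 - 1.5 * samples$x2 + 0.8 * samples$x3 - 2 * samples$x4
  }
  # the surrogate weight of a feature is relative to the instance's own bin:
  # keeping a top-quartile value versus jumping lower moves the response in
  # the coefficient's direction, so signs align when the instance sits high
  inst <- vapply(data, function(v) unname(quantile(v, 0.9)), numeric(1))
  e <- fit_local_surrogate(f, inst, bins, n = 2000L, seed = 6L)
  expect_s3_class(e, "explanation")
  w <- e$weights$weight[match(sprintf("x%d", 1:4), e$weights$feature)]
  expect_equal(sign(w), c(1, -1, 1, -1))
  expect_true(e$r_squared > 0.5 && e$r_squared <= 1)
  expect_equal(e$prediction,
               2.5 * inst[["x1"]] - 1.5 * inst[["x2"]] + 0.8 * inst[["x3"]] -
                 2 * inst[["x4"]])
  # weights are sorted by decreasing magnitude
  expect_true(all(diff(abs(e$weights$weight)) <= 1e-12))
})

test_that("a constant black box earns (near) zero weights", {
  data <- ref_table()
  bins <- discretize_features(data)
  e <- fit_local_surrogate(function(s) rep(7, nrow(s)), unlist(data[1, ]),
                           bins, n = 500L, seed = 8L)
  expect_true(all(abs(e$weights$weight) < 1e-6))
  expect_equal(e$intercept, 7, tolerance = 1e-6)
})

test_that("a black box returning non-finite values is an error", {
  data <- ref_table()
  bins <- discretize_features(data)
  expect_error(
    fit_local_surrogate(function(s) rep(NaN, nrow(s)), unlist(data[1, ]),
                        bins, n = 100L, seed = 1L),
    "non-finite")
})

test_that("explanations render as text and round-trip through JSON", {
  data <- ref_table()
  bins <- discretize_features(data)
  e <- fit_local_surrogate(function(s) s$x1 - s$x2, unlist(data[2, ]), bins,
                           n = 300L, seed = 9L, instance_id = "cmpd_42")
  txt <- render_explanation(e, top_k = 2)
  expect_length(txt, 2L)
  expect_match(txt[1], "support|oppose")
  expect_warning(render_explanation(e, top_k = 99), "available features")
  json <- render_explanation(e, format = "json")
  back <- parse_explanation_json(json)
  expect_equal(back$weights, e$weights)
  expect_equal(back$intercept, e$intercept)
  expect_equal(back$r_squared, e$r_squared)
  expect_equal(back$prediction, e$prediction)
  expect_identical(back$instance_id, "cmpd_42")
  expect_output(print(e), "cmpd_42")
})

test_that("a trained regressor can be explained end to end", {
  set.seed(33)
  data <- tibble::as_tibble(as.data.frame(matrix(runif(60 * 8), 60, 8)))
  names(data) <- sprintf("x%d", 1:8)
  targets <- 1 + 60 * data$x3
  cfg <- cnn_config(conv_filters = c(2L, 3L), dense_units = 4L, epochs = 25L,
                    batch_size = 8L, seed = 2L)
  model <- train_regressor(build_cnn_regressor(8L, cfg), data, targets)
  bins <- discretize_features(data)
  e <- explain_prediction(model, data[7, ], bins, n = 500L, seed = 3L)
  expect_s3_class(e, "explanation")
  expect_equal(nrow(e$weights), 8L)
  expect_equal(e$prediction, predict(model, data[7, ]))
})
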