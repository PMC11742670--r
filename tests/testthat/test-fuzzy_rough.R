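# Similarity relations, approximations, dependency degree, reduct search.

test_that("attribute similarity is 1 at equality and 0 at opposite extremes", {
  v <- c(0, 5, 10)
  expect_equal(attribute_similarity(v, 1, 2), 0.5)
  expect_equal(attribute_similarity(v, 2, 2), 1)
  expect_equal(attribute_similarity(v, 1, 3), 0)
  expect_equal(attribute_similarity(c(3, 3, 3), 1, 3), 1)  # constant feature
  expect_error(attribute_similarity(c(1, NA), 1, 2), "Non-finite")
})

test_that("the induced relation is reflexive, symmetric, and the min t-norm", {
  set.seed(11)
  data <- tibble::tibble(name = letters[1:6],
                         f1 = runif(6), f2 = runif(6), f3 = runif(6))
  rel <- fuzzy_similarity_relation(data, c("f1", "f2", "f3"))
  expect_equal(diag(rel), rep(1, 6))
  expect_equal(unclass(rel)[seq_len(36)], t(rel)[seq_len(36)])
  for (f in c("f1", "f2", "f3")) {
    single <- fuzzy_similarity_relation(data, f)
    expect_true(all(rel <= single + 1e-12))
  }
  empty <- fuzzy_similarity_relation(data, character(0))
  expect_true(all(empty == 1))
  expect_error(fuzzy_similarity_relation(data, "nope"), "Unknown feature")
})

test_that("lower approximation is contained in the set, which is in the upper", {
  set.seed(12)
  data <- tibble::tibble(f1 = runif(8), f2 = runif(8))
  rel <- fuzzy_similarity_relation(data, c("f1", "f2"))
  a <- runif(8)
  lo <- fuzzy_lower_approx(rel, a)
  hi <- fuzzy_upper_approx(rel, a)
  # with a reflexive relation: lower <= membership <= upper, pointwise
  expect_true(all(lo <= a + 1e-12))
  expect_true(all(a <= hi + 1e-12))
  expect_error(fuzzy_lower_approx(rel, a[-1]), "Dimension mismatch")
  expect_error(fuzzy_upper_approx(rel, c(a[-1], 2)), "\\[0, 1\\]")
})

test_that("crisp tertile fuzzification partitions the compounds", {
  targets <- c(0.5, 3, 12, 40, 80, 7, 22, 65, 1.2)
  sets <- fuzzify_targets(targets)
  expect_named(sets, c("potent", "moderate", "weak"))
  total <- Reduce(`+`, sets)
  expect_equal(total, rep(1, length(targets)))   # each compound in one class
  expect_true(all(unlist(sets) %in% c(0, 1)))
  # low IC50 = potent: the smallest target sits in the first class
  expect_equal(sets$potent[which.min(targets)], 1)
  expect_error(fuzzify_targets(c(1, 1, 1)), "distinct")
})

test_that("fuzzy decision classes give every compound full self-membership", {
  targets <- c(1, 2, 10, 50)
  sets <- fuzzify_targets(targets, method = "fuzzy")
  expect_length(sets, 4L)
  for (k in seq_along(sets)) expect_equal(sets[[k]][k], 1)
})

test_that("dependency degree is 0 for the empty subset and 1 for a decisive one", {
  tbl <- generate_crisp_table(6, list(1:2, 3:4, 5:6))
  expect_equal(dependency_degree(tbl$data, character(0), tbl$decision), 0)
  expect_equal(
    dependency_degree(tbl$data, c("f01", "f02"), tbl$decision), 1)
})

test_that("quickreduct reaches the full-set dependency and records its trace", {
  tbl <- generate_crisp_table(8, list(1:2, 3:4, 5:6, 7:8), n_features = 4)
  red <- quickreduct(tbl$data, tbl$decision)
  expect_s3_class(red, "reduct_result")
  g <- tail(red$gamma_trace, 1)
  expect_equal(g, red$gamma_full, tolerance = 1e-9)
  expect_true(all(diff(red$gamma_trace) >= -1e-12))  # non-decreasing
  expect_true(all(red$selected %in% red$feature_universe))
  expect_output(print(red), "QuickReduct")
})

test_that("quickreduct breaks gain ties by the lexicographically smallest name", {
  tbl <- generate_crisp_table(4, list(1:2, 3:4))
  data <- tbl$data
  data$zz_twin <- data$f01       # identical gain as f01, later name
  red <- quickreduct(data, tbl$decision)
  expect_equal(red$selected, "f01")
})

test_that("exhaustive reduct enumeration finds minimal subsets only", {
  tbl <- generate_crisp_table(8, list(1:2, 3:4, 5:6, 7:8), n_features = 3)
  # f01/f02 code the 4 blocks; f03 is the parity bit and is redundant
  data <- plant_duplicate_feature(tbl$data, "f01")
  reducts <- brute_force_reducts(data, tbl$decision)
  expect_true(length(reducts) >= 1)
  for (r in reducts) {
    expect_false(all(c("f01", "f01_copy") %in% r))  # never both copies
    for (f in r) {   # minimality: dropping any feature loses dependency
      g <- dependency_degree(data, setdiff(r, f), tbl$decision)
      expect_lt(g, 1 - 1e-9)
    }
    expect_equal(dependency_degree(data, r, tbl$decision), 1)
  }
  wide <- tibble::as_tibble(as.data.frame(matrix(runif(2 * 13), 2, 13)))
  expect_error(brute_force_reducts(wide, tbl$decision), "12 features")
})

test_that("adding the duplicate of a selected feature never changes gamma", {
  set.seed(21)
  data <- tibble::tibble(f1 = runif(10), f2 = runif(10), f3 = runif(10))
  decision <- fuzzify_targets(runif(10, 1, 100))
  g0 <- dependency_degree(data, c("f1", "f2"), decision)
  data2 <- plant_duplicate_feature(data, "f1")
  g1 <- dependency_degree(data2, c("f1", "f2", "f1_copy"), decision)
  expect_equal(g0, g1, tolerance = 1e-12)
})
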