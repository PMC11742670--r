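# SMILES validation, descriptor computation, CSV round trips, normalization.

test_that("ring closures are counted by their paired labels", {
  out <- parse_smiles(c("O1CCOCC1", "C1CCCC2CCCCC12", "c1ccccc1",
                        "C%12CCCCCCCCCCC%12"))
  expect_true(all(out$valid))
  expect_equal(out$ring_closures, c(1L, 2L, 1L, 1L))
})

test_that("syntactically broken SMILES are rejected with a reason", {
  out <- parse_smiles(c("C1CC",        # dangling ring label
                        "",            # empty
                        "C(C",         # unbalanced parenthesis
                        "CC)",         # unbalanced parenthesis
                        "[C@H",        # unbalanced bracket
                        "C=",          # dangling bond
                        "(C)C",        # branch with no root atom
                        "C C",         # whitespace
                        "CEC"))        # unknown atom symbol
  expect_false(any(out$valid))
  expect_true(all(!is.na(out$reason)))
  expect_match(out$reason[1], "ring-closure")
  expect_match(out$reason[3], "parenthesis")
  expect_match(out$reason[6], "bond")
  expect_true(all(is.na(out$canonical)))
})

test_that("bracket atoms, branches and disconnected components parse", {
  out <- parse_smiles(c("[NH4+].[Cl-]", "CC(=O)O[C@@H]1CCCC1",
                        "N#Cc1ccccc1", "C/C=C/C"))
  expect_true(all(out$valid))
  expect_equal(out$ring_closures, c(0L, 1L, 1L, 0L))
})

test_that("a pluggable canonicalizer rewrites only the valid rows", {
  canon <- function(s) tolower(s)
  out <- parse_smiles(c("CCO", "C1CC"), canonicalizer = canon)
  expect_equal(out$canonical, c("cco", NA))
})

test_that("Open Babel canonicalization agrees with the validator on benzene", {
  canon <- ob_canonicalizer()
  kekule <- canon("C1=CC=CC=C1")
  aromatic <- canon("c1ccccc1")
  expect_true(nzchar(kekule))
  expect_identical(kekule, aromatic)   # both spellings of benzene
  expect_true(is.na(canon("C1CC")))    # rejected structure -> NA
})

test_that("the default descriptor vocabulary has 44 distinct names", {
  d <- default_descriptor_list()
  expect_length(d, 44L)
  expect_false(anyDuplicated(d) > 0)
})

test_that("descriptor computation assembles a name + descriptor tibble", {
  records <- tibble::tibble(name = c("a", "b"), smiles = c("CCO", "CCC"))
  out <- compute_descriptors(records, descriptors = c("MW", "SLogP"),
                             provider = stub_provider(value = 1.5))
  expect_equal(names(out), c("name", "MW", "SLogP"))
  expect_equal(out$MW, c(1.5, 1.5))
})

test_that("unsupported descriptor names and missing SMILES are errors", {
  records <- tibble::tibble(name = "a", smiles = "CCO")
  expect_error(
    compute_descriptors(records, descriptors = c("MW", "NotADescriptor"),
                        provider = stub_provider(supported = "MW")),
    "NotADescriptor")
  expect_error(
    compute_descriptors(tibble::tibble(name = "b", smiles = ""),
                        provider = stub_provider()),
    "without SMILES")
})

test_that("rows with non-finite descriptor values are dropped with a message", {
  records <- tibble::tibble(name = c("ok", "broken"), smiles = c("CCO", "CCC"))
  provider <- structure(list(
    compute = function(smiles, descriptor_names) {
      m <- matrix(1, length(smiles), length(descriptor_names),
                  dimnames = list(NULL, descriptor_names))
      m[smiles == "CCC", 1] <- NaN
      m
    },
    supported = NULL), class = "descriptor_provider")
  expect_message(
    out <- compute_descriptors(records, descriptors = c("MW", "SLogP"),
                               provider = provider),
    "broken")
  expect_equal(out$name, "ok")
})

test_that("descriptor CSVs round-trip through write and read", {
  lib <- generate_library(library_spec(n_compounds = 12L, n_features = 6L,
                                       n_relevant = 2L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(lib$data, path, targets = lib$targets)
  back <- read_descriptor_csv(path, target_column = "IC50")
  expect_equal(back$data$name, lib$data$name)
  expect_equal(as.matrix(back$data[-1]), as.matrix(lib$data[-1]),
               tolerance = 1e-12)
  expect_equal(back$targets, lib$targets, tolerance = 1e-12)
  nolab <- read_descriptor_csv(path)   # prediction-mode read keeps IC50 out
  expect_null(nolab$targets)
})

test_that("malformed CSV input fails with the offending location", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,f1,f1", "a,1,2"), dup)
  expect_error(read_descriptor_csv(dup), "Duplicate column")

  txt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,f1,f2", "a,1,2", "b,oops,3"), txt)
  expect_error(read_descriptor_csv(txt), "feature column 'f1' \\(row 2\\)")

  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,f1,f2", "a,1,2", "b,,3"), gap)
  expect_message(out <- read_descriptor_csv(gap), "1 row\\(s\\) dropped")
  expect_equal(out$data$name, "a")
})

test_that("min-max normalization maps to [0, 1] and round-trips", {
  data <- tibble::tibble(name = c("a", "b", "c"),
                         f1 = c(2, 4, 6), f2 = c(-1, 0, 3), f3 = c(5, 5, 5))
  norm <- normalize_descriptors(data)
  expect_equal(norm$f1, c(0, 0.5, 1))
  expect_equal(norm$f3, c(0, 0, 0))          # constant column
  p <- norm_params(norm)
  expect_true(p$constant[p$feature == "f3"])
  back <- denormalize_descriptors(norm)
  expect_equal(back$f1, data$f1)
  expect_equal(back$f3, data$f3)             # constant restored from params
})

test_that("stored normalization parameters clip out-of-range candidates", {
  train <- tibble::tibble(name = c("a", "b"), f1 = c(0, 10))
  p <- norm_params(normalize_descriptors(train))
  cand <- normalize_descriptors(tibble::tibble(name = "c", f1 = 15), params = p)
  expect_equal(cand$f1, 1)
  expect_error(
    normalize_descriptors(tibble::tibble(name = "c", f2 = 1), params = p),
    "do not match")
})
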