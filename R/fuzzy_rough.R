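# Fuzzy-rough-set machinery: graded similarity relations, lower/upper
# approximations, dependency degree, and reduct search (greedy QuickReduct
# plus an exhaustive enumerator for small tables).
#
# Conventions (stated once, relied on everywhere):
#   * per-feature similarity  s_a(x, y) = 1 - |a(x) - a(y)| / range(a),
#     with s = 1 when the feature is constant;
#   * a feature subset induces R_S(x, y) = min_a s_a(x, y)  (min t-norm);
#   * lower approximation uses the Lukasiewicz implicator
#     I(r, s) = min(1, 1 - r + s); upper uses the min t-norm.
# With 0/1 similarities and crisp sets these reduce exactly to the classical
# rough lower/upper approximations.

#' Pairwise similarity of two objects on one descriptor
#'
#' Fuzzy indiscernibility of objects `i` and `j` on a single feature:
#' `1 - |v_i - v_j| / range`. Identical values give 1, values at opposite
#' range extremes give 0, and a constant feature (zero range) makes every
#' pair fully similar.
#'
#' @param values Numeric vector of one feature's values over all compounds.
#' @param i,j Object indices (vectorized, recycled).
#' @param range Feature range; defaults to `max(values) - min(values)`.
#' @return Similarity degree(s) in `[0, 1]`.
#' @examples
#' attribute_similarity(c(0, 5, 10), 1, 2)  # 0.5
#' @export
attribute_similarity <- function(values, i, j, range = NULL) {
  if (!all(is.finite(values))) stop("Non-finite feature values.", call. = FALSE)
  if (is.null(range)) range <- max(values) - min(values)
  if (range == 0) return(rep(1, max(length(i), length(j))))
  v <- 1 - abs(values[i] - values[j]) / range
  pmin(pmax(v, 0), 1)
}

# Full n x n similarity matrix for one feature.
similarity_matrix <- function(values, range = NULL) {
  if (!all(is.finite(values))) stop("Non-finite feature values.", call. = FALSE)
  if (is.null(range)) range <- max(values) - min(values)
  n <- length(values)
  if (range == 0) return(matrix(1, n, n))
  m <- 1 - abs(outer(values, values, "-")) / range
  pmin(pmax(m, 0), 1)
}

new_fuzzy_relation <- function(matrix, subset) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  structure(matrix, class = c("fuzzy_relation", "matrix", "array"),
            subset = subset)
}

#' Fuzzy similarity relation induced by a feature subset
#'
#' Builds the reflexive, symmetric relation `R_S(x, y) = min over features a
#' in S of attribute_similarity(a, x, y)`. The empty subset induces the
#' all-ones relation (every pair fully indiscernible), the convention that
#' makes the dependency degree of the empty feature set vanish for any
#' non-trivial crisp decision.
#'
#' @param data Tibble of compounds by descriptors (numeric columns are
#'   features).
#' @param subset Character vector of feature names (possibly empty).
#' @return An n x n `fuzzy_relation` matrix with attribute `subset`.
#' @export
fuzzy_similarity_relation <- function(data, subset) {
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  unknown <- setdiff(subset, feats)
  if (length(unknown)) {
    stop("Unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  rel <- matrix(1, n, n)
  for (f in subset) rel <- pmin(rel, similarity_matrix(data[[f]]))
  new_fuzzy_relation(rel, subset)
}

#' Fuzzy lower and upper approximations
#'
#' For a fuzzy relation `R` and fuzzy set `A` on the same universe, the lower
#' approximation at `x` is `inf over y of I(R(x,y), A(y))` with the
#' Lukasiewicz implicator `I(r, s) = min(1, 1 - r + s)`; the upper
#' approximation is `sup over y of min(R(x,y), A(y))`. On crisp (0/1)
#' relations and sets these are the classical rough approximations: `x` is in
#' the lower approximation iff its indiscernibility class is contained in
#' `A`, and in the upper iff the class intersects `A`.
#'
#' @param relation An n x n fuzzy relation (see
#'   [fuzzy_similarity_relation()]).
#' @param a Numeric membership vector of length n with values in `[0, 1]`.
#' @return Membership vector of length n.
#' @export
fuzzy_lower_approx <- function(relation, a) {
  check_relation_set(relation, a)
  # row x: min over y of min(1, 1 - R[x, y] + a[y])
  m <- pmin(1 - relation + matrix(a, nrow(relation), length(a), byrow = TRUE), 1)
  apply(m, 1, min)
}

#' @rdname fuzzy_lower_approx
#' @export
fuzzy_upper_approx <- function(relation, a) {
  check_relation_set(relation, a)
  m <- pmin(relation, matrix(a, nrow(relation), length(a), byrow = TRUE))
  apply(m, 1, max)
}

check_relation_set <- function(relation, a) {
  if (!is.matrix(relation) || nrow(relation) != ncol(relation)) {
    stop("`relation` must be a square matrix.", call. = FALSE)
  }
  if (length(a) != nrow(relation)) {
    stop("Dimension mismatch: relation is ", nrow(relation), " x ",
         ncol(relation), " but the set has ", length(a), " memberships.",
         call. = FALSE)
  }
  if (any(a < 0 | a > 1) || !all(is.finite(a))) {
    stop("Memberships must lie in [0, 1].", call. = FALSE)
  }
  invisible(TRUE)
}

#' Turn continuous IC50 targets into decision classes
#'
#' The rough-set machinery needs decision classes, not a continuous potency.
#' The default carves the targets into equal-frequency bins (tertiles by
#' default, labelled from most to least potent — low IC50 means high
#' potency) returned as crisp 0/1 membership vectors. The `"fuzzy"` method
#' instead returns one fuzzy decision class per compound, with memberships
#' given by [attribute_similarity()] on the min-max-normalized target, so
#' nearby potencies are partially indiscernible; use it when the targets have
#' too few distinct values for crisp binning.
#'
#' @param targets Numeric IC50 vector (micrograms per mL), length >= 3.
#' @param n_bins Number of crisp bins (default 3).
#' @param method `"crisp"` (equal-frequency bins) or `"fuzzy"`.
#' @return A named list of membership vectors, each of length
#'   `length(targets)`.
#' @export
fuzzify_targets <- function(targets, n_bins = 3, method = c("crisp", "fuzzy")) {
  method <- match.arg(method)
  stopifnot(is.numeric(targets), length(targets) >= 3, all(is.finite(targets)))
  if (method == "fuzzy") {
    sim <- similarity_matrix(targets)
    sets <- lapply(seq_along(targets), function(k) sim[, k])
    names(sets) <- paste0("class_", seq_along(targets))
    return(sets)
  }
  if (length(unique(targets)) < n_bins) {
    stop("Only ", length(unique(targets)), " distinct target value(s) for ",
         n_bins, " bins; consider method = \"fuzzy\".", call. = FALSE)
  }
  bin <- dplyr::ntile(targets, n_bins)
  labels <- if (n_bins == 3) {
    c("potent", "moderate", "weak")
  } else {
    paste0("bin_", seq_len(n_bins))
  }
  sets <- lapply(seq_len(n_bins), function(b) as.numeric(bin == b))
  names(sets) <- labels
  sets
}

#' Dependency degree of a decision on a feature subset
#'
#' The fuzzy positive region of a decision is, at each compound, the largest
#' lower-approximation membership over the decision classes; the dependency
#' degree `gamma` is its mean. `gamma = 1` means every compound is
#' unambiguously assignable to its decision class from the subset's
#' similarity relation alone; the empty subset gives `gamma = 0` whenever
#' there are at least two non-trivial crisp classes.
#'
#' @inheritParams fuzzy_similarity_relation
#' @param decision Named list of decision membership vectors (see
#'   [fuzzify_targets()]).
#' @return `gamma` in `[0, 1]`.
#' @export
dependency_degree <- function(data, subset, decision) {
  if (!length(decision)) stop("Empty decision list.", call. = FALSE)
  rel <- fuzzy_similarity_relation(data, subset)
  gamma_of_relation(rel, decision)
}

# gamma from a precomputed relation matrix (hot path of the reduct search).
gamma_of_relation <- function(rel, decision) {
  n <- nrow(rel)
  pos <- rep(0, n)
  for (a in decision) {
    m <- pmin(1 - rel + matrix(a, n, n, byrow = TRUE), 1)
    pos <- pmax(pos, apply(m, 1, min))
  }
  mean(pos)
}

#' Greedy QuickReduct feature selection
#'
#' Forward selection on the dependency degree: starting from the empty
#' subset, repeatedly add the feature with the largest `gamma` gain (ties
#' broken by lexicographically smallest name), stopping once `gamma` is
#' within `tolerance` of the full feature set's dependency. A zero-gain
#' addition is still made (the classical QuickReduct rule): some decisive
#' feature combinations — parity-style interactions — yield no gain
#' one feature at a time, and skipping them would strand the search below
#' the full dependency. Because the relation is a min t-norm over features,
#' `gamma` is non-decreasing along the search and the loop always
#' terminates, at worst with every feature selected.
#'
#' @param data Tibble of compounds by descriptors, min-max normalized.
#' @param decision Named list of decision membership vectors.
#' @param tolerance Non-negative stopping tolerance on `gamma`
#'   (default `1e-6`).
#' @return A `reduct_result`: `selected` (ordered feature names),
#'   `gamma_trace` (dependency after each addition), `gamma_full`,
#'   `tolerance`, and `feature_universe`.
#' @export
quickreduct <- function(data, decision, tolerance = 1e-6) {
  stopifnot(tolerance >= 0, length(decision) >= 1)
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  m <- as.matrix(data[feats])
  assert_finite_matrix(m)
  n <- nrow(data)

  sims <- lapply(feats, function(f) similarity_matrix(data[[f]]))
  names(sims) <- feats

  full_rel <- Reduce(pmin, sims, matrix(1, n, n))
  gamma_full <- gamma_of_relation(full_rel, decision)

  selected <- character(0)
  gamma_trace <- numeric(0)
  current_rel <- matrix(1, n, n)
  current_gamma <- gamma_of_relation(current_rel, decision)

  while (current_gamma < gamma_full - tolerance) {
    remaining <- sort(setdiff(feats, selected))
    if (!length(remaining)) break
    gains <- vapply(remaining, function(f) {
      gamma_of_relation(pmin(current_rel, sims[[f]]), decision)
    }, numeric(1))
    best <- remaining[which.max(gains)]   # ties -> first of sorted names
    selected <- c(selected, best)
    current_rel <- pmin(current_rel, sims[[best]])
    current_gamma <- gains[[best]]
    gamma_trace <- c(gamma_trace, current_gamma)
  }

  structure(
    list(selected = selected, gamma_trace = gamma_trace,
         gamma_full = gamma_full, tolerance = tolerance,
         feature_universe = feats),
    class = "reduct_result"
  )
}

#' @export
print.reduct_result <- function(x, ...) {
  cat("QuickReduct result\n")
  cat("  selected (", length(x$selected), "/", length(x$feature_universe),
      "): ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  gamma: ",
      if (length(x$gamma_trace)) signif(utils::tail(x$gamma_trace, 1), 6) else 0,
      " (full set: ", signif(x$gamma_full, 6), ", tolerance ",
      format(x$tolerance), ")\n", sep = "")
  invisible(x)
}

#' Exhaustively enumerate all minimal reducts
#'
#' Brute-force oracle for small tables: enumerates feature subsets in
#' increasing size and returns every subset whose dependency degree matches
#' the full set's (within `1e-12`) and that has no qualifying proper subset.
#' Refuses tables with more than 12 features.
#'
#' @inheritParams quickreduct
#' @return List of character vectors, each one minimal reduct.
#' @export
brute_force_reducts <- function(data, decision) {
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  if (length(feats) > 12) {
    stop("Exhaustive search refuses more than 12 features (got ",
         length(feats), ").", call. = FALSE)
  }
  n <- nrow(data)
  sims <- lapply(feats, function(f) similarity_matrix(data[[f]]))
  names(sims) <- feats
  gamma_of <- function(subset) {
    rel <- Reduce(pmin, sims[subset], matrix(1, n, n))
    gamma_of_relation(rel, decision)
  }
  gamma_full <- gamma_of(feats)

  reducts <- list()
  for (size in seq_along(feats)) {
    for (idx in utils::combn(length(feats), size, simplify = FALSE)) {
      subset <- feats[idx]
      contains_reduct <- any(vapply(reducts, function(r) all(r %in% subset),
                                    logical(1)))
      if (contains_reduct) next
      if (gamma_of(subset) >= gamma_full - 1e-12) {
        reducts[[length(reducts) + 1L]] <- subset
      }
    }
    if (length(reducts) && size >= max(lengths(reducts))) {
      # all smaller subsets already checked; supersets are pruned above, but
      # keep scanning larger sizes only for incomparable subsets
      next
    }
  }
  reducts
}
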