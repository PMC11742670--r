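# Seeded synthetic compound libraries.
#
# The generator emulates the statistical shape the screening pipeline
# assumes: a descriptor table of ~40-120 compounds x ~44 continuous
# descriptors in which a small planted subset drives a positive, bounded
# IC50-like response plus additive noise. Crisp decision tables with a
# prescribed indiscernibility partition serve as oracles for the classical
# rough-set degenerations.

#' Specification of a synthetic compound library
#'
#' Descriptors are i.i.d. uniform on `[0, 1]`. A latent potency is the
#' logistic of a centred weighted sum of the planted relevant descriptors,
#' mapped affinely onto `ic50_range`, so IC50 stays positive and bounded the
#' way measured micrograms-per-mL potencies are. Observed targets add
#' Gaussian noise (clipped to stay positive).
#'
#' @param n_compounds Number of compounds (>= 10; default 90).
#' @param n_features Number of descriptors (default 44).
#' @param n_relevant Number of planted relevant descriptors (default 5);
#'   ignored when `relevant_features` is given.
#' @param relevant_features Optional explicit names of the planted subset.
#' @param effect_weights Signed weights of the planted descriptors on the
#'   latent potency. The default `(6, -5, 4.5, -4, 3.5)` (recycled/truncated
#'   to `n_relevant`) gives each relevant descriptor an effect well above
#'   the noise floor, as in a curated QSAR panel.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   IC50 scale; default 5% of the IC50 range.
#' @param ic50_range Positive `(lo, hi)` bounds of the latent IC50 in
#'   micrograms per mL (default `c(0.01, 100)`, the span typical of
#'   cell-line potency panels).
#' @param seed Integer seed; the library is a pure function of the spec.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_compounds = 90L, n_features = 44L,
                         n_relevant = 5L, relevant_features = NULL,
                         effect_weights = NULL, noise_sd = NULL,
                         ic50_range = c(0.01, 100), seed = 1L) {
  stopifnot(n_features >= 1, ic50_range[1] > 0,
            ic50_range[2] > ic50_range[1])
  if (is.null(noise_sd)) noise_sd <- 0.05 * diff(ic50_range)
  stopifnot(noise_sd >= 0)
  if (!is.null(relevant_features)) n_relevant <- length(relevant_features)
  if (is.null(effect_weights)) {
    effect_weights <- rep_len(c(6, -5, 4.5, -4, 3.5), n_relevant)
  }
  stopifnot(length(effect_weights) == n_relevant, n_relevant <= n_features)
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_features = as.integer(n_features),
         n_relevant = as.integer(n_relevant),
         relevant_features = relevant_features,
         effect_weights = effect_weights,
         noise_sd = noise_sd, ic50_range = ic50_range,
         seed = as.integer(seed)),
    class = "library_spec"
  )
}

#' Generate a synthetic compound library
#'
#' @param spec A [library_spec()].
#' @return A list of class `synthetic_library`: `data` (tibble `name` +
#'   descriptor columns `desc_01` ...), `targets` (observed IC50 vector),
#'   and `truth` (planted subset, effect weights, and the noiseless IC50
#'   vector) — enough to score feature-selection recall and ranking quality
#'   without re-deriving anything.
#' @export
generate_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "library_spec"))
  if (spec$n_compounds < 10) {
    stop("n_compounds must be at least 10 (got ", spec$n_compounds, ").",
         call. = FALSE)
  }
  feats <- sprintf("desc_%02d", seq_len(spec$n_features))
  relevant <- spec$relevant_features
  out <- with_seed(spec$seed, {
    if (is.null(relevant)) {
      relevant <- sort(sample(feats, spec$n_relevant))
    } else {
      stopifnot(all(relevant %in% feats))
    }
    x <- matrix(stats::runif(spec$n_compounds * spec$n_features),
                spec$n_compounds, spec$n_features,
                dimnames = list(NULL, feats))
    latent <- stats::plogis(
      drop(x[, relevant, drop = FALSE] %*% (spec$effect_weights)) -
        sum(spec$effect_weights) / 2
    )
    lo <- spec$ic50_range[1]; hi <- spec$ic50_range[2]
    ic50_true <- lo + latent * (hi - lo)
    noise <- if (spec$noise_sd > 0) {
      stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
    } else {
      rep(0, spec$n_compounds)
    }
    targets <- pmax(ic50_true + noise, lo * 1e-3)
    list(x = x, relevant = relevant, ic50_true = ic50_true,
         targets = targets)
  })
  data <- dplyr::bind_cols(
    tibble::tibble(name = sprintf("cmpd_%03d", seq_len(spec$n_compounds))),
    tibble::as_tibble(as.data.frame(out$x))
  )
  structure(
    list(data = data, targets = out$targets,
         truth = list(relevant_features = out$relevant,
                      effect_weights = spec$effect_weights,
                      ic50_true = out$ic50_true),
         spec = spec),
    class = "synthetic_library"
  )
}

#' Generate a crisp decision table realizing a given partition
#'
#' Builds a small categorical-coded (0/1) descriptor table whose full-set
#' indiscernibility relation is exactly the requested partition — objects in
#' the same block are identical on every feature, objects in different
#' blocks differ somewhere. Used as an oracle fixture for the classical
#' rough-set degeneration of the fuzzy approximations.
#'
#' @param n_objects Number of objects (<= 12).
#' @param partition List of integer vectors that together cover
#'   `1:n_objects` exactly once; each vector is one indiscernibility block.
#' @param decision Optional decision partition in the same format; defaults
#'   to the feature partition (a consistent table). Returned as crisp 0/1
#'   membership sets.
#' @param n_features Number of binary features (default: just enough to code
#'   the blocks).
#' @return List with `data` (tibble `name` + binary feature columns) and
#'   `decision` (named list of crisp membership vectors).
#' @export
generate_crisp_table <- function(n_objects, partition, decision = NULL,
                                 n_features = NULL) {
  if (n_objects > 12) stop("n_objects must be <= 12.", call. = FALSE)
  members <- sort(unlist(partition))
  if (!identical(members, seq_len(n_objects))) {
    stop("`partition` must cover 1:", n_objects, " exactly once.",
         call. = FALSE)
  }
  n_blocks <- length(partition)
  min_feats <- max(1L, ceiling(log2(n_blocks)))
  if (is.null(n_features)) n_features <- min_feats
  if (n_features < min_feats) {
    stop("Need at least ", min_feats, " binary features to code ",
         n_blocks, " blocks.", call. = FALSE)
  }
  block_of <- integer(n_objects)
  for (b in seq_along(partition)) block_of[partition[[b]]] <- b
  codes <- vapply(seq_len(n_features), function(bit) {
    ((block_of - 1L) %/% 2L^(bit - 1L)) %% 2L
  }, numeric(n_objects))
  codes <- matrix(as.numeric(codes), n_objects, n_features,
                  dimnames = list(NULL, sprintf("f%02d", seq_len(n_features))))
  data <- dplyr::bind_cols(
    tibble::tibble(name = sprintf("x%d", seq_len(n_objects))),
    tibble::as_tibble(as.data.frame(codes))
  )
  if (is.null(decision)) decision <- partition
  dm <- sort(unlist(decision))
  if (!identical(dm, seq_len(n_objects))) {
    stop("`decision` must cover 1:", n_objects, " exactly once.",
         call. = FALSE)
  }
  sets <- lapply(decision, function(blk) as.numeric(seq_len(n_objects) %in% blk))
  names(sets) <- paste0("d", seq_along(decision))
  list(data = data, decision = sets)
}

#' Duplicate one descriptor column bit-exactly
#'
#' Reduct-minimality fixture: after planting an exact copy of a feature, no
#' minimal reduct can contain both copies, and the dependency degree of any
#' subset containing the original is unchanged by adding the copy.
#'
#' @param data Tibble of compounds by descriptors.
#' @param feature Name of the column to duplicate.
#' @param new_name Name of the copy (default `<feature>_copy`).
#' @return The table with one extra column.
#' @export
plant_duplicate_feature <- function(data, feature,
                                    new_name = paste0(feature, "_copy")) {
  data <- tibble::as_tibble(data)
  if (!feature %in% names(data)) {
    stop("No such feature: ", feature, call. = FALSE)
  }
  if (new_name %in% names(data)) {
    stop("Name collision: '", new_name, "' already exists.", call. = FALSE)
  }
  data[[new_name]] <- data[[feature]]
  data
}

#' Write a synthetic library as reference/candidate CSV files
#'
#' The reference file carries the IC50 column; the candidate file omits it
#' (prediction-mode layout). The planted truth is written alongside as JSON.
#'
#' @param library A `synthetic_library` from [generate_library()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_library_csv <- function(library, dir, prefix = "library") {
  stopifnot(inherits(library, "synthetic_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- file.path(dir, paste0(prefix, "_reference.csv"))
  cand <- file.path(dir, paste0(prefix, "_candidates.csv"))
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  write_descriptor_csv(library$data, ref, targets = library$targets)
  write_descriptor_csv(library$data, cand)
  jsonlite::write_json(library$truth, truth, auto_unbox = TRUE, digits = I(17))
  invisible(c(reference = ref, candidates = cand, truth = truth))
}
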