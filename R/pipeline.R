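# End-to-end screening pipeline: assemble a reference set (optionally with a
# lead compound), select descriptors by fuzzy-rough QuickReduct, train the
# 1-D CNN on the selected columns, predict candidate IC50s, rank ascending,
# and explain the top hits. Every stage is seeded; a manifest with content
# hashes makes two identical-config runs byte-comparable.

#' Configuration of a screening run
#'
#' @param reference Reference dataset: either a CSV path (Table-style layout
#'   with an IC50 column) or a list with `data` (tibble) and `targets`.
#' @param candidates Candidate dataset: CSV path without a target column, or
#'   a tibble of `name` + descriptors.
#' @param lead Optional lead compound: a one-row data frame or named list
#'   with `name`, the descriptor columns, and `ic50`.
#' @param target_column Name of the activity column in the reference CSV.
#' @param n_bins Decision bins for [fuzzify_targets()] (default 3).
#' @param fuzzify_method `"crisp"` or `"fuzzy"` decision construction.
#' @param tolerance QuickReduct stopping tolerance on the dependency degree.
#' @param cnn A [cnn_config()].
#' @param train_on `"selected"` trains the regressor on the reduct columns
#'   only (the default); `"all"` is an ablation that keeps every descriptor.
#' @param top_k Number of top-ranked candidates to keep and explain.
#' @param n_explain How many of the top candidates get a surrogate
#'   explanation (default 1).
#' @param explainer_samples,kernel_width Local-surrogate settings.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory where artifacts and the manifest are
#'   written.
#' @return A `screen_config` list.
#' @export
screen_config <- function(reference, candidates, lead = NULL,
                          target_column = "IC50", n_bins = 3L,
                          fuzzify_method = "crisp", tolerance = 0.05,
                          cnn = cnn_config(), train_on = c("selected", "all"),
                          top_k = 10L, n_explain = 1L,
                          explainer_samples = 5000L, kernel_width = NULL,
                          seed = 1L, out_dir = NULL) {
  train_on <- match.arg(train_on)
  stopifnot(top_k >= 1, n_explain >= 0)
  structure(
    list(reference = reference, candidates = candidates, lead = lead,
         target_column = target_column, n_bins = as.integer(n_bins),
         fuzzify_method = fuzzify_method, tolerance = tolerance,
         cnn = cnn, train_on = train_on, top_k = as.integer(top_k),
         n_explain = as.integer(n_explain),
         explainer_samples = as.integer(explainer_samples),
         kernel_width = kernel_width, seed = as.integer(seed),
         out_dir = out_dir),
    class = "screen_config"
  )
}

#' Append a lead compound to a reference panel
#'
#' The lead (the measured anchor compound whose features guide the screen)
#' is appended as an ordinary labelled row. Duplicate compound names and a
#' lead without a measured IC50 are errors.
#'
#' @param data Reference tibble of `name` + descriptors.
#' @param targets Measured IC50 vector aligned with `data`.
#' @param lead `NULL`, or a one-row data frame / named list carrying `name`,
#'   every descriptor column of `data`, and `ic50`.
#' @return List with the augmented `data` and `targets`.
#' @export
assemble_training_set <- function(data, targets, lead = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(length(targets) == nrow(data))
  if (anyDuplicated(data$name)) {
    stop("Duplicate compound name(s) in the reference set: ",
         paste(unique(data$name[duplicated(data$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(lead)) return(list(data = data, targets = targets))
  lead <- as.list(lead)
  if (is.null(lead$ic50) || length(lead$ic50) != 1 || is.na(lead$ic50) ||
      lead$ic50 <= 0) {
    stop("Lead compound must carry a positive measured IC50.", call. = FALSE)
  }
  if (is.null(lead$name)) stop("Lead compound must be named.", call. = FALSE)
  if (lead$name %in% data$name) {
    stop("Duplicate compound name: '", lead$name, "'.", call. = FALSE)
  }
  feats <- feature_names_of(data)
  missing <- setdiff(feats, names(lead))
  if (length(missing)) {
    stop("Lead compound is missing descriptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  row <- tibble::as_tibble(c(list(name = lead$name),
                             lead[feats]))
  list(data = dplyr::bind_rows(data, row),
       targets = c(targets, as.numeric(lead$ic50)))
}

#' Rank candidate compounds by ascending predicted IC50
#'
#' Lower IC50 means higher potency, so the most potent candidates come
#' first; ties are ordered by compound name.
#'
#' @param predictions Tibble (or data frame) with columns `name` and
#'   `ic50_pred`.
#' @param top_k Number of rows to keep.
#' @return A `ranked_candidates` tibble: `rank`, `name`, `ic50_pred`.
#' @export
rank_candidates <- function(predictions, top_k = nrow(predictions)) {
  predictions <- tibble::as_tibble(predictions)
  if (!nrow(predictions)) stop("Empty prediction list.", call. = FALSE)
  stopifnot(all(c("name", "ic50_pred") %in% names(predictions)),
            all(is.finite(predictions$ic50_pred)), top_k >= 1)
  out <- dplyr::arrange(predictions, .data$ic50_pred, .data$name)
  out <- out[seq_len(min(top_k, nrow(out))), c("name", "ic50_pred")]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("ranked_candidates", class(out))
  out
}

#' Compare the reducts selected with and without the lead compound
#'
#' @param with_lead,without_lead `reduct_result` objects from the same
#'   feature universe.
#' @return List of class `reduct_comparison`: `shared`, `only_with_lead`,
#'   `only_without_lead`.
#' @export
compare_reducts <- function(with_lead, without_lead) {
  stopifnot(inherits(with_lead, "reduct_result"),
            inherits(without_lead, "reduct_result"))
  if (!setequal(with_lead$feature_universe, without_lead$feature_universe)) {
    stop("Reducts come from different feature universes.", call. = FALSE)
  }
  structure(
    list(shared = sort(intersect(with_lead$selected, without_lead$selected)),
         only_with_lead = sort(setdiff(with_lead$selected,
                                       without_lead$selected)),
         only_without_lead = sort(setdiff(without_lead$selected,
                                          with_lead$selected))),
    class = "reduct_comparison"
  )
}

#' @rdname compare_reducts
#' @param comparison A `reduct_comparison`.
#' @param path Output CSV path; two columns listing the descriptors selected
#'   without and with the lead compound.
#' @export
write_reduct_comparison_csv <- function(comparison, path) {
  without <- sort(c(comparison$shared, comparison$only_without_lead))
  with <- sort(c(comparison$shared, comparison$only_with_lead))
  n <- max(length(without), length(with), 1L)
  out <- tibble::tibble(
    selected_without_lead = c(without, rep("", n - length(without))),
    selected_with_lead = c(with, rep("", n - length(with)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Resolve a reference/candidate config entry into data (+ targets).
resolve_dataset <- function(x, target_column = NULL) {
  if (is.character(x) && length(x) == 1) {
    read_descriptor_csv(x, target_column = target_column)
  } else if (is.list(x) && !is.data.frame(x) && "data" %in% names(x)) {
    list(data = tibble::as_tibble(x$data), targets = x$targets)
  } else {
    list(data = tibble::as_tibble(x), targets = NULL)
  }
}

# Zero-pad a descriptor matrix on the right so the conv/pool stack fits.
# Padding columns are constant zeros and carry no information; they only
# extend the input sequence to the architecture's minimum length.
pad_features <- function(data, min_features) {
  feats <- feature_names_of(data)
  n_pad <- max(0L, min_features - length(feats))
  if (n_pad > 0) {
    for (k in seq_len(n_pad)) data[[sprintf(".pad%02d", k)]] <- 0
  }
  data
}

#' Run the full screening pipeline
#'
#' Executes the dry-lab phases end to end: load the reference panel, append
#' the lead compound if given, min-max normalize, fuzzify the IC50 decision,
#' select descriptors by QuickReduct, train the convolutional regressor on
#' the selected columns, evaluate it, predict and rank the candidate
#' library, and explain the top-ranked candidates with local surrogates.
#' The run is deterministic given `config$seed`. When `config$out_dir` is
#' set, every artifact is written there (reduct JSON, metrics CSV, ranked
#' CSV, explanation JSONs, model checkpoint, training history) together with
#' a `manifest.json` carrying a config echo and the MD5 hash of each file.
#'
#' @param config A [screen_config()].
#' @return A `screen_result` list: `reduct`, `model`, `metrics`, `ranked`,
#'   `explanations`, `manifest`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 4L)

  ref <- stage("load_reference",
               resolve_dataset(config$reference, config$target_column))
  if (is.null(ref$targets)) {
    stop("Stage [load_reference] failed: reference set has no targets.",
         call. = FALSE)
  }
  cand <- stage("load_candidates", resolve_dataset(config$candidates))

  assembled <- stage("assemble",
                     assemble_training_set(ref$data, ref$targets, config$lead))
  message("[assemble] ", nrow(assembled$data), " reference compounds, ",
          nrow(cand$data), " candidates")

  # candidate rows must never enter training
  overlap <- intersect(assembled$data$name, cand$data$name)
  train_ids <- assembled$data$name

  norm_ref <- stage("normalize", normalize_descriptors(assembled$data))
  params <- norm_params(norm_ref)

  decision <- stage("fuzzify",
                    fuzzify_targets(assembled$targets, n_bins = config$n_bins,
                                    method = config$fuzzify_method))
  reduct <- stage("select", quickreduct(norm_ref, decision,
                                        tolerance = config$tolerance))
  message("[select] ", length(reduct$selected), " of ",
          length(reduct$feature_universe), " descriptors kept (gamma ",
          signif(if (length(reduct$gamma_trace))
            utils::tail(reduct$gamma_trace, 1) else 0, 4), ")")

  keep <- if (config$train_on == "selected" && length(reduct$selected)) {
    reduct$selected
  } else {
    reduct$feature_universe
  }
  cnn_cfg <- config$cnn
  cnn_cfg$seed <- seeds[2]
  train_tbl <- pad_features(
    dplyr::select(norm_ref, dplyr::all_of(c("name", keep))),
    min_cnn_features(cnn_cfg)
  )
  n_feats <- length(feature_names_of(train_tbl))

  model <- stage("train", {
    m <- build_cnn_regressor(n_feats, cnn_cfg)
    train_regressor(m, train_tbl, assembled$targets)
  })
  metrics <- stage("evaluate",
                   evaluate_regressor(model, train_tbl, assembled$targets,
                                      cell_line = "synthetic",
                                      scale = "scaled"))
  message("[evaluate] scaled MSE ", signif(metrics$mse, 4), ", MAE ",
          signif(metrics$mae, 4))

  cand_norm <- stage("normalize_candidates",
                     normalize_descriptors(cand$data, params = params))
  cand_tbl <- pad_features(
    dplyr::select(cand_norm, dplyr::all_of(c("name", keep))),
    min_cnn_features(cnn_cfg)
  )
  preds <- stage("predict", tibble::tibble(
    name = cand_tbl$name,
    ic50_pred = stats::predict(model, cand_tbl)
  ))
  ranked <- stage("rank", rank_candidates(preds, top_k = config$top_k))
  message("[rank] top candidate: ", ranked$name[1], " (predicted IC50 ",
          signif(ranked$ic50_pred[1], 4), ")")

  explanations <- list()
  if (config$n_explain > 0) {
    bins <- stage("discretize", discretize_features(train_tbl))
    for (k in seq_len(min(config$n_explain, nrow(ranked)))) {
      nm <- ranked$name[k]
      inst <- cand_tbl[cand_tbl$name == nm, , drop = FALSE][1, ]
      explanations[[nm]] <- stage("explain", explain_prediction(
        model, inst, bins, n = config$explainer_samples,
        seed = seeds[3] %/% 2L + k, kernel_width = config$kernel_width
      ))
    }
  }

  manifest <- list(
    config = config_echo(config),
    seed = config$seed,
    n_reference = nrow(assembled$data),
    n_candidates = nrow(cand$data),
    training_ids_disjoint_from_candidates = length(overlap) == 0,
    overlapping_names = overlap,
    selected_features = reduct$selected,
    files = list()
  )

  result <- structure(
    list(reduct = reduct, model = model, metrics = metrics, ranked = ranked,
         explanations = explanations, manifest = manifest,
         norm_params = params),
    class = "screen_result"
  )

  if (!is.null(config$out_dir)) {
    result$manifest <- write_screen_artifacts(result, config$out_dir)
  }
  result
}

# Plain-list echo of the config for the manifest (drops in-memory tables).
config_echo <- function(config) {
  echo <- unclass(config)
  for (nm in c("reference", "candidates", "lead")) {
    if (!is.character(echo[[nm]]) && !is.null(echo[[nm]])) {
      echo[[nm]] <- paste0("<in-memory ", nm, ">")
    }
  }
  echo$cnn <- unclass(echo$cnn)
  echo
}

# Write all artifacts and return the manifest (with per-file MD5 hashes).
write_screen_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reduct = file.path(out_dir, "reduct.json"),
    metrics = file.path(out_dir, "metrics.csv"),
    ranked = file.path(out_dir, "ranked_candidates.csv"),
    model = file.path(out_dir, "model.json"),
    history = file.path(out_dir, "training_history.csv")
  )
  write_reduct_json(result$reduct, paths[["reduct"]])
  write_metrics_csv(result$metrics, paths[["metrics"]])
  readr::write_csv(result$ranked, paths[["ranked"]], progress = FALSE)
  write_regressor(result$model, paths[["model"]])
  readr::write_csv(result$model$history, paths[["history"]], progress = FALSE)
  for (nm in names(result$explanations)) {
    p <- file.path(out_dir, paste0("explanation_", nm, ".json"))
    writeLines(render_explanation(result$explanations[[nm]],
                                  top_k = nrow(result$explanations[[nm]]$weights),
                                  format = "json"), p)
    paths[[paste0("explanation_", nm)]] <- p
  }
  manifest <- result$manifest
  manifest$files <- as.list(unname(tools::md5sum(unlist(paths))))
  names(manifest$files) <- basename(unlist(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  manifest
}

#' Serialize a reduct as JSON
#'
#' @param reduct A `reduct_result`.
#' @param path Output path.
#' @export
write_reduct_json <- function(reduct, path) {
  jsonlite::write_json(
    list(selected = reduct$selected, gamma_trace = reduct$gamma_trace,
         gamma_full = reduct$gamma_full, tolerance = reduct$tolerance,
         feature_universe = reduct$feature_universe),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screening run\n")
  cat("  selected descriptors:", length(x$reduct$selected), "of",
      length(x$reduct$feature_universe), "\n")
  cat("  scaled MSE:", signif(x$metrics$mse, 4),
      " MAE:", signif(x$metrics$mae, 4), "\n")
  cat("  top candidates:\n")
  top <- utils::head(x$ranked, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %2d. %-20s %.4g\n", top$rank[i], top$name[i],
                top$ic50_pred[i]))
  }
  invisible(x)
}
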