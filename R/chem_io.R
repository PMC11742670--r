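# Compound dataset input/output: SMILES validation, descriptor computation
# through a pluggable provider, CSV round trips, and min-max normalization.

SMILES_ORGANIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s", "*")
SMILES_BONDS <- c("-", "=", "#", "$", ":", "/", "\\")

#' Validate SMILES strings and count ring closures
#'
#' Performs a syntactic validation of SMILES line notation: balanced
#' parentheses and square brackets, recognised atom symbols (organic subset
#' plus arbitrary bracket atoms), bond characters (`-`, `=`, `#`, `$`, `:`,
#' `/`, `\`), and paired ring-closure digit labels (including `%nn` two-digit
#' labels). Ring systems are counted by their closure labels: dioxane
#' `O1CCOCC1` has one, decalin `C1CCCC2CCCCC12` has two (both closing on the
#' final carbon).
#'
#' Canonicalization is delegated to a pluggable provider function; by default
#' the string is returned as-is for valid input. Use [ob_canonicalizer()] to
#' canonicalize through Open Babel (ChemmineOB).
#'
#' @param smiles Character vector of SMILES strings.
#' @param canonicalizer Either `NULL` (canonical form = input) or a function
#'   mapping a SMILES string to its canonical form (`NA` if the provider
#'   rejects it).
#' @return A tibble with one row per input: `smiles`, `valid`, `reason`
#'   (`NA` when valid), `canonical` (`NA` when invalid), `ring_closures`.
#' @examples
#' parse_smiles(c("O1CCOCC1", "C1CCCC2CCCCC12", "C1CC", ""))
#' @export
parse_smiles <- function(smiles, canonicalizer = NULL) {
  stopifnot(is.character(smiles))
  res <- purrr::map(smiles, parse_smiles_one)
  out <- tibble::tibble(
    smiles = smiles,
    valid = purrr::map_lgl(res, "valid"),
    reason = purrr::map_chr(res, "reason"),
    ring_closures = purrr::map_int(res, "ring_closures")
  )
  canonical <- ifelse(out$valid, out$smiles, NA_character_)
  if (!is.null(canonicalizer)) {
    stopifnot(is.function(canonicalizer))
    canonical[out$valid] <- vapply(out$smiles[out$valid],
                                   function(s) as.character(canonicalizer(s)[1]),
                                   character(1))
  }
  out$canonical <- canonical
  out[c("smiles", "valid", "reason", "canonical", "ring_closures")]
}

# Single-string tokenizer. Returns valid flag, reason, ring-closure count.
parse_smiles_one <- function(text) {
  bad <- function(reason) list(valid = FALSE, reason = reason, ring_closures = 0L)
  if (is.na(text) || !nzchar(text)) return(bad("empty input"))
  if (grepl("[^\\x20-\\x7E]", text, perl = TRUE)) return(bad("non-ASCII character"))
  if (grepl("\\s", text)) return(bad("whitespace in SMILES"))

  chars <- strsplit(text, "")[[1]]
  i <- 1L
  n <- length(chars)
  depth <- 0L
  open_rings <- integer(0)       # currently open ring labels
  n_closures <- 0L
  last_was_atom <- FALSE
  atom_seen <- FALSE

  take_ring_label <- function(lab) {
    if (lab %in% open_rings) {
      open_rings <<- setdiff(open_rings, lab)
      n_closures <<- n_closures + 1L
    } else {
      open_rings <<- c(open_rings, lab)
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(bad("unbalanced square bracket"))
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]*[A-Za-z@*][A-Za-z0-9@+:H'-]*$", inner)) {
        return(bad(paste0("malformed bracket atom [", inner, "]")))
      }
      last_was_atom <- TRUE
      atom_seen <- TRUE
      i <- j + 1L
    } else if (ch == "(") {
      if (!last_was_atom) return(bad("branch not attached to an atom"))
      depth <- depth + 1L
      last_was_atom <- FALSE
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(bad("unbalanced parenthesis"))
      last_was_atom <- TRUE   # branch closes back onto its root atom
      i <- i + 1L
    } else if (ch %in% SMILES_BONDS) {
      i <- i + 1L
      if (i > n) return(bad("dangling bond symbol"))
      last_was_atom <- FALSE
    } else if (ch == ".") {
      last_was_atom <- FALSE
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (!last_was_atom) return(bad("ring-closure digit not attached to an atom"))
      take_ring_label(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (!last_was_atom) return(bad("ring-closure label not attached to an atom"))
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = ""))) {
        return(bad("malformed %nn ring-closure label"))
      }
      take_ring_label(as.integer(paste(chars[i + 1:2], collapse = "")))
      i <- i + 3L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% SMILES_ORGANIC) {
        last_was_atom <- TRUE; atom_seen <- TRUE; i <- i + 2L
      } else if (ch %in% SMILES_ORGANIC) {
        last_was_atom <- TRUE; atom_seen <- TRUE; i <- i + 1L
      } else {
        return(bad(paste0("unrecognised character '", ch, "'")))
      }
    }
  }
  if (depth != 0L) return(bad("unbalanced parenthesis"))
  if (length(open_rings)) {
    return(bad(paste0("dangling ring-closure label ",
                      paste(open_rings, collapse = ","))))
  }
  if (!atom_seen) return(bad("no atoms"))
  list(valid = TRUE, reason = NA_character_, ring_closures = n_closures)
}

#' Open Babel canonicalization provider
#'
#' Returns a function that canonicalizes one SMILES string through
#' ChemmineOB / Open Babel, yielding `NA` for strings the toolkit rejects.
#' Intended as the `canonicalizer` argument of [parse_smiles()] and as an
#' independent cross-check of the syntactic validator.
#'
#' @return A function `character(1) -> character(1)`.
#' @export
ob_canonicalizer <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is not installed.", call. = FALSE)
  }
  function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }
}

#' Descriptor providers
#'
#' A descriptor provider is a list with elements `compute` (a function
#' `(smiles, descriptor_names) -> numeric matrix` with one row per SMILES)
#' and `supported` (a character vector of descriptor names, or `NULL` when
#' the provider accepts any name). [stub_provider()] returns a constant value
#' for every descriptor and is what the test-suite uses so the package works
#' offline; [rdkit_provider()] shells out to a Python interpreter with RDKit
#' on its path and computes any descriptor in
#' `rdkit.Chem.Descriptors.descList`.
#'
#' @param value Constant value returned by the stub for every cell.
#' @param supported Optional vector of names the stub claims to support.
#' @param python Path to the Python interpreter for the RDKit provider.
#' @return A `descriptor_provider` object.
#' @name descriptor_providers
NULL

#' @rdname descriptor_providers
#' @export
stub_provider <- function(value = 0, supported = NULL) {
  structure(
    list(
      compute = function(smiles, descriptor_names) {
        matrix(value, nrow = length(smiles), ncol = length(descriptor_names),
               dimnames = list(NULL, descriptor_names))
      },
      supported = supported
    ),
    class = "descriptor_provider"
  )
}

#' @rdname descriptor_providers
#' @export
rdkit_provider <- function(python = "python") {
  list_code <- "from rdkit.Chem import Descriptors; print('\\n'.join(n for n,_ in Descriptors.descList))"
  supported <- tryCatch(
    system2(python, c("-c", shQuote(list_code)), stdout = TRUE, stderr = FALSE),
    error = function(e) character(0),
    warning = function(w) character(0)
  )
  if (!length(supported)) {
    stop("RDKit is not reachable through `", python, "`.", call. = FALSE)
  }
  compute <- function(smiles, descriptor_names) {
    inp <- tempfile(fileext = ".json")
    outp <- tempfile(fileext = ".json")
    on.exit(unlink(c(inp, outp)), add = TRUE)
    jsonlite::write_json(list(smiles = smiles, names = descriptor_names), inp,
                         auto_unbox = FALSE)
    code <- paste(
      "import json, sys, math",
      "from rdkit import Chem",
      "from rdkit.Chem import Descriptors",
      sprintf("spec = json.load(open('%s'))", inp),
      "fns = dict(Descriptors.descList)",
      "rows = []",
      "for s in spec['smiles']:",
      "    mol = Chem.MolFromSmiles(s)",
      "    if mol is None:",
      "        rows.append([float('nan')] * len(spec['names']))",
      "        continue",
      "    row = []",
      "    for n in spec['names']:",
      "        try:",
      "            v = float(fns[n](mol))",
      "        except Exception:",
      "            v = float('nan')",
      "        row.append(v if math.isfinite(v) else None)",
      "    rows.append(row)",
      sprintf("json.dump(rows, open('%s', 'w'))", outp),
      sep = "\n")
    status <- system2(python, c("-c", shQuote(code)))
    if (status != 0L) stop("RDKit descriptor computation failed.", call. = FALSE)
    rows <- jsonlite::fromJSON(outp, simplifyVector = FALSE)
    m <- do.call(rbind, lapply(rows, function(r) {
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    }))
    colnames(m) <- descriptor_names
    m
  }
  structure(list(compute = compute, supported = supported),
            class = "descriptor_provider")
}

#' Default descriptor vocabulary
#'
#' The 44-name descriptor list used by the screening pipeline: a mixture of
#' 2-D autocorrelation (ATS/ATSC/AATS/MATS/GATS), electrotopological-state
#' (E-state), charged-partial-surface (PEOE_VSA/SMR_VSA/EState_VSA), path and
#' walk count, and constitutional descriptors, i.e. the vocabulary typical of
#' Mordred/RDKit 2-D descriptor sets used in IC50 QSAR work.
#'
#' @return Character vector of 44 descriptor names.
#' @export
default_descriptor_list <- function() {
  c(
    "ATSC4dv", "ATSC1m", "ATSC7are", "Xch-6d", "SssO", "fMF", "PEOE_VSA3",
    "SMR_VSA7", "EState_VSA4", "MATS1i", "Mp", "SaaN", "JGI10", "AATS0dv",
    "ATSC3v", "GATS2dv", "SdCH2", "SssNH", "SdS", "IC2", "EState_VSA2",
    "piPC8", "SsNH2", "ZMIC3", "PEOE_VSA4", "PEOE_VSA5", "PEOE_VSA11",
    "SMR_VSA4", "EState_VSA9", "SRW07", "AATSC2pe", "AATSC1are", "GATS1i",
    "AATS1dv", "JGT10",
    # constitutional padding to 44
    "MW", "nHeavyAtom", "nC", "nN", "nO", "nRotB", "nRing", "TopoPSA", "SLogP"
  )
}

#' Compute a descriptor table for a set of compounds
#'
#' Maps each compound's SMILES through a descriptor provider and assembles a
#' compounds-by-descriptors tibble. Rows whose provider output contains any
#' non-finite value are dropped with a message (conservative handling of
#' descriptors the provider cannot evaluate for a structure).
#'
#' @param records A data frame with columns `name` and `smiles` (and
#'   optionally `ic50`).
#' @param descriptors Character vector of descriptor names to compute, in
#'   output order. Defaults to [default_descriptor_list()].
#' @param provider A `descriptor_provider`; see [stub_provider()].
#' @return A tibble: `name` column plus one numeric column per descriptor.
#' @export
compute_descriptors <- function(records,
                                descriptors = default_descriptor_list(),
                                provider = stub_provider()) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("name", "smiles") %in% names(records)),
            length(descriptors) > 0)
  if (anyNA(records$smiles) || !all(nzchar(records$smiles))) {
    missing <- records$name[is.na(records$smiles) | !nzchar(records$smiles)]
    stop("Records without SMILES: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(provider$supported)) {
    unknown <- setdiff(descriptors, provider$supported)
    if (length(unknown)) {
      stop("Unsupported descriptor name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  m <- provider$compute(records$smiles, descriptors)
  stopifnot(nrow(m) == nrow(records), ncol(m) == length(descriptors))
  keep <- apply(m, 1, function(r) all(is.finite(r)))
  if (any(!keep)) {
    message(sum(!keep), " compound(s) dropped (non-finite descriptor values): ",
            paste(records$name[!keep], collapse = ", "))
  }
  out <- tibble::as_tibble(as.data.frame(m[keep, , drop = FALSE]),
                           .name_repair = "minimal")
  names(out) <- descriptors
  dplyr::bind_cols(tibble::tibble(name = records$name[keep]), out)
}

#' Read / write compound descriptor CSV files
#'
#' Reads a comma-separated decision table in the usual QSAR layout: one
#' compound-name column, numeric descriptor columns, and optionally a
#' measured-activity column (e.g. `IC50` in micrograms per mL). Non-numeric
#' cells in a feature column and duplicate column names are errors with the
#' offending location; rows containing non-finite feature values are dropped
#' with a message.
#'
#' @param path CSV file path.
#' @param target_column Name of the activity column to split off as the
#'   target vector, or `NULL` for prediction-mode inputs without targets.
#' @param id_column Name of the compound-name column; by default the first
#'   non-numeric column (or `Drug_name`/`name` if present).
#' @return For `read_descriptor_csv`: a list with `data` (tibble of `name` +
#'   numeric descriptors), `targets` (numeric vector or `NULL`) and
#'   `compound_names`. For `write_descriptor_csv`: the path, invisibly.
#' @export
read_descriptor_csv <- function(path, target_column = NULL, id_column = NULL) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (anyDuplicated(header)) {
    stop("Duplicate column name(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (!nrow(raw)) stop("Empty dataset: ", path, call. = FALSE)
  if (is.null(id_column)) {
    id_column <- intersect(c("Drug_name", "drug_name", "name"), names(raw))[1]
    if (is.na(id_column)) {
      non_num <- names(raw)[!vapply(raw, is.numeric, logical(1))]
      id_column <- if (length(non_num)) non_num[[1]] else NA_character_
    }
  }
  if (!is.null(target_column) && !target_column %in% names(raw)) {
    stop("Target column '", target_column, "' not found.", call. = FALSE)
  }
  feat_cols <- setdiff(names(raw), c(id_column, target_column, "smiles", "SMILES"))
  for (cn in feat_cols) {
    col <- raw[[cn]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad_row <- which(is.na(parsed) & !is.na(col))[1]
      stop("Non-numeric cell in feature column '", cn, "' (row ",
           if (is.na(bad_row)) "?" else bad_row, ").", call. = FALSE)
    }
  }
  names_vec <- if (!is.na(id_column) && !is.null(id_column)) {
    as.character(raw[[id_column]])
  } else {
    sprintf("compound_%03d", seq_len(nrow(raw)))
  }
  targets <- if (!is.null(target_column)) as.numeric(raw[[target_column]]) else NULL
  data <- dplyr::bind_cols(tibble::tibble(name = names_vec), raw[feat_cols])
  finite <- apply(as.matrix(raw[feat_cols]), 1, function(r) all(is.finite(r)))
  if (any(!finite)) {
    message(sum(!finite), " row(s) dropped (non-finite descriptor values).")
    data <- data[finite, , drop = FALSE]
    if (!is.null(targets)) targets <- targets[finite]
  }
  list(data = data, targets = targets, compound_names = data$name)
}

#' @rdname read_descriptor_csv
#' @param data Tibble of `name` + numeric descriptor columns.
#' @param targets Optional numeric vector written as the target column.
#' @export
write_descriptor_csv <- function(data, path, targets = NULL,
                                 target_column = "IC50") {
  data <- tibble::as_tibble(data)
  out <- data
  if (!is.null(targets)) {
    stopifnot(length(targets) == nrow(data))
    out[[target_column]] <- as.numeric(targets)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Min-max normalize descriptor columns
#'
#' Scales every numeric column to `[0, 1]` using per-column minimum and
#' maximum, the scaling assumed by the fuzzy similarity relation and the
#' regressor. Constant columns map to 0 and are flagged. The fitted
#' parameters are attached so candidate tables can be scaled with the
#' training-set ranges (values are clipped to `[0, 1]` in that case).
#'
#' @param data Tibble of compounds by descriptors.
#' @param params Optional normalization parameters from a previous call
#'   (a tibble with columns `feature`, `min`, `max`, `constant`); feature
#'   names must match exactly.
#' @return The normalized tibble with attribute `"norm_params"`; retrieve it
#'   with [norm_params()].
#' @export
normalize_descriptors <- function(data, params = NULL) {
  data <- tibble::as_tibble(data)
  feats <- feature_names_of(data)
  if (nrow(data) < 2 && is.null(params)) {
    stop("Need at least 2 rows to fit normalization.", call. = FALSE)
  }
  assert_finite_matrix(as.matrix(data[feats]))
  if (is.null(params)) {
    params <- tibble::tibble(
      feature = feats,
      min = unname(vapply(data[feats], min, numeric(1))),
      max = unname(vapply(data[feats], max, numeric(1)))
    )
    params$constant <- params$max == params$min
  } else {
    if (!setequal(params$feature, feats) ||
        !identical(params$feature, feats)) {
      stop("Normalization parameters do not match the table's features.",
           call. = FALSE)
    }
  }
  for (k in seq_along(feats)) {
    f <- params$feature[k]
    if (params$constant[k]) {
      data[[f]] <- rep(0, nrow(data))
    } else {
      v <- (data[[f]] - params$min[k]) / (params$max[k] - params$min[k])
      data[[f]] <- pmin(1, pmax(0, v))
    }
  }
  attr(data, "norm_params") <- params
  data
}

#' @rdname normalize_descriptors
#' @export
norm_params <- function(data) attr(data, "norm_params")

#' @rdname normalize_descriptors
#' @export
denormalize_descriptors <- function(data, params = norm_params(data)) {
  if (is.null(params)) stop("No normalization parameters found.", call. = FALSE)
  data <- tibble::as_tibble(data)
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    if (params$constant[k]) {
      data[[f]] <- rep(params$min[k], nrow(data))
    } else {
      data[[f]] <- data[[f]] * (params$max[k] - params$min[k]) + params$min[k]
    }
  }
  attr(data, "norm_params") <- NULL
  data
}
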