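# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic stages route their randomness through this so results are a
# pure function of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Extract the numeric descriptor matrix of a compound table
#'
#' Compound tables in frscreen are ordinary tibbles: non-numeric columns
#' (typically `name`) identify compounds, numeric columns are molecular
#' descriptors. This helper pulls out the numeric block as a matrix with the
#' identifier column as row names.
#'
#' @param data A data frame of compounds by descriptors.
#' @param id_col Optional name of the identifier column. Defaults to the
#'   first non-numeric column, if any.
#' @return A numeric matrix (compounds x descriptors).
#' @export
descriptor_matrix <- function(data, id_col = NULL) {
  data <- tibble::as_tibble(data)
  num <- vapply(data, is.numeric, logical(1))
  if (is.null(id_col)) {
    non_num <- names(data)[!num]
    id_col <- if (length(non_num)) non_num[[1]] else NULL
  }
  m <- as.matrix(data[num])
  if (!is.null(id_col) && id_col %in% names(data)) {
    rownames(m) <- as.character(data[[id_col]])
  }
  m
}

feature_names_of <- function(data) {
  data <- tibble::as_tibble(data)
  names(data)[vapply(data, is.numeric, logical(1))]
}

assert_finite_matrix <- function(m, what = "descriptor table") {
  if (!all(is.finite(m))) {
    stop("Non-finite values in ", what, ".", call. = FALSE)
  }
  invisible(m)
}
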