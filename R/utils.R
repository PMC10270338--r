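# shared helpers: series extraction, validation, seed derivation

#' Extract the numeric series from a data frame or vector
#'
#' Most functions in mpnoise are data-frame-first: they take a data frame with
#' a numeric `value` column (the convention all generators follow) or a bare
#' numeric vector. This helper implements that contract in one place.
#'
#' @param data A data frame with a numeric series column, or a numeric vector.
#' @param value Column holding the series when `data` is a data frame.
#'   Defaults to a column named `value`, falling back to the single numeric
#'   column if there is exactly one.
#' @param allow_na Permit missing values (ingestion paths clean them later).
#' @return A numeric vector.
#' @keywords internal
#' @noRd
series_values <- function(data, value = NULL, allow_na = FALSE) {
  if (is.numeric(data)) {
    x <- as.numeric(data)
  } else if (is.data.frame(data)) {
    if (!is.null(value)) {
      col <- value
      if (!col %in% names(data)) {
        abort(sprintf("column '%s' not found in `data`", col))
      }
    } else if ("value" %in% names(data)) {
      col <- "value"
    } else {
      num <- names(data)[vapply(data, is.numeric, logical(1))]
      if (length(num) != 1) {
        abort("`data` must have a 'value' column or exactly one numeric column")
      }
      col <- num
    }
    x <- as.numeric(data[[col]])
  } else {
    abort("`data` must be a data frame or a numeric vector")
  }
  if (length(x) < 1) abort("series is empty")
  if (!allow_na && !all(is.finite(x))) {
    abort("series contains non-finite values (NA/NaN/Inf)")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

#' Derive a per-condition seed from a master seed
#'
#' Deterministic, so adding conditions never perturbs the randomness of
#' others; always a valid 32-bit integer.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, index, replicate = 1L) {
  seed <- as.double(seed)
  s <- (seed * 131 + index + 7919 * (replicate - 1)) %% 2147483647
  as.integer(s)
}
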