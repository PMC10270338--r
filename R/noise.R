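#' Describe one noise-corruption condition
#'
#' A `noise_spec` fully parameterises a corruption: its kind, the kind's own
#' parameter (duplication `factor` k, or insertion `proportion` p), the
#' anomaly fraction, the placement mode for duplicates, and the seed that
#' makes the injection reproducible.
#'
#' @param kind `"duplicated_anomaly"` (a random 5% of values each repeated k
#'   times, emulating recording errors) or `"irrelevant_features"` (a
#'   proportion p of extra values drawn from Unif(min(X), max(X)) inserted at
#'   random positions, emulating measurement noise).
#' @param factor Duplication multiplicity k >= 1 (duplicated_anomaly only).
#' @param proportion Insertion proportion p in [0, 1] (irrelevant_features only).
#' @param anomaly_fraction Fraction of positions flagged as anomalies before
#'   duplication; default 0.05.
#' @param seed Integer seed; fully determines the injection.
#' @param placement Where duplicate copies go: `"adjacent"` (immediately after
#'   the original, the default — duplicates then appear in the profile as a
#'   local pattern) or `"scattered"` (uniform-random gaps).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("duplicated_anomaly", "irrelevant_features"),
                       factor = NULL, proportion = NULL,
                       anomaly_fraction = 0.05, seed = 1L,
                       placement = c("adjacent", "scattered")) {
  kind <- match.arg(kind)
  placement <- match.arg(placement)
  if (kind == "duplicated_anomaly") {
    if (is.null(factor)) abort("duplicated_anomaly requires `factor`")
    factor <- check_count(factor, "factor", min = 1L)
    if (!is.null(proportion)) abort("`proportion` is not used for duplicated_anomaly")
  } else {
    if (is.null(proportion)) abort("irrelevant_features requires `proportion`")
    if (!is.numeric(proportion) || proportion < 0 || proportion > 1) {
      abort("`proportion` must be in [0, 1]")
    }
    if (!is.null(factor)) abort("`factor` is not used for irrelevant_features")
  }
  if (!is.numeric(anomaly_fraction) || anomaly_fraction <= 0 ||
      anomaly_fraction >= 1) {
    abort("`anomaly_fraction` must be in (0, 1)")
  }
  structure(
    list(kind = kind, factor = factor, proportion = proportion,
         anomaly_fraction = anomaly_fraction,
         seed = as.integer(seed), placement = placement),
    class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  p <- if (x$kind == "duplicated_anomaly") {
    sprintf("factor = %d, anomaly fraction = %g, placement = %s",
            x$factor, x$anomaly_fraction, x$placement)
  } else {
    sprintf("proportion = %g", x$proportion)
  }
  cat(sprintf("<noise_spec> %s (%s), seed = %d\n", x$kind, p, x$seed))
  invisible(x)
}

new_injection_result <- function(value, is_inserted, spec) {
  structure(
    tibble::tibble(value = value, is_inserted = is_inserted),
    inserted_positions = which(is_inserted),
    original_length = sum(!is_inserted),
    spec = spec,
    class = c("injection_result", class(tibble::tibble())))
}

# interleave original values with insertions after the given gaps
# (gap g in 0..n means "after original element g"); stable order() keeps
# the originals' relative order and the insertions' draw order
interleave_at_gaps <- function(x, ins, gaps) {
  n <- length(x)
  key <- c(seq_len(n), gaps + 0.5)
  ord <- order(key)
  list(value = c(x, ins)[ord],
       is_inserted = c(rep(FALSE, n), rep(TRUE, length(ins)))[ord])
}

#' Corrupt a series by duplicating a random subset of values
#'
#' A `floor(anomaly_fraction * n)` subset of positions is drawn without
#' replacement; each selected value then appears `factor` times in total. With
#' the default adjacent placement, the `factor - 1` extra copies sit
#' immediately after the original occurrence, so the corrupted length is
#' exactly `n + (factor - 1) * floor(anomaly_fraction * n)` and deleting the
#' recorded insertions recovers the original series.
#'
#' @inheritParams matrix_profile
#' @param factor Duplication multiplicity k >= 1; k = 1 is the identity.
#' @param anomaly_fraction Fraction of positions duplicated; default 0.05.
#' @param seed Integer seed.
#' @param placement `"adjacent"` (default) or `"scattered"`.
#' @return An `injection_result`: a tibble with columns `value` and
#'   `is_inserted`, plus attributes `inserted_positions` (1-based positions in
#'   the corrupted series), `original_length` and `spec`.
#' @export
inject_duplicated_anomalies <- function(data, factor, anomaly_fraction = 0.05,
                                        seed = 1L,
                                        placement = c("adjacent", "scattered"),
                                        value = NULL) {
  x <- series_values(data, value)
  n <- length(x)
  placement <- match.arg(placement)
  spec <- noise_spec("duplicated_anomaly", factor = factor,
                     anomaly_fraction = anomaly_fraction, seed = seed,
                     placement = placement)
  k <- spec$factor
  s <- floor(anomaly_fraction * n)
  if (k > 1 && s < 1) {
    abort("floor(anomaly_fraction * n) must be >= 1 when factor > 1")
  }
  if (k == 1 || s == 0) {
    return(new_injection_result(x, rep(FALSE, n), spec))
  }
  withr::with_seed(seed, {
    sel <- sort(sample.int(n, s))
    if (placement == "adjacent") {
      counts <- rep(1L, n)
      counts[sel] <- k
      value_out <- rep(x, counts)
      flag <- rep(FALSE, n)
      ins_flag <- unlist(lapply(counts, function(c) c(FALSE, rep(TRUE, c - 1L))))
      res <- list(value = value_out, is_inserted = ins_flag)
    } else {
      ins <- rep(x[sel], each = k - 1L)
      gaps <- sample(0:n, length(ins), replace = TRUE)
      res <- interleave_at_gaps(x, ins, gaps)
    }
  })
  new_injection_result(res$value, res$is_inserted, spec)
}

#' Corrupt a series by inserting irrelevant uniform values
#'
#' Inserts `floor(proportion * n)` values drawn i.i.d. from the continuous
#' uniform distribution on `[min(X), max(X)]` (bounds from the clean series)
#' at insertion gaps chosen uniformly at random among the n + 1 gaps, without
#' shuffling the original order.
#'
#' @inheritParams inject_duplicated_anomalies
#' @param proportion Insertion proportion p in [0, 1]; p = 0 is the identity.
#' @return An `injection_result` (see [inject_duplicated_anomalies()]).
#' @export
inject_irrelevant_features <- function(data, proportion, seed = 1L,
                                       value = NULL) {
  x <- series_values(data, value)
  n <- length(x)
  spec <- noise_spec("irrelevant_features", proportion = proportion,
                     seed = seed)
  n_ins <- floor(proportion * n)
  if (n_ins == 0) {
    return(new_injection_result(x, rep(FALSE, n), spec))
  }
  if (n < 2) abort("need n >= 2 to insert irrelevant features")
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    inform("degenerate series (min == max): all inserted values equal that constant")
  }
  withr::with_seed(seed, {
    ins <- runif(n_ins, lo, hi)
    gaps <- sample(0:n, n_ins, replace = TRUE)
  })
  res <- interleave_at_gaps(x, ins, gaps)
  new_injection_result(res$value, res$is_inserted, spec)
}

#' Apply a noise specification to a series
#'
#' Dispatches to [inject_duplicated_anomalies()] or
#' [inject_irrelevant_features()] according to `spec$kind`.
#'
#' @inheritParams matrix_profile
#' @param spec A [noise_spec()].
#' @return An `injection_result`.
#' @export
inject_noise <- function(data, spec, value = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$kind == "duplicated_anomaly") {
    inject_duplicated_anomalies(data, factor = spec$factor,
                                anomaly_fraction = spec$anomaly_fraction,
                                seed = spec$seed, placement = spec$placement,
                                value = value)
  } else {
    inject_irrelevant_features(data, proportion = spec$proportion,
                               seed = spec$seed, value = value)
  }
}

#' Recover the original series from an injection result
#'
#' Deletes the recorded insertions; the result equals the clean input exactly.
#'
#' @param result An `injection_result`.
#' @return A tibble with a `value` column.
#' @export
recover_original <- function(result) {
  stopifnot(inherits(result, "injection_result"))
  tibble::tibble(value = result$value[!result$is_inserted])
}

#' The standard ten-condition noise grid
#'
#' Duplication factors k = 2..6 (at the default 5% anomaly fraction) and
#' irrelevant-feature proportions p = 1%, 5%, 10%, 25%, 50% — the grid the
#' study pipeline sweeps by default. Each condition gets its own seed derived
#' deterministically from `seed`.
#'
#' @param seed Master seed for the grid.
#' @param anomaly_fraction Anomaly fraction for the duplication conditions.
#' @return A tibble with columns `condition`, `kind`, `param`, `seed` and a
#'   list-column `spec` of [noise_spec()] objects.
#' @export
study_noise_grid <- function(seed = 1L, anomaly_fraction = 0.05) {
  ks <- 2:6
  ps <- c(0.01, 0.05, 0.10, 0.25, 0.50)
  grid <- tibble::tibble(
    condition = c(sprintf("Duplicated Anomaly x %d", ks),
                  sprintf("Irrelevant Features - %d%%", as.integer(100 * ps))),
    kind = rep(c("duplicated_anomaly", "irrelevant_features"), each = 5),
    param = c(ks, ps)
  )
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) derive_seed(seed, i),
                      integer(1))
  grid$spec <- purrr::pmap(grid, function(condition, kind, param, seed) {
    if (kind == "duplicated_anomaly") {
      noise_spec(kind, factor = param, anomaly_fraction = anomaly_fraction,
                 seed = seed)
    } else {
      noise_spec(kind, proportion = param, seed = seed)
    }
  })
  grid
}

#' Write a corrupted series (with its insertion mask) to CSV
#'
#' @param result An `injection_result`.
#' @param path Output CSV path; columns `value`, `is_inserted`.
#' @return `path`, invisibly.
#' @export
write_corrupted <- function(result, path) {
  readr::write_csv(tibble::as_tibble(result)[c("value", "is_inserted")], path)
  invisible(path)
}
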