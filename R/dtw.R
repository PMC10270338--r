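#' Exact dynamic time warping with absolute-difference cost
#'
#' Full dynamic-programming alignment of two numeric sequences under the local
#' cost |a_i - b_j| with steps (1,0), (0,1), (1,1). Ties between predecessor
#' cells are broken towards the diagonal, so paths are deterministic.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list of class `dtw_alignment` with elements `cost` (the summed
#'   absolute matched difference over the path) and `path` (a tibble of
#'   1-based index pairs `i`, `j` from (1,1) to (|a|, |b|)).
#' @examples
#' dtw_exact(c(1, 2, 3), c(2, 3, 4))$cost # 2
#' @export
dtw_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("empty input sequence")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("non-finite values")
  res <- dtw_window_cpp(a, b, rep(1L, length(a)), rep(length(b), length(a)))
  new_dtw_alignment(res, mode = "exact", radius = NA_integer_)
}

new_dtw_alignment <- function(res, mode, radius) {
  structure(
    list(cost = res$cost,
         path = tibble::tibble(i = res$i, j = res$j),
         mode = mode, radius = radius),
    class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> %s, cost = %g, path length = %d\n",
              x$mode, x$cost, nrow(x$path)))
  invisible(x)
}

#' @export
tidy.dtw_alignment <- function(x, ...) x$path

#' @export
glance.dtw_alignment <- function(x, ...) {
  tibble::tibble(cost = x$cost, path_length = nrow(x$path),
                 mode = x$mode, radius = x$radius)
}

# coarsen a sequence by averaging adjacent pairs; an odd tail element is
# carried down unchanged
halve_series <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  out <- (x[seq(1, 2 * h, by = 2)] + x[seq(2, 2 * h, by = 2)]) / 2
  if (n %% 2 == 1) out <- c(out, x[n])
  out
}

# expand a coarse-resolution path into per-row column windows at the fine
# resolution, widened by `radius` cells in rows and columns
project_window <- function(path_i, path_j, n, m, radius) {
  fi <- c(2 * path_i - 1, pmin(2 * path_i, n))
  fj <- c(2 * path_j - 1, pmin(2 * path_j, m))
  fi <- pmin(fi, n)
  lo <- rep(NA_integer_, n); hi <- rep(NA_integer_, n)
  for (k in seq_along(fi)) {
    r <- fi[k]
    lo[r] <- min(lo[r], fj[k], na.rm = TRUE)
    hi[r] <- max(hi[r], fj[k], na.rm = TRUE)
  }
  # rows untouched by the projection (possible at odd tails): bridge from
  # neighbours so the window stays row-contiguous
  for (r in seq_len(n)) {
    if (is.na(lo[r])) { lo[r] <- lo[r - 1]; hi[r] <- hi[r - 1] }
  }
  # widen by `radius` rows in each direction ...
  if (radius > 0) {
    lo_w <- lo; hi_w <- hi
    for (s in seq_len(radius)) {
      lo_w <- pmin(lo_w, c(lo[-seq_len(s)], rep(lo[n], s)),
                   c(rep(lo[1], s), lo[seq_len(n - s)]))
      hi_w <- pmax(hi_w, c(hi[-seq_len(s)], rep(hi[n], s)),
                   c(rep(hi[1], s), hi[seq_len(n - s)]))
    }
    # ... and by `radius` columns
    lo <- pmax(lo_w - radius, 1L)
    hi <- pmin(hi_w + radius, m)
  }
  lo[1] <- 1L
  hi[n] <- m
  # enforce monotone, overlapping row windows so the DP can always connect
  for (r in 2:n) {
    if (r <= n) {
      if (lo[r] > hi[r - 1]) lo[r] <- hi[r - 1]
      if (hi[r] < hi[r - 1]) hi[r] <- hi[r - 1]
    }
  }
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' FastDTW: multilevel approximate dynamic time warping
#'
#' Recursively coarsens both sequences by averaging adjacent pairs, solves the
#' coarse problem, projects the coarse path up one resolution, widens it by
#' `radius` cells in every direction and runs the windowed dynamic program on
#' the fine grid. The approximation cost is always >= the exact DTW cost, with
#' equality guaranteed once `radius >= max(length(a), length(b))`.
#'
#' @inheritParams dtw_exact
#' @param radius Refinement half-width (cells); default 30.
#' @return A `dtw_alignment` (see [dtw_exact()]).
#' @export
fastdtw <- function(a, b, radius = 30L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("empty input sequence")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("non-finite values")
  radius <- check_count(radius, "radius", min = 0L)
  res <- fastdtw_rec(a, b, radius)
  new_dtw_alignment(res, mode = "fast", radius = radius)
}

fastdtw_rec <- function(a, b, radius) {
  n <- length(a); m <- length(b)
  if (min(n, m) <= radius + 2) {
    return(dtw_window_cpp(a, b, rep(1L, n), rep(m, n)))
  }
  coarse <- fastdtw_rec(halve_series(a), halve_series(b), radius)
  win <- project_window(coarse$i, coarse$j, n, m, radius)
  dtw_window_cpp(a, b, win$lo, win$hi)
}

#' Normalised dissimilarity between two matrix profiles
#'
#' Aligns the two profile value sequences (which generally have different
#' lengths, since noise adds points) with FastDTW at the given radius, sums
#' the absolute matched differences along the warping path, and normalises by
#' dividing by the original series length `x1 = N` and the maximum value `y1`
#' of the original profile. Identical profiles score exactly 0; the measure is
#' deliberately asymmetric (the normaliser uses the original side only).
#'
#' @param mp_original `matrix_profile` of the clean series (the reference).
#' @param mp_corrupted `matrix_profile` of the corrupted series.
#' @param radius FastDTW radius; default 30.
#' @param mode `"fast"` (FastDTW, default) or `"exact"` (full DP).
#' @return A list of class `mp_dissimilarity` with fields `sum_abs_diffs`,
#'   `normalised`, `x1`, `x2`, `y1`, `y2`, `path_length`, `radius`, `mode`
#'   and the warping `path`.
#' @export
mp_dissimilarity <- function(mp_original, mp_corrupted, radius = 30L,
                             mode = c("fast", "exact")) {
  mode <- match.arg(mode)
  a <- mp_original$mp_value
  b <- mp_corrupted$mp_value
  if (is.null(a) || is.null(b) || length(a) == 0 || length(b) == 0) {
    abort("both matrix profiles must be non-empty")
  }
  x1 <- attr(mp_original, "source_length") %||% length(a)
  x2 <- attr(mp_corrupted, "source_length") %||% length(b)
  y1 <- max(a)
  y2 <- max(b)
  if (y1 <= 0) {
    abort("original profile has maximum 0: normalised dissimilarity undefined")
  }
  al <- if (mode == "fast") fastdtw(a, b, radius) else dtw_exact(a, b)
  structure(
    list(sum_abs_diffs = al$cost,
         normalised = al$cost / (x1 * y1),
         x1 = x1, x2 = x2, y1 = y1, y2 = y2,
         path_length = nrow(al$path),
         radius = if (mode == "fast") as.integer(radius) else NA_integer_,
         mode = mode,
         path = al$path),
    class = "mp_dissimilarity")
}

#' @export
print.mp_dissimilarity <- function(x, ...) {
  cat(sprintf(
    paste0("<mp_dissimilarity> sum |diff| = %.4g, normalised = %.4g\n",
           "  x1 = %d, x2 = %d, y1 = %.4g, y2 = %.4g (%s",
           "%s)\n"),
    x$sum_abs_diffs, x$normalised, x$x1, x$x2, x$y1, x$y2, x$mode,
    if (x$mode == "fast") sprintf(", radius %d", x$radius) else ""))
  invisible(x)
}

#' @export
tidy.mp_dissimilarity <- function(x, ...) x$path

#' @export
glance.mp_dissimilarity <- function(x, ...) {
  tibble::tibble(
    sum_abs_diffs = x$sum_abs_diffs, normalised = x$normalised,
    x1 = x$x1, x2 = x$x2, y1 = x$y1, y2 = x$y2,
    path_length = x$path_length, mode = x$mode, radius = x$radius)
}

#' Export a dissimilarity result as JSON
#'
#' Writes every scalar field of the result (not the warping path) with full
#' numeric precision.
#'
#' @param x An `mp_dissimilarity`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(x, path) {
  stopifnot(inherits(x, "mp_dissimilarity"))
  jsonlite::write_json(x[setdiff(names(x), "path")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
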