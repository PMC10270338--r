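#' z-normalised Euclidean distance between two equal-length windows
#'
#' Each window is shifted to mean zero and scaled to unit standard deviation
#' (population convention, dividing by the window length) before the ordinary
#' Euclidean distance is taken. The result is invariant under positive affine
#' transforms of either argument and bounded by `2 * sqrt(m)`.
#'
#' Degenerate windows: if both windows are constant the distance is 0; if
#' exactly one is constant it is `sqrt(m)`. This convention is shared by every
#' distance path in the package.
#'
#' @param a,b Numeric vectors of equal length `m >= 2`.
#' @return A single non-negative number.
#' @examples
#' z_normalised_distance(sin(1:8), 3 * sin(1:8) + 7) # 0: affine invariance
#' @export
z_normalised_distance <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  m <- length(a)
  if (m < 2) abort("window length must be at least 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("non-finite values")
  sa <- sqrt(max(mean(a^2) - mean(a)^2, 0))
  sb <- sqrt(max(mean(b^2) - mean(b)^2, 0))
  if (sa == 0 && sb == 0) return(0)
  if (sa == 0 || sb == 0) return(sqrt(m))
  za <- (a - mean(a)) / sa
  zb <- (b - mean(b)) / sb
  min(sqrt(sum((za - zb)^2)), 2 * sqrt(m))
}

# rolling window mean/sd (population sd) via compensated cumulative sums;
# series is centred first so the squares do not lose precision
roll_stats <- function(x, m) {
  xc <- x - mean(x)
  cs <- cumsum(c(0, xc))
  cs2 <- cumsum(c(0, xc^2))
  l <- length(x) - m + 1
  mu <- (cs[(m + 1):(length(x) + 1)] - cs[1:l]) / m
  v <- (cs2[(m + 1):(length(x) + 1)] - cs2[1:l]) / m - mu^2
  list(mu = mu, sigma = sqrt(pmax(v, 0)))
}

#' Distance profile of one query window against a whole series
#'
#' Computes the z-normalised Euclidean distance between the window starting at
#' `query_start` and every other window of the same length, using a
#' convolution-filter sliding dot product rather than a per-window loop.
#' Entries inside the exclusion zone of the query (|j - query_start| <=
#' `exclusion_radius`) are masked to `Inf`; pass `exclusion_radius = 0` to
#' keep the self-match (which is exactly 0).
#'
#' @param data Data frame with a `value` column, or numeric vector.
#' @param query_start 1-based start position of the query window.
#' @param window Window length `m` (2 <= m <= n).
#' @param exclusion_radius Half-width of the masked zone around the query.
#' @param value Tidy-select style column name when `data` is a data frame.
#' @return A tibble with columns `index` and `distance` (length n - m + 1).
#' @export
distance_profile <- function(data, query_start, window,
                             exclusion_radius = ceiling(window / 4),
                             value = NULL) {
  x <- series_values(data, value)
  n <- length(x)
  m <- check_count(window, "window", min = 2L)
  if (m > n) abort("`window` exceeds the series length")
  l <- n - m + 1L
  query_start <- check_count(query_start, "query_start", min = 1L)
  if (query_start > l) abort("`query_start` out of range (must be <= n - m + 1)")

  xc <- x - mean(x)
  q <- xc[query_start:(query_start + m - 1)]
  # stats::filter with the reversed query gives the sliding dot product:
  # out[i] = sum_k q[k] * xc[i - m + k], so window starting at s is out[s+m-1]
  qt <- stats::filter(xc, rev(q), method = "convolution", sides = 1)
  qt <- as.numeric(qt[m:n])

  rs <- roll_stats(x, m)
  mu <- rs$mu; sig <- rs$sigma
  i <- query_start
  d <- numeric(l)
  both_flat <- sig[i] == 0 & sig == 0
  one_flat <- xor(sig[i] == 0, sig == 0)
  ok <- !both_flat & !one_flat
  corr <- rep(0, l)
  corr[ok] <- (qt[ok] - m * mu[i] * mu[ok]) / (m * sig[i] * sig[ok])
  corr <- pmin(pmax(corr, -1), 1)
  d[ok] <- sqrt(2 * m * (1 - corr[ok]))
  d[both_flat] <- 0
  d[one_flat] <- sqrt(m)
  d[i] <- 0  # self-distance is identically zero
  if (exclusion_radius > 0) {
    d[abs(seq_len(l) - i) <= exclusion_radius] <- Inf
  }
  tibble::tibble(index = seq_len(l), distance = d)
}

#' Compute the exact matrix profile of a univariate series
#'
#' For every length-`window` subsequence, the z-normalised Euclidean distance
#' to its nearest neighbour elsewhere in the series (outside the exclusion
#' zone, which prevents trivial self-matches) together with that neighbour's
#' position. Low values mark motifs (repeated patterns); the maximum marks the
#' discord (the most anomalous subsequence).
#'
#' The implementation is an exact STOMP-style O(n^2) pass with recursively
#' updated sliding dot products, run in compiled code; it returns the same
#' values as the brute-force definition.
#'
#' @param data Data frame with a `value` column, or numeric vector, length n.
#' @param window Subsequence length `m`; the series must satisfy `n >= 2m` so
#'   every position has a candidate neighbour outside its exclusion zone.
#' @param exclusion_radius Positions with |i - j| <= this are never matched;
#'   default `ceiling(window / 4)`, the community convention.
#' @param value Column name when `data` is a data frame.
#' @param label Optional free-text label carried into reports.
#' @return A tibble of class `matrix_profile` with columns `index`,
#'   `mp_value`, `nn_index` and n - m + 1 rows; attributes `window`,
#'   `exclusion_radius`, `source_length` and `label`.
#' @examples
#' mp <- matrix_profile(sin(seq(0, 20 * pi, length.out = 400)), window = 16)
#' glance(mp)
#' @export
matrix_profile <- function(data, window,
                           exclusion_radius = ceiling(window / 4),
                           value = NULL, label = NULL) {
  x <- series_values(data, value)
  n <- length(x)
  m <- check_count(window, "window", min = 2L)
  exclusion_radius <- check_count(exclusion_radius, "exclusion_radius", min = 1L)
  if (n < 2 * m) {
    abort(sprintf(
      "series too short for window %d: need n >= 2m, got n = %d", m, n))
  }
  res <- stomp_cpp(x - mean(x), m, exclusion_radius)
  out <- tibble::tibble(
    index = seq_len(n - m + 1L),
    mp_value = res$values,
    nn_index = res$indices
  )
  new_matrix_profile(out, window = m, exclusion_radius = exclusion_radius,
                     source_length = n, label = label)
}

new_matrix_profile <- function(df, window, exclusion_radius, source_length,
                               label = NULL) {
  structure(df,
            window = as.integer(window),
            exclusion_radius = as.integer(exclusion_radius),
            source_length = as.integer(source_length),
            label = label,
            class = c("matrix_profile", class(tibble::tibble())))
}

#' Summary statistics of a matrix profile
#'
#' Arithmetic mean, maximum and minimum of the profile values — the
#' descriptive columns used in the study report tables.
#'
#' @param mp A `matrix_profile`, or any data frame with an `mp_value` column.
#' @return A one-row tibble with columns `mean`, `max`, `min`.
#' @export
mp_summary <- function(mp) {
  v <- if (is.data.frame(mp)) mp$mp_value else as.numeric(mp)
  if (is.null(v) || length(v) == 0) abort("empty matrix profile")
  tibble::tibble(mean = mean(v), max = max(v), min = min(v))
}

#' Locate the top motif pair and the discord
#'
#' The motif pair is the position of the smallest profile value together with
#' its recorded nearest neighbour; the discord is the position of the largest
#' value. Ties are broken towards the lowest index.
#'
#' @param mp A `matrix_profile`.
#' @return A one-row tibble with columns `motif_a`, `motif_b`, `discord`.
#' @export
locate_motif_discord <- function(mp) {
  if (!is.data.frame(mp) || nrow(mp) == 0) abort("empty matrix profile")
  i <- which.min(mp$mp_value)
  tibble::tibble(
    motif_a = mp$index[i],
    motif_b = mp$nn_index[i],
    discord = mp$index[which.max(mp$mp_value)]
  )
}

#' @export
print.matrix_profile <- function(x, ...) {
  cat(sprintf(
    "<matrix_profile> n = %d, window = %d, exclusion radius = %d, %d values\n",
    attr(x, "source_length"), attr(x, "window"),
    attr(x, "exclusion_radius"), nrow(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname matrix_profile
#' @param x A `matrix_profile`.
#' @param ... Unused.
#' @export
tidy.matrix_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("index", "mp_value", "nn_index")])
}

#' @rdname matrix_profile
#' @export
glance.matrix_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      source_length = attr(x, "source_length"),
      window = attr(x, "window"),
      n_values = nrow(x)
    ),
    mp_summary(x),
    locate_motif_discord(x)
  )
}

#' @rdname matrix_profile
#' @param object A `matrix_profile`.
#' @export
autoplot.matrix_profile <- function(object, ...) {
  marks <- locate_motif_discord(object)
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$index, .data$mp_value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(marks$motif_a, marks$motif_b),
                        colour = "steelblue", linetype = 2) +
    ggplot2::geom_vline(xintercept = marks$discord,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(
      x = "subsequence start", y = "nearest-neighbour distance",
      title = sprintf("Matrix profile (m = %d)", attr(object, "window")),
      subtitle = "blue: motif pair, red: discord") +
    ggplot2::theme_minimal()
}

#' Read a series from CSV
#'
#' Accepts a single-column CSV of values (with or without a header) or a
#' two-column CSV of ISO-8601 timestamp and value.
#'
#' @param path CSV file path.
#' @return A tibble with a `value` column, plus `timestamp` when present.
#' @export
read_series <- function(path) {
  probe <- readr::read_csv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  two <- ncol(probe) >= 2
  has_header <- !any(vapply(probe[1, ], function(v)
    !is.na(suppressWarnings(as.numeric(v))), logical(1))[ncol(probe)])
  df <- readr::read_csv(path, col_names = has_header,
                        show_col_types = FALSE, progress = FALSE)
  if (two) {
    names(df)[1:2] <- c("timestamp", "value")
    ts <- suppressWarnings(readr::parse_datetime(as.character(df$timestamp)))
    if (!all(is.na(ts))) df$timestamp <- ts
    else df$timestamp <- as.numeric(df$timestamp)
  } else {
    names(df)[1] <- "value"
  }
  df$value <- as.numeric(df$value)
  df <- df[is.finite(df$value), , drop = FALSE]
  tibble::as_tibble(df)
}

#' Write a matrix profile to CSV
#'
#' Columns `index`, `mp_value`, `nn_index` (all indices 1-based).
#'
#' @param mp A `matrix_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(mp, path) {
  readr::write_csv(tidy(mp), path)
  invisible(path)
}
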