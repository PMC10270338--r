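#' Acceleration magnitude of a tri-axial accelerometer record
#'
#' Adds `a_mag = sqrt(accel_x^2 + accel_y^2 + accel_z^2)`, the
#' orientation-invariant movement signal used when a body-worn sensor can
#' rotate freely: any rotation of the component vector leaves it unchanged.
#'
#' @param data Data frame with numeric columns `accel_x`, `accel_y`,
#'   `accel_z` (a `timestamp` column, if present, is carried through).
#' @return `data` as a tibble with an `a_mag` column appended.
#' @examples
#' acceleration_magnitude(tibble::tibble(accel_x = 3, accel_y = 4, accel_z = 12))
#' @export
acceleration_magnitude <- function(data) {
  need <- c("accel_x", "accel_y", "accel_z")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns accel_x, accel_y, accel_z")
  }
  comp <- as.matrix(data[need])
  if (!all(is.finite(comp))) abort("non-finite acceleration components")
  dplyr::mutate(tibble::as_tibble(data),
                a_mag = sqrt(.data$accel_x^2 + .data$accel_y^2 + .data$accel_z^2))
}

#' Resample a timestamped series to fixed non-overlapping intervals
#'
#' Bins are anchored at the first timestamp and are `interval` wide; each bin
#' contributes one output value (its mean or sum). A partial trailing bin —
#' detected as the final bin holding fewer samples than `floor(interval /
#' median sampling step)` — is dropped. Interior empty bins are emitted as 0
#' for `agg = "sum"` and carry the previous bin's mean for `agg = "mean"`.
#'
#' @param data Data frame with non-decreasing `timestamp` (numeric seconds or
#'   POSIXct) and a value column.
#' @param interval Bin width in seconds (> 0).
#' @param agg `"mean"` or `"sum"`.
#' @param timestamp,value Column names; default `timestamp` / `value`.
#' @return A tibble with columns `timestamp` (bin start, seconds from the
#'   first sample) and `value`.
#' @export
resample_fixed_interval <- function(data, interval, agg = c("mean", "sum"),
                                    timestamp = "timestamp", value = NULL) {
  agg <- match.arg(agg)
  if (!is.numeric(interval) || length(interval) != 1 || interval <= 0) {
    abort("`interval` must be a single positive number")
  }
  if (!timestamp %in% names(data)) abort("`data` must have a timestamp column")
  t <- as.numeric(data[[timestamp]])
  x <- series_values(data[setdiff(names(data), timestamp)], value)
  if (length(t) != length(x)) abort("timestamp/value length mismatch")
  if (is.unsorted(t)) abort("timestamps must be non-decreasing")

  rel <- t - t[1]
  bin <- floor(rel / interval)
  counts <- tapply(x, bin, length)
  agg_fun <- if (agg == "mean") mean else sum
  vals <- tapply(x, bin, agg_fun)
  bins_present <- as.integer(names(vals))

  # drop a partial trailing bin: fewer samples than one full interval's worth
  if (length(t) > 1) {
    dt <- stats::median(diff(t))
    expected <- if (dt > 0) floor(interval / dt) else 1
    last <- length(bins_present)
    if (last > 1 && counts[last] < expected) {
      bins_present <- bins_present[-last]
      vals <- vals[-last]
    }
  }

  all_bins <- 0:max(bins_present)
  out <- rep(NA_real_, length(all_bins))
  out[bins_present + 1] <- vals
  if (anyNA(out)) {
    if (agg == "sum") {
      out[is.na(out)] <- 0
    } else {
      for (i in which(is.na(out))) out[i] <- out[i - 1]
    }
  }
  tibble::tibble(timestamp = all_bins * interval, value = as.numeric(out))
}

#' Synthetic inter-keystroke timing series
#'
#' Emulates the timing of one frequently typed bigram: positive inter-key
#' intervals in milliseconds, right-skewed (log-normal), truncated at 1,000 ms
#' (longer pauses are treated as typing breaks, not bigram timings). Optional
#' exact-copy timing patterns can be planted to give the profile a known
#' motif.
#'
#' @param n Series length; default 56,545 (the case-study size).
#' @param seed Integer seed; fully determines the series.
#' @param meanlog,sdlog Log-normal parameters of the base distribution
#'   (default `log(180)` ms and 0.45, a typical fluent-typist bigram).
#' @param max_ms Upper truncation bound; default 1,000 ms.
#' @param pattern_positions Optional integer start positions at which one
#'   shared pattern of `pattern_length` values is written (exact copies).
#' @param pattern_length Length of the planted pattern; default 20, the
#'   analysis window for this family.
#' @return A tibble with columns `index` and `value` (ms).
#' @export
gen_keystroke_like <- function(n = 56545, seed = 1L,
                               meanlog = log(180), sdlog = 0.45,
                               max_ms = 1000,
                               pattern_positions = NULL, pattern_length = 20) {
  n <- check_count(n, "n", min = 1L)
  withr::with_seed(seed, {
    x <- rlnorm(n, meanlog, sdlog)
    while (any(bad <- x > max_ms | x <= 0)) {
      x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    }
    if (!is.null(pattern_positions)) {
      if (any(pattern_positions < 1 |
              pattern_positions + pattern_length - 1 > n)) {
        abort("planted pattern falls outside the series")
      }
      pat <- rlnorm(pattern_length, meanlog, sdlog / 2)
      pat <- pmin(pat, max_ms)
      for (p in pattern_positions) x[p:(p + pattern_length - 1)] <- pat
    }
  })
  tibble::tibble(index = seq_len(n), value = x)
}

# one day of 12.5 Hz tri-axial accelerometer signal: a slowly rotating ~1 g
# gravity vector plus activity noise whose amplitude follows a 24 h cycle
calf_day_accel <- function(day, sample_rate, base_activity, circadian_amp,
                           noise_sd) {
  n <- round(86400 * sample_rate)
  t <- (day - 1) * 86400 + (seq_len(n) - 1) / sample_rate
  phase <- 2 * pi * (t %% 86400) / 86400
  # activity amplitude peaks mid-day, troughs at night
  amp <- base_activity + circadian_amp * (1 + sin(phase - pi / 2)) / 2
  theta <- 2 * pi * t / (3600 * 7)   # slow collar rotation, ~7 h period
  gx <- cos(theta) * 0.55
  gy <- sin(theta) * 0.55
  gz <- sqrt(pmax(1 - gx^2 - gy^2, 0))
  tibble::tibble(
    timestamp = t,
    accel_x = gx + rnorm(n, sd = amp + noise_sd),
    accel_y = gy + rnorm(n, sd = amp + noise_sd),
    accel_z = gz + rnorm(n, sd = amp + noise_sd))
}

#' Synthetic calf accelerometer series (1-minute mean magnitude)
#'
#' Emulates a neck-worn 12.5 Hz tri-axial accelerometer on a young calf: a ~1 g
#' gravity component that rotates slowly as the collar turns, plus activity
#' noise whose amplitude follows the animal's 24-hour circadian rhythm. The
#' raw tri-axial trace is mapped through [acceleration_magnitude()] and
#' resampled to one-minute means with [resample_fixed_interval()], exactly the
#' preprocessing used for real collar data, giving 1,440 points per day
#' (60,480 for the default 42 days). Generation is chunked one day at a time
#' so the full-scale default stays within ordinary memory.
#'
#' @param days Number of whole days (>= 1); default 42.
#' @param seed Integer seed.
#' @param sample_rate Raw sampling rate in Hz; default 12.5.
#' @param base_activity,circadian_amp,noise_sd Activity amplitude floor, the
#'   peak-to-trough circadian swing added to it, and orientation sensor noise
#'   (g units); defaults 0.05, 0.35, 0.02.
#' @param raw If `TRUE`, return the 12.5 Hz tri-axial tibble (`timestamp`,
#'   `accel_x`, `accel_y`, `accel_z`) instead of the resampled magnitude;
#'   only allowed for `days <= 2` to bound memory.
#' @return A tibble with `timestamp` (seconds) and `value` (g), one row per
#'   minute; or the raw tri-axial tibble when `raw = TRUE`.
#' @export
gen_calf_like <- function(days = 42, seed = 1L, sample_rate = 12.5,
                          base_activity = 0.05, circadian_amp = 0.35,
                          noise_sd = 0.02, raw = FALSE) {
  days <- check_count(days, "days", min = 1L)
  if (raw && days > 2) abort("`raw = TRUE` is limited to days <= 2")
  withr::with_seed(seed, {
    chunks <- lapply(seq_len(days), function(day) {
      acc <- calf_day_accel(day, sample_rate, base_activity, circadian_amp,
                            noise_sd)
      if (raw) return(acc)
      res <- resample_fixed_interval(
        acceleration_magnitude(acc)[c("timestamp", "a_mag")],
        interval = 60, agg = "mean", value = "a_mag")
      res$timestamp <- res$timestamp + (day - 1) * 86400
      res
    })
  })
  dplyr::bind_rows(chunks)
}

#' Synthetic hourly city-traffic volume series
#'
#' Emulates aggregated hourly vehicle counts for a city centre: a double-peak
#' (commuter) daily profile, weekend damping, Poisson count noise, and
#' optionally a few anomalous low-volume days (e.g. closures) that a matrix
#' profile should flag as discords.
#'
#' @param n Number of hourly points (>= 48); default 3,600 (150 days).
#' @param seed Integer seed.
#' @param daily_peak Mean count at the weekday evening peak; default 2,000.
#' @param n_anomalous_days Number of anomalous days; default 1.
#' @param anomaly_scale Multiplier applied to anomalous days; default 0.35.
#' @return A tibble with columns `hour` (0-based), `value` and attribute
#'   `anomalous_days` (1-based day numbers).
#' @export
gen_traffic_like <- function(n = 3600, seed = 1L, daily_peak = 2000,
                             n_anomalous_days = 1, anomaly_scale = 0.35) {
  n <- check_count(n, "n", min = 48L)
  hour <- 0:(n - 1)
  hod <- hour %% 24
  day <- hour %/% 24
  # commuter double peak at 08:00 and 17:30 over a small night-time base
  profile <- 0.08 +
    0.85 * exp(-((hod - 8)^2) / (2 * 1.8^2)) +
    exp(-((hod - 17.5)^2) / (2 * 2.2^2))
  weekend <- (day %% 7) %in% c(5, 6)
  lambda <- daily_peak * profile * ifelse(weekend, 0.7, 1)
  n_days <- ceiling(n / 24)
  withr::with_seed(seed, {
    anom <- if (n_anomalous_days > 0) {
      sort(sample.int(n_days, min(n_anomalous_days, n_days)))
    } else integer(0)
    lambda[day %in% (anom - 1)] <- lambda[day %in% (anom - 1)] * anomaly_scale
    x <- rpois(n, lambda)
  })
  structure(tibble::tibble(hour = hour, value = as.numeric(x)),
            anomalous_days = anom)
}

#' Quasi-periodic background with planted motif pairs and discords
#'
#' Generates a unit-amplitude sinusoidal background (period `2.5 * window`)
#' with additive Gaussian noise and plants ground truth into it: motif pairs
#' are two exact copies of one smooth random-walk window (their z-normalised
#' distance is exactly 0, so they pin the profile minimum), discords are one
#' window of out-of-distribution rough noise (every other window has a close
#' match one background period away, the discord does not, so it pins the
#' maximum). Plant positions are drawn so windows never overlap and sit
#' outside each other's exclusion zones.
#'
#' A structured background is essential here: in pure i.i.d. noise the
#' nearest-neighbour distance of *any* planted window has the same
#' distribution as the background windows' (z-normalised correlation against
#' noise is shape-independent), so a discord plant would not be recoverable.
#'
#' @param n Series length.
#' @param window Plant (and intended analysis) window length.
#' @param n_motif_pairs,n_discords How many motif pairs / discord windows.
#' @param noise_sd Background additive noise standard deviation relative to
#'   the unit-amplitude background; default 0.1.
#' @param seed Integer seed.
#' @return A list with `series` (tibble with `value`) and `plants` (tibble
#'   with `kind`, `position`, `length`; motif rows share a `pair` id).
#' @export
gen_planted <- function(n = 500, window = 16, n_motif_pairs = 1,
                        n_discords = 1, noise_sd = 0.1, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  m <- check_count(window, "window", min = 2L)
  n_plants <- 2 * n_motif_pairs + n_discords
  if (n_plants * (2 * m) > n) abort("plants do not fit in the series")
  withr::with_seed(seed, {
    t <- seq_len(n)
    phase <- runif(1, 0, 2 * pi)
    x <- sin(2 * pi * t / (2.5 * m) + phase) + rnorm(n, sd = noise_sd)
    # draw non-overlapping starts separated by >= 2m (outside exclusion zones)
    starts <- integer(0)
    tries <- 0
    while (length(starts) < n_plants) {
      cand <- sample.int(n - m + 1, 1)
      if (all(abs(cand - starts) >= 2 * m)) starts <- c(starts, cand)
      tries <- tries + 1
      if (tries > 10000) abort("could not place non-overlapping plants")
    }
    plants <- tibble::tibble(kind = character(0), position = integer(0),
                             length = integer(0), pair = integer(0))
    s_idx <- 1
    for (p in seq_len(n_motif_pairs)) {
      pat <- cumsum(rnorm(m))
      pat <- 1.2 * (pat - mean(pat)) / max(sd(pat), 1e-12)
      for (copy in 1:2) {
        pos <- starts[s_idx]; s_idx <- s_idx + 1
        x[pos:(pos + m - 1)] <- pat
        plants <- dplyr::bind_rows(plants, tibble::tibble(
          kind = "motif", position = pos, length = m, pair = p))
      }
    }
    for (d in seq_len(n_discords)) {
      pos <- starts[s_idx]; s_idx <- s_idx + 1
      x[pos:(pos + m - 1)] <- rnorm(m, sd = 2)
      plants <- dplyr::bind_rows(plants, tibble::tibble(
        kind = "discord", position = pos, length = m, pair = NA_integer_))
    }
  })
  list(series = tibble::tibble(value = x), plants = plants)
}
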