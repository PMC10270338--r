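test_that("acceleration magnitude is the Euclidean norm and rotation-invariant", {
  df <- tibble::tibble(accel_x = c(3, 0, 1), accel_y = c(4, 0, 1),
                       accel_z = c(12, 0, 1))
  out <- acceleration_magnitude(df)
  expect_equal(out$a_mag, c(13, 0, sqrt(3)))

  withr::with_seed(1, {
    v <- rnorm(3)
    theta <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
    vr <- as.numeric(R %*% v)
  })
  m1 <- acceleration_magnitude(tibble::tibble(
    accel_x = v[1], accel_y = v[2], accel_z = v[3]))$a_mag
  m2 <- acceleration_magnitude(tibble::tibble(
    accel_x = vr[1], accel_y = vr[2], accel_z = vr[3]))$a_mag
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_error(acceleration_magnitude(tibble::tibble(accel_x = 1)), "columns")
  expect_error(acceleration_magnitude(tibble::tibble(
    accel_x = NA_real_, accel_y = 1, accel_z = 1)), "non-finite")
})

test_that("fixed-interval resampling: bins, aggregation and trailing-bin rule", {
  # constant 2.0 at 12.5 Hz for two minutes -> two one-minute means
  ts2 <- tibble::tibble(timestamp = seq(0, by = 0.08, length.out = 1500),
                        value = 2)
  expect_equal(resample_fixed_interval(ts2, 60, "mean")$value, c(2, 2))

  # exactly one minute at 12.5 Hz -> a single bin of 750 samples
  ts1 <- tibble::tibble(timestamp = seq(0, by = 0.08, length.out = 750),
                        value = rnorm(750))
  r1 <- resample_fixed_interval(ts1, 60, "mean")
  expect_equal(nrow(r1), 1)
  expect_equal(r1$value, mean(ts1$value))

  # one value per minute for 42 days -> 60,480 points
  nmin <- 42 * 1440
  tsd <- tibble::tibble(timestamp = 60 * (0:(nmin - 1)), value = 1)
  expect_equal(nrow(resample_fixed_interval(tsd, 60, "mean")), 60480)

  # a partial trailing bin is dropped
  ts3 <- tibble::tibble(timestamp = seq(0, by = 0.08, length.out = 1875),
                        value = 1)  # 2.5 minutes
  expect_equal(nrow(resample_fixed_interval(ts3, 60, "mean")), 2)

  # piecewise-constant round trip is exact; sums add
  tspc <- tibble::tibble(timestamp = 0:599,
                         value = rep(c(5, -1, 3, 8, 0), each = 120))
  expect_equal(resample_fixed_interval(tspc, 120, "mean")$value,
               c(5, -1, 3, 8, 0))
  expect_equal(resample_fixed_interval(tspc, 120, "sum")$value,
               120 * c(5, -1, 3, 8, 0))

  # interior empty bins: zero for sums, carried mean for means
  gap <- tibble::tibble(timestamp = c(0:9, 30:39), value = c(rep(2, 10), rep(4, 10)))
  expect_equal(resample_fixed_interval(gap, 10, "sum")$value, c(20, 0, 0, 40))
  expect_equal(resample_fixed_interval(gap, 10, "mean")$value, c(2, 2, 2, 4))

  expect_error(resample_fixed_interval(ts1, 0), "positive")
  expect_error(resample_fixed_interval(
    tibble::tibble(timestamp = c(3, 1, 2), value = 1:3), 1), "non-decreasing")
})

test_that("keystroke-like series: bounds, determinism, planted timing motif", {
  ks <- gen_keystroke_like(n = 4000, seed = 3)
  expect_equal(nrow(ks), 4000)
  expect_true(all(ks$value > 0 & ks$value <= 1000))
  expect_identical(gen_keystroke_like(n = 4000, seed = 3), ks)
  expect_false(identical(gen_keystroke_like(n = 4000, seed = 4)$value, ks$value))

  kp <- gen_keystroke_like(n = 2000, seed = 5,
                           pattern_positions = c(300, 1500))
  mp <- matrix_profile(kp, 20)
  loc <- locate_motif_discord(mp)
  expect_lte(min(abs(loc$motif_a - c(300, 1500))), 20)
  expect_lte(min(abs(loc$motif_b - c(300, 1500))), 20)
})

test_that("calf-like series: per-day length, non-negativity, circadian lag", {
  calf <- gen_calf_like(days = 4, seed = 2)
  expect_equal(nrow(calf), 4 * 1440)
  expect_true(all(calf$value >= 0))
  expect_identical(gen_calf_like(days = 4, seed = 2), calf)

  a <- stats::acf(calf$value, lag.max = 1440, plot = FALSE)$acf
  expect_gt(a[1441], a[721])  # 24 h peak above the 12 h trough

  raw <- gen_calf_like(days = 1, seed = 2, raw = TRUE)
  expect_named(raw, c("timestamp", "accel_x", "accel_y", "accel_z"))
  expect_equal(nrow(raw), 12.5 * 86400)
  expect_error(gen_calf_like(days = 3, raw = TRUE), "days <= 2")
})

test_that("the 42-day calf default reproduces the case-study length", {
  calf <- gen_calf_like(days = 42, seed = 7)
  expect_equal(nrow(calf), 60480)
})

test_that("traffic-like series: length, counts, daily structure, planted anomaly", {
  tr <- gen_traffic_like(seed = 4)
  expect_equal(nrow(tr), 3600)
  expect_true(all(tr$value >= 0 & tr$value == round(tr$value)))
  expect_identical(gen_traffic_like(seed = 4)$value, tr$value)

  # daily periodicity: lag-24 autocorrelation dominates neighbouring lags
  a <- stats::acf(tr$value, lag.max = 30, plot = FALSE)$acf
  expect_gt(a[25], a[13])

  mp <- matrix_profile(tr, 24)
  loc <- locate_motif_discord(mp)
  plant_start <- (attr(tr, "anomalous_days") - 1) * 24 + 1
  expect_lte(abs(loc$discord - plant_start), 24)
  expect_error(gen_traffic_like(n = 24), ">= 48")
})

test_that("planted generator honours its ground-truth contract", {
  g <- gen_planted(n = 400, window = 16, seed = 9)
  expect_equal(nrow(g$series), 400)
  expect_equal(nrow(g$plants), 3)  # one motif pair + one discord
  starts <- g$plants$position
  expect_true(all(diff(sort(starts)) >= 2 * 16))  # non-overlap, exclusion-safe
  # motif copies are exact
  mpos <- g$plants$position[g$plants$kind == "motif"]
  expect_identical(g$series$value[mpos[1]:(mpos[1] + 15)],
                   g$series$value[mpos[2]:(mpos[2] + 15)])

  g0 <- gen_planted(n = 300, window = 8, n_motif_pairs = 0, n_discords = 0,
                    seed = 1)
  expect_equal(nrow(g0$plants), 0)
  expect_error(gen_planted(n = 50, window = 16), "do not fit")
})
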