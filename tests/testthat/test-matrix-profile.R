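test_that("z-normalised distance: identity, affine invariance, direct formula", {
  withr::with_seed(11, {
    a <- rnorm(12)
    expect_equal(z_normalised_distance(a, a), 0)
    expect_equal(z_normalised_distance(a, 3 * a + 7), 0, tolerance = 1e-12)

    for (k in 1:10) {
      p <- rnorm(4); q <- rnorm(4)
      expect_equal(z_normalised_distance(p, q), oracle_zdist(p, q),
                   tolerance = 1e-12)
    }
  })
  expect_error(z_normalised_distance(1:3, 1:4), "equal length")
  expect_error(z_normalised_distance(1, 2), "at least 2")
})

test_that("z-normalised distance degenerate-window convention", {
  m <- 8
  expect_equal(z_normalised_distance(rep(2, m), rep(-5, m)), 0)
  expect_equal(z_normalised_distance(rep(2, m), rnorm(m)), sqrt(m))
  expect_equal(z_normalised_distance(rnorm(m), rep(0, m)), sqrt(m))
})

test_that("distance profile has length n - m + 1 and matches the naive loop", {
  withr::with_seed(21, x <- rnorm(128))
  dp <- distance_profile(x, query_start = 1, window = 20,
                         exclusion_radius = 0)
  expect_equal(nrow(distance_profile(rnorm(100), 5, 20)), 81)
  expect_equal(dp$distance[1], 0)  # unmasked self-distance

  m <- 9
  dp2 <- distance_profile(x, query_start = 40, window = m,
                          exclusion_radius = 0)
  naive <- vapply(seq_len(128 - m + 1), function(j)
    oracle_zdist(x[40:(40 + m - 1)], x[j:(j + m - 1)]), numeric(1))
  expect_lt(max(abs(dp2$distance - naive)), 1e-8)

  dp3 <- distance_profile(x, query_start = 40, window = m,
                          exclusion_radius = 3)
  expect_true(all(is.infinite(dp3$distance[abs(dp3$index - 40) <= 3])))
  expect_error(distance_profile(x, query_start = 125, window = 9),
               "out of range")
})

test_that("matrix profile equals the brute-force definition", {
  withr::with_seed(31, {
    for (k in 1:10) {
      n <- sample(64:200, 1)
      m <- sample(4:16, 1)
      x <- rnorm(n)
      mp <- matrix_profile(x, m)
      o <- oracle_mp(x, m)
      expect_lt(max(abs(mp$mp_value - o$values)), 1e-8)
      expect_equal(mp$nn_index, o$indices)
    }
  })
})

test_that("matrix profile length, bounds and exclusion invariants", {
  withr::with_seed(41, x <- rnorm(100))
  mp <- matrix_profile(x, 20)
  expect_s3_class(mp, "matrix_profile")
  expect_equal(nrow(mp), 81)  # n - m + 1
  expect_true(all(mp$mp_value >= 0 & mp$mp_value <= 2 * sqrt(20)))
  expect_true(all(abs(mp$index - mp$nn_index) > attr(mp, "exclusion_radius")))

  for (m in c(4, 8, 13)) {
    mp <- matrix_profile(x, m)
    expect_equal(nrow(mp), 100 - m + 1)
    expect_true(all(mp$mp_value <= 2 * sqrt(m) + 1e-12))
  }
})

test_that("strictly periodic series yields a near-zero profile", {
  withr::with_seed(51, pat <- rnorm(20))
  x <- rep(pat, 10)  # n = 200, period 20
  mp <- matrix_profile(x, 16)
  expect_lt(max(mp$mp_value), 1e-6)
})

test_that("short or non-finite series are refused", {
  expect_error(matrix_profile(rnorm(30), 20), "too short")
  expect_error(matrix_profile(c(rnorm(50), NA), 10), "non-finite")
})

test_that("planted exact pair pins the profile minimum at both copies", {
  m <- 12
  x <- planted_pair_series(n = 300, m = m, pos1 = 40, pos2 = 220, seed = 61)
  mp <- matrix_profile(x, m)
  others <- mp$mp_value[-c(40, 220)]
  expect_lt(mp$mp_value[40], min(others))
  expect_lt(mp$mp_value[220], min(others))
  expect_equal(mp$nn_index[40], 220)
})

test_that("summary and motif/discord location follow argmin/argmax with low-index ties", {
  mp <- structure(
    tibble::tibble(index = 1:4, mp_value = c(5, 1, 7, 1),
                   nn_index = c(3L, 4L, 1L, 2L)),
    class = c("matrix_profile", class(tibble::tibble())))
  s <- mp_summary(mp)
  expect_equal(s$mean, 3.5)
  expect_equal(s$max, 7)
  expect_equal(s$min, 1)
  loc <- locate_motif_discord(mp)
  expect_equal(loc$motif_a, 2)
  expect_equal(loc$motif_b, 4)
  expect_equal(loc$discord, 3)

  const <- structure(
    tibble::tibble(index = 1:3, mp_value = rep(2.5, 3), nn_index = c(3L, 3L, 1L)),
    class = class(mp))
  locc <- locate_motif_discord(const)
  expect_equal(locc$motif_a, 1)
  expect_equal(locc$motif_b, 3)
  expect_equal(locc$discord, 1)
  sc <- mp_summary(const)
  expect_true(sc$mean == 2.5 && sc$max == 2.5 && sc$min == 2.5)
})

test_that("series CSV round trip and profile export", {
  withr::with_seed(71, x <- rnorm(120))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(value = x), f)
  rd <- read_series(f)
  expect_equal(rd$value, x)

  f1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(as.character(x), f1)  # headerless single column
  expect_equal(read_series(f1)$value, x)

  mp <- matrix_profile(x, 10)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_profile(mp, fp)
  back <- readr::read_csv(fp, show_col_types = FALSE)
  expect_equal(names(back), c("index", "mp_value", "nn_index"))
  expect_equal(back$mp_value, mp$mp_value)
})

test_that("tidy/glance expose values and summary of a profile", {
  withr::with_seed(81, x <- rnorm(90))
  mp <- matrix_profile(x, 9)
  td <- tidy(mp)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("index", "mp_value", "nn_index"))
  g <- glance(mp)
  expect_equal(g$source_length, 90)
  expect_equal(g$window, 9)
  expect_equal(g$n_values, 82)
  expect_equal(g$min, min(mp$mp_value))
})
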