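# Independent oracles: direct-definition implementations kept deliberately
# separate from the package's fast paths (no sliding dot products, no
# windowed DP reuse).

# z-normalise one window (population sd); NA signals a flat window
oracle_znorm <- function(w) {
  s <- sqrt(max(mean(w^2) - mean(w)^2, 0))
  if (s == 0) return(rep(NA_real_, length(w)))
  (w - mean(w)) / s
}

oracle_zdist <- function(a, b) {
  za <- oracle_znorm(a); zb <- oracle_znorm(b)
  if (anyNA(za) && anyNA(zb)) return(0)
  if (anyNA(za) || anyNA(zb)) return(sqrt(length(a)))
  sqrt(sum((za - zb)^2))
}

# brute-force matrix profile straight from the definition: z-normalise every
# window, then per-query minimise the direct Euclidean distance
oracle_mp <- function(x, m, excl = ceiling(m / 4)) {
  n <- length(x)
  l <- n - m + 1
  Z <- t(vapply(seq_len(l), function(i) oracle_znorm(x[i:(i + m - 1)]),
                numeric(m)))
  flat <- apply(is.na(Z), 1, any)
  vals <- numeric(l)
  idx <- integer(l)
  for (i in seq_len(l)) {
    d <- rep(Inf, l)
    for (j in seq_len(l)) {
      if (abs(i - j) <= excl) next
      d[j] <- if (flat[i] && flat[j]) 0
      else if (flat[i] || flat[j]) sqrt(m)
      else sqrt(sum((Z[i, ] - Z[j, ])^2))
    }
    vals[i] <- min(d)
    idx[i] <- which.min(d)
  }
  list(values = vals, indices = idx)
}

# plain full-table DTW dynamic program (cost only), |a_i - b_j| local cost
oracle_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# iid-noise series with an exact-copy window pair planted at two positions
planted_pair_series <- function(n, m, pos1, pos2, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    pat <- rnorm(m)
    x[pos1:(pos1 + m - 1)] <- pat
    x[pos2:(pos2 + m - 1)] <- pat
  })
  x
}
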