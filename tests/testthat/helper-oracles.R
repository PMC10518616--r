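# Independent brute-force oracles used to validate the package's vectorized
# implementations. These deliberately share no code with R/.

naive_minmax <- function(x) {
  lo <- min(x); hi <- max(x)
  out <- x
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      out[i, j] <- (x[i, j] - lo) / (hi - lo)
  out
}

# 2-D correlation with a 3x3 kernel and symmetric (edge-replicating) padding
naive_correlate3 <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w))
      for (di in -1:1)
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          out[i, j] <- out[i, j] + k[di + 2, dj + 2] * x[ii, jj]
        }
  out
}

naive_histogram <- function(x, L) {
  counts <- numeric(L)
  for (v in as.vector(x)) {
    lev <- min(floor(v * L), L - 1)
    counts[lev + 1] <- counts[lev + 1] + 1
  }
  counts
}

# classical single-threshold Otsu by direct per-threshold class statistics
naive_otsu1 <- function(counts) {
  L <- length(counts)
  total <- sum(counts)
  lev <- 0:(L - 1)
  mu <- sum(counts * lev) / total
  best_t <- NA
  best_f <- -Inf
  for (t in 1:(L - 1)) {
    c0 <- counts[1:t]; c1 <- counts[(t + 1):L]
    w0 <- sum(c0) / total; w1 <- sum(c1) / total
    f <- 0
    if (w0 > 0) f <- f + w0 * (sum(c0 * lev[1:t]) / sum(c0) - mu)^2
    if (w1 > 0) f <- f + w1 * (sum(c1 * lev[(t + 1):L]) / sum(c1) - mu)^2
    if (f > best_f) { best_f <- f; best_t <- t }
  }
  list(t = best_t, f = best_f)
}

# LBP code by direct neighbor enumeration (east start, counter-clockwise,
# bilinear off-grid sampling); ties s >= 0 count as 1
naive_lbp_code <- function(x, row, col, n = 8, radius = 1) {
  qd <- x[row, col]
  code <- 0
  for (t in 0:(n - 1)) {
    theta <- 2 * pi * t / n
    rr <- row - radius * sin(theta)
    cc <- col + radius * cos(theta)
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    qt <- x[r0, c0] * (1 - fr) * (1 - fc) +
      x[min(r0 + 1, nrow(x)), c0] * fr * (1 - fc) +
      x[r0, min(c0 + 1, ncol(x))] * (1 - fr) * fc +
      x[min(r0 + 1, nrow(x)), min(c0 + 1, ncol(x))] * fr * fc
    if (qt - qd >= 0) code <- code + 2^t
  }
  code
}

naive_maxpool <- function(x) {
  ho <- nrow(x) / 2; wo <- ncol(x) / 2
  y <- matrix(0, ho, wo)
  idx <- matrix(0L, ho, wo)
  for (i in seq_len(ho))
    for (j in seq_len(wo)) {
      win <- c(x[2 * i - 1, 2 * j - 1], x[2 * i - 1, 2 * j],
               x[2 * i, 2 * j - 1], x[2 * i, 2 * j])  # row-major window order
      y[i, j] <- max(win)
      idx[i, j] <- which.max(win) - 1L
    }
  list(y = y, idx = idx)
}

# discrete disk pixel count by direct enumeration
naive_disk_area <- function(radius) {
  n <- 0
  for (dr in -ceiling(radius):ceiling(radius))
    for (dc in -ceiling(radius):ceiling(radius))
      if (dr^2 + dc^2 <= radius^2) n <- n + 1
  n
}

# left-rotate the low `n` bits of `code` by `s` positions
bit_rotl <- function(code, s, n = 8) {
  ((code * 2^s) %% 2^n) + (code %/% 2^(n - s))
}

# standard phantom set fixtures
tiny_phantom_spec <- function(noise = 0, seed = 1) {
  phantom_spec(height = 32, width = 32, nodule_radius_range = c(2, 4),
               noise_sigma = noise, seed = seed)
}
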