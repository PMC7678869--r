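# Independent oracles used across the test files.

# brute-force projector: rasterise each pixel into sub x sub point masses and
# bin them onto the rotated detector
subpixel_project <- function(img, angle, sub = 16L) {
  n <- nrow(img)
  th <- angle * pi / 180
  proj <- numeric(n)
  for (ix in seq_len(n)) {
    for (iz in seq_len(n)) {
      v <- img[iz, ix]
      if (v == 0) next
      for (sx in seq_len(sub)) {
        for (sz in seq_len(sub)) {
          x <- (ix - 1) + (sx - 0.5) / sub - n / 2
          z <- (iz - 1) + (sz - 0.5) / sub - n / 2
          t0 <- floor(x * cos(th) + z * sin(th) + n / 2) + 1
          if (t0 >= 1 && t0 <= n) proj[t0] <- proj[t0] + v / sub^2
        }
      }
    }
  }
  proj
}

# explicit system matrix: rows = (bin, angle) pairs, columns = pixels in
# R column-major order; built from the projector one unit image at a time
system_matrix <- function(n, angles) {
  A <- matrix(0, n * length(angles), n * n)
  for (k in seq_len(n * n)) {
    e <- matrix(0, n, n)
    e[k] <- 1
    A[, k] <- as.vector(forward_project(e, angles, drop = FALSE))
  }
  A
}

# image supported inside the inscribed circle (fully in view at every tilt)
disc_image <- function(n, seed = 1) {
  set.seed(seed)
  img <- matrix(0, n, n)
  ctr <- n / 2 + 0.5
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - ctr)^2 + (j - ctr)^2 < (0.45 * n)^2) img[i, j] <- runif(1)
    }
  }
  img
}

# rss of a counts arrangement against a series, via the public projector
arrangement_rss <- function(counts, q, series) {
  sum((forward_project(counts * q, series$angles, drop = FALSE) -
         series$projections)^2)
}
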