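test_that("binary phantom is deterministic, binary and geometrically sound", {
  p1 <- phantom_binary(64)
  p2 <- phantom_binary(64)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% c(0, 1)))
  expect_gt(sum(p1), 0)

  # annulus hole interior is empty, ring interior is filled (radial oracle;
  # reference layout: centre (-0.17, -0.08), radii 0.115/0.21 of the side)
  n <- 64
  u <- (seq_len(n) - 0.5) / n - 0.5
  r <- sqrt(outer(u + 0.08, u + 0.17, function(z, x) x^2 + z^2))
  expect_true(all(p1[r < 0.10] == 0))
  expect_true(all(p1[r > 0.125 & r < 0.20] == 1))
  # everything inside the inscribed circle (fully in view at any tilt)
  rad <- sqrt(outer(u, u, function(z, x) x^2 + z^2))
  expect_true(all(p1[rad > 0.5] == 0))
})

test_that("general phantom peaks at 255 with a monotone interior gradient", {
  g <- phantom_general(64)
  expect_identical(g, phantom_general(64))
  expect_equal(max(g), 255)
  expect_true(all(g >= 0))

  # interior of the rectangle brightens monotonically towards low z (scan a
  # column strip away from holes, inside the edge anti-aliasing margin)
  n <- 64
  col <- round((0.20 + 0.5) * n)
  rows <- seq(ceiling((-0.27 + 0.5) * n) + 1, floor((0.24 + 0.5) * n) - 1)
  prof <- g[rows, col]
  expect_true(all(diff(prof) <= 1e-9))

  u <- (seq_len(n) - 0.5) / n - 0.5
  rad <- sqrt(outer(u, u, function(z, x) x^2 + z^2))
  expect_true(all(g[rad > 0.5] == 0))
})

test_that("tilt series simulation conserves mass and reproduces Poisson noise", {
  expect_equal(simulate_tilt_series(matrix(0, 16, 16), c(-30, 0, 30))$projections,
               matrix(0, 16, 3))

  model <- phantom_binary(32)
  ts <- simulate_tilt_series(model, tilt_angles(60, 10))
  expect_s3_class(ts, "tilt_series")
  expect_lt(max(abs(colSums(ts$projections) - sum(model))) / sum(model), 1e-9)

  # Poisson draws: per-bin mean over repeats within 3 standard errors
  scale <- 1e4
  reps <- 100
  acc <- matrix(0, 32, length(ts$angles))
  for (r in seq_len(reps)) {
    acc <- acc + simulate_tilt_series(model, ts$angles, noise = "poisson",
                                      scale = scale, seed = 1000 + r)$projections
  }
  mu <- acc / reps
  se <- sqrt(ts$projections / (scale * reps))
  busy <- ts$projections > 1
  z <- abs(mu - ts$projections)[busy] / se[busy]
  # per-bin means are unbiased: z-scores look standard normal across the
  # ~hundreds of bins (3-sigma per bin, allowing the expected extremes)
  expect_lt(mean(z), 1.3)
  expect_lt(stats::quantile(z, 0.95), 3)
  expect_lt(max(z), 5)

  # seeded draws are reproducible and leave the caller's RNG untouched
  set.seed(99); before <- .Random.seed
  s1 <- simulate_tilt_series(model, 0, noise = "poisson", scale = 10, seed = 5)
  expect_identical(before, .Random.seed)
  s2 <- simulate_tilt_series(model, 0, noise = "poisson", scale = 10, seed = 5)
  expect_identical(s1$projections, s2$projections)

  expect_error(simulate_tilt_series(matrix(-1, 4, 4), 0), "non-negative")
})
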