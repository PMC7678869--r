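test_that("forward projection: axis-aligned sums, zeros, mass conservation", {
  expect_equal(forward_project(matrix(0, 8, 8), 37), numeric(8))
  expect_equal(forward_project(rbind(c(1, 0), c(2, 3)), 0), c(3, 3))
  expect_equal(forward_project(rbind(c(1, 0), c(2, 3)), 90), c(1, 5))

  img <- disc_image(16)
  s0 <- sum(img)
  for (a in c(-90, -61.7, -45, -10, 0, 17, 33.3, 45, 80, 90)) {
    expect_lt(abs(sum(forward_project(img, a)) - s0) / s0, 1e-9)
  }
  # angle-independence of the projection integral
  p <- forward_project(img, c(-70, -35, 0, 20, 55), drop = FALSE)
  expect_lt(diff(range(colSums(p))) / s0, 1e-9)
})

test_that("forward projection matches the subpixel point-mass oracle", {
  set.seed(3)
  img <- matrix(runif(25), 5)
  for (a in c(30, -57, 12.5)) {
    oracle <- subpixel_project(img, a)
    got <- forward_project(img, a)
    expect_lt(max(abs(got - oracle) / pmax(oracle, max(oracle) * 0.05)), 0.02)
  }
})

test_that("back projection: zeros, single-ray smear, matrix adjoint", {
  expect_equal(back_project(matrix(0, 6, 2), c(0, 45)), matrix(0, 6, 6))

  r <- numeric(8); r[3] <- 1
  bp <- back_project(r, 0)
  expect_equal(bp[, 3], rep(1, 8))
  expect_equal(sum(bp != 0), 8)

  set.seed(7)
  angs <- c(0, 90)
  res <- matrix(rnorm(8), 4, 2)
  A <- system_matrix(4, angs)
  want <- matrix(crossprod(A, as.vector(res)), 4, 4) / 2
  expect_equal(back_project(res, angs), want, tolerance = 1e-12)
})

test_that("projector pair is adjoint and respects 90-degree rotation", {
  set.seed(11)
  angs <- c(-50, -5, 30, 75)
  x <- matrix(rnorm(64), 8)
  y <- matrix(rnorm(32), 8, 4)
  lhs <- sum(forward_project(x, angs, drop = FALSE) * y)
  rhs <- sum(x * back_project(y, angs)) * length(angs)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)

  img <- disc_image(12)
  rot90 <- function(mm) t(mm)[ncol(mm):1, ]  # +90 deg in this convention
  expect_equal(forward_project(img, 20), forward_project(rot90(img), -70),
               tolerance = 1e-12)
})

test_that("column_index partitions the grid and matches the rotation oracle", {
  ci0 <- column_index(6, 0)
  expect_equal(ci0, matrix(rep(1:6, each = 6), 6, 6), ignore_attr = TRUE)
  # pixels sharing x share a column at 0 degrees
  expect_true(all(ci0[1, ] == ci0[4, ]))

  n <- 4
  ci <- column_index(n, 45)
  th <- 45 * pi / 180
  for (ix in seq_len(n)) {
    for (iz in seq_len(n)) {
      cc <- (ix - 0.5 - n / 2) * cos(th) + (iz - 0.5 - n / 2) * sin(th) + n / 2
      expect_equal(ci[iz, ix], min(max(floor(cc), 0), n - 1) + 1)
    }
  }
  # partition: every pixel maps to exactly one valid column
  for (a in c(-88, -45, 13, 70)) {
    cia <- column_index(8, a)
    expect_true(all(cia >= 1 & cia <= 8))
  }
})

test_that("geometry validation rejects bad inputs", {
  expect_error(tilt_geometry(c(0, 0, 10), 8), "strictly increasing")
  expect_error(tilt_geometry(c(-100, 0), 8), "degrees")
  expect_error(forward_project(matrix(0, 3, 4), 0), "square")
  expect_error(back_project(matrix(0, 4, 2), c(0, 10, 20)), "per angle")
})
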