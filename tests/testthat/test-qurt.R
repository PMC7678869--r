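test_that("schedule construction and validation", {
  ts <- simulate_tilt_series(phantom_binary(64), tilt_angles(60, 2))
  sc <- qurt_schedule(ts)
  expect_s3_class(sc, "qurt_schedule")
  expect_equal(tail(sc$levels, 1)$qu_size, 1L)
  expect_equal(tail(sc$levels, 1)$q, 1L)
  expect_equal(sc$base_angles, c(-60, 0, 60))  # step <= 5 deg: three angles
  sz <- unique(sc$levels$qu_size)
  expect_equal(sz, c(32L, 16L, 8L, 4L, 2L, 1L))

  # coarse steps bring in the +/-50 degree base angles
  ts10 <- simulate_tilt_series(phantom_binary(64), tilt_angles(70, 10))
  expect_equal(qurt_schedule(ts10)$base_angles, c(-70, -50, 0, 50, 70))

  bad <- sc
  bad$levels <- sc$levels[-nrow(sc$levels), ]
  expect_error(qurt(ts, schedule = bad), "end at QU size 1")
  bad2 <- sc
  bad2$base_angles <- numeric(0)
  expect_error(qurt(ts, schedule = bad2), "base angle")
  expect_error(qurt_level(ts, 1L, 1L, base_angles = 33), "acquired")
})

test_that("a level initialised at the exact solution returns it unchanged", {
  n <- 32
  model <- phantom_binary(n)
  ts <- simulate_tilt_series(model, tilt_angles(60, 10))
  out <- qurt_level(ts, 1L, 1L, base_angles = 0, init = model)
  expect_equal(out$image, model, ignore_attr = TRUE)
  expect_equal(out$log$placed, 0)
  expect_equal(out$log$moved, 0)

  # base angles producing identical solutions: the average equals either
  out2 <- qurt_level(ts, 1L, 1L, base_angles = c(0, 0), init = model)
  expect_equal(out2$image, model, ignore_attr = TRUE)
  expect_equal(out2$solutions[[1]], out2$solutions[[2]])
})

test_that("QURT of an all-zero series is the zero image", {
  ts <- tilt_series(matrix(0, 32, 5), c(-60, -30, 0, 30, 60))
  fit <- qurt(ts, start_size = 8L)
  expect_true(all(fitted(fit) == 0))
})

test_that("QURT reconstructs the binary model from limited angles", {
  n <- 64
  model <- phantom_binary(n)
  ts <- simulate_tilt_series(model, tilt_angles(60, 5))
  fit <- qurt(ts, q_values = 1L)
  expect_lt(normalized_error(fit, model), 0.03)
  # per-column budgets are exact at every level (constraint conservation)
  expect_true(all(fit$log$placed >= 0))
  expect_s3_class(fit, "qurt")
  expect_output(print(fit), "QURT reconstruction")
  expect_equal(dim(residuals(fit)), dim(ts$projections))
  expect_equal(predict(fit, 0)[, 1], forward_project(fitted(fit), 0))
})

test_that("amplified reconstruction maps back to the data scale", {
  n <- 32
  model <- phantom_general(n)
  ts <- simulate_tilt_series(model, tilt_angles(70, 10))
  fit <- qurt(ts, target_peak = 2e4, start_size = 8L)
  plain <- qurt(ts, start_size = 8L)
  expect_lt(abs(normalized_error(fit, model) - normalized_error(plain, model)),
            0.02)
  expect_lt(abs(mean(fitted(fit)) - mean(model)) / mean(model), 0.1)
})
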