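test_that("integral invariance diagnostic flags inconsistent projections", {
  model <- phantom_binary(32)
  ts <- simulate_tilt_series(model, tilt_angles(60, 15))
  rep0 <- integral_invariance(ts, tol = 1e-9)
  expect_true(all(rep0$deviation < 1e-9))
  expect_false(any(rep0$flagged))

  p <- ts$projections
  p[, 3] <- 2 * p[, 3]
  rep1 <- integral_invariance(tilt_series(p, ts$angles), tol = 1e-3)
  expect_true(rep1$flagged[3])
  expect_false(any(rep1$flagged[-3]))

  # Poisson noise: deviations on the order of 1/sqrt(total counts)
  tsn <- simulate_tilt_series(model, tilt_angles(60, 15), noise = "poisson",
                              scale = 1e4, seed = 42)
  repn <- integral_invariance(tsn, tol = 1)
  expected_order <- 1 / sqrt(sum(model) * 1e4)
  expect_lt(median(repn$deviation), 10 * expected_order)
  expect_gt(max(repn$deviation), expected_order / 10)
})

test_that("QU budgets: rounding, identity N = sum of counts, scaling with q", {
  cs <- qu_constraints(c(4, 2, 0), q = 2)
  expect_equal(cs$column_counts, c(2L, 1L, 0L))
  expect_equal(cs$total_count, 3L)

  expect_equal(qu_constraints(numeric(5), 3)$total_count, 0L)
  expect_error(qu_constraints(c(-1, 2), 1), "non-negative")

  # rounding bound: N*q within bins*q/2 of the projection integral
  set.seed(4)
  for (q in c(1, 3, 8)) {
    p <- runif(24, 0, 50)
    cs <- qu_constraints(p, q)
    expect_lte(abs(cs$total_count * q - sum(p)), length(p) * q / 2)
    expect_equal(sum(cs$column_counts), cs$total_count)
  }
})

test_that("QU count quadruples when the linear image definition doubles", {
  for (kind in c("binary", "general")) {
    model <- phantom(kind, 64)
    ts <- simulate_tilt_series(model, tilt_angles(70, 10))
    p0 <- ts$projections[, ts$angles == 0]
    n_fine <- qu_constraints(p0, 1)$total_count
    p_bin <- qurt:::bin_projections(ts$projections, 2L)[, ts$angles == 0]
    n_coarse <- qu_constraints(p_bin, 1)$total_count
    expect_lt(abs(n_fine / n_coarse - 4), 0.2)
  }
})

test_that("amplification produces integer budgets and is invertible", {
  model <- phantom_general(32)
  ts <- simulate_tilt_series(model, tilt_angles(60, 10))
  amp <- amplify_projections(ts, target_peak = 5000)
  expect_true(all(amp$series$projections == round(amp$series$projections)))
  expect_equal(max(amp$series$projections), 5000)
  # inverse mapping recovers the data up to rounding
  expect_lt(max(abs(amp$series$projections / amp$scale - ts$projections)),
            0.5 / amp$scale + 1e-12)

  # already-integer series at the target peak is unchanged
  pi0 <- round(ts$projections)
  tsi <- tilt_series(pi0, ts$angles)
  ampi <- amplify_projections(tsi, target_peak = max(pi0))
  expect_equal(ampi$scale, 1)
  expect_equal(ampi$series$projections, pi0)

  # doubling the target doubles the integers within rounding
  amp2 <- amplify_projections(ts, target_peak = 10000)
  expect_lt(max(abs(amp2$series$projections - 2 * amp$series$projections)), 1.01)

  expect_error(amplify_projections(tilt_series(matrix(0, 8, 1), 0)), "all-zero")
})

test_that("background subtraction clips at zero and is exactly invertible", {
  model <- phantom_binary(32)
  ts <- simulate_tilt_series(model, tilt_angles(50, 25))

  expect_equal(subtract_background(ts, 0)$projections, ts$projections,
               ignore_attr = TRUE)

  shifted <- tilt_series(ts$projections + 7.25, ts$angles)
  back <- subtract_background(shifted, 7.25)
  expect_lt(max(abs(back$projections - ts$projections)), 1e-12)

  mins <- apply(shifted$projections, 2, min)
  floored <- subtract_background(shifted, mins)
  expect_equal(unname(apply(floored$projections, 2, min)),
               numeric(length(ts$angles)))

  over <- subtract_background(ts, 1e6)
  expect_true(all(over$projections == 0))
  expect_equal(attr(over, "clipped_fraction"), 1)
  expect_error(subtract_background(ts, c(1, 2)), "offset per angle")
  expect_error(subtract_background(ts, Inf), "finite")
})
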