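test_that("resampling interpolates linearly and honors the auto step", {
  tr <- flat_trace(c(0, 10, 20))
  out <- resample_uniform(tr, dt = 0.5)
  expect_equal(out$intensity, c(0, 5, 10, 15, 20))
  expect_equal(out$time_min, seq(0, 2, by = 0.5))

  const <- flat_trace(rep(7, 5))
  expect_true(all(resample_uniform(const, dt = 0.3)$intensity == 7))

  irregular <- trace_tbl(c(0, 0.9, 1.0, 2.1), c(1, 2, 3, 4), label = "x")
  out <- resample_uniform(irregular, dt = "auto")
  expect_equal(diff(out$time_min)[1], 0.9)  # median of {0.9, 0.1, 1.1}

  expect_error(resample_uniform(tr, dt = -1),
               class = "pcisr_validation_error")
})

test_that("resampling a trace already on the target grid is the identity", {
  tr <- flat_trace(c(3, 1, 4, 1, 5), dt = 0.25)
  out <- resample_uniform(tr, dt = 0.25)
  expect_equal(out$intensity, tr$intensity)
  expect_equal(out$time_min, tr$time_min)
})

test_that("moving average truncates at edges and preserves constants", {
  expect_equal(moving_average(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  x <- c(2, 8, 1, 9, 4)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(4.2, 6), 3), rep(4.2, 6))
  expect_error(moving_average(x, 2), class = "pcisr_validation_error")

  # output never leaves the local input range
  withr::with_seed(42, {
    for (i in 1:20) {
      v <- runif(15)
      sm <- moving_average(v, 5)
      expect_true(all(sm >= min(v) - 1e-12 & sm <= max(v) + 1e-12))
    }
  })
})

test_that("windows are half-open [t_start, t_end)", {
  tr <- flat_trace(0:10, dt = 1)
  win <- window_traces(tr, 2, 5)
  expect_equal(win$time_min, c(2, 3, 4))
  whole <- window_traces(tr, 0, 10.5)
  expect_equal(nrow(whole), 11)
  expect_error(window_traces(tr, 20, 30), "empty window",
               class = "pcisr_window_error")
})

test_that("pearson_r matches hand-computed coefficients", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "pcisr_constant_signal_error")
  expect_error(pearson_r(1:2, 1:2), class = "pcisr_validation_error")
})

test_that("pearson_r is symmetric and affine-invariant", {
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- rnorm(20)
      b <- rnorm(20)
      expect_equal(pearson_r(a, b), pearson_r(b, a))
      expect_equal(pearson_r(2.5 * a + 3, b), pearson_r(a, b),
                   tolerance = 1e-12)
    }
  })
})
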