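test_that("apex location takes the earliest maximum in the RT window", {
  g <- gaussian_trace(rt = 5, sigma = 0.1)
  apex <- locate_apex(g, 5, 0.5)
  expect_equal(apex$time, 5)
  expect_false(apex$no_signal)

  flat <- flat_trace(rep(0, 11), dt = 1)
  apex0 <- locate_apex(flat, 5, 2)
  expect_true(apex0$no_signal)

  twin <- flat_trace(c(0, 0, 5, 1, 5, 0, 0), dt = 0.1, t0 = 4.7)
  apex2 <- locate_apex(twin, 5, 0.3)
  expect_equal(apex2$time, 4.9)  # tie broken to the earlier time

  expect_error(locate_apex(g, 50, 0.1), class = "pcisr_window_error")
})

test_that("height-fraction integration matches hand-computed examples", {
  tr <- flat_trace(c(1, 10, 100, 10, 1))
  p99 <- integrate_height_fraction(tr, 3, 0.99)
  expect_equal(p99$area, 122)
  expect_equal(p99$n_points, 5L)

  p90 <- integrate_height_fraction(tr, 3, 0.90)
  expect_equal(p90$area, 120)
  expect_equal(c(p90$left_index, p90$right_index), c(2L, 4L))

  narrow <- flat_trace(c(0.5, 100, 0.5))
  pn <- integrate_height_fraction(narrow, 2, 0.99)
  expect_equal(pn$area, 100)
  expect_equal(pn$n_points, 1L)
})

test_that("integration agrees exactly with the brute-force enumerator", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(5:50, 1)
      v <- round(runif(n, 0, 100), 2)
      apex <- which.max(v)
      hf <- runif(1, 0.5, 0.995)
      tr <- flat_trace(v)
      got <- integrate_height_fraction(tr, apex, hf)
      expect_identical(c(got$left_index, got$right_index),
                       as.integer(brute_force_bounds(v, apex, hf)))
      expect_equal(got$area, brute_force_area(v, apex, hf))
    }
  })
})

test_that("integration is monotone in height fraction and scales linearly", {
  withr::with_seed(17, {
    for (i in 1:25) {
      v <- runif(30, 0, 50)
      apex <- which.max(v)
      tr <- flat_trace(v)
      fr <- sort(runif(4, 0.5, 0.99))
      res <- lapply(fr, function(f) integrate_height_fraction(tr, apex, f))
      areas <- vapply(res, function(p) p$area, numeric(1))
      npts <- vapply(res, function(p) p$n_points, integer(1))
      expect_true(all(diff(areas) >= -1e-12))
      expect_true(all(diff(npts) >= 0))

      c_scale <- 3.5
      scaled <- integrate_height_fraction(
        flat_trace(v * c_scale), apex, fr[1])
      expect_equal(scaled$area, res[[1]]$area * c_scale,
                   tolerance = 1e-12)
      expect_identical(scaled$n_points, res[[1]]$n_points)
    }
  })
})

test_that("masked points terminate extension and are counted", {
  v <- c(10, 50, 100, 50, 10)
  tr <- flat_trace(v)
  tr$ratio <- v
  tr$ratio[4] <- NA
  tr$below_lloq <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  p <- integrate_height_fraction(tr, 3, 0.99)
  expect_equal(c(p$left_index, p$right_index), c(1L, 3L))
  expect_equal(p$area, 160)
  expect_equal(p$n_masked_in_bounds, 1L)
})

test_that("a double-peak target integrates one region spanning both apices", {
  t <- seq(0, 10, by = 0.02)
  v <- 100 * exp(-(t - 4.9)^2 / (2 * 0.05^2)) +
    80 * exp(-(t - 5.2)^2 / (2 * 0.05^2))
  tr <- trace_tbl(t, v, label = "AG", sample_id = "s",
                  precursor_mz = 100, product_mz = 50)
  target <- tibble::tibble(name = "AG", expected_rt = 5, rt_window = 0.5,
                           double_peak = TRUE)
  got <- quantify_target(tr, NULL, target)
  # oracle: union of the two single-apex regions, saddle included
  a1 <- integrate_height_fraction(tr, which.min(abs(t - 4.9)), 0.99)
  a2 <- integrate_height_fraction(tr, which.min(abs(t - 5.2)), 0.99)
  idx <- min(a1$left_index, a2$left_index):max(a1$right_index,
                                               a2$right_index)
  expect_equal(got$area, sum(v[idx]))
  expect_true(got$left_time < 4.9 && got$right_time > 5.2)
})

test_that("quantify_target with a constant PCIS divides the area exactly", {
  ana <- gaussian_trace(rt = 5, sigma = 0.1, height = 1000)
  p <- flat_trace(rep(250, nrow(ana)), dt = 0.02, label = "p")
  corrected <- pcis_correct(ana, p, lloq = 1)
  target <- tibble::tibble(name = "g", expected_rt = 5, rt_window = 0.5,
                           double_peak = FALSE)
  got <- quantify_target(ana, corrected, target)
  raw <- dplyr::filter(got, source == "raw")
  cor <- dplyr::filter(got, source == "corrected")
  expect_equal(cor$area, raw$area / 250, tolerance = 1e-12)
  expect_equal(raw$n_points, cor$n_points)

  zero <- flat_trace(rep(0, 201), dt = 0.02)
  got0 <- quantify_target(zero, NULL,
                          tibble::tibble(name = "z", expected_rt = 2,
                                         rt_window = 0.5,
                                         double_peak = FALSE))
  expect_true(got0$no_signal)
  expect_equal(got0$area, 0)
})
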