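test_that("Method 1 pools ME percentages across samples and levels", {
  areas <- tibble::tibble(
    name = "d4-LEA", source = "raw",
    sample_id = c("m1", "m2", "m3"), area = c(80, 100, 120))
  neat <- tibble::tibble(name = "d4-LEA", source = "raw", area = 100)
  m1 <- method1_across_matrices(areas, neat)
  expect_equal(m1$summary$mean_me, 100)
  expect_equal(m1$summary$cv, 20)  # sample sd 20 over mean 100
  expect_equal(m1$per_sample$me_pct, c(80, 100, 120))

  equal_areas <- dplyr::mutate(areas, area = 100)
  m0 <- method1_across_matrices(equal_areas, neat)
  expect_equal(m0$summary$mean_me, 100)
  expect_equal(m0$summary$cv, 0)

  expect_error(
    method1_across_matrices(dplyr::mutate(areas, name = "other"), neat),
    "missing neat", class = "pcisr_reference_error")
})

test_that("Method 2 reports ME per concentration factor", {
  cfs <- c(0.5, 1, 2, 4)
  pts <- tidyr::expand_grid(name = "x", source = "raw", cf = cfs,
                            replicate = 1:2) |>
    dplyr::mutate(area = 50)
  neat <- tibble::tibble(name = "x", source = "raw", area = 50)
  me <- method2_cf_series(pts, neat)
  expect_equal(me$me_pct, rep(100, 4))  # no suppression anywhere

  supp <- dplyr::mutate(pts, area = 50 * (1 + cf)^(-0.7))
  me2 <- method2_cf_series(supp, neat)
  expect_equal(me2$me_pct, 100 * (1 + cfs)^(-0.7), tolerance = 1e-12)
  expect_true(all(diff(me2$me_pct) < 0))
})

test_that("Method 3 linearity matches direct formula evaluation", {
  cfs <- c(0.25, 0.5, 1, 2, 3, 4, 5)
  exact <- tibble::tibble(name = "x", source = "raw", cf = cfs,
                          area = 10 * cfs)
  r <- method3_dilution_linearity(exact)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$cv_area_over_cf, 0)

  curved <- dplyr::mutate(exact, area = 10 * cf * (1 + cf)^(-0.5))
  got <- method3_dilution_linearity(curved)
  # oracle: explicit least squares and CV on the closed-form values
  y <- 10 * cfs * (1 + cfs)^(-0.5)
  beta <- sum((cfs - mean(cfs)) * (y - mean(y))) / sum((cfs - mean(cfs))^2)
  alpha <- mean(y) - beta * mean(cfs)
  r2_oracle <- 1 - sum((y - alpha - beta * cfs)^2) / sum((y - mean(y))^2)
  cv_oracle <- 100 * sd(y / cfs) / mean(y / cfs)
  expect_equal(got$r2, r2_oracle, tolerance = 1e-12)
  expect_equal(got$cv_area_over_cf, cv_oracle, tolerance = 1e-12)

  expect_error(
    method3_dilution_linearity(exact[1:3, ]),
    "4 distinct", class = "pcisr_validation_error")
})

test_that("calibration fits are ordinary least squares with free intercept", {
  fit <- fit_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  shifted <- fit_calibration(c(1, 2, 3), c(2, 4, 6) + 5)
  expect_equal(shifted$slope, 2)
  expect_equal(shifted$intercept, 5)

  expect_warning(two <- fit_calibration(c(1, 3), c(10, 20)), "2 points")
  expect_equal(two$slope, 5)

  g <- glance(fit)
  expect_equal(g$slope, 2)
  expect_equal(g$response_type, "raw_area")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)),
               class = "pcisr_validation_error")
})

test_that("repeated noisy fits recover the slope without bias", {
  true_slope <- 3
  conc <- 1:7
  est <- withr::with_seed(11, {
    vapply(1:500, function(i) {
      fit_calibration(conc, true_slope * conc + rnorm(7, 0, 0.5))$slope
    }, numeric(1))
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_slope), 4 * se)
})

test_that("slope comparison applies the 15/20% verdicts inclusively", {
  cmp <- compare_slopes(0.8, 1.0)
  expect_equal(cmp$pct_difference, -20)
  expect_equal(cmp$verdict, "acceptable")

  expect_equal(slope_verdict(-24), "outside")
  expect_equal(slope_verdict(9), "preferable")
  expect_equal(slope_verdict(c(15, -15, 20, 20.01)),
               c("preferable", "preferable", "acceptable", "outside"))
  expect_error(compare_slopes(1, 0), class = "pcisr_validation_error")
})

test_that("ME statistics are invariant to a common area rescale", {
  withr::with_seed(5, {
    areas <- tidyr::expand_grid(name = c("a", "b"), source = "raw",
                                sample_id = paste0("m", 1:6)) |>
      dplyr::mutate(area = runif(dplyr::n(), 10, 100))
    neat <- tibble::tibble(name = c("a", "b"), source = "raw",
                           area = c(40, 60))
    base <- method1_across_matrices(areas, neat)$summary
    scaled <- method1_across_matrices(
      dplyr::mutate(areas, area = area * 7.3),
      dplyr::mutate(neat, area = area * 7.3))$summary
    expect_equal(scaled$mean_me, base$mean_me)
    expect_equal(scaled$cv, base$cv)
  })
})

test_that("SIL area-ratio response divides analyte by ISTD area", {
  expect_equal(sil_ratio_response(200, 100), 2)
  expect_equal(sil_ratio_response(c(50, 75), c(50, 75)), c(1, 1))
  expect_error(sil_ratio_response(10, 0), class = "pcisr_validation_error")
})
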