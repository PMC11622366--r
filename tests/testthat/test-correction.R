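test_that("LLOQ rule takes the lower of 1% infusion mean and 10x noise", {
  a <- compute_lloq(rep(10000, 5), rep(5, 5))
  expect_equal(a$value, 50)
  expect_equal(a$rule_used, "ten_times_noise")

  b <- compute_lloq(rep(1000, 5), rep(20, 5))
  expect_equal(b$value, 10)
  expect_equal(b$rule_used, "one_percent_of_infusion_mean")

  # exact tie: both branches give 25; the noise rule is reported
  d <- compute_lloq(rep(2500, 5), rep(2.5, 5))
  expect_equal(d$value, 25)
  expect_equal(d$rule_used, "ten_times_noise")

  expect_error(compute_lloq(rep(0, 5), rep(1, 5)),
               class = "pcisr_validation_error")
})

test_that("below-LLOQ counting is strict and windowed", {
  tr <- flat_trace(c(60, 40, 55, 10, 80), dt = 1)
  expect_equal(count_below_lloq(tr, 50, 0, 4), 2)
  expect_equal(count_below_lloq(tr, 50, 0, 5), 2)  # 80 at t=4 included
  expect_equal(count_below_lloq(tr, 5, 0, 5), 0)
  expect_equal(count_below_lloq(tr, 0, 0, 5), 0)   # nothing is < 0
})

test_that("pcis_correct is the scan-by-scan ratio with LLOQ policies", {
  ana <- flat_trace(c(100, 200, 100), label = "a")
  p <- flat_trace(c(50, 50, 50), label = "p")
  out <- pcis_correct(ana, p, lloq = 10)
  expect_equal(out$ratio, c(2, 4, 2))
  expect_false(any(out$below_lloq))

  pdip <- flat_trace(c(50, 5, 50), label = "p")
  masked <- pcis_correct(ana, pdip, lloq = 10, policy = "mask")
  expect_equal(masked$below_lloq, c(FALSE, TRUE, FALSE))
  expect_true(is.na(masked$ratio[2]))

  interp <- pcis_correct(ana, pdip, lloq = 10, policy = "interpolate")
  expect_equal(interp$ratio, c(2, 4, 2))  # gap bridged as 50
  expect_equal(interp$below_lloq, c(FALSE, TRUE, FALSE))

  clamped <- pcis_correct(ana, pdip, lloq = 10, policy = "clamp")
  expect_equal(clamped$ratio[2], 200 / 10)

  expect_error(pcis_correct(ana, pdip, lloq = 100),
               class = "pcisr_pcis_lost_error")
  far <- flat_trace(c(1, 1, 1), label = "p", t0 = 100)
  expect_error(pcis_correct(ana, far, lloq = 0.1),
               class = "pcisr_alignment_error")
})

test_that("a shared multiplicative suppression profile cancels exactly", {
  t <- seq(0, 10, by = 0.05)
  s <- 1 - 0.6 * exp(-(t - 6)^2 / 0.5) - 0.25 * exp(-(t - 8)^2 / 0.1)
  a_clean <- 1000 * exp(-(t - 5)^2 / (2 * 0.04))
  p_clean <- rep(2e4, length(t))
  mk <- function(v, lab) trace_tbl(t, v, label = lab, sample_id = "s")

  plain <- pcis_correct(mk(a_clean, "a"), mk(p_clean, "p"), lloq = 1)
  suppressed <- pcis_correct(mk(a_clean * s, "a"), mk(p_clean * s, "p"),
                             lloq = 1)
  expect_equal(suppressed$ratio, plain$ratio, tolerance = 1e-12)
})

test_that("scaling the PCIS level divides ratios by the same factor", {
  ana <- gaussian_trace()
  p <- flat_trace(rep(100, nrow(ana)), dt = 0.02, label = "p")
  base <- pcis_correct(ana, p, lloq = 1)
  k <- 3.7
  pk <- dplyr::mutate(p, intensity = intensity * k)
  scaled <- pcis_correct(ana, pk, lloq = 1)
  expect_equal(scaled$ratio, base$ratio / k, tolerance = 1e-12)
})

test_that("raising the LLOQ never unsets a below-LLOQ flag", {
  withr::with_seed(3, {
    p <- flat_trace(runif(50, 0, 100), dt = 1, label = "p")
    ana <- flat_trace(runif(50, 0, 1000), dt = 1, label = "a")
    lloqs <- c(5, 20, 40, 60)
    masks <- lapply(lloqs, function(l) {
      pcis_correct(ana, p, lloq = l)$below_lloq
    })
    for (i in seq_len(length(lloqs) - 1)) {
      expect_true(all(masks[[i + 1]] | !masks[[i]]))
    }
  })
})
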