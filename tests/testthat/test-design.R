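test_that("suppression correlation recovers a designed block structure", {
  sim <- simulate_dataset("exploration")
  corr <- suppression_correlation(sim$traces, 10.5, 14)
  shared <- sim$manifest$name[sim$manifest$profile == "shared"]
  others <- setdiff(sim$manifest$name, shared)
  within <- corr$r[shared, shared][upper.tri(diag(length(shared)))]
  expect_true(all(within >= 0.95))
  for (o in others) {
    expect_true(all(corr$r[o, setdiff(rownames(corr$r), o)] < 0.95))
  }
  expect_equal(diag(corr$r), setNames(rep(1, 8), rownames(corr$r)))
  expect_equal(corr$r, t(corr$r))
})

test_that("identically and oppositely suppressed signals give r = +/-1", {
  t <- seq(10, 14, by = 0.02)
  s <- 1 - 0.5 * exp(-(t - 12)^2 / 0.2)
  tr <- dplyr::bind_rows(
    trace_tbl(t, 1000 * s, label = "a", sample_id = "i",
              precursor_mz = 1, product_mz = 1),
    trace_tbl(t, 500 * s, label = "b", sample_id = "i",
              precursor_mz = 2, product_mz = 2),
    trace_tbl(t, 800 * (2 - s), label = "c", sample_id = "i",
              precursor_mz = 3, product_mz = 3))
  corr <- suppression_correlation(tr, 10, 14)
  expect_equal(corr$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(corr$r["a", "c"], -1, tolerance = 1e-12)
})

test_that("grouping reproduces the worked three-group example", {
  r <- block_cor_matrix()  # 6 mutual >= 0.95; 2 below 0.91 vs all, 0.75 together
  g <- group_by_pcis(r, threshold = 0.95)
  expect_equal(g$n_pcis_needed, 3)
  sizes <- sort(vapply(g$groups, length, integer(1)))
  expect_equal(unname(sizes), c(1, 1, 6))
})

test_that("grouping handles the degenerate extremes", {
  labels <- paste0("A", 1:5)
  all_hi <- matrix(0.99, 5, 5, dimnames = list(labels, labels))
  diag(all_hi) <- 1
  expect_equal(group_by_pcis(all_hi)$n_pcis_needed, 1)

  all_lo <- matrix(0.1, 5, 5, dimnames = list(labels, labels))
  diag(all_lo) <- 1
  expect_equal(group_by_pcis(all_lo)$n_pcis_needed, 5)
})

test_that("grouping is deterministic and invariant to label order", {
  r <- block_cor_matrix()
  g1 <- group_by_pcis(r)
  perm <- sample(rownames(r))
  g2 <- group_by_pcis(r[perm, perm])
  expect_equal(g1$groups, g2$groups)

  # lowering the threshold can only merge, never split
  thresholds <- c(0.98, 0.9, 0.8, 0.7, 0.5)
  ns <- vapply(thresholds,
               function(th) group_by_pcis(r, th)$n_pcis_needed,
               integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("infusion signal stats give mean and sample RSD", {
  expect_equal(infusion_signal_stats(flat_trace(rep(100, 5)))$rsd, 0)
  st <- infusion_signal_stats(flat_trace(c(90, 100, 110)))
  expect_equal(st$mean_intensity, 100)
  expect_equal(st$rsd, 10)
  st2 <- infusion_signal_stats(flat_trace(7 * c(90, 100, 110)))
  expect_equal(st2$rsd, 10)  # scale invariant
  expect_error(infusion_signal_stats(flat_trace(c(1, 2))),
               class = "pcisr_validation_error")
})

test_that("PCIS-induced matrix effect is the percent ratio vs blank infusion", {
  with_pcis <- tibble::tibble(name = c("a", "b", "c"),
                              area = c(70, 80, 90))
  blank <- tidyr::expand_grid(name = c("a", "b", "c"), replicate = 1:3) |>
    dplyr::mutate(area = 100)
  me <- pcis_induced_matrix_effect(with_pcis, blank)
  expect_equal(me$me_pct, c(70, 80, 90))
  expect_equal(attr(me, "mean_me"), 80)

  same <- pcis_induced_matrix_effect(
    tibble::tibble(name = "a", area = 55),
    tibble::tibble(name = "a", area = rep(55, 3)))
  expect_equal(same$me_pct, 100)

  # invariant to a common rescale of every area
  scaled <- pcis_induced_matrix_effect(
    dplyr::mutate(with_pcis, area = area * 12),
    dplyr::mutate(blank, area = area * 12))
  expect_equal(scaled$me_pct, me$me_pct)
})

test_that("the concentration scan reproduces its designed behavior", {
  sim <- simulate_dataset("concentration_scan")
  scan <- concentration_scan(sim$entries, stats_window = c(0.2, 1.8),
                             noise_window = c(0, 0.5),
                             count_window = c(10, 14))
  expect_equal(nrow(scan), nrow(sim$manifest))
  # mean infusion intensity is linear in concentration
  fit <- fit_calibration(scan$concentration, scan$mean_intensity)
  expect_gt(fit$r2, 0.999)
  # signal RSD falls (constant additive noise, growing signal)
  expect_true(all(diff(scan$rsd) < 0))
  # sub-LLOQ scans in the elution zone become rarer as the level rises
  expect_true(all(diff(scan$n_below_lloq) <= 0))
  expect_gt(scan$n_below_lloq[1], scan$n_below_lloq[nrow(scan)])
  # induced matrix effect tracks the designed truth
  expect_equal(scan$induced_me, sim$manifest$true_induced_me,
               tolerance = 0.05)
})
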