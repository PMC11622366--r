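test_that("suppression factor follows its closed form", {
  sup <- suppression_model(dips = data.frame(center = 12, width = 0.3,
                                             depth = 0.5),
                           cf_exponent = 0.5)
  expect_equal(suppression_factor(sup, 12, cf = 0), 0.5)
  expect_equal(suppression_factor(sup, 12, cf = 1), 0.5 * 2^(-0.5))
  expect_equal(suppression_factor(sup, 0, cf = 0), 1, tolerance = 1e-9)
  expect_equal(suppression_factor(NULL, c(1, 2)), c(1, 1))
})

test_that("infusion traces match the scenario closed form", {
  sc <- sim_scenario(suppression = NULL, noise_sd = 0, noise_rsd = 0)
  tr <- simulate_infusion_trace(sc)
  expect_true(all(tr$intensity == sc$pcis_level))

  sc2 <- sim_scenario(
    suppression = suppression_model(dips = data.frame(
      center = 12, width = 0.3, depth = 0.5)))
  tr2 <- simulate_infusion_trace(sc2)
  expect_equal(min(tr2$intensity), 0.5 * sc2$pcis_level)
  expect_equal(tr2$time_min[which.min(tr2$intensity)], 12)
})

test_that("identical seeds give bit-identical traces and datasets", {
  sc <- sim_scenario(noise_rsd = 0.05, seed = 99L)
  expect_identical(simulate_infusion_trace(sc), simulate_infusion_trace(sc))
  expect_identical(
    simulate_analyte_trace(sc, "LEA", 2),
    simulate_analyte_trace(sc, "LEA", 2))
  s1 <- simulate_dataset("multi_matrix",
                         default_scenario("multi_matrix", seed = 7L))
  s2 <- simulate_dataset("multi_matrix",
                         default_scenario("multi_matrix", seed = 7L))
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$manifest, s2$manifest)
})

test_that("noise-free analyte areas match the sampled-Gaussian sum", {
  sc <- sim_scenario(suppression = NULL)
  tr <- simulate_analyte_trace(sc, "LEA", amount = 2)
  a <- sc$analytes[1, ]
  t <- seq(0, sc$run_length, by = sc$dt)
  oracle <- sum(a$gain * 2 * exp(-(t - a$rt)^2 / (2 * a$peak_sigma^2)))
  expect_equal(attr(tr, "true_area"), oracle)
  apex <- locate_apex(tr, a$rt, 0.3)
  peak <- integrate_height_fraction(tr, apex$index, 0.99)
  # the 99% rule keeps everything down to 1% of apex; compare against
  # the oracle restricted to the same points
  expect_equal(peak$area,
               brute_force_area(tr$intensity, apex$index, 0.99))
  expect_gt(peak$area / oracle, 0.99)

  doubled <- simulate_analyte_trace(sc, "LEA", amount = 4)
  expect_equal(doubled$intensity, tr$intensity * 2, tolerance = 1e-12)

  none <- simulate_analyte_trace(sc, "LEA", amount = 0)
  expect_true(all(none$intensity == 0))
})

test_that("simulated mzML bundles round-trip through the reader", {
  sc <- default_scenario("multi_matrix", seed = 3L)
  sim <- simulate_dataset("multi_matrix", sc, n_matrices = 2)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, format = "mzml")
  files <- list.files(dir, pattern = "\\.mzML$", full.names = TRUE)
  expect_equal(length(files), 3)  # 2 matrices + neat reference
  back <- purrr::map_dfr(files, read_mzml_chromatograms)
  for (sid in unique(sim$traces$sample_id)) {
    for (lab in unique(sim$traces$label)) {
      a <- dplyr::filter(sim$traces, sample_id == sid, label == lab)
      b <- dplyr::filter(back, sample_id == sid, label == lab)
      expect_equal(b$intensity, a$intensity, tolerance = 1e-6)
    }
  }
})

test_that("design-level expectations hold by construction", {
  expect_error(simulate_dataset("nonsense"),
               class = "pcisr_validation_error")

  # k = 0: no CF dependence, expected uncorrected ME is 100% everywhere
  sc <- default_scenario("cf_series")
  sc$suppression <- suppression_model(cf_exponent = 0)
  sim <- simulate_dataset("cf_series", sc, n_replicates = 1)
  expect_true(all(sim$manifest$expected_uncorrected_me == 100))

  # calibration pair, shared suppression, noise-free: corrected slopes equal
  cal_sc <- default_scenario("calibration_pair")
  cal_sc$noise_rsd <- 0
  cal <- simulate_dataset("calibration_pair", cal_sc)
  expect_equal(cal$manifest$expected_corrected_slope_diff, c(0, 0))
  q <- quantify_targets(cal$traces, cal$targets, cal$pcis,
                        run_config(smoothing_window = 1))
  areas <- dplyr::inner_join(write_quant_report(q), cal$samples,
                             by = "sample_id")
  slopes <- areas |>
    dplyr::filter(name == "ANA") |>
    dplyr::group_by(cond) |>
    dplyr::summarise(s = fit_calibration(lvl, corrected_area)$slope)
  expect_equal(slopes$s[slopes$cond == "matrix"],
               slopes$s[slopes$cond == "neat"], tolerance = 1e-9)
})

test_that("scenario validation rejects impossible suppression", {
  expect_error(
    sim_scenario(suppression = suppression_model(
      dips = data.frame(center = c(12, 12), width = 0.3,
                        depth = c(0.6, 0.6)))),
    class = "pcisr_validation_error")
})
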