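#' Simulate a complete study design with known ground truth
#'
#' Generates every injection one of the package's study designs requires,
#' together with a manifest of ground truths, and target/PCIS tables ready
#' for [quantify_targets()]:
#'
#' * `"exploration"` — one infusion trace per candidate analyte during a
#'   matrix injection, with a designed group structure of suppression
#'   profiles (for [suppression_correlation()] / [group_by_pcis()]).
#' * `"concentration_scan"` — per candidate PCIS concentration: an
#'   isocratic infusion trace, a matrix-injection PCIS trace (infusion
#'   diverted to waste for the first 0.5 min), and analyte areas with /
#'   without PCIS infusion (for [concentration_scan()]).
#' * `"multi_matrix"` — n matrices whose suppression differs by a
#'   per-matrix factor drawn uniformly from `factor_range`, plus a neat
#'   reference (for [method1_across_matrices()]).
#' * `"cf_series"` — a concentration-factor series with
#'   `S(cf) = (1 + cf)^(-k)`, a constant spiked standard and a
#'   CF-proportional endogenous analyte, plus neat references (for
#'   [method2_cf_series()] / [method3_dilution_linearity()]).
#' * `"calibration_pair"` — identical calibration series in neat solution
#'   (no suppression) and in matrix, with a SIL internal standard eluting
#'   `sil_rt_offset` earlier into deeper suppression (for
#'   [fit_calibration()] / [compare_slopes()]).
#'
#' All randomness is governed by `scenario$seed`; identical seeds give
#' bit-identical datasets.
#'
#' @param design One of the design names above.
#' @param scenario A [sim_scenario()]; `NULL` uses the design's default
#'   scenario (see [default_scenario()]).
#' @param ... Design-specific options, see Details of
#'   [default_scenario()].
#' @return An object of class `pcis_simulation`: a list with `design`,
#'   `scenario`, `traces` (long trace tibble; `concentration_scan` instead
#'   carries `entries`), `manifest`, `targets`, `pcis`.
#' @export
simulate_dataset <- function(design = c("exploration", "concentration_scan",
                                        "multi_matrix", "cf_series",
                                        "calibration_pair"),
                             scenario = NULL, ...) {
  design <- tryCatch(match.arg(design), error = function(e) {
    abort(paste0("unknown design: ", design[1]),
          class = "pcisr_validation_error")
  })
  scenario <- scenario %||% default_scenario(design)
  gen <- switch(design,
    exploration = generate_exploration,
    concentration_scan = generate_concentration_scan,
    multi_matrix = generate_multi_matrix,
    cf_series = generate_cf_series,
    calibration_pair = generate_calibration_pair)
  out <- withr::with_seed(scenario$seed, gen(scenario, ...))
  structure(c(list(design = design, scenario = scenario), out),
            class = "pcis_simulation")
}

#' Default scenario per study design
#'
#' The default scenarios fix the study conditions each design emulates:
#' a 15 min run sampled every 0.02 min, analytes eluting in the 11-13 min
#' high-suppression region as narrow Gaussian peaks (sigma 0.03 min), a
#' PCIS infusion at 1e5 counts, and suppression parameters stated in each
#' generator's documentation.
#'
#' @param design Design name as in [simulate_dataset()].
#' @param seed Integer seed.
#' @return A [sim_scenario()].
#' @export
default_scenario <- function(design, seed = 1L) {
  switch(design,
    exploration = sim_scenario(
      analytes = tibble::tibble(
        name = paste0("STD", 1:8), rt = seq(11, 13.5, length.out = 8),
        peak_sigma = 0.03, gain = 1e4,
        profile = c(rep("shared", 6), "glycerol", "lowcorr")),
      profiles = list(
        shared = suppression_model(dips = tibble::tibble(
          center = c(10.8, 12.2, 13.3), width = c(0.3, 0.4, 0.25),
          depth = c(0.55, 0.5, 0.4))),
        glycerol = suppression_model(dips = tibble::tibble(
          center = c(11.3, 12.9), width = c(0.5, 0.3),
          depth = c(0.35, 0.55))),
        lowcorr = suppression_model(dips = tibble::tibble(
          center = c(10.6, 11.9, 13.6), width = c(0.15, 0.6, 0.15),
          depth = c(0.3, 0.35, 0.5)))),
      noise_rsd = 0.01, seed = seed),
    concentration_scan = sim_scenario(
      analytes = tibble::tibble(
        name = paste0("ANA", 1:3), rt = c(11.5, 12.1, 12.8),
        peak_sigma = 0.03, gain = 1e4),
      suppression = suppression_model(dips = tibble::tibble(
        center = 12, width = 0.4, depth = 0.997)),
      noise_sd = 25, seed = seed),
    multi_matrix = sim_scenario(
      analytes = tibble::tibble(
        name = c("ANA1", "ANA2"), rt = c(11.8, 12.4),
        peak_sigma = 0.03, gain = 1e4),
      suppression = suppression_model(dips = tibble::tibble(
        center = 11.9, width = 0.25, depth = 0.3)),
      noise_rsd = 0.02, seed = seed),
    cf_series = sim_scenario(
      analytes = tibble::tibble(
        name = c("SPIKED", "ENDO"), rt = c(11.6, 12.4),
        peak_sigma = 0.03, gain = 1e4),
      suppression = suppression_model(cf_exponent = 0.5),
      noise_rsd = 0.02, seed = seed),
    calibration_pair = sim_scenario(
      analytes = tibble::tibble(
        name = "ANA", rt = 12, peak_sigma = 0.03, gain = 1e4),
      suppression = suppression_model(dips = tibble::tibble(
        center = 11.85, width = 0.15, depth = 0.5)),
      noise_rsd = 0.02, sil_rt_offset = -0.08, seed = seed),
    abort(paste0("unknown design: ", design),
          class = "pcisr_validation_error"))
}

sim_targets_table <- function(scenario, names = scenario$analytes$name,
                              rt_window = 0.3, rt_shift = 0,
                              istd = NA_character_) {
  an <- scenario$analytes[match(names, scenario$analytes$name), ]
  mz <- purrr::map(an$name, analyte_mz)
  tibble::tibble(
    name = an$name,
    precursor_mz = purrr::map_dbl(mz, 1),
    product_mz = purrr::map_dbl(mz, 2),
    polarity = "positive",
    expected_rt = an$rt + rt_shift,
    rt_window = rt_window,
    pcis_name = scenario$pcis_name,
    istd_name = istd,
    double_peak = FALSE
  )
}

sim_pcis_table <- function(scenario, lloq) {
  tibble::tibble(
    name = scenario$pcis_name, precursor_mz = 350.3, product_mz = 269.2,
    polarity = "positive", lloq = lloq,
    noise_start = 0, noise_end = 0.5
  )
}

# LLOQ used by the quantification designs: half the lowest clean PCIS
# intensity anywhere in the design, so no scan masks in the noise-free
# closure case while the threshold stays meaningful.
design_lloq <- function(scenario, cf_max = 1) {
  grid <- scenario_grid(scenario)
  smin <- min(suppression_factor(scenario$suppression, grid, cf_max))
  0.5 * scenario$pcis_level * smin
}

generate_exploration <- function(scenario) {
  traces <- purrr::map_dfr(seq_len(nrow(scenario$analytes)), function(i) {
    a <- scenario$analytes[i, ]
    model <- scenario$profiles[[a$profile]] %||% scenario$suppression
    sim_infusion_(scenario, cf = 1, sample_id = "plasma_injection",
                  label = a$name, suppression = model,
                  precursor_mz = analyte_mz(a$name)[1],
                  product_mz = analyte_mz(a$name)[2])
  })
  manifest <- dplyr::select(scenario$analytes, "name", "profile") |>
    dplyr::mutate(n_profiles = dplyr::n_distinct(.data$profile))
  list(traces = traces, manifest = manifest,
       targets = sim_targets_table(scenario),
       pcis = sim_pcis_table(scenario, NA_real_))
}

generate_concentration_scan <- function(scenario,
                                        concentrations = c(25, 50, 100,
                                                           200, 300),
                                        gain_per_conc = 400,
                                        induced_me = NULL,
                                        divert_until = 0.55,
                                        noise_baseline = 15) {
  # the diversion valve switches just after the 0-0.5 min noise window, so
  # edge smoothing cannot pull the full infusion signal into the noise
  # mean; the diverted segment carries a small constant detector baseline
  # plus noise, as a real pre-run segment does
  induced_me <- induced_me %||%
    approx(c(25, 300), c(0.82, 0.73), xout = concentrations)$y
  entries <- purrr::map(seq_along(concentrations), function(i) {
    conc <- concentrations[i]
    level <- conc * gain_per_conc
    sc <- scenario
    sc$pcis_level <- level
    t_iso <- seq(0, 2, by = scenario$dt)
    infusion <- trace_tbl(
      t_iso, add_noise(rep(level, length(t_iso)), sc),
      label = scenario$pcis_name,
      sample_id = sprintf("iso_%g", conc),
      precursor_mz = 350.3, product_mz = 269.2)
    plasma <- sim_infusion_(sc, cf = 1,
                            sample_id = sprintf("plasma_%g", conc))
    # electronic baseline noise is far smaller than signal shot noise
    n_div <- sum(plasma$time_min < divert_until)
    plasma$intensity[plasma$time_min < divert_until] <-
      pmax(0, rnorm(n_div, noise_baseline, noise_baseline / 5))
    true_areas <- purrr::map_dbl(scenario$analytes$name, function(nm) {
      a <- scenario$analytes[scenario$analytes$name == nm, ]
      sum(a$gain * exp(-(scenario_grid(scenario) - a$rt)^2 /
                         (2 * a$peak_sigma^2)))
    })
    jitter <- function(x) x * (1 + rnorm(length(x), 0, scenario$noise_rsd))
    blank <- tidyr::expand_grid(name = scenario$analytes$name,
                                replicate = 1:3) |>
      dplyr::mutate(area = jitter(rep(true_areas, each = 3)))
    with_pcis <- tibble::tibble(
      name = scenario$analytes$name,
      area = jitter(true_areas * induced_me[i]))
    list(concentration = conc, infusion = infusion, plasma_pcis = plasma,
         areas_with_pcis = with_pcis, areas_blank = blank)
  })
  manifest <- tibble::tibble(concentration = concentrations,
                             true_level = concentrations * gain_per_conc,
                             true_induced_me = 100 * induced_me)
  list(entries = entries, manifest = manifest,
       traces = purrr::map_dfr(entries,
                               ~ dplyr::bind_rows(.x$infusion,
                                                  .x$plasma_pcis)),
       targets = sim_targets_table(scenario),
       pcis = sim_pcis_table(scenario, NA_real_))
}

generate_multi_matrix <- function(scenario, n_matrices = 9,
                                  factor_range = c(0.3, 1),
                                  amount = 1) {
  factors <- stats::runif(n_matrices, factor_range[1], factor_range[2])
  lloq <- 0.5 * scenario$pcis_level * factor_range[1] *
    min(suppression_factor(scenario$suppression, scenario_grid(scenario), 1))

  # per-matrix factor applied to the clean signal before noise, so the
  # proportional noise component tracks the final (suppressed) signal
  build <- function(sid, m, suppressed) {
    t <- scenario_grid(scenario)
    s <- if (suppressed)
      m * suppression_factor(scenario$suppression, t, 1) else rep(1, length(t))
    pcis_tr <- trace_tbl(
      t, add_noise(scenario$pcis_level * s, scenario),
      label = scenario$pcis_name, sample_id = sid,
      precursor_mz = 350.3, product_mz = 269.2)
    ana <- purrr::map_dfr(seq_len(nrow(scenario$analytes)), function(i) {
      a <- scenario$analytes[i, ]
      clean <- a$gain * amount *
        exp(-(t - a$rt)^2 / (2 * a$peak_sigma^2)) * s
      trace_tbl(t, add_noise(clean, scenario), label = a$name,
                sample_id = sid, precursor_mz = analyte_mz(a$name)[1],
                product_mz = analyte_mz(a$name)[2])
    })
    dplyr::bind_rows(pcis_tr, ana)
  }
  traces <- purrr::map_dfr(seq_len(n_matrices), function(i) {
    build(sprintf("matrix%02d", i), factors[i], TRUE)
  })
  traces <- dplyr::bind_rows(traces, build("neat_mid", 1, FALSE))
  manifest <- tibble::tibble(
    sample_id = sprintf("matrix%02d", seq_len(n_matrices)),
    matrix_factor = factors,
    designed_cv = cv_pct(factors)
  )
  list(traces = traces, manifest = manifest,
       targets = sim_targets_table(scenario),
       pcis = sim_pcis_table(scenario, lloq))
}

generate_cf_series <- function(scenario,
                               cfs = c(0.25, 0.5, 1, 2, 3, 4, 5),
                               n_replicates = 3,
                               spiked_amount = 1, endo_base = 1) {
  k <- scenario$suppression$cf_exponent
  lloq <- 0.5 * scenario$pcis_level *
    min(suppression_factor(scenario$suppression, scenario_grid(scenario),
                           max(cfs)))
  one_injection <- function(sid, cf) {
    # endogenous amount scales with cf (absent, amount 0, in neat solution)
    dplyr::bind_rows(
      sim_analyte_(scenario, "SPIKED", spiked_amount, cf, sample_id = sid),
      sim_analyte_(scenario, "ENDO", endo_base * cf, cf, sample_id = sid),
      sim_infusion_(scenario, cf = cf, sample_id = sid))
  }
  traces <- purrr::map_dfr(cfs, function(cf) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      one_injection(sprintf("cf%g_r%d", cf, r), cf)
    })
  })
  traces <- dplyr::bind_rows(
    traces,
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      one_injection(sprintf("neat_r%d", r), 0)
    }))
  manifest <- tibble::tibble(
    cf = cfs,
    expected_uncorrected_me = 100 * (1 + cfs)^(-k),
    true_endo_amount = endo_base * cfs
  )
  list(traces = traces, manifest = manifest,
       targets = sim_targets_table(scenario),
       pcis = sim_pcis_table(scenario, lloq))
}

generate_calibration_pair <- function(scenario, levels = 1:7,
                                      n_replicates = 2, sil_amount = 2) {
  ana <- scenario$analytes[1, ]
  sil_name <- paste0(ana$name, "_SIL")
  t <- scenario_grid(scenario)
  s_rt <- suppression_factor(scenario$suppression, ana$rt, 1)
  s_sil <- suppression_factor(scenario$suppression,
                              ana$rt + scenario$sil_rt_offset, 1)
  lloq <- design_lloq(scenario)

  one_sample <- function(cond, lvl, rep) {
    sid <- sprintf("cal_%s_L%d_r%d", cond, lvl, rep)
    sup <- if (cond == "matrix") scenario$suppression else NULL
    pcis_sup <- if (cond == "matrix" && scenario$pcis_shares_suppression)
      sup else NULL
    ana_tr <- sim_analyte_(scenario, ana$name, lvl, cf = 1,
                           sample_id = sid, suppression = sup)
    sil_tr <- sim_analyte_(scenario, ana$name, sil_amount, cf = 1,
                           sample_id = sid, suppression = sup,
                           rt_shift = scenario$sil_rt_offset,
                           label = sil_name)
    sil_tr$precursor_mz <- analyte_mz(sil_name)[1]
    sil_tr$product_mz <- analyte_mz(sil_name)[2]
    pcis_tr <- sim_infusion_(scenario, cf = 1, sample_id = sid,
                             suppression = pcis_sup)
    dplyr::bind_rows(ana_tr, sil_tr, pcis_tr)
  }
  grid_df <- tidyr::expand_grid(cond = c("neat", "matrix"),
                                lvl = as.integer(levels),
                                rep = seq_len(n_replicates))
  traces <- purrr::pmap_dfr(grid_df, one_sample)
  targets <- dplyr::bind_rows(
    sim_targets_table(scenario, ana$name, istd = sil_name),
    sim_targets_table(scenario, ana$name,
                      rt_shift = scenario$sil_rt_offset) |>
      dplyr::mutate(name = sil_name,
                    precursor_mz = analyte_mz(sil_name)[1],
                    product_mz = analyte_mz(sil_name)[2]))
  manifest <- tibble::tibble(
    condition = c("neat", "matrix"),
    designed_suppression_at_rt = c(1, s_rt),
    designed_suppression_at_sil_rt = c(1, s_sil),
    expected_uncorrected_slope_diff = c(0, 100 * (s_rt - 1)),
    expected_sil_slope_diff = c(0, 100 * (s_rt / s_sil - 1)),
    expected_corrected_slope_diff = 0
  )
  list(traces = traces, manifest = manifest, targets = targets,
       pcis = sim_pcis_table(scenario, lloq),
       samples = dplyr::mutate(
         grid_df, sample_id = sprintf("cal_%s_L%d_r%d", .data$cond,
                                      .data$lvl, .data$rep)))
}

#' @export
print.pcis_simulation <- function(x, ...) {
  cat(sprintf("Simulated '%s' dataset (seed %d)\n", x$design,
              x$scenario$seed))
  if (!is.null(x$traces)) {
    cat(sprintf("  %d traces, %d points\n",
                dplyr::n_distinct(x$traces$sample_id, x$traces$label),
                nrow(x$traces)))
  }
  cat("  manifest:\n")
  print(x$manifest)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the traces of a [simulate_dataset()] result in one of the
#' formats [read_trace_table()] / [read_mzml_chromatograms()] consume,
#' plus the manifest and the target/PCIS tables as CSV.
#'
#' @param sim A `pcis_simulation`.
#' @param dir Output directory (created if needed).
#' @param format `"table"` (one `traces.csv`) or `"mzml"` (one mzML file
#'   per sample).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("table", "mzml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "table") {
    write_trace_table(sim$traces, file.path(dir, "traces.csv"))
  } else {
    for (sid in unique(sim$traces$sample_id)) {
      write_mzml_chromatograms(
        dplyr::filter(sim$traces, .data$sample_id == sid),
        file.path(dir, paste0(sid, ".mzML")))
    }
  }
  readr::write_csv(sim$manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(sim$targets, file.path(dir, "targets.csv"))
  readr::write_csv(sim$pcis, file.path(dir, "pcis.csv"))
  invisible(dir)
}
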