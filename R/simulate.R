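#' Time- and concentration-dependent suppression model
#'
#' Ion suppression is modeled multiplicatively: a baseline of 1 (no
#' suppression), Gaussian-shaped dips localized in time (emulating the
#' late-gradient high-suppression zone where co-eluting matrix components
#' quench ionization), and a matrix-concentration term `(1 + cf)^(-k)`
#' that decreases with the concentration factor and reduces to 1 for neat
#' solution (`cf = 0`). The functional form is a modeling choice that
#' reproduces the qualitative phenomenology (localized dips, ME falling
#' with increasing CF); it is not a mechanistic ESI model.
#'
#' @param dips Data frame with columns `center` (min), `width` (min,
#'   Gaussian sigma), `depth` (fraction in \[0, 1)), or `NULL` for none.
#' @param cf_exponent Non-negative exponent `k` of the `(1 + cf)^(-k)`
#'   concentration-factor term (0 = no CF dependence).
#' @return An object of class `suppression_model`.
#' @export
#' @examples
#' sup <- suppression_model(dips = data.frame(center = 12, width = 0.3,
#'                                            depth = 0.5))
#' suppression_factor(sup, t = c(10, 12), cf = 1)
suppression_model <- function(dips = NULL, cf_exponent = 0) {
  if (!is.null(dips)) {
    dips <- tibble::as_tibble(dips)
    stopifnot(all(c("center", "width", "depth") %in% names(dips)),
              all(dips$width > 0), all(dips$depth >= 0), all(dips$depth < 1))
  }
  if (cf_exponent < 0) {
    abort("cf_exponent must be >= 0", class = "pcisr_validation_error")
  }
  structure(list(dips = dips, cf_exponent = cf_exponent),
            class = "suppression_model")
}

#' @rdname suppression_model
#' @param model A `suppression_model` (or `NULL`, meaning no suppression).
#' @param t Numeric vector of times in minutes.
#' @param cf Concentration factor (>= 0; 0 = neat).
#' @export
suppression_factor <- function(model, t, cf = 1) {
  if (is.null(model)) return(rep(1, length(t)))
  s <- rep(1, length(t))
  if (!is.null(model$dips)) {
    for (i in seq_len(nrow(model$dips))) {
      d <- model$dips[i, ]
      s <- s - d$depth * exp(-(t - d$center)^2 / (2 * d$width^2))
    }
  }
  s * (1 + cf)^(-model$cf_exponent)
}

#' Simulation scenario
#'
#' Bundles everything needed to generate synthetic MRM chromatograms with
#' known ground truth: the run geometry, the analyte peak models, the PCIS
#' infusion level, the noise model, and the suppression model. An analyte
#' peak is `gain * amount * exp(-(t - rt)^2 / (2 sigma^2))`; the PCIS is a
#' constant infusion at `pcis_level`; both are multiplied by the
#' suppression factor, then additive Gaussian noise of standard deviation
#' `noise_sd + noise_rsd * clean_signal` is added and the result clamped
#' at zero.
#'
#' @param run_length Run length in minutes.
#' @param dt Scan interval in minutes.
#' @param analytes Data frame with columns `name`, `rt` (min), `peak_sigma`
#'   (min), `gain` (counts per amount unit), and optionally `profile`
#'   (name into `profiles` for per-analyte suppression).
#' @param pcis_name Label of the PCIS transition.
#' @param pcis_level Clean PCIS infusion intensity in counts.
#' @param noise_sd Additive noise sd in counts.
#' @param noise_rsd Multiplicative noise component: sd as a fraction of the
#'   clean signal (0.02 = 2% RSD).
#' @param suppression A [suppression_model()] shared by analytes and PCIS
#'   (or `NULL` for none).
#' @param profiles Optional named list of [suppression_model()]s for
#'   analytes whose `profile` field names one (used by the exploration
#'   design).
#' @param pcis_shares_suppression Does the PCIS experience the same
#'   suppression profile as the analytes (the ideal-PCIS assumption)?
#' @param sil_rt_offset Retention-time offset in minutes of a simulated
#'   spiked SIL internal standard relative to its analyte (negative =
#'   elutes earlier).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(run_length = 15, dt = 0.02,
                         analytes = tibble::tibble(
                           name = "LEA", rt = 12, peak_sigma = 0.03,
                           gain = 1e4),
                         pcis_name = "PCIS", pcis_level = 1e5,
                         noise_sd = 0, noise_rsd = 0,
                         suppression = suppression_model(
                           dips = tibble::tibble(center = 11.85,
                                                 width = 0.15, depth = 0.5)),
                         profiles = NULL,
                         pcis_shares_suppression = TRUE,
                         sil_rt_offset = -0.08,
                         seed = 1L) {
  analytes <- tibble::as_tibble(analytes)
  stopifnot(all(c("name", "rt", "peak_sigma", "gain") %in% names(analytes)),
            dt > 0, run_length > dt, noise_sd >= 0, noise_rsd >= 0,
            pcis_level > 0)
  if (any(analytes$rt <= 0) || any(analytes$rt >= run_length)) {
    abort("analyte retention times must lie inside the run",
          class = "pcisr_validation_error")
  }
  sc <- structure(
    list(run_length = run_length, dt = dt, analytes = analytes,
         pcis_name = pcis_name, pcis_level = pcis_level,
         noise_sd = noise_sd, noise_rsd = noise_rsd,
         suppression = suppression, profiles = profiles,
         pcis_shares_suppression = isTRUE(pcis_shares_suppression),
         sil_rt_offset = sil_rt_offset, seed = as.integer(seed)),
    class = "sim_scenario")
  validate_scenario_suppression(sc, cf = 1)
  sc
}

validate_scenario_suppression <- function(scenario, cf) {
  grid <- scenario_grid(scenario)
  models <- c(list(scenario$suppression), scenario$profiles)
  for (m in models) {
    if (!is.null(m) && any(suppression_factor(m, grid, cf) <= 0)) {
      abort("suppression model reaches <= 0 inside the run",
            class = "pcisr_validation_error")
    }
  }
  invisible(scenario)
}

scenario_grid <- function(scenario) {
  seq(0, scenario$run_length, by = scenario$dt)
}

# Additive + proportional Gaussian noise, clamped at zero.
add_noise <- function(clean, scenario) {
  sdv <- scenario$noise_sd + scenario$noise_rsd * clean
  if (all(sdv == 0)) return(clean)
  pmax(0, clean + rnorm(length(clean), 0, sdv))
}

# --- unseeded internals (used inside simulate_dataset's single RNG scope) --

sim_infusion_ <- function(scenario, cf = 1, sample_id = "infusion",
                          label = scenario$pcis_name,
                          suppression = scenario$suppression,
                          precursor_mz = 350.3, product_mz = 269.2) {
  t <- scenario_grid(scenario)
  clean <- scenario$pcis_level * suppression_factor(suppression, t, cf)
  trace_tbl(t, add_noise(clean, scenario), label = label,
            sample_id = sample_id, precursor_mz = precursor_mz,
            product_mz = product_mz)
}

sim_analyte_ <- function(scenario, analyte, amount, cf = 1,
                         sample_id = "sample", rt_shift = 0,
                         suppression = scenario$suppression,
                         label = NULL) {
  if (is.character(analyte)) {
    analyte <- scenario$analytes[scenario$analytes$name == analyte, ]
  }
  stopifnot(nrow(analyte) == 1, amount >= 0)
  t <- scenario_grid(scenario)
  rt <- analyte$rt + rt_shift
  shape <- exp(-(t - rt)^2 / (2 * analyte$peak_sigma^2))
  clean_unsup <- analyte$gain * amount * shape
  clean <- clean_unsup * suppression_factor(suppression, t, cf)
  out <- trace_tbl(t, add_noise(clean, scenario),
                   label = label %||% analyte$name, sample_id = sample_id,
                   precursor_mz = analyte_mz(analyte$name)[1],
                   product_mz = analyte_mz(analyte$name)[2])
  attr(out, "true_area") <- sum(clean_unsup)  # point-sum, as integrated
  out
}

# Deterministic synthetic Q1/Q3 assignment per label.
analyte_mz <- function(name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 397
  c(300 + h / 10, 150 + h / 10)
}

#' Simulate a PCIS infusion trace
#'
#' Constant infusion at the scenario's PCIS level, multiplied by the
#' suppression profile at the given concentration factor, plus noise.
#' Reproducible: the scenario seed is applied on each call.
#'
#' @param scenario A [sim_scenario()].
#' @param cf Concentration factor of the injected matrix (0 = neat).
#' @param sample_id,label Identifiers for the returned trace.
#' @return A trace tibble.
#' @export
simulate_infusion_trace <- function(scenario, cf = 1,
                                    sample_id = "infusion",
                                    label = scenario$pcis_name) {
  validate_scenario_suppression(scenario, cf)
  withr::with_seed(scenario$seed,
                   sim_infusion_(scenario, cf, sample_id, label))
}

#' Simulate an analyte elution trace
#'
#' A Gaussian elution peak of the named analyte at the stated amount,
#' multiplied by the suppression profile, plus noise. The ground-truth
#' suppression-free point-sum area is attached as attribute `"true_area"`.
#'
#' @inheritParams simulate_infusion_trace
#' @param analyte Analyte name (a row of `scenario$analytes`).
#' @param amount Amount in arbitrary units (peak height =
#'   `gain * amount`).
#' @return A trace tibble with attribute `true_area`.
#' @export
simulate_analyte_trace <- function(scenario, analyte, amount, cf = 1,
                                   sample_id = "sample") {
  validate_scenario_suppression(scenario, cf)
  withr::with_seed(scenario$seed,
                   sim_analyte_(scenario, analyte, amount, cf, sample_id))
}
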