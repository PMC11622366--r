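#' Run configuration
#'
#' Processing parameters shared by the correction pipeline. Defaults follow
#' common practice for PCIS-corrected MRM processing: a 3-point moving
#' average, peak integration down to 99% below the apex, and a Pearson
#' correlation of 0.95 between infusion profiles as the threshold for two
#' analytes to share a PCIS.
#'
#' @param smoothing_window Odd number of points for the moving average
#'   (default 3).
#' @param integration_height_fraction Fraction of the apex height that
#'   bounds the integrated region, in (0, 1); the default 0.99 includes
#'   points down to 1% of the apex.
#' @param correlation_window Length-2 numeric, `(t_start, t_end)` minutes of
#'   the high-suppression zone used for infusion-profile correlation
#'   (`NULL` until set; it is a property of the chromatographic gradient).
#' @param pcis_share_threshold Pearson r at or above which two analytes may
#'   share a PCIS (default 0.95).
#' @param resample_step Uniform grid step in minutes, or `"auto"` to use the
#'   median inter-scan interval of the PCIS trace.
#' @param below_lloq_policy Handling of scans where the PCIS signal is below
#'   its LLOQ: `"mask"` (drop from the corrected trace), `"interpolate"`
#'   (bridge the PCIS gap linearly), or `"clamp"` (divide by the LLOQ).
#' @param area_times_dt Multiply point-sum areas by the grid step for
#'   time-based units (default `FALSE`; all workflow comparisons are ratios
#'   of areas on one grid, so the point sum suffices).
#'
#' @return A list with class `"pcis_run_config"`.
#' @export
run_config <- function(smoothing_window = 3,
                       integration_height_fraction = 0.99,
                       correlation_window = NULL,
                       pcis_share_threshold = 0.95,
                       resample_step = "auto",
                       below_lloq_policy = c("mask", "interpolate", "clamp"),
                       area_times_dt = FALSE) {
  below_lloq_policy <- match.arg(below_lloq_policy)
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    abort("smoothing_window must be an odd integer >= 1",
          class = "pcisr_validation_error")
  }
  if (!(integration_height_fraction > 0 && integration_height_fraction < 1)) {
    abort("integration_height_fraction must be in (0, 1)",
          class = "pcisr_validation_error")
  }
  if (!(pcis_share_threshold > 0 && pcis_share_threshold <= 1)) {
    abort("pcis_share_threshold must be in (0, 1]",
          class = "pcisr_validation_error")
  }
  if (!identical(resample_step, "auto")) {
    if (!is.numeric(resample_step) || resample_step <= 0) {
      abort("resample_step must be a positive number of minutes or \"auto\"",
            class = "pcisr_validation_error")
    }
  }
  if (!is.null(correlation_window)) {
    if (length(correlation_window) != 2 ||
        correlation_window[1] >= correlation_window[2]) {
      abort("correlation_window must be (t_start, t_end) with t_start < t_end",
            class = "pcisr_validation_error")
    }
  }
  structure(
    list(smoothing_window = as.integer(smoothing_window),
         integration_height_fraction = integration_height_fraction,
         correlation_window = correlation_window,
         pcis_share_threshold = pcis_share_threshold,
         resample_step = resample_step,
         below_lloq_policy = below_lloq_policy,
         area_times_dt = isTRUE(area_times_dt)),
    class = "pcis_run_config"
  )
}

#' Read a run configuration file
#'
#' Parses a YAML configuration with three sections: `run` (processing
#' parameters, see [run_config()]; omitted keys take the defaults),
#' `targets` (one entry per quantified compound) and `pcis` (one entry per
#' infused standard). Each target names the PCIS that corrects it; a target
#' referencing an undeclared PCIS is an error.
#'
#' Target fields: `name`, `precursor_mz`, `product_mz`, `expected_rt`,
#' `rt_window`, optional `polarity`, `pcis`, `istd`, `double_peak`.
#' PCIS fields: `name`, `precursor_mz`, `product_mz`, optional `polarity`,
#' `lloq` (computed from the data when absent) and `noise_window`
#' (`[t_start, t_end]` minutes of the pre-run, diverted-to-waste segment).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `run` (a `pcis_run_config`), `targets`
#'   (tibble) and `pcis` (tibble).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "pcisr_io_error")
  }
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw$run %||% list())

  if (is.null(raw$targets) || length(raw$targets) == 0) {
    abort("config declares no targets", class = "pcisr_validation_error")
  }
  targets <- purrr::map_dfr(raw$targets, function(t) {
    tibble::tibble(
      name = t$name %||% abort("target without a name",
                               class = "pcisr_validation_error"),
      precursor_mz = as.numeric(t$precursor_mz),
      product_mz = as.numeric(t$product_mz),
      polarity = t$polarity %||% "positive",
      expected_rt = as.numeric(t$expected_rt),
      rt_window = as.numeric(t$rt_window),
      pcis_name = t$pcis %||% NA_character_,
      istd_name = t$istd %||% NA_character_,
      double_peak = isTRUE(t$double_peak)
    )
  })
  if (any(is.na(targets$expected_rt)) || any(targets$expected_rt <= 0) ||
      any(is.na(targets$rt_window)) || any(targets$rt_window <= 0)) {
    abort("every target needs expected_rt > 0 and rt_window > 0",
          class = "pcisr_validation_error")
  }
  check_transitions(targets, "target")

  pcis <- purrr::map_dfr(raw$pcis %||% list(), function(p) {
    nw <- p$noise_window %||% c(NA_real_, NA_real_)
    tibble::tibble(
      name = p$name %||% abort("pcis entry without a name",
                               class = "pcisr_validation_error"),
      precursor_mz = as.numeric(p$precursor_mz),
      product_mz = as.numeric(p$product_mz),
      polarity = p$polarity %||% "positive",
      lloq = as.numeric(p$lloq %||% NA_real_),
      noise_start = as.numeric(nw[1]),
      noise_end = as.numeric(nw[2])
    )
  })
  if (nrow(pcis) == 0) {
    pcis <- tibble::tibble(name = character(), precursor_mz = numeric(),
                           product_mz = numeric(), polarity = character(),
                           lloq = numeric(), noise_start = numeric(),
                           noise_end = numeric())
  }
  if (nrow(pcis) > 0) {
    check_transitions(pcis, "pcis")
    bad_nw <- !is.na(pcis$noise_start) & !is.na(pcis$noise_end) &
      pcis$noise_start >= pcis$noise_end
    if (any(bad_nw)) {
      abort("pcis noise_window must have t_start < t_end",
            class = "pcisr_validation_error")
    }
  }
  dangling <- setdiff(stats::na.omit(targets$pcis_name), pcis$name)
  if (length(dangling) > 0) {
    abort(paste0("target references undeclared PCIS: ",
                 paste(dangling, collapse = ", ")),
          class = "pcisr_reference_error")
  }
  list(run = cfg, targets = targets, pcis = pcis)
}

check_transitions <- function(df, what) {
  if (any(is.na(df$precursor_mz)) || any(df$precursor_mz <= 0) ||
      any(is.na(df$product_mz)) || any(df$product_mz <= 0)) {
    abort(paste0("every ", what,
                 " needs positive precursor_mz and product_mz"),
          class = "pcisr_validation_error")
  }
  invisible(df)
}
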