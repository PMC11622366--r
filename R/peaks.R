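#' Locate a peak apex inside a retention-time window
#'
#' Finds the maximum of the trace within the half-open window
#' `[expected_rt - rt_window, expected_rt + rt_window)`. Ties are broken to
#' the earliest time. A zero maximum is reported as a no-signal flag, not
#' an error.
#'
#' @param trace A single trace tibble (raw or corrected; the `ratio` column
#'   is used when present, otherwise `intensity`).
#' @param expected_rt Expected retention time in minutes.
#' @param rt_window Half-width of the search window in minutes.
#' @return A one-row tibble: `index` (row index into the trace), `time`,
#'   `value`, `no_signal`.
#' @export
locate_apex <- function(trace, expected_rt, rt_window) {
  v <- peak_values(trace)
  t <- trace$time_min
  in_win <- t >= expected_rt - rt_window & t < expected_rt + rt_window
  if (!any(in_win)) {
    abort(sprintf("empty RT window [%g, %g) on trace",
                  expected_rt - rt_window, expected_rt + rt_window),
          class = "pcisr_window_error")
  }
  cand <- which(in_win)
  vv <- v[cand]
  if (all(is.na(vv))) {
    abort("all points masked in the RT window", class = "pcisr_data_error")
  }
  best <- cand[which.max(vv)]  # which.max: first (earliest) maximum, skips NA
  tibble::tibble(index = best, time = t[best], value = v[best],
                 no_signal = v[best] <= 0)
}

peak_values <- function(trace) {
  if ("ratio" %in% names(trace)) trace$ratio else trace$intensity
}

#' Integrate a peak by the height-fraction rule
#'
#' The integrated region is the maximal contiguous run of points around the
#' apex whose value stays at or above
#' `(1 - height_fraction) * apex_value`; with the default
#' `height_fraction = 0.99` points are included down to 1% of the apex
#' height ("99% below maximum"). The area is the plain sum of the included
#' point values; masked (`NA`) points terminate extension in their
#' direction and are counted in `n_masked_in_bounds`, as are any
#' below-LLOQ-flagged points inside the bounds.
#'
#' @param trace A single trace tibble (`ratio` used when present, else
#'   `intensity`; a `below_lloq` column, if present, feeds the masked
#'   count).
#' @param apex_index Row index of the apex (e.g. from [locate_apex()]).
#' @param height_fraction Fraction of the apex height defining the
#'   inclusion threshold, in (0, 1); default 0.99.
#' @param area_times_dt Multiply the point-sum area by the grid step.
#' @param source Provenance tag stored in the result (`"raw"` or
#'   `"corrected"`).
#' @return A one-row `Peak` tibble: `apex_time`, `apex_value`,
#'   `left_index`, `right_index`, `left_time`, `right_time`, `n_points`,
#'   `area`, `n_masked_in_bounds`, `source`, `no_signal`.
#' @export
#' @examples
#' tr <- trace_tbl(0:4, c(1, 10, 100, 10, 1), label = "x")
#' integrate_height_fraction(tr, apex_index = 3, height_fraction = 0.90)
integrate_height_fraction <- function(trace, apex_index,
                                      height_fraction = 0.99,
                                      area_times_dt = FALSE,
                                      source = "raw") {
  v <- peak_values(trace)
  check_height_fraction(height_fraction)
  apex_index <- as.integer(apex_index)
  apex_value <- v[apex_index]
  if (is.na(apex_value) || apex_value <= 0) {
    return(empty_peak(trace, apex_index, source))
  }
  # tiny relative slack so a point sitting exactly at the threshold is
  # included despite fp representation of (1 - height_fraction)
  threshold <- (1 - height_fraction) * apex_value - 1e-12 * apex_value
  n <- length(v)
  n_masked <- 0L

  left <- apex_index
  while (left > 1) {
    nxt <- v[left - 1]
    if (is.na(nxt)) { n_masked <- n_masked + 1L; break }
    if (nxt < threshold) break
    left <- left - 1
  }
  right <- apex_index
  while (right < n) {
    nxt <- v[right + 1]
    if (is.na(nxt)) { n_masked <- n_masked + 1L; break }
    if (nxt < threshold) break
    right <- right + 1
  }
  build_peak(trace, v, apex_index, left, right, n_masked, source,
             area_times_dt)
}

check_height_fraction <- function(height_fraction) {
  if (!(height_fraction > 0 && height_fraction < 1)) {
    abort("height_fraction must be in (0, 1)",
          class = "pcisr_validation_error")
  }
}

build_peak <- function(trace, v, apex_index, left, right, n_masked, source,
                       area_times_dt) {
  left <- as.integer(left)
  right <- as.integer(right)
  idx <- left:right
  if ("below_lloq" %in% names(trace)) {
    n_masked <- n_masked + sum(trace$below_lloq[idx], na.rm = TRUE)
  }
  area <- sum(v[idx])
  if (isTRUE(area_times_dt)) {
    area <- area * median(diff(trace$time_min))
  }
  tibble::tibble(
    apex_time = trace$time_min[apex_index],
    apex_value = v[apex_index],
    left_index = left, right_index = right,
    left_time = trace$time_min[left], right_time = trace$time_min[right],
    n_points = right - left + 1L,
    area = area,
    n_masked_in_bounds = n_masked,
    source = source,
    no_signal = FALSE
  )
}

empty_peak <- function(trace, apex_index, source) {
  apex_index <- as.integer(apex_index)
  tibble::tibble(
    apex_time = trace$time_min[apex_index],
    apex_value = peak_values(trace)[apex_index],
    left_index = apex_index, right_index = apex_index,
    left_time = trace$time_min[apex_index],
    right_time = trace$time_min[apex_index],
    n_points = 0L, area = 0,
    n_masked_in_bounds = 0L, source = source, no_signal = TRUE
  )
}

# Double-peak integration: two partially resolved isomers (e.g. a 1-/2-
# monoacylglycerol pair interconverting on column) are integrated as one
# region spanning both apices, saddle included.
integrate_double_peak <- function(trace, expected_rt, rt_window,
                                  height_fraction = 0.99,
                                  area_times_dt = FALSE, source = "raw") {
  v <- peak_values(trace)
  apex1 <- locate_apex(trace, expected_rt, rt_window)
  if (apex1$no_signal) return(empty_peak(trace, apex1$index, source))
  p1 <- integrate_height_fraction(trace, apex1$index, height_fraction,
                                  source = source)
  t <- trace$time_min
  in_win <- which(t >= expected_rt - rt_window & t < expected_rt + rt_window)
  outside_run <- setdiff(in_win, p1$left_index:p1$right_index)
  threshold <- (1 - height_fraction) * apex1$value
  cand <- outside_run[!is.na(v[outside_run]) & v[outside_run] >= threshold]
  if (length(cand) == 0) return(p1)  # no resolved second apex
  apex2 <- cand[which.max(v[cand])]
  p2 <- integrate_height_fraction(trace, apex2, height_fraction,
                                  source = source)
  left <- min(p1$left_index, p2$left_index)
  right <- max(p1$right_index, p2$right_index)
  build_peak(trace, v, apex1$index, left, right,
             0L, source, area_times_dt)
}

#' Quantify one target on raw and PCIS-corrected traces
#'
#' Locates the apex on the raw trace inside the target's RT window, then
#' integrates the raw trace and (when supplied) the corrected trace by the
#' height-fraction rule. The apex time found on the raw trace is reused on
#' the corrected trace, so the two areas describe the same chromatographic
#' peak; the integration bounds themselves are determined independently on
#' each trace. Targets flagged `double_peak` integrate one region spanning
#' both isomer apices.
#'
#' @param raw A single uniform (smoothed) trace tibble.
#' @param corrected Optional `pcis_corrected` tibble from [pcis_correct()].
#' @param target One row of a targets table (see [read_run_config()]).
#' @param config A [run_config()].
#' @return A `Peak` tibble with one row per available source
#'   (`"raw"`, `"corrected"`), plus `sample_id` and `name` columns.
#' @export
quantify_target <- function(raw, corrected = NULL, target,
                            config = run_config()) {
  raw <- single_trace(raw, "raw trace")
  hf <- config$integration_height_fraction
  tdt <- config$area_times_dt
  dbl <- isTRUE(target$double_peak)

  if (dbl) {
    raw_peak <- integrate_double_peak(raw, target$expected_rt,
                                      target$rt_window, hf, tdt, "raw")
  } else {
    apex <- locate_apex(raw, target$expected_rt, target$rt_window)
    raw_peak <- if (apex$no_signal) empty_peak(raw, apex$index, "raw") else
      integrate_height_fraction(raw, apex$index, hf, tdt, "raw")
  }
  peaks <- raw_peak
  if (!is.null(corrected)) {
    if (dbl) {
      cor_peak <- integrate_double_peak(corrected, target$expected_rt,
                                        target$rt_window, hf, tdt,
                                        "corrected")
    } else {
      ci <- which.min(abs(corrected$time_min - raw_peak$apex_time))
      cv <- peak_values(corrected)[ci]
      cor_peak <- if (is.na(cv) || cv <= 0) {
        empty_peak(corrected, ci, "corrected")
      } else {
        integrate_height_fraction(corrected, ci, hf, tdt, "corrected")
      }
    }
    peaks <- dplyr::bind_rows(peaks, cor_peak)
  }
  tibble::tibble(sample_id = raw$sample_id[1], name = target$name, peaks)
}

#' Run the full correction-and-quantification pipeline
#'
#' For every sample in `traces` and every entry of the target list:
#' extracts the analyte and assigned PCIS transitions, resamples both onto
#' a uniform grid (step from the PCIS trace when `resample_step = "auto"`),
#' smooths, derives the PCIS LLOQ (stated value, or the LLOQ rule applied
#' to the PCIS trace using its noise window against the rest of the run),
#' computes the scan-by-scan ratio, and integrates raw and corrected peaks.
#'
#' @param traces A trace tibble covering one or more samples.
#' @param targets,pcis Target and PCIS tables (see [read_run_config()]).
#' @param config A [run_config()].
#' @param tol Transition-match tolerance in Th.
#' @param keep_traces Keep the processed raw/corrected traces and peak
#'   bounds for each (sample, target) in the `"details"` attribute (used
#'   by [render_chromatograms()]).
#' @return A peak tibble, one row per (sample, target, source): areas,
#'   apex RT, below-LLOQ counts inside the integration bounds, and flags.
#'   [write_quant_report()] reshapes it to one row per (sample, target).
#' @export
quantify_targets <- function(traces, targets, pcis, config = run_config(),
                             tol = 0.05, keep_traces = FALSE) {
  traces <- validate_traces(traces)
  samples <- unique(traces$sample_id)
  details <- list()
  out <- purrr::map_dfr(samples, function(sid) {
    sample_traces <- dplyr::filter(traces, .data$sample_id == sid)

    pcis_ready <- list()
    for (i in seq_len(nrow(pcis))) {
      p <- pcis[i, ]
      ptr <- match_transitions(sample_traces, p, tol = tol)
      dt <- if (identical(config$resample_step, "auto"))
        median_scan_interval(ptr) else config$resample_step
      ptr <- smooth_traces(resample_uniform(ptr, dt),
                           config$smoothing_window)
      lloq <- if (!is.na(p$lloq)) p$lloq else {
        noise <- window_traces(ptr, p$noise_start, p$noise_end)
        infusion <- dplyr::filter(ptr, .data$time_min >= p$noise_end)
        compute_lloq(infusion, noise)$value
      }
      pcis_ready[[p$name]] <- list(trace = ptr, lloq = lloq, dt = dt)
    }

    purrr::map_dfr(seq_len(nrow(targets)), function(j) {
      tg <- targets[j, ]
      atr <- match_transitions(sample_traces, tg, tol = tol)
      has_pcis <- !is.na(tg$pcis_name)
      dt <- if (has_pcis) pcis_ready[[tg$pcis_name]]$dt else
        if (identical(config$resample_step, "auto"))
          median_scan_interval(atr) else config$resample_step
      atr <- smooth_traces(resample_uniform(atr, dt),
                           config$smoothing_window)
      corrected <- NULL
      if (has_pcis) {
        pr <- pcis_ready[[tg$pcis_name]]
        corrected <- pcis_correct(atr, pr$trace, pr$lloq,
                                  policy = config$below_lloq_policy)
      }
      peaks <- quantify_target(atr, corrected, tg, config)
      if (keep_traces) {
        details[[paste(sid, tg$name, sep = "/")]] <<- list(
          raw = atr, corrected = corrected, peaks = peaks)
      }
      peaks
    })
  })
  if (keep_traces) attr(out, "details") <- details
  out
}
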