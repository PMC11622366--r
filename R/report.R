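#' Write the quantification data report
#'
#' Reshapes the long peak table from [quantify_targets()] to one row per
#' (sample, target) — raw area, PCIS-corrected area, apex retention time,
#' number of below-LLOQ scans inside the corrected integration bounds,
#' and a no-signal flag — and writes it as CSV.
#'
#' @param peaks Peak tibble from [quantify_targets()].
#' @param path Output CSV path (`NULL` to skip writing).
#' @return The wide report tibble, invisibly when written.
#' @export
write_quant_report <- function(peaks, path = NULL) {
  raw <- dplyr::filter(peaks, .data$source == "raw")
  cor <- dplyr::filter(peaks, .data$source == "corrected")
  report <- raw |>
    dplyr::transmute(.data$sample_id, .data$name,
                     apex_rt = .data$apex_time,
                     raw_area = .data$area,
                     no_signal = .data$no_signal)
  if (nrow(cor) > 0) {
    report <- report |>
      dplyr::left_join(
        dplyr::transmute(cor, .data$sample_id, .data$name,
                         corrected_area = .data$area,
                         n_below_lloq = .data$n_masked_in_bounds,
                         corrected_no_signal = .data$no_signal),
        by = c("sample_id", "name"))
  }
  if (!is.null(path)) {
    readr::write_csv(report, path)
    return(invisible(report))
  }
  report
}

#' Render a before/after chromatogram gallery
#'
#' Writes a PDF with one page per (sample, target): the raw trace and the
#' PCIS-corrected trace around the peak, with the integration bounds
#' marked, so peak integration can be checked visually and the input
#' parameters adapted when needed.
#'
#' @param quant Result of [quantify_targets()] called with
#'   `keep_traces = TRUE`.
#' @param path Output PDF path.
#' @param margin Minutes of context shown either side of the integration
#'   bounds.
#' @return A list with `path` and `n_pages`, invisibly.
#' @export
render_chromatograms <- function(quant, path, margin = 0.5) {
  details <- attr(quant, "details")
  if (is.null(details)) {
    abort("run quantify_targets(..., keep_traces = TRUE) first",
          class = "pcisr_validation_error")
  }
  grDevices::pdf(path, width = 8, height = 5, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (key in names(details)) {
    print(correction_page_plot(details[[key]], key, margin))
  }
  invisible(list(path = path, n_pages = length(details)))
}

correction_page_plot <- function(detail, title, margin = 0.5) {
  raw_peak <- dplyr::filter(detail$peaks, .data$source == "raw")
  lo <- raw_peak$left_time - margin
  hi <- raw_peak$right_time + margin
  raw_df <- dplyr::filter(detail$raw, .data$time_min >= lo,
                          .data$time_min <= hi) |>
    dplyr::transmute(.data$time_min, value = .data$intensity,
                     panel = "raw (counts)")
  df <- raw_df
  bounds <- dplyr::transmute(raw_peak, panel = "raw (counts)",
                             left = .data$left_time,
                             right = .data$right_time)
  if (!is.null(detail$corrected)) {
    cor_peak <- dplyr::filter(detail$peaks, .data$source == "corrected")
    cor_df <- dplyr::filter(detail$corrected, .data$time_min >= lo,
                            .data$time_min <= hi) |>
      dplyr::transmute(.data$time_min, value = .data$ratio,
                       panel = "PCIS-corrected (ratio)")
    df <- dplyr::bind_rows(df, cor_df)
    if (nrow(cor_peak) > 0 && !cor_peak$no_signal) {
      bounds <- dplyr::bind_rows(
        bounds,
        dplyr::transmute(cor_peak, panel = "PCIS-corrected (ratio)",
                         left = .data$left_time,
                         right = .data$right_time))
    }
  }
  df$panel <- factor(df$panel, levels = unique(df$panel))
  bounds$panel <- factor(bounds$panel, levels = levels(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_vline(data = bounds,
                        ggplot2::aes(xintercept = .data$left),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(data = bounds,
                        ggplot2::aes(xintercept = .data$right),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(title = title, x = "retention time (min)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}
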