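#' Build a trace tibble
#'
#' The universal signal object of the package is a long tibble of MRM
#' chromatogram points: one row per scan, one trace per combination of
#' `sample_id` and `label`. All times are in minutes, intensities in
#' detector counts (or dimensionless ratio units after correction).
#'
#' @param time_min Numeric vector of retention times in minutes, strictly
#'   increasing within a trace.
#' @param intensity Numeric vector of intensities, same length as `time_min`.
#'   Negative values are clamped to zero with a warning.
#' @param label Compound / transition label (non-empty string).
#' @param sample_id Injection identifier.
#' @param precursor_mz,product_mz Q1 and Q3 m/z of the monitored transition
#'   (Th, positive).
#' @param polarity `"positive"` or `"negative"`.
#'
#' @return A tibble with columns `sample_id`, `label`, `precursor_mz`,
#'   `product_mz`, `polarity`, `time_min`, `intensity`.
#' @export
#' @examples
#' trace_tbl(c(0, 0.5, 1), c(10, 20, 15), label = "AEA", sample_id = "s1",
#'           precursor_mz = 348.3, product_mz = 62.1)
trace_tbl <- function(time_min, intensity, label, sample_id = "sample",
                      precursor_mz = NA_real_, product_mz = NA_real_,
                      polarity = "positive") {
  out <- tibble::tibble(
    sample_id = sample_id,
    label = label,
    precursor_mz = precursor_mz,
    product_mz = product_mz,
    polarity = polarity,
    time_min = as.numeric(time_min),
    intensity = as.numeric(intensity)
  )
  validate_traces(out)
}

trace_cols <- c("sample_id", "label", "precursor_mz", "product_mz",
                "polarity", "time_min", "intensity")

#' Validate a trace tibble
#'
#' Checks the trace invariants per `(sample_id, label)` group: at least two
#' points, strictly increasing time axis, non-negative intensities. Negative
#' intensities (detectors occasionally baseline-subtract below zero) are
#' clamped to 0 with a warning rather than rejected.
#'
#' @param traces A trace tibble (see [trace_tbl()]).
#' @param min_points Minimum points per trace (default 2).
#' @return The validated (possibly clamped) tibble, invisibly classed.
#' @export
validate_traces <- function(traces, min_points = 2) {
  missing <- setdiff(c("sample_id", "label", "time_min", "intensity"),
                     names(traces))
  if (length(missing) > 0) {
    abort(paste0("trace table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pcisr_schema_error")
  }
  if (nrow(traces) == 0) {
    abort("trace table is empty", class = "pcisr_schema_error")
  }
  if (any(is.na(traces$time_min)) || any(is.na(traces$intensity))) {
    abort("trace table contains missing time or intensity values",
          class = "pcisr_data_error")
  }
  if (any(traces$intensity < 0)) {
    n_neg <- sum(traces$intensity < 0)
    warn(paste0(n_neg, " negative intensity value(s) clamped to 0"))
    traces$intensity <- pmax(traces$intensity, 0)
  }
  bad <- traces |>
    dplyr::group_by(.data$sample_id, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      monotone = all(diff(.data$time_min) > 0),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n < min_points | !.data$monotone)
  if (nrow(bad) > 0) {
    abort(paste0("invalid trace(s) (need >= ", min_points,
                 " points and a strictly increasing time axis): ",
                 paste(bad$sample_id, bad$label, sep = "/", collapse = ", ")),
          class = "pcisr_data_error")
  }
  traces
}

#' Read / write delimited trace tables
#'
#' A simple plain-text interchange format for chromatogram traces: one row
#' per scan with columns `sample_id`, `label`, `precursor_mz`, `product_mz`,
#' `time_min`, `intensity` (an optional `polarity` column defaults to
#' positive). Writing then reading is the identity on times and intensities.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @return For `read_trace_table()`, a validated trace tibble.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pcisr_io_error")
  }
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- suppressWarnings(reader(path, show_col_types = FALSE))
  required <- c("sample_id", "label", "precursor_mz", "product_mz",
                "time_min", "intensity")
  missing <- setdiff(required, names(df))
  if (nrow(df) == 0) {
    abort(paste0("empty trace table: ", path), class = "pcisr_schema_error")
  }
  if (length(missing) > 0) {
    abort(paste0("trace table ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pcisr_schema_error")
  }
  if (!"polarity" %in% names(df)) df$polarity <- "positive"
  validate_traces(dplyr::select(df, dplyr::all_of(trace_cols)))
}

#' @rdname read_trace_table
#' @param traces A trace tibble.
#' @export
write_trace_table <- function(traces, path) {
  traces <- validate_traces(traces)
  if (!"polarity" %in% names(traces)) traces$polarity <- "positive"
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(dplyr::select(traces, dplyr::all_of(trace_cols)), path)
  invisible(path)
}

# Split a trace tibble into a named list of single traces ("sample/label").
trace_split <- function(traces) {
  key <- paste(traces$sample_id, traces$label, sep = "/")
  split(traces, factor(key, levels = unique(key)))
}

# Single-trace accessor with a clear error when the selection is ambiguous.
single_trace <- function(traces, what = "trace") {
  n_tr <- dplyr::n_distinct(traces$sample_id, traces$label)
  if (n_tr != 1) {
    abort(paste0("expected exactly one ", what, ", got ", n_tr,
                 " (filter on sample_id/label first)"),
          class = "pcisr_data_error")
  }
  traces
}
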