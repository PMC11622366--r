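#' Correlate infusion suppression profiles
#'
#' Computes pairwise Pearson correlations between the infusion traces of a
#' set of candidate analytes over a stated time window (typically the
#' high-suppression zone late in the gradient). Analytes whose infusion
#' profiles correlate strongly respond alike to matrix effect and can
#' share a single PCIS.
#'
#' @param traces Trace tibble with one infusion trace per analyte label
#'   (>= 2 labels). Traces are windowed to `[t_start, t_end)` and
#'   interpolated onto a shared grid before correlating.
#' @param t_start,t_end Correlation window bounds in minutes.
#' @return An object of class `pcis_cor`: the correlation matrix (`$r`,
#'   labels x labels, diagonal 1), the window, and any pairs that failed
#'   (constant signal). `tidy()` returns the long pair table;
#'   `autoplot()` draws the matrix.
#' @export
suppression_correlation <- function(traces, t_start, t_end) {
  win <- window_traces(validate_traces(traces), t_start, t_end)
  parts <- split(win, win$label)
  labels <- sort(names(parts))
  if (length(labels) < 2) {
    abort("need at least 2 analyte labels to correlate",
          class = "pcisr_validation_error")
  }
  lo <- max(purrr::map_dbl(parts, ~ min(.x$time_min)))
  hi <- min(purrr::map_dbl(parts, ~ max(.x$time_min)))
  if (lo >= hi) {
    abort("infusion traces do not overlap inside the window",
          class = "pcisr_alignment_error")
  }
  dt <- median(diff(parts[[1]]$time_min))
  grid <- seq(lo, hi, by = dt)
  signals <- purrr::map(parts[labels], function(tr) {
    approx(tr$time_min, tr$intensity, xout = grid)$y
  })

  n <- length(labels)
  r <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(r) <- 1
  failed <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- tryCatch(pearson_r(signals[[i]], signals[[j]]),
                      pcisr_constant_signal_error = function(e) NA_real_)
      if (is.na(val)) {
        failed <- c(failed, paste(labels[i], labels[j], sep = " ~ "))
      }
      r[i, j] <- r[j, i] <- val
    }
  }
  structure(list(r = r, window = c(t_start, t_end), failed = failed),
            class = "pcis_cor")
}

#' @export
tidy.pcis_cor <- function(x, ...) {
  as.data.frame.table(x$r, responseName = "r", stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(label_a = "Var1", label_b = "Var2")
}

#' @export
print.pcis_cor <- function(x, ...) {
  cat(sprintf("Suppression-profile correlation over [%g, %g) min\n",
              x$window[1], x$window[2]))
  print(round(x$r, 3))
  if (length(x$failed) > 0) {
    cat("failed (constant signal):", paste(x$failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Group analytes that can share a PCIS
#'
#' Partitions analytes into groups that can be corrected by the same PCIS,
#' using a deterministic greedy procedure on the suppression-profile
#' correlation matrix: repeatedly pick the unassigned analyte with the
#' most unassigned partners at or above the threshold (ties broken
#' alphabetically) as a group seed and absorb those partners; analytes with
#' no qualifying partner become singleton groups. The number of groups is
#' the estimated number of distinct PCIS compounds needed. Only positive
#' correlations at or above the threshold qualify.
#'
#' @param corr A `pcis_cor` object (or a plain symmetric correlation matrix
#'   with dimnames).
#' @param threshold Pearson r required to share a PCIS (default 0.95).
#' @return An object of class `pcis_grouping`: `$groups` (named list of
#'   label vectors, named by seed), `$threshold`, `$n_pcis_needed`.
#' @export
group_by_pcis <- function(corr, threshold = 0.95) {
  r <- if (inherits(corr, "pcis_cor")) corr$r else as.matrix(corr)
  labels <- sort(rownames(r))
  r <- r[labels, labels, drop = FALSE]
  unassigned <- labels
  groups <- list()
  while (length(unassigned) > 0) {
    n_partners <- vapply(unassigned, function(lab) {
      sum(r[lab, setdiff(unassigned, lab)] >= threshold, na.rm = TRUE)
    }, numeric(1))
    # most partners, alphabetical tie-break (unassigned is kept sorted)
    seed <- unassigned[which.max(n_partners)]
    partners <- setdiff(unassigned, seed)
    partners <- partners[!is.na(r[seed, partners]) &
                           r[seed, partners] >= threshold]
    groups[[seed]] <- c(seed, partners)
    unassigned <- setdiff(unassigned, groups[[seed]])
  }
  structure(list(groups = groups, threshold = threshold,
                 n_pcis_needed = length(groups)),
            class = "pcis_grouping")
}

#' @export
tidy.pcis_grouping <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(members, seed) {
    tibble::tibble(label = members, seed = seed,
                   group = match(seed, names(x$groups)))
  })
}

#' @export
print.pcis_grouping <- function(x, ...) {
  cat(sprintf("PCIS grouping at r >= %g: %d PCIS compound(s) needed\n",
              x$threshold, x$n_pcis_needed))
  for (seed in names(x$groups)) {
    cat(sprintf("  [%s] %s\n", seed, paste(x$groups[[seed]],
                                           collapse = ", ")))
  }
  invisible(x)
}

#' Mean and RSD of an infusion signal
#'
#' Signal stability statistics of a (smoothed) constant-infusion trace
#' over a half-open window: the mean intensity and the relative standard
#' deviation `100 * sd / mean` (sample standard deviation, n - 1).
#'
#' @param trace A single trace tibble.
#' @param t_start,t_end Optional window bounds in minutes (default: whole
#'   trace).
#' @return A one-row tibble: `mean_intensity`, `rsd`, `n`.
#' @export
infusion_signal_stats <- function(trace, t_start = NULL, t_end = NULL) {
  tr <- single_trace(trace)
  if (!is.null(t_start)) tr <- window_traces(tr, t_start, t_end)
  if (nrow(tr) < 3) {
    abort("need at least 3 points for signal statistics",
          class = "pcisr_validation_error")
  }
  m <- mean(tr$intensity)
  if (m == 0) {
    abort("zero mean intensity: RSD undefined",
          class = "pcisr_validation_error")
  }
  tibble::tibble(mean_intensity = m, rsd = 100 * sd(tr$intensity) / m,
                 n = nrow(tr))
}

#' Matrix effect induced by the PCIS itself
#'
#' Infusing a PCIS adds material to the ion source and can itself suppress
#' the analytes. This is quantified as the percent ratio of each analyte's
#' peak area while infusing the PCIS solution to its mean area while
#' infusing blank solvent (measured in replicate).
#'
#' @param areas_with_pcis Tibble with columns `name`, `area`: one area per
#'   analyte measured during PCIS infusion.
#' @param areas_blank_infusion Tibble with columns `name`, `area`: the
#'   blank-infusion replicates (e.g. triplicate) per analyte.
#' @return A tibble with `name` and `me_pct` per analyte; the across-analyte
#'   mean is in the `"mean_me"` attribute (and is the `mean(out$me_pct)`).
#' @export
pcis_induced_matrix_effect <- function(areas_with_pcis,
                                       areas_blank_infusion) {
  blank <- areas_blank_infusion |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(blank_mean = mean(.data$area), .groups = "drop")
  if (any(blank$blank_mean <= 0)) {
    abort("blank-infusion mean area must be > 0 for every analyte",
          class = "pcisr_validation_error")
  }
  missing <- setdiff(areas_with_pcis$name, blank$name)
  if (length(missing) > 0) {
    abort(paste0("no blank-infusion areas for: ",
                 paste(missing, collapse = ", ")),
          class = "pcisr_reference_error")
  }
  out <- areas_with_pcis |>
    dplyr::inner_join(blank, by = "name") |>
    dplyr::mutate(me_pct = 100 * .data$area / .data$blank_mean) |>
    dplyr::select("name", "me_pct")
  attr(out, "mean_me") <- mean(out$me_pct)
  out
}

#' PCIS concentration scan
#'
#' Combines, for each candidate PCIS concentration, the three criteria of
#' concentration optimization: (i) mean intensity and RSD of the isocratic
#' infusion signal, (ii) the matrix effect the PCIS infusion itself induces
#' on the analytes, and (iii) the number of scans of the PCIS signal during
#' a matrix injection that drop below the LLOQ in the analyte elution
#' region. The choice of concentration is left to the user: low enough to
#' limit cost and induced suppression, high enough for a stable signal
#' that stays above the LLOQ.
#'
#' @param entries A list with one element per concentration, each a list
#'   with fields `concentration` (ng/mL), `infusion` (isocratic infusion
#'   trace), `plasma_pcis` (PCIS trace during a matrix injection),
#'   `areas_with_pcis` and `areas_blank` (tibbles `name`/`area`, see
#'   [pcis_induced_matrix_effect()]).
#' @param stats_window Length-2 minutes: window of the isocratic infusion
#'   trace used for mean/RSD.
#' @param noise_window Length-2 minutes: pre-run diverted-to-waste segment
#'   of the matrix injection, used for the LLOQ noise branch.
#' @param count_window Length-2 minutes: analyte elution region in which
#'   sub-LLOQ scans are counted.
#' @param smoothing_window Moving-average width applied before statistics
#'   and counting (default 3).
#' @return A tibble with one row per concentration: `concentration`,
#'   `mean_intensity`, `rsd`, `induced_me`, `lloq`, `n_below_lloq`.
#' @export
concentration_scan <- function(entries, stats_window, noise_window,
                               count_window, smoothing_window = 3) {
  purrr::map_dfr(entries, function(e) {
    infusion <- smooth_traces(e$infusion, smoothing_window)
    stats <- infusion_signal_stats(infusion, stats_window[1],
                                   stats_window[2])
    plasma <- smooth_traces(e$plasma_pcis, smoothing_window)
    noise <- window_traces(plasma, noise_window[1], noise_window[2])
    lloq <- compute_lloq(window_traces(infusion, stats_window[1],
                                       stats_window[2]), noise)
    me <- pcis_induced_matrix_effect(e$areas_with_pcis, e$areas_blank)
    lloq_value <- lloq$value
    tibble::tibble(
      concentration = e$concentration,
      mean_intensity = stats$mean_intensity,
      rsd = stats$rsd,
      induced_me = attr(me, "mean_me"),
      lloq = lloq_value,
      n_below_lloq = count_below_lloq(plasma, lloq_value,
                                      count_window[1], count_window[2])
    )
  })
}
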