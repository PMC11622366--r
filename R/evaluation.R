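# Sample (n - 1) coefficient of variation, in percent.
cv_pct <- function(x) 100 * sd(x) / mean(x)

# Coefficient of determination without summary.lm's perfect-fit warning.
rsquared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Method 1: matrix effect and precision across diverse matrices
#'
#' For each compound (typically a spiked stable-isotope-labeled standard),
#' the matrix effect in every matrix sample is its peak area divided by its
#' peak area in neat solution at the MID concentration, in percent. ME
#' percentages are pooled across all samples and levels; the mean is the
#' compound's matrix effect and the CV across samples/levels its
#' precision. Computed separately for raw and PCIS-corrected areas, an
#' effective correction drives the mean toward 100% and shrinks the CV.
#'
#' @param areas Tibble with columns `name`, `source` (`"raw"` /
#'   `"corrected"`), `sample_id`, `area`, and optionally `level` /
#'   `replicate` (carried through to the per-sample table).
#' @param neat_mid Tibble with columns `name`, `source`, `area`: the neat
#'   reference area per compound and response type.
#' @return A list of class `pcis_method1`: `$per_sample` (one ME% row per
#'   input area) and `$summary` (per `name` x `source`: `mean_me`, `cv`,
#'   `n`).
#' @export
method1_across_matrices <- function(areas, neat_mid) {
  neat <- dplyr::rename(neat_mid, neat_area = "area")
  if (any(neat$neat_area <= 0)) {
    abort("neat MID reference areas must be > 0",
          class = "pcisr_validation_error")
  }
  missing <- dplyr::anti_join(dplyr::distinct(areas, .data$name, .data$source),
                              neat, by = c("name", "source"))
  if (nrow(missing) > 0) {
    abort(paste0("missing neat reference for: ",
                 paste(missing$name, missing$source, sep = "/",
                       collapse = ", ")),
          class = "pcisr_reference_error")
  }
  per_sample <- areas |>
    dplyr::inner_join(neat, by = c("name", "source")) |>
    dplyr::mutate(me_pct = 100 * .data$area / .data$neat_area) |>
    dplyr::select(-"neat_area")
  summary <- per_sample |>
    dplyr::group_by(.data$name, .data$source) |>
    dplyr::summarise(mean_me = mean(.data$me_pct),
                     cv = cv_pct(.data$me_pct),
                     n = dplyr::n(), .groups = "drop")
  structure(list(per_sample = per_sample, summary = summary),
            class = "pcis_method1")
}

#' @export
tidy.pcis_method1 <- function(x, ...) x$per_sample

#' @export
glance.pcis_method1 <- function(x, ...) x$summary

#' @export
print.pcis_method1 <- function(x, ...) {
  cat("Matrix effect across matrices (Method 1)\n")
  print(x$summary)
  invisible(x)
}

#' Method 2: matrix effect along a concentration-factor series
#'
#' When only one matrix source is available, its concentration factor (CF)
#' can be varied instead: the matrix effect at each CF is the mean
#' replicate peak area at that CF divided by the area in neat solution, in
#' percent. Without correction the ME typically falls as the matrix is
#' concentrated; after PCIS correction it should sit near 100% at every
#' CF.
#'
#' @param points Tibble with columns `name`, `source`, `cf`, `area` (and
#'   optionally `replicate`).
#' @param neat_areas Tibble with columns `name`, `source`, `area`.
#' @return A tibble: `name`, `source`, `cf`, `me_pct`, `n_replicates`.
#' @export
method2_cf_series <- function(points, neat_areas) {
  neat <- dplyr::rename(neat_areas, neat_area = "area")
  if (any(neat$neat_area <= 0)) {
    abort("neat reference areas must be > 0",
          class = "pcisr_validation_error")
  }
  missing <- dplyr::anti_join(dplyr::distinct(points, .data$name,
                                              .data$source),
                              neat, by = c("name", "source"))
  if (nrow(missing) > 0) {
    abort(paste0("missing neat reference for: ",
                 paste(missing$name, missing$source, sep = "/",
                       collapse = ", ")),
          class = "pcisr_reference_error")
  }
  points |>
    dplyr::group_by(.data$name, .data$source, .data$cf) |>
    dplyr::summarise(area = mean(.data$area), n_replicates = dplyr::n(),
                     .groups = "drop") |>
    dplyr::inner_join(neat, by = c("name", "source")) |>
    dplyr::mutate(me_pct = 100 * .data$area / .data$neat_area) |>
    dplyr::select("name", "source", "cf", "me_pct", "n_replicates")
}

#' Method 3: dilution linearity of endogenous analytes
#'
#' Needs neither diverse matrices nor isotope-labeled standards: across a
#' matrix dilution series the endogenous analyte's peak area should be
#' proportional to the concentration factor. Performance is judged by (i)
#' the coefficient of determination of an unweighted least-squares fit of
#' area on CF (replicates pooled into the fit) and (ii) the CV of the
#' per-injection ratios area / CF.
#'
#' @param points Tibble with columns `name`, `source`, `cf`, `area` (and
#'   optionally `replicate`); at least 4 distinct CFs per compound.
#' @return A tibble per `name` x `source`: `r2`, `cv_area_over_cf`,
#'   `slope`, `intercept`, `n`.
#' @export
method3_dilution_linearity <- function(points) {
  points |>
    dplyr::group_by(.data$name, .data$source) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$cf) < 4) {
        abort(paste0("need >= 4 distinct concentration factors (",
                     key$name, "/", key$source, ")"),
              class = "pcisr_validation_error")
      }
      fit <- lm(area ~ cf, data = df)
      tibble::tibble(
        r2 = rsquared(df$area, stats::fitted(fit)),
        cv_area_over_cf = cv_pct(df$area / df$cf),
        slope = coef(fit)[["cf"]],
        intercept = coef(fit)[["(Intercept)"]],
        n = nrow(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Fit a linear calibration curve
#'
#' Unweighted ordinary least squares of response on concentration with a
#' free intercept, as used for both neat and matrix calibration series.
#' Exactly two points give the closed-form two-point line with a warning
#' (no residual degrees of freedom).
#'
#' @param data Either a data frame with columns `concentration` and
#'   `response`, or a numeric vector of concentrations.
#' @param response Numeric responses when `data` is a vector.
#' @param response_type Which response was fitted: `"raw_area"`,
#'   `"pcis_corrected_area"` or `"sil_area_ratio"`.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r2`, `n`, `response_type` and the underlying `lm` in
#'   `$model`. `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' fit_calibration(c(1, 2, 3), c(2, 4, 6))
fit_calibration <- function(data, response = NULL,
                            response_type = c("raw_area",
                                              "pcis_corrected_area",
                                              "sil_area_ratio")) {
  response_type <- match.arg(response_type)
  if (is.data.frame(data)) {
    conc <- data$concentration
    resp <- data$response
  } else {
    conc <- as.numeric(data)
    resp <- as.numeric(response)
  }
  if (length(conc) != length(resp) || length(conc) < 2) {
    abort("need >= 2 matched concentration/response points",
          class = "pcisr_validation_error")
  }
  if (sd(conc) == 0) {
    abort("degenerate calibration: concentrations have zero variance",
          class = "pcisr_validation_error")
  }
  if (length(conc) == 2) {
    warn("calibration fit on exactly 2 points: slope is the two-point line")
  }
  fit <- lm(resp ~ conc)
  r2 <- if (length(conc) == 2) 1 else rsquared(resp, stats::fitted(fit))
  structure(
    list(slope = coef(fit)[["conc"]],
         intercept = coef(fit)[["(Intercept)"]],
         r2 = r2, n = length(conc),
         response_type = response_type, model = fit),
    class = "calibration_fit"
  )
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "concentration"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 n = x$n, response_type = x$response_type)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration fit (%s): response = %.6g * conc + %.6g (r2 = %.4f, n = %d)\n",
    x$response_type, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Compare matrix and neat calibration slopes (parallelism)
#'
#' Quantifying matrix samples against a neat-solution calibration curve is
#' only defensible when the two curves are parallel. The slope difference
#' is `100 * (slope_matrix / slope_neat - 1)` percent; its magnitude is
#' judged preferable up to 15%, acceptable up to 20% (both bounds
#' inclusive), and outside beyond that.
#'
#' @param fit_matrix,fit_neat `calibration_fit` objects (or bare numeric
#'   slopes).
#' @return A one-row tibble: `slope_matrix`, `slope_neat`,
#'   `pct_difference`, `verdict`.
#' @export
compare_slopes <- function(fit_matrix, fit_neat) {
  sm <- if (inherits(fit_matrix, "calibration_fit")) fit_matrix$slope else
    as.numeric(fit_matrix)
  sn <- if (inherits(fit_neat, "calibration_fit")) fit_neat$slope else
    as.numeric(fit_neat)
  if (sn == 0) {
    abort("neat slope is zero: slope difference undefined",
          class = "pcisr_validation_error")
  }
  pct <- 100 * (sm / sn - 1)
  tibble::tibble(slope_matrix = sm, slope_neat = sn, pct_difference = pct,
                 verdict = slope_verdict(pct))
}

#' @rdname compare_slopes
#' @param pct_difference Numeric vector of percent slope differences.
#' @export
slope_verdict <- function(pct_difference) {
  dplyr::case_when(
    abs(pct_difference) <= 15 ~ "preferable",
    abs(pct_difference) <= 20 ~ "acceptable",
    TRUE ~ "outside"
  )
}

#' SIL internal-standard area-ratio response
#'
#' The conventional comparator to PCIS correction: the response is the
#' analyte peak area divided by the peak area of its spiked stable
#' isotope-labeled internal standard.
#'
#' @param analyte_area,istd_area Numeric vectors of peak areas.
#' @return `analyte_area / istd_area`.
#' @export
sil_ratio_response <- function(analyte_area, istd_area) {
  if (any(istd_area <= 0)) {
    abort("ISTD area must be > 0", class = "pcisr_validation_error")
  }
  analyte_area / istd_area
}
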