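#' Lower limit of quantification for a PCIS signal
#'
#' The LLOQ of a PCIS signal is set at either 1% of its mean intensity
#' during constant infusion under isocratic conditions, or 10 times the
#' mean noise measured while the infusion line is still diverted to waste
#' (typically the first ~0.5 min of an injection), whichever is lowest.
#' When the two branches tie, the noise branch is reported.
#'
#' @param infusion_trace Trace tibble (or numeric vector of intensities)
#'   covering the isocratic infusion segment.
#' @param noise_trace Trace tibble (or numeric vector) covering the
#'   diverted-to-waste segment.
#' @return A one-row tibble with columns `value`, `rule_used`
#'   (`"one_percent_of_infusion_mean"` or `"ten_times_noise"`),
#'   `infusion_mean`, `noise_mean`.
#' @export
#' @examples
#' compute_lloq(rep(10000, 10), rep(5, 10))  # 10x noise wins: LLOQ 50
compute_lloq <- function(infusion_trace, noise_trace) {
  inf <- trace_intensities(infusion_trace)
  noi <- trace_intensities(noise_trace)
  if (length(inf) == 0 || length(noi) == 0) {
    abort("infusion and noise traces must be nonempty",
          class = "pcisr_validation_error")
  }
  infusion_mean <- mean(inf)
  noise_mean <- mean(noi)
  if (infusion_mean <= 0) {
    abort("infusion mean must be > 0 to define an LLOQ",
          class = "pcisr_validation_error")
  }
  one_pct <- 0.01 * infusion_mean
  ten_noise <- 10 * noise_mean
  # tie broken to the noise rule
  rule <- if (ten_noise <= one_pct) "ten_times_noise" else
    "one_percent_of_infusion_mean"
  tibble::tibble(
    value = min(one_pct, ten_noise),
    rule_used = rule,
    infusion_mean = infusion_mean,
    noise_mean = noise_mean
  )
}

trace_intensities <- function(x) {
  if (is.data.frame(x)) x$intensity else as.numeric(x)
}

#' Count scans below the LLOQ in a time window
#'
#' Counts points of a (smoothed) trace whose intensity is strictly below
#' the LLOQ within the half-open window `[t_start, t_end)` — e.g. the
#' elution region of the analytes, where every sub-LLOQ scan potentially
#' disturbs the ratio correction.
#'
#' @param trace A single trace tibble.
#' @param lloq LLOQ in counts.
#' @param t_start,t_end Window bounds in minutes.
#' @return Integer count.
#' @export
count_below_lloq <- function(trace, lloq, t_start, t_end) {
  tr <- window_traces(single_trace(trace), t_start, t_end)
  sum(tr$intensity < lloq)
}

#' PCIS-correct an analyte trace
#'
#' The core correction: the corrected signal is the scan-by-scan ratio of
#' the analyte intensity to the PCIS intensity. Because ionization
#' suppression acts multiplicatively on both signals at the same instant,
#' any shared suppression profile cancels exactly in the ratio.
#'
#' Scans where the PCIS signal falls below its LLOQ are unreliable; they
#' are flagged in `below_lloq` under every policy and handled per
#' `policy`: `"mask"` sets the ratio to `NA`, `"interpolate"` bridges the
#' PCIS gap linearly from the flanking valid scans (edge gaps extend the
#' nearest valid value) before taking the ratio, `"clamp"` divides by the
#' LLOQ itself.
#'
#' @param analyte,pcis Single uniform trace tibbles. When their grids
#'   differ, the PCIS trace is interpolated onto the analyte grid over the
#'   overlapping time span; non-overlapping spans are an error.
#' @param lloq PCIS lower limit of quantification in counts (a number or a
#'   row from [compute_lloq()]).
#' @param policy Sub-LLOQ handling: `"mask"` (default), `"interpolate"`,
#'   or `"clamp"`.
#' @return A tibble of class `pcis_corrected` with columns `sample_id`,
#'   `label`, `time_min`, `analyte`, `pcis`, `ratio`, `below_lloq`; the
#'   policy is kept in the `"policy"` attribute.
#' @export
pcis_correct <- function(analyte, pcis, lloq,
                         policy = c("mask", "interpolate", "clamp")) {
  policy <- match.arg(policy)
  analyte <- single_trace(analyte, "analyte trace")
  pcis <- single_trace(pcis, "PCIS trace")
  if (is.data.frame(lloq)) lloq <- lloq$value
  stopifnot(is.numeric(lloq), length(lloq) == 1, lloq >= 0)

  shared <- isTRUE(all.equal(analyte$time_min, pcis$time_min,
                             tolerance = 1e-9))
  if (!shared) {
    lo <- max(analyte$time_min[1], pcis$time_min[1])
    hi <- min(max(analyte$time_min), max(pcis$time_min))
    if (lo > hi) {
      abort("analyte and PCIS time spans do not overlap",
            class = "pcisr_alignment_error")
    }
    keep <- analyte$time_min >= lo & analyte$time_min <= hi
    analyte <- analyte[keep, ]
    if (nrow(analyte) < 2) {
      abort("analyte/PCIS overlap too short to correct",
            class = "pcisr_alignment_error")
    }
    p_int <- approx(pcis$time_min, pcis$intensity,
                    xout = analyte$time_min)$y
  } else {
    p_int <- pcis$intensity
  }

  below <- p_int < lloq
  if (all(below)) {
    abort("PCIS signal lost: entirely below the LLOQ",
          class = "pcisr_pcis_lost_error")
  }
  divisor <- p_int
  if (policy == "interpolate" && any(below)) {
    ok <- which(!below)
    divisor[below] <- approx(analyte$time_min[ok], p_int[ok],
                             xout = analyte$time_min[below], rule = 2)$y
  } else if (policy == "clamp") {
    divisor[below] <- lloq
  }
  ratio <- analyte$intensity / divisor
  if (policy == "mask") ratio[below] <- NA_real_

  out <- tibble::tibble(
    sample_id = analyte$sample_id,
    label = analyte$label,
    time_min = analyte$time_min,
    analyte = analyte$intensity,
    pcis = p_int,
    ratio = ratio,
    below_lloq = below
  )
  attr(out, "policy") <- policy
  attr(out, "lloq") <- lloq
  class(out) <- c("pcis_corrected", class(out))
  out
}
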