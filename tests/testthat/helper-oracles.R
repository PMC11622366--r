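# Independent oracles and tiny fixture builders used across the suite.

# Brute-force height-fraction integration: enumerate every contiguous run
# [l, r] containing the apex whose values all sit at or above the
# threshold, and keep the longest. NA values never qualify.
brute_force_bounds <- function(v, apex, height_fraction) {
  threshold <- (1 - height_fraction) * v[apex]
  best <- c(apex, apex)
  for (l in seq_len(apex)) {
    for (r in apex:length(v)) {
      vals <- v[l:r]
      if (!any(is.na(vals)) && all(vals >= threshold) &&
          (r - l) > (best[2] - best[1])) {
        best <- c(l, r)
      }
    }
  }
  best
}

brute_force_area <- function(v, apex, height_fraction) {
  b <- brute_force_bounds(v, apex, height_fraction)
  sum(v[b[1]:b[2]])
}

# A flat-grid single trace.
flat_trace <- function(intensity, dt = 1, label = "x", sample_id = "s1",
                       t0 = 0) {
  trace_tbl(t0 + (seq_along(intensity) - 1) * dt, intensity,
            label = label, sample_id = sample_id,
            precursor_mz = 100, product_mz = 50)
}

# A sampled Gaussian peak on a uniform grid.
gaussian_trace <- function(rt = 5, sigma = 0.1, height = 1000,
                           t = seq(0, 10, by = 0.02), label = "g",
                           sample_id = "s1") {
  trace_tbl(t, height * exp(-(t - rt)^2 / (2 * sigma^2)), label = label,
            sample_id = sample_id, precursor_mz = 100, product_mz = 50)
}

# Synthetic correlation matrix for the grouping worked example: m labels
# mutually correlated at r_in, plus extras correlated at r_out with every
# other label and r_pair with each other.
block_cor_matrix <- function(main = paste0("M", 1:6),
                             extra = c("GLY", "NADA"),
                             r_in = 0.97, r_out = 0.89, r_pair = 0.75) {
  labels <- c(main, extra)
  n <- length(labels)
  r <- matrix(r_out, n, n, dimnames = list(labels, labels))
  r[main, main] <- r_in
  r[extra, extra] <- r_pair
  diag(r) <- 1
  r
}
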