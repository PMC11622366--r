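---
title: "PCIS correction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCIS correction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcisr)
```

## The correction model

Electrospray ionization efficiency at time $t$ is modulated by co-eluting
matrix components. Writing $S(t) > 0$ for the instantaneous suppression
(or enhancement) factor, the measured signals of an analyte $a$ and a
postcolumn infused standard (PCIS) $p$ are

$$ y_a(t) = a(t)\,S(t) + \varepsilon_a(t), \qquad
   y_p(t) = p\,S(t) + \varepsilon_p(t), $$

where $a(t)$ is the clean elution peak, $p$ the constant infusion level
and $\varepsilon$ detector noise. Because $S(t)$ multiplies both signals
at the same scan, the corrected trace

$$ r(t) = \frac{y_a(t)}{y_p(t)} \approx \frac{a(t)}{p} $$

is free of any suppression the two signals share. This cancellation is
exact in the noise-free case and is asserted to machine precision in the
test suite. Two consequences shape everything downstream:

* **Scale covariance** — multiplying the PCIS level by $k$ divides every
  ratio by $k$. All evaluation statistics are therefore ratios of
  corrected areas measured on the same grid (matrix vs neat, area vs CF),
  which are invariant to $k$.
* **Failure mode** — the correction is only as good as the assumption
  that the PCIS shares the analyte's response to matrix effect. The
  exploration step quantifies that sharing before any correction is
  attempted.

## Pipeline order and numerical choices

The processing order is: extract MRM traces, resample to a uniform grid,
smooth, ratio, integrate.

* **Resampling** is linear interpolation, never extrapolating beyond the
  recorded span. The `"auto"` step is the median raw inter-scan interval
  of the PCIS trace, so analyte and PCIS land on one shared grid; when
  grids still differ, `pcis_correct()` interpolates the PCIS onto the
  analyte grid over the overlapping span and errors when there is no
  overlap.
* **Smoothing** is a centered moving average (default 3 points) whose
  window truncates at the trace edges; a window of 1 is the identity, and
  no value can leave the local input range. Smoothing precedes the ratio.
  Where $S(t)$ has curvature this ordering biases the ratio by
  $O((\Delta t\, S'/S)^2)$ — about 0.2% of a corrected area for the
  default simulator geometry — which is why the machine-precision
  cancellation checks run with the smoother disabled (window 1) or with
  a locally constant suppression factor.
* **Windows** are everywhere half-open, $[t_0, t_1)$, so adjacent windows
  never double-count a boundary scan.
* **Transitions** match when both Q1 and Q3 m/z lie within 0.05 Th (a
  unit-resolution quadrupole assumption), with a $10^{-9}$ Th guard so a
  key exactly at the boundary matches despite floating-point
  representation.
* **Peak integration** follows the height-fraction rule: the integrated
  region is the maximal contiguous run around the apex with values at or
  above $(1 - f)\times\text{apex}$; the default $f = 0.99$ means points
  down to 1% of the apex height are included. The area is the plain sum
  of point values, not a trapezoidal time integral — every comparison in
  the workflow is a ratio of areas on one grid, so the grid density
  cancels; a `run_config(area_times_dt = TRUE)` switch multiplies by the
  step for interoperability. Contiguity prevents detached noise spikes
  from joining a peak. The threshold carries a $10^{-12}\times$apex slack
  so values exactly at the threshold are included. Apex ties break to the
  earliest time; the apex is located on the raw trace and its time reused
  on the corrected trace so raw and corrected areas describe the same
  chromatographic peak, while the bounds themselves are re-derived on
  each trace.
* **Double peaks** (e.g. a 1-/2-monoacylglycerol isomer pair
  interconverting on column) integrate one region spanning both apices,
  saddle included.

## LLOQ and sub-LLOQ policy

The PCIS lower limit of quantification is
$\min(1\%\times\text{mean infusion signal},\ 10\times\text{mean pre-run
noise})$, the noise being measured over the first 0.5 min of an
injection while the infusion line is still diverted to waste. An exact
tie reports the noise branch. Scans where the PCIS falls below its LLOQ
make the ratio unreliable; they are always flagged, and handled by one of
three policies: `mask` (default — the ratio becomes `NA`, and a masked
point terminates peak extension on its side), `interpolate` (the PCIS gap
is bridged linearly from flanking valid scans; edge gaps extend the
nearest valid value) or `clamp` (divide by the LLOQ itself). Raising the
LLOQ can only add flags, never remove them.

## Grouping analytes to a PCIS

Suppression profiles are compared by Pearson correlation over a
user-chosen high-suppression window (the window is a property of the
gradient, not of the method). Grouping is greedy and deterministic:
repeatedly seed a group with the unassigned analyte that has the most
unassigned partners at $r \ge$ threshold (alphabetical tie-break) and
absorb those partners. Only positive correlations qualify — an
anti-correlated profile cannot be corrected by sharing that PCIS. The
group count is the estimated number of PCIS compounds the panel needs; it
is non-increasing as the threshold is relaxed and invariant to label
order.

## Evaluation statistics

All coefficients of variation use the sample (n−1) standard deviation
over the mean, ×100. Matrix effects are $100\times$ area ratios. Method 1
pools ME percentages across samples and levels (after normalizing areas
to the nominal level where levels differ); Method 3 pools replicates into
one unweighted fit of area on CF rather than fitting means, so replicate
scatter is reflected in $r^2$. Calibration fits are unweighted ordinary
least squares with a free intercept; a two-point fit degenerates to the
closed-form line with a warning. Slope-difference verdicts are inclusive
at their bounds: $|\Delta| \le 15\%$ preferable, $\le 20\%$ acceptable,
otherwise outside.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the five study designs with known ground
truth. Its suppression model is

$$ S(t, \mathrm{cf}) = (1+\mathrm{cf})^{-k}\,
   \Big(1 - \sum_j d_j\, e^{-(t-c_j)^2/2w_j^2}\Big), $$

i.e. Gaussian-shaped dips localized late in the run (the
high-suppression zone) times a concentration-factor term that decreases
as the matrix is concentrated and equals 1 for neat solution. This form
is a modeling choice: it reproduces the two qualitative phenomena the
designs need — localized dips and ME falling smoothly with CF — and
nothing more. Noise is additive Gaussian with standard deviation
`noise_sd + noise_rsd * clean_signal`, clamped at zero; peaks are
Gaussian; there is no retention-time drift, no baseline drift, no
isotope interference and no physically realistic ESI chemistry.
Consequently, passing tests demonstrate that the *algorithms* recover
designed truths, not that a real PCIS will share a real analyte's
suppression — that judgment is exactly what the exploration and
evaluation steps exist to make on real data.

Study conditions fixed by the default scenarios (all on a 15 min run
sampled every 0.02 min, peaks of sigma 0.03 min eluting at 11–13.5 min,
PCIS infusion at $10^5$ counts):

* **exploration** — 8 infused standards, 6 sharing one dip profile and 2
  with distinct profiles, 1% noise RSD; grouping at $r \ge 0.95$ yields
  3 groups.
* **concentration_scan** — candidate levels 25–300 ng/mL at 400 counts
  per ng/mL, constant additive noise of 25 counts (so the signal RSD
  falls as the level rises), one deep dip (depth 0.997), and a designed
  PCIS-induced ME interpolating from 82% at the lowest to 73% at the
  highest level. The diversion valve switches at 0.55 min so the 0–0.5
  min noise window is untouched by smoothing spill-over, and the
  diverted segment carries a small detector baseline (15 counts) whose
  noise is one fifth of it — without that, the LLOQ's noise branch is
  estimated from ~25 near-zero scans and jitters enough to obscure the
  designed monotone sub-LLOQ counts.
* **multi_matrix** — 9 matrices with per-matrix suppression factors drawn
  uniformly from [0.3, 1.0], a shared mild dip, 2% noise RSD, plus a
  neat reference; the designed across-matrix CV is the CV of the drawn
  factors.
* **cf_series** — CFs {0.25, 0.5, 1, 2, 3, 4, 5} in triplicate with
  $S = (1+\mathrm{cf})^{-1/2}$ and no dips (so the designed uncorrected
  ME is exactly $100\,(1+\mathrm{cf})^{-1/2}$), one spiked standard at
  constant amount and one endogenous analyte proportional to CF.
* **calibration_pair** — 7 levels in duplicate, neat vs matrix, a dip of
  depth 0.5 centered 0.15 min before the analyte so the clean
  suppression at the apex is 0.697, and a SIL internal standard eluting
  0.08 min earlier into the deeper flank (clean suppression 0.552) —
  reproducing the mechanism by which a slightly offset SIL
  over-corrects while the co-eluting PCIS does not.

Quantification designs state an explicit PCIS LLOQ (half the lowest
clean PCIS intensity in the design) so that the noise-free closure
property — pipeline output equals manifest expectation to $10^{-9}$ —
holds without masking.

All randomness flows from a single scenario seed; identical seeds give
bit-identical datasets. The standalone trace simulators re-seed on each
call, so repeated calls are reproducible by construction.

## File formats

mzML reading uses `mzR` (ProteoWizard backend); since that API does not
expose the stored time unit, the unit is read from the XML and seconds
are converted to minutes. mzML writing emits a standard chromatogram
list with uncompressed 64-bit float arrays and the sample/label embedded
in each chromatogram id, so write–read is the identity. The delimited
trace-table format (`sample_id`, `label`, `precursor_mz`, `product_mz`,
`time_min`, `intensity`) is the lightweight alternative. Configuration
is YAML with `run`, `targets` and `pcis` sections; omitted run keys take
the documented defaults (smoothing 3, height fraction 0.99, share
threshold 0.95, policy `mask`).

## Known limitations

* No baseline estimation or subtraction; the ratio step is the
  correction. Analytes with chemical background on their transition
  (the interference failure mode) surface as poor corrected statistics,
  not as a diagnosed cause.
* No correction for sample-preparation recovery or injection volume —
  those need a spiked internal (or external) standard, itself
  PCIS-corrected.
* Co-eluting peaks are not deconvolved beyond the double-peak union
  rule.
* Point-sum areas are grid-density dependent by design; compare areas
  only within one grid, or enable `area_times_dt`.
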