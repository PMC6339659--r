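---
title: "Quantifying lateral flow strips: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral flow strips: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement problem

A gold-nanoparticle lateral flow strip carries two printed lines: a test
line whose color depends on the analyte and a control line that captures
probe regardless of analyte, confirming flow. In the competitive format the
test line *fades* as analyte concentration rises, because analyte bound to
the probe antibodies blocks capture at the test line. A photograph of the
strip — smartphone in a darkbox, or a benchtop imager — is the raw datum;
the quantity of interest is the analyte concentration.

The chain implemented here is: pixel raster → darkness profile along the
flow axis → background-corrected band areas → control/test intensity ratio
→ linear calibration → concentration and detection limits. Normalizing by
the control line cancels strip-to-strip variation in probe load, exposure
and illumination, which is what makes a consumer camera usable at all.

## Signal model and densitometry

**Channel and polarity.** Nanoparticle bands are red/pink, so absorbance
contrast is strongest in the green channel; `to_signal_channel()` defaults
to green with `luminance` as fallback for grayscale imagers. Signal is
defined as darkness, `1 - value`, so bands are positive peaks and all
downstream math assumes maxima. Note that the measurement itself is
polarity-agnostic: whether the test line rises or falls with analyte only
changes the sign of the calibration slope, never the densitometry, so no
configuration beyond the choice of ratio is needed.

**Profile.** `extract_profile()` averages the central 60% of the strip
width at each flow position. The flanks are excluded because cut edges and
membrane borders carry artefacts; 60% is a compromise between noise
averaging and edge avoidance and can be overridden via `lane_geometry()`.

**Baseline.** Membrane background is not zero and often drifts along the
strip (wetting fronts, illumination gradients). The default
`flank_linear` corrector fits a straight line by iteratively clipping
values above the fit, which converges onto the band-free flanks and the
inter-band valley; it is exact whenever the true background is linear and
the bands occupy a minority of the profile. `rolling_min` (smoothed rolling
minimum) is offered for curved backgrounds; its window must be at least
three band widths or it erodes the bands themselves, hence the parameter
check. Corrected values are floored at zero.

**Band detection.** The corrected profile is smoothed with a moving
average one nominal band width wide (reflected boundaries), local maxima
are ranked by topographic prominence, and among all peak pairs whose
separation lies within ±25% of the expected line spacing (5 mm on these
strips) the pair with the largest summed prominence wins. The upstream
peak is the test line. Prominence-with-spacing-prior is deliberately
simple: with only two bands expected at a known distance, more elaborate
deconvolution adds failure modes without accuracy. Exact prominence ties
(within 1e-9) raise an ambiguity error rather than being broken silently.

**Quantity = integrated area.** Each band is integrated over a half-open
window of 1.5 band widths centred on its peak (0-based pixel intervals,
clipped to the profile). Area rather than peak height is used because
focus blur — the main difference between a phone and an imager — spreads a
band without changing its integral, and because with equal band sigmas the
area ratio equals the amplitude ratio exactly, which the synthetic tests
exploit. If more than 1% of ROI pixels sit at 0 or 1 before inversion the
measurement is flagged `saturated` but still computed.

**Resolution.** When px/mm is unknown it is estimated from the detected
tl–cl separation and the 5 mm physical spacing; the spacing is printed
hardware geometry and is the one reliable ruler in an uncontrolled photo.

**Orientation.** Canonical orientation places flow along the longer image
axis with the test line upstream. `auto` inference has to decide which
band is the control line from content alone; the rule adopted is that the
*more prominent* band is the control line, with an error raised when the
two are within 5% of each other. This rule is correct whenever the control
line is at least as strong as the test line — but in a competitive assay
the test line dominates at low analyte, so `auto` is only trustworthy on
known layouts. Batch pipelines photograph strips in a fixed template, so
`run_config()` defaults to the explicit `tl_first` hint and `auto` stays a
per-strip convenience.

## Calibration and detection limits

The ratio (normalized cl/tl by default, standardized tl/cl as the
reciprocal alternative) is regressed on concentration by ordinary least
squares over *individual replicates*, not per-concentration means — the
replicate scatter is the information the confidence intervals and limits
need. Per-concentration summaries use the sample SD (n − 1) and Student-t
intervals; with the small replicate counts typical of strip experiments
(3–5) the normal approximation would be noticeably anticonservative.

Detection limits follow the two standard blank-statistic constructions
(method 1: LOD = mean + 3·sd of blanks, LOQ = mean + 10·sd; method 2 via
the limit of blank with one-sided 95% z = 1.645 and the 1 nM calibrator
spread). Both are computed on the intensity-ratio scale, where the
formulas live, and then converted to nmol·L⁻¹ through the inverse fitted
line — the conversion route is stated in every report (`scale_note`)
because it is a genuine choice: direct concentration-scale statistics
would give different numbers. Inverse predictions below zero are returned
as-is with a `below_range` flag rather than censored, so blank-adjacent
limits remain algebraically consistent. With a negative slope
(standardized mode) the same algebraic inverse applies; the LOD ≤ LOQ
orderings are guaranteed on the intensity scale only.

## The synthetic generator: what it emulates, what it does not

`generate_strip()` renders darkness
`offset + slope·x + Σ A_k exp(−(x−μ_k)²/2σ²)` replicated across the strip
width, adds i.i.d. Gaussian pixel noise, clips to [0, 1], and stores the
analytic centers, areas (`A·σ·√(2π)`) and noiseless profile as a
manifest. Defaults — 120×30 px at 10 px/mm, bands at 4 and 9 mm, σ =
0.4 mm — mirror the physical strips (lines 5 mm apart) at a resolution a
phone comfortably exceeds. Every output is a pure function of (spec,
seed), restoring the caller's RNG state.

`generate_calibration_set()` targets a ratio `r = β₀ + β₁c + ε` per strip
and sets amplitudes `A_cl = A·r/(1+r)`, `A_tl = A/(1+r)`, so the analytic
cl/tl area ratio equals `r` *exactly* — ground truth by construction,
rather than through a mechanistic competitive-binding model whose own
parameters would need calibrating. Defaults are the assay's calibration
design (0, 1, 20, 40, 60, 80, 100 nM, five replicates), a true line of
β₀ = 0.5, β₁ = 0.02 per nM (keeping both amplitudes comfortably inside
(0, 1] across the design), and ratio noise SD 0.01, i.e. ~1–2% replicate
CV, typical of imaging densitometry under controlled lighting. Pixel
noise defaults to zero in scenarios so the ratio-level truth is exact;
set `pixel_noise_sd` (or write strips as quality-85 JPEG) to add
realistic image noise.

What the generator does *not* emulate: membrane texture, shadows,
perspective, uneven illumination beyond a linear gradient, band asymmetry
from chromatographic tailing, or saturation behaviour of real sensors.
Passing tests therefore demonstrate the correctness of the algorithms
under the stated signal model, not robustness to every field photograph;
real-image robustness rests on the baseline corrector and the ratio
normalization, and should be spot-checked on each new imaging setup.

## Numerical choices and degenerate inputs

- 0-based pixel positions and half-open `[start, stop)` windows
  everywhere.
- Peak-pair tie-break: none — ties within 1e-9 in summed prominence are
  an error, because silently picking one of two equally plausible layouts
  would corrupt the measurement.
- `flank_linear` iterates at most 60 clip-and-refit rounds, stopping when
  the fitted line moves by < 1e-12; on exactly linear backgrounds it
  converges in two rounds.
- Zero test-line intensity leaves the normalized ratio undefined (`NA`)
  and flags the strip; such rows are listed in the fit's rejects table
  and excluded from regression, which proceeds if at least two distinct
  concentrations survive.
- A calibration slope of exactly zero (constant ratios) makes the model
  non-invertible and inverse prediction errors out rather than returning
  infinities.
- Reports are written into per-run directories (`run-<timestamp>`), so a
  new analysis never overwrites an earlier report; two runs on identical
  inputs differ only in the timestamp line.

## Problem sizes used in validation

The shipped tests validate band localization on 100 seeded noisy strips
(SNR ≥ 10, requiring every center within 2 px of truth), slope recovery
and 95% CI coverage over 100 simulated calibration experiments at the
full design (35 strips each), and the limit formulas against hand-worked
values plus 1000 randomized ordering checks. The acceptance script runs a
single seeded experiment end-to-end plus 50 recovery replicates; all
sizes were chosen to estimate the relevant rates to a few percent.

## Known limitations

- Exactly two bands: multiplex strips with more lines are out of scope.
- Linear calibration only; no 4PL/logistic fit, no weighted least
  squares, no outlier rejection beyond undefined-ratio rejects.
- One strip per photograph; no multi-strip segmentation, lens or
  illumination correction.
- The `auto` orientation rule assumes the control line is the stronger
  band; use explicit hints otherwise.
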