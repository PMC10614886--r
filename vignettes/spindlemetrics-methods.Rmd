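---
title: "Methods: spindle fluorescence metrics and their validation"
author: "spindlemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle fluorescence metrics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemetrics)
```

# Scope and rationale

`spindlemetrics` quantifies kinesin-8 (KIF18A) function on the mitotic
spindle from multi-channel fluorescence images, time-lapse stacks,
plate-reader tables and growth curves. The original measurements of this
kind are made interactively (wide line tools and boxed plot-profiles in
Fiji, curve fitting in Prism) on images that are not publicly deposited,
which leaves two gaps this package closes: every step is specified
exactly (sampling, interpolation, normalization, initialization,
tie-breaks), and every step is validated by parameter recovery against a
synthetic-data generator whose ground truth is known in closed form.

# Coordinate and sampling conventions

Pixels are indexed 0-based with `(0, 0)` top-left; the centre of pixel
`k` lies at `k * pixelSize` micrometres, and annotation coordinates are
0-based pixel units with sub-pixel floats. Off-grid intensities are
bilinearly interpolated. A scan from `start` to `end` takes
`round(length_px) + 1` samples, uniformly spaced, spanning the endpoints
exactly — so a 6.5 µm scan at 0.1083 µm/px yields 61 samples, matching
the pixel-per-sample convention of interactive plot-profile tools. Wide
lines average `width_px` perpendicular offsets spaced one pixel apart,
symmetric about the line; the boxed pole-to-pole profile is the same
sampler with its width set by the box height (default 5 µm — the
interactive protocol fixes the height without stating it; the FWHM is
insensitive to this choice because the band's lateral envelope is
narrower) and the *mean* across the box, not the sum, is used at each
axial position (the two differ by a constant factor and the profile is
normalized afterwards, so the statistic is unchanged).

# The alignment statistic

The kinetochore (ACA) or DNA (DAPI) profile along the pole-to-pole axis
is normalized internally to its maximum and fitted with

$$I(x) = c + A \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right),$$

by bounded Levenberg–Marquardt, initialized from the profile moments
(centre = intensity-weighted mean above baseline, σ = weighted SD,
offset = minimum, amplitude = range), with σ bounded to the axis length
and the centre to the axis. The reported alignment metric is
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. An additive offset is
included although the interactive protocol does not state one:
cytoplasmic background is nonzero, and offset-free fits bias σ upward.
The fit is invariant to profile rescaling, so normalization is a
convention, not a numerical necessity. Non-converged fits (or σ at a
bound) are flagged on the result and excluded from summaries by the
caller, never silently dropped. The same operation serves ACA-stained
cancer lines and DAPI-based rescue experiments; only the channel choice
differs.

# Motor localization

Each 10-pixel-wide line scan runs from a γ-tubulin pole signal toward
the spindle centre. Channels are normalized to their own maxima; scans
are aligned by shifting whole samples so each γ-tubulin argmax sits at
distance 0 (integer shifts, because averaging is per pixel distance),
and averaged per distance over the scans that cover it. The
*distance to maximum* of the KIF18A channel is computed per scan — each
scan is one observation in the per-condition distribution — with ties
broken toward the pole and target maxima at or behind the γ-tubulin
peak clamped to 0 µm (the pole-accumulated, inhibited-like pattern).
The averaged profile's peak distance is also reported for comparison.
Scans from the two half-spindles of one cell are treated as independent
observations. Scan length defaults to 6.5 µm and is configurable.

# Time-lapse relocalization

KIF18A fluorescence within a rectangular spindle ROI is profiled along
the pole-to-pole axis (summed across the ROI height; the Final/Initial
ratio is invariant to sum-versus-mean for a fixed ROI), at an initial
timepoint (−1.5 min, before treatment) and a final one (+12 min).
Profiles are linearly resampled onto a fixed 101-point 0–100%
spindle-length grid to remove spindle-length differences between cells,
and divided pointwise. Grid points where the initial profile falls at or
below 1% of its maximum are masked; the ratio's trapezoidal area is
computed over segments whose endpoints are both unmasked (masked points
are never interpolated into the area) and requires ≥ 90% coverage. Two
areas are reported: the baseline-0 AUC (100 for a flat ratio of 1,
matching the common graphing-software default) and the area of
`|ratio − 1|`, which is 0 for no relocalization and grows with the
mid-spindle gap — the more interpretable discrimination statistic, used
for the treated-versus-control separation check.

# Population and pharmacology statistics

Mitotic index is `100 · Σ mitotic / Σ total` over fields, with
per-field percentages retained for replicate plotting; the multipolar
fraction counts mitotic cells with more than two poles (monopolar cells
count in the denominator only). Mitotic and pole-count labels are
inputs: the original scoring is by eye, and automating it is out of
scope. Proliferation fold change is final count over first count per
well, normalized to the mean control fold change *within the same
experiment batch*, making the statistic scale-invariant and pinning the
control batch mean at exactly 1. Expression level is mean spindle-ROI
intensity minus mean background-ROI intensity, normalized to the control
mean; negative corrected values are kept but flagged.

Percent inhibition is `100·(pos − sample)/(pos − neg)` with per-plate
control means (controls never shared across plates); values outside
[−20, 120] are flagged, not clipped. The four-parameter logistic
(variable-slope) model is fitted on log10 concentration with
initialization bottom = min y, top = max y, IC50 at the concentration
nearest 50% response, Hill = 1, and the Hill slope bounded to
[0.1, 10]; log-concentration fitting is numerically stable over 4-fold
serial dilutions. IC50 standard errors are delta-method propagated from
log10(IC50). A fit ending on a bound is flagged.

# The synthetic-data generator

The generator is the validation instrument: its defaults are the study
conditions, not tuning knobs. A scene renders four channels at pixel
centres: poles as isotropic 2D Gaussians (σ 0.4 µm), α-tubulin as a
stadium-shaped density around the pole-pole segment (σ 1.2 µm), the
kinetochore band as an axial Gaussian of σ = `kinetochoreSigma` times a
lateral envelope (σ 1.5 µm), and KIF18A as two mirrored axial peaks (σ
0.5 µm) at `kif18aPeakDistance` from each pole plus a faint (15%)
lattice term. True FWHM is `2.3548 · kinetochoreSigma` by construction.
Noise is Poisson on expected counts followed by additive Gaussian read
noise, both optional and fully seeded; noise-off renders are exact and
serve as oracles downstream. The default geometry is an 11 µm spindle
on a 0.1 µm grid (120×180 px) — typical of the transformed and
non-transformed epithelial lines this assay family targets — and
default amplitudes (kinetochore peak 120 a.u. over background 20, read
SD 3) put the kinetochore peak SNR near 10, defined as peak amplitude
over the noise SD at the peak. Absolute intensity scales and SNR are
not published for the original images; these defaults are an assumption
chosen once for realistic recoverability and stated here as such.

Time-lapses suppress the KIF18A channel within a growing half-width of
the spindle midpoint (smooth 0.2 µm edge) and redistribute exactly the
suppressed intensity to the poles, conserving total motor signal — an
idealization of inhibitor-induced relocalization under microtubule
flux. Plate tables, growth curves and count tables are direct draws
from the 4PL, exponential-growth and binomial models the analyses
assume.

What the generator does *not* emulate: 3D point-spread functions,
photobleaching, cell-to-cell shape variation, neighbouring cells,
chromosome-arm structure, or segmentation error. Passing recovery tests
therefore demonstrates correctness of the measurement pipeline under
the stated image-formation model, not robustness to every real-world
artefact.

# Numerical choices and degenerate inputs

Gaussian and 4PL fits use bounded Levenberg–Marquardt with tight
(1e-10–1e-14) convergence tolerances; flat profiles, empty scans,
coincident poles, all-masked ratio curves, zero-cell tables and missing
in-batch controls are rejected with explicit errors naming the cell,
batch or field involved. Argmax ties break to the first (pole-proximal)
sample. TIFF round trips are lossless for integer rasters (16-bit
pages) and float rasters are stored as scaled 32-bit with the scale in
the JSON sidecar.

# Validation problem sizes

The recovery studies run 20 noisy spindles per dispersion level
σ ∈ {1, 1.5, 2, 3} µm for the FWHM statistic (median within 5% of
truth), 30 scans per true peak distance ∈ {0, 2, 4} µm for localization
(noiseless within one pixel; noisy median error ≤ 0.3 µm), 10 control
versus 10 gap-expansion time-lapses for relocalization (deviation-AUC
ranges must not overlap), 100 plates per reported potency (8.2 and
41.3 nM; median IC50 within 10%), and 200 binomial count tables plus 12
well pairs for the estimators. These sizes give stable medians while
keeping the whole validation suite fast to re-run.

# Known limitations

Pole detection from γ-tubulin is a convenience helper (two brightest
separated maxima), not a validated detector; annotations take
precedence. The relocalization analysis assumes a registered, fixed ROI
(no drift correction or bleaching model). Integer-sample scan alignment
quantizes offsets at one pixel, which bounds the localization statistic's
resolution at the pixel size — visible in the recovery results, where
the noiseless error equals one pixel or less.
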