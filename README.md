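# spindlemetrics

Quantitative image- and assay-analysis for mitotic spindle studies of the
kinesin-8 motor KIF18A. KIF18A accumulates at kinetochore-microtubule
plus-ends, where it dampens microtubule dynamics and confines chromosomes
to the metaphase plate; losing or inhibiting the motor widens the
chromosome distribution, lengthens the spindle, arrests chromosomally
unstable tumour cells in mitosis and relocalizes the motor to the spindle
poles. `spindlemetrics` implements the full quantitative pipeline used to
measure those phenotypes, plus a synthetic-data generator with known
ground truth so every stage can be validated by parameter recovery.

## What it computes

- **Chromosome alignment (FWHM).** A boxed region along the pole-to-pole
  axis yields the kinetochore (ACA) or DNA (DAPI) intensity profile,
  normalized internally to its maximum and fitted with
  `I(x) = c + A·exp(−(x−μ)² / 2σ²)`. The reported statistic is the
  full width at half maximum, `FWHM = 2·sqrt(2·ln 2)·σ ≈ 2.3548·σ`,
  together with the spindle length (Euclidean pole-pole distance).
- **Motor localization.** 10-pixel-wide line scans from a γ-tubulin pole
  toward the spindle centre, each channel normalized to its own maximum,
  aligned on peak γ-tubulin and averaged per pixel distance; each scan
  contributes one *distance from pole to maximum KIF18A signal*.
- **Time-lapse relocalization.** Spindle-ROI KIF18A profiles at an
  initial (−1.5 min) and final (+12 min) timepoint, resampled to a
  0–100% spindle-length grid; the Final/Initial ratio curve and its
  trapezoidal area under the curve (and the area of `|ratio − 1|`).
- **Population statistics.** Mitotic index, multipolar-spindle fraction,
  background-subtracted spindle expression levels, and proliferation
  fold change normalized to an in-batch control.
- **ATPase pharmacology.** Percent inhibition
  `100·(pos − sample)/(pos − neg)` and a four-parameter logistic
  (variable-slope) fit `y = bottom + (top − bottom)/(1 + (IC50/x)^h)` on
  log10 concentration.

## Worked example

```r
library(spindlemetrics)

# A noise-free synthetic spindle: 11 um pole-pole axis, kinetochore band
# sigma = 1.5 um, KIF18A peaking 2 um from each pole.
scene <- SpindleScene(shotNoise = FALSE, readSD = 0, pixelSize = 0.1,
                      imageShape = c(120L, 180L),
                      poleA = c(3, 6), poleB = c(14, 6))
res <- generateSpindleImage(scene)

res$truth$true_fwhm
#> [1] 3.53223

align <- chromosomeAlignment(res$image, c(30, 60), c(140, 60))
align
#> AlignmentResult [cell]: FWHM 3.532 um, spindle 11.000 um

scan <- normalizeProfile(extractLineProfile(
  res$image, c(30, 60), c(95, 60), widthPx = 10,
  channels = c("gamma_tubulin", "kif18a")))
distanceToMax(scan)
#> [1] 2
```

The FWHM recovered by the full pipeline (3.532 µm) matches the
closed-form ground truth `2.3548 × 1.5 µm` of the generating scene, and
the line-scan analysis recovers the 2 µm pole-to-peak distance of the
rendered motor exactly. A dose-response fit works the same way:

```r
plate <- generateDoseResponse(trueIC50 = 8.2, hill = 1, cv = 0, seed = 1)
doseResponseAnalysis(plate)$fit
#> FourPLFit: IC50 8.2 nM (hill 1.00, bottom -0.0, top 100.0)
```

A command-line wrapper (`inst/scripts/spindlemetrics`) exposes the same
pipeline as subcommands (`simulate`, `align`, `localize`, `relocalize`,
`counts`, `growth`, `expression`, `doseresponse`) driven by a YAML
configuration; outputs are CSVs stamped with the package version and
config hash.

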