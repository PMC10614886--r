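# Shared fixtures: scenes are built in code, never stored on disk.

# Noise-free scene on a 0.1 um/px grid with poles at exact pixel centres.
cleanScene <- function(kinetochoreSigma = 1.5, kif18aPeakDistance = 2,
                       ...) {
  SpindleScene(poleA = c(3, 6), poleB = c(14, 6),
               kinetochoreSigma = kinetochoreSigma,
               kif18aPeakDistance = kif18aPeakDistance,
               shotNoise = FALSE, readSD = 0,
               pixelSize = 0.1, imageShape = c(120L, 180L), ...)
}

# Same geometry with the default Poisson + read noise (kinetochore peak
# SNR about 10).
noisyScene <- function(seed, kinetochoreSigma = 1.5,
                       kif18aPeakDistance = 2, ...) {
  SpindleScene(poleA = c(3, 6), poleB = c(14, 6),
               kinetochoreSigma = kinetochoreSigma,
               kif18aPeakDistance = kif18aPeakDistance,
               pixelSize = 0.1, imageShape = c(120L, 180L),
               seed = seed, ...)
}

# Pole positions of the helper scenes in 0-based pixels.
polePxA <- c(30, 60)
polePxB <- c(140, 60)

# Single-channel profile built directly from samples.
mkProfile <- function(values, spacing = 0.1, channel = "kinetochore") {
  v <- matrix(values, ncol = 1, dimnames = list(NULL, channel))
  new("IntensityProfile",
      positions = (seq_along(values) - 1) * spacing, values = v)
}

# Two-channel (gamma + target) scan profile from sample vectors.
mkScan <- function(gamma, target, spacing = 0.1) {
  v <- cbind(gamma_tubulin = gamma, kif18a = target)
  new("IntensityProfile",
      positions = (seq_along(gamma) - 1) * spacing, values = v)
}
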