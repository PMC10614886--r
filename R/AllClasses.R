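#' @import methods
NULL

CHANNEL_ROLES <- c("gamma_tubulin", "alpha_tubulin", "kinetochore", "kif18a")

#' Multi-channel spindle image
#'
#' A single-focal-plane fluorescence image of a mitotic spindle: one 2D
#' intensity raster per named channel role, sharing a pixel size.  Pixel
#' coordinates are 0-based with the centre of pixel \code{(0, 0)} at the
#' top-left; a point at pixel coordinate \code{k} lies at \code{k *
#' pixelSize} micrometres.  Intensities are arbitrary units, non-negative.
#'
#' @slot channels named list of numeric matrices (role -> raster), all of
#'   one shape.  Conventional roles are \code{gamma_tubulin} (poles),
#'   \code{alpha_tubulin} (spindle), \code{kinetochore} (ACA or DAPI band)
#'   and \code{kif18a} (motor).
#' @slot pixelSize micrometres per pixel (> 0).
#' @slot frameTime acquisition time in seconds relative to the start of a
#'   time-lapse; \code{NA} for fixed-cell images.
#' @export
setClass("SpindleImage",
  representation(channels = "list", pixelSize = "numeric",
                 frameTime = "numeric"),
  prototype(frameTime = NA_real_))

setValidity("SpindleImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel raster is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be a named list (role -> raster)")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims != dims[, 1]))
    return("all channel rasters must share one shape")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/px)")
  TRUE
})

#' Time-lapse stack of spindle images
#'
#' @slot frames list of \linkS4class{SpindleImage}, identical geometry.
#' @slot frameTimes acquisition times in minutes relative to treatment.
#' @export
setClass("SpindleStack",
  representation(frames = "list", frameTimes = "numeric"))

setValidity("SpindleStack", function(object) {
  if (length(object@frames) == 0L) return("stack must contain >= 1 frame")
  if (!all(vapply(object@frames, is, logical(1), "SpindleImage")))
    return("frames must be SpindleImage objects")
  if (length(object@frameTimes) != length(object@frames))
    return("frameTimes must have one entry per frame")
  if (is.unsorted(object@frameTimes, strictly = TRUE))
    return("frameTimes must be strictly increasing")
  TRUE
})

#' Parameters of a synthetic spindle scene
#'
#' Describes a two-pole spindle to be rendered by
#' \code{\link{generateSpindleImage}}: pole positions, the axial dispersion
#' of the kinetochore/DNA band, the distance from each pole at which the
#' KIF18A channel peaks (0 renders a pole-accumulated, inhibited-like
#' motor), per-channel amplitudes, background and noise model.
#'
#' @slot poleA,poleB pole positions in micrometres, \code{c(x, y)}.
#' @slot kinetochoreSigma axial standard deviation of the kinetochore band
#'   (um); the true alignment FWHM is \code{2*sqrt(2*log(2))} times this.
#' @slot kif18aPeakDistance distance (um) from each pole to the KIF18A
#'   intensity maximum; must not exceed half the pole-pole distance.
#' @slot channelAmplitudes named peak amplitudes (a.u.) for the roles in
#'   \code{gamma_tubulin}, \code{alpha_tubulin}, \code{kinetochore},
#'   \code{kif18a}.
#' @slot background additive background level (a.u.).
#' @slot shotNoise logical; apply Poisson noise to expected counts.
#' @slot readSD standard deviation of additive Gaussian read noise (a.u.).
#' @slot pixelSize micrometres per pixel.
#' @slot imageShape raster shape in pixels, \code{c(nrow, ncol)}.
#' @slot seed integer RNG seed used whenever noise is drawn.
#' @export
setClass("SpindleScene",
  representation(poleA = "numeric", poleB = "numeric",
                 kinetochoreSigma = "numeric",
                 kif18aPeakDistance = "numeric",
                 channelAmplitudes = "numeric", background = "numeric",
                 shotNoise = "logical", readSD = "numeric",
                 pixelSize = "numeric", imageShape = "integer",
                 seed = "integer"))

setValidity("SpindleScene", function(object) {
  if (length(object@poleA) != 2L || length(object@poleB) != 2L)
    return("poleA and poleB must be length-2 (x, y) in um")
  if (all(object@poleA == object@poleB))
    return("poleA and poleB must differ")
  if (object@kinetochoreSigma <= 0)
    return("kinetochoreSigma must be > 0")
  L <- sqrt(sum((object@poleB - object@poleA)^2))
  if (object@kif18aPeakDistance < 0 || object@kif18aPeakDistance > L / 2)
    return("kif18aPeakDistance must lie in [0, half pole-pole distance]")
  if (!all(CHANNEL_ROLES %in% names(object@channelAmplitudes)))
    return(paste("channelAmplitudes must name all of:",
                 paste(CHANNEL_ROLES, collapse = ", ")))
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    return("imageShape must be c(nrow, ncol), each >= 8 px")
  if (object@background < 0) return("background must be >= 0")
  if (object@readSD < 0) return("readSD must be >= 0")
  TRUE
})

#' Intensity profile along a scan axis
#'
#' Mean intensity per channel sampled at uniformly spaced positions along a
#' line or box axis, as produced by \code{\link{extractLineProfile}} and
#' \code{\link{extractBoxProfile}}.  Positions are micrometres from the
#' scan start (strictly increasing, uniform spacing).
#'
#' @slot positions micrometres along the scan axis.
#' @slot values numeric matrix, one row per position and one named column
#'   per channel role (a.u., or unitless once normalized).
#' @slot widthPx perpendicular averaging width in pixels.
#' @slot cellId identifier of the source cell/scan.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", values = "matrix",
                 widthPx = "numeric", cellId = "character"),
  prototype(widthPx = 1, cellId = NA_character_))

setValidity("IntensityProfile", function(object) {
  n <- length(object@positions)
  if (n < 2L) return("a profile needs >= 2 samples")
  d <- diff(object@positions)
  if (any(d <= 0)) return("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * max(d))
    return("positions must be uniformly spaced")
  if (nrow(object@values) != n)
    return("values must have one row per position")
  if (is.null(colnames(object@values)))
    return("values columns must be named by channel role")
  if (object@widthPx < 1) return("widthPx must be >= 1")
  TRUE
})

#' Gaussian fit of an intensity profile
#'
#' Least-squares fit of \code{offset + amplitude * exp(-(x - center)^2 /
#' (2 * sigma^2))}; \code{fwhm} is always \code{2*sqrt(2*log(2)) * sigma}.
#'
#' @slot amplitude,offset a.u.
#' @slot center,sigma,fwhm micrometres.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag; non-converged fits are
#'   reported, never silently dropped.
#' @export
setClass("GaussianFit",
  representation(amplitude = "numeric", center = "numeric",
                 sigma = "numeric", offset = "numeric", fwhm = "numeric",
                 rss = "numeric", converged = "logical"))

setValidity("GaussianFit", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (abs(object@fwhm - 2 * sqrt(2 * log(2)) * object@sigma) >
      1e-8 * max(1, object@fwhm))
    return("fwhm must equal 2*sqrt(2*log(2)) * sigma")
  TRUE
})

#' Per-cell chromosome alignment result
#'
#' @slot cellId cell identifier.
#' @slot fwhm chromosome-distribution FWHM (um).
#' @slot spindleLength pole-to-pole distance (um).
#' @slot fit the underlying \linkS4class{GaussianFit}.
#' @slot flags character vector of quality flags (e.g.
#'   \code{"fwhm_exceeds_spindle_length"}); empty when clean.
#' @export
setClass("AlignmentResult",
  representation(cellId = "character", fwhm = "numeric",
                 spindleLength = "numeric", fit = "GaussianFit",
                 flags = "character"),
  prototype(flags = character()))

setValidity("AlignmentResult", function(object) {
  if (object@spindleLength <= 0) return("spindleLength must be > 0")
  if (object@fwhm <= 0) return("fwhm must be > 0")
  TRUE
})

#' Aligned and averaged set of pole line scans
#'
#' Normalized line scans shifted by whole samples so that every
#' gamma-tubulin peak sits at distance 0, then averaged per distance over
#' the scans that cover it.
#'
#' @slot distances micrometres from the aligned gamma-tubulin peak (the
#'   common grid; may extend to negative values where shifted scans reach
#'   behind the pole).
#' @slot meanValues matrix of per-distance mean normalized intensity, one
#'   named column per channel.
#' @slot nScans number of scans contributing at each distance.
#' @slot offsets integer sample shift applied to each scan.
#' @slot distanceToMax per-scan distance from the gamma-tubulin peak to
#'   the maximum of the target channel (um, >= 0).
#' @slot targetChannel the channel whose peak distance is reported.
#' @export
setClass("AlignedScanSet",
  representation(distances = "numeric", meanValues = "matrix",
                 nScans = "integer", offsets = "integer",
                 distanceToMax = "numeric", targetChannel = "character"))

setValidity("AlignedScanSet", function(object) {
  if (any(object@distanceToMax < 0))
    return("distanceToMax must be >= 0")
  if (length(object@nScans) != length(object@distances))
    return("nScans must align with distances")
  TRUE
})

#' Time-lapse relocalization result
#'
#' Final/Initial fluorescence ratio on a fixed 0--100 percent
#' spindle-length grid, with trapezoidal areas under the ratio curve
#' (baseline 0) and under \code{|ratio - 1|}.
#'
#' @slot percentPositions the 101-point grid 0,1,...,100.
#' @slot ratio Final/Initial per grid point; \code{NA} where the initial
#'   profile fell below the mask floor.
#' @slot auc area under the ratio curve above baseline 0 (percent x
#'   unitless; 100 for a flat ratio of 1).
#' @slot deviationAuc area under \code{|ratio - 1|}.
#' @slot maskedFraction fraction of grid points masked.
#' @slot initialTime,finalTime minutes relative to treatment.
#' @export
setClass("RelocalizationResult",
  representation(percentPositions = "numeric", ratio = "numeric",
                 auc = "numeric", deviationAuc = "numeric",
                 maskedFraction = "numeric", initialTime = "numeric",
                 finalTime = "numeric"))

setValidity("RelocalizationResult", function(object) {
  g <- object@percentPositions
  if (g[1] != 0 || g[length(g)] != 100)
    return("percent grid must span [0, 100]")
  if (any(object@ratio[!is.na(object@ratio)] < 0))
    return("ratio must be >= 0 where defined")
  TRUE
})

#' Four-parameter logistic (variable slope) dose-response fit
#'
#' Fit of \code{y = bottom + (top - bottom) / (1 + (ic50/x)^hill)} to
#' percent inhibition versus concentration, performed on log10
#' concentration.
#'
#' @slot bottom,top asymptotes (percent inhibition).
#' @slot ic50 half-maximal inhibitory concentration (nM).
#' @slot hill Hill slope (unitless, bounded to [0.1, 10]).
#' @slot rss residual sum of squares.
#' @slot se named per-parameter standard errors (bottom, top, ic50, hill).
#' @slot converged logical; FALSE also when a parameter sits at a bound.
#' @slot flags character quality flags.
#' @export
setClass("FourPLFit",
  representation(bottom = "numeric", top = "numeric", ic50 = "numeric",
                 hill = "numeric", rss = "numeric", se = "numeric",
                 converged = "logical", flags = "character"),
  prototype(flags = character()))

setValidity("FourPLFit", function(object) {
  if (object@ic50 <= 0) return("ic50 must be > 0")
  if (object@bottom >= object@top) return("bottom must be < top")
  TRUE
})

#' Per-field mitotic count table
#'
#' Counts of mitotic and total cells per imaging field plus, for each
#' mitotic cell, its scored number of spindle poles.
#'
#' @slot fields data.frame with columns \code{field}, \code{total_cells},
#'   \code{mitotic_cells}.
#' @slot poles data.frame with columns \code{field}, \code{cell},
#'   \code{n_poles} (one row per mitotic cell; \code{n_poles >= 1}).
#' @export
setClass("CountTable",
  representation(fields = "data.frame", poles = "data.frame"))

setValidity("CountTable", function(object) {
  f <- object@fields
  need <- c("field", "total_cells", "mitotic_cells")
  if (!all(need %in% names(f)))
    return(paste("fields needs columns:", paste(need, collapse = ", ")))
  if (any(f$mitotic_cells < 0) || any(f$mitotic_cells > f$total_cells))
    return("need 0 <= mitotic_cells <= total_cells in every field")
  p <- object@poles
  if (!all(c("field", "cell", "n_poles") %in% names(p)))
    return("poles needs columns: field, cell, n_poles")
  if (nrow(p) > 0 && any(p$n_poles < 1))
    return("n_poles must be >= 1")
  if (nrow(p) != sum(f$mitotic_cells))
    return("poles must have one row per mitotic cell")
  TRUE
})
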