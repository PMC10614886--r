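PERCENT_GRID <- 0:100

#' Resample a spindle profile onto the 0--100% spindle-length grid
#'
#' Linear interpolation of a pole-to-pole profile onto the fixed 101-point
#' percent grid (0, 1, ..., 100), normalizing out spindle-length
#' differences between cells.  Idempotent on a profile already on the
#' grid.
#'
#' @param p an \linkS4class{IntensityProfile} spanning the full spindle
#'   ROI (>= 2 samples).
#' @return an \linkS4class{IntensityProfile} whose positions are the
#'   percent grid.
#' @export
percentLengthResample <- function(p) {
  stopifnot(is(p, "IntensityProfile"))
  if (length(p@positions) < 2L)
    stop("need >= 2 samples to resample", call. = FALSE)
  x <- p@positions
  pct <- (x - x[1]) / (x[length(x)] - x[1]) * 100
  v <- apply(p@values, 2, function(y)
    stats::approx(pct, y, xout = PERCENT_GRID)$y)
  colnames(v) <- colnames(p@values)
  new("IntensityProfile", positions = as.numeric(PERCENT_GRID),
      values = v, widthPx = p@widthPx, cellId = p@cellId)
}

onPercentGrid <- function(p) {
  length(p@positions) == 101L &&
    max(abs(p@positions - PERCENT_GRID)) < 1e-9
}

# Trapezoidal area over grid segments whose both endpoints are unmasked;
# masked points are never interpolated into the area.
maskedTrapz <- function(x, y) {
  ok <- !is.na(y)
  seg <- ok[-length(ok)] & ok[-1]
  sum(((y[-length(y)] + y[-1]) / 2 * diff(x))[seg])
}

#' Final/Initial fluorescence ratio across the spindle
#'
#' Divides the final-timepoint profile by the initial-timepoint profile,
#' pointwise on the percent-spindle-length grid.  Grid points where the
#' initial profile falls at or below the mask floor (a fraction
#' \code{epsFrac} of the initial maximum) are masked (\code{NA}) and
#' counted in \code{maskedFraction}.  Areas under the ratio curve
#' (baseline 0) and under \code{|ratio - 1|} are computed over unmasked
#' segments when coverage is at least \code{minCoverage}, else left
#' \code{NA} with a warning.
#'
#' @param initial,final single-channel \linkS4class{IntensityProfile}s on
#'   the percent grid (see \code{\link{percentLengthResample}}).
#' @param channel channel to use when the profiles carry several.
#' @param epsFrac mask floor as a fraction of the initial maximum.
#' @param initialTime,finalTime minutes relative to treatment (defaults:
#'   -1.5 and 12, the acquisition protocol's Initial and Final).
#' @param minCoverage minimum unmasked fraction for AUCs.
#' @return a \linkS4class{RelocalizationResult}.
#' @export
finalInitialRatio <- function(initial, final, channel = NULL,
                              epsFrac = 0.01, initialTime = -1.5,
                              finalTime = 12, minCoverage = 0.9) {
  stopifnot(is(initial, "IntensityProfile"), is(final, "IntensityProfile"))
  if (!onPercentGrid(initial) || !onPercentGrid(final))
    stop("both profiles must be resampled to the 0-100% grid first",
         call. = FALSE)
  pick <- function(p) {
    if (is.null(channel)) {
      if (ncol(p@values) != 1L)
        stop("profiles have several channels; name one", call. = FALSE)
      p@values[, 1]
    } else p@values[, channel]
  }
  yi <- pick(initial); yf <- pick(final)
  eps <- epsFrac * max(yi)
  masked <- yi <= eps
  if (all(masked))
    stop("initial profile below the mask floor everywhere", call. = FALSE)
  ratio <- ifelse(masked, NA_real_, yf / yi)
  maskedFraction <- mean(masked)
  if (1 - maskedFraction >= minCoverage) {
    auc <- maskedTrapz(PERCENT_GRID, ratio)
    dev <- maskedTrapz(PERCENT_GRID, abs(ratio - 1))
  } else {
    warning("unmasked coverage ", round(100 * (1 - maskedFraction)),
            "% below ", round(100 * minCoverage),
            "%; AUCs not computed", call. = FALSE)
    auc <- NA_real_; dev <- NA_real_
  }
  new("RelocalizationResult", percentPositions = as.numeric(PERCENT_GRID),
      ratio = ratio, auc = auc, deviationAuc = dev,
      maskedFraction = maskedFraction, initialTime = initialTime,
      finalTime = finalTime)
}

#' Area under a relocalization ratio curve
#'
#' Trapezoidal area over the 0--100% grid.  \code{type = "baseline0"} is
#' the area of the ratio curve above zero (100 for a flat ratio of 1);
#' \code{type = "deviation"} is the area of \code{|ratio - 1|}, the
#' magnitude of relocalization regardless of direction.
#'
#' @param r a \linkS4class{RelocalizationResult}.
#' @param type which area to compute.
#' @param minCoverage minimum unmasked fraction of the grid.
#' @return area in percent x unitless.
#' @export
ratioAUC <- function(r, type = c("baseline0", "deviation"),
                     minCoverage = 0.9) {
  stopifnot(is(r, "RelocalizationResult"))
  type <- match.arg(type)
  cov <- 1 - r@maskedFraction
  if (cov < minCoverage)
    stop("unmasked coverage ", round(100 * cov), "% is below the ",
         round(100 * minCoverage), "% threshold", call. = FALSE)
  y <- if (type == "baseline0") r@ratio else abs(r@ratio - 1)
  maskedTrapz(r@percentPositions, y)
}

#' Spindle-ROI fluorescence profile from one time-lapse frame
#'
#' Sums the target-channel fluorescence across the height of a
#' rectangular ROI spanning the spindle, per axial position, producing
#' the per-frame profile consumed by \code{\link{finalInitialRatio}}.
#' (The Final/Initial ratio is invariant to summing versus averaging over
#' a fixed ROI height.)
#'
#' @param image a \linkS4class{SpindleImage} frame.
#' @param poleA,poleB pole positions, \code{c(x, y)} 0-based px.
#' @param roiHeightUm ROI height in um.
#' @param channel fluorescence channel (default \code{"kif18a"}).
#' @return an \linkS4class{IntensityProfile} of summed intensity.
#' @export
spindleROIProfile <- function(image, poleA, poleB, roiHeightUm = 5,
                              channel = "kif18a") {
  prof <- extractBoxProfile(image, poleA, poleB, roiHeightUm, channel)
  initialize(prof, values = prof@values * prof@widthPx)
}

#' Relocalization analysis of a time-lapse stack
#'
#' End-to-end per-cell quantification: extracts the spindle-ROI profile
#' from the initial and final frames, resamples both to the percent grid,
#' and forms the Final/Initial ratio and its areas.
#'
#' @param stack a \linkS4class{SpindleStack}.
#' @param poleA,poleB pole positions, \code{c(x, y)} 0-based px.
#' @param initialFrame,finalFrame frame indices (defaults: first, last).
#' @param roiHeightUm ROI height in um.
#' @param channel fluorescence channel.
#' @param ... passed to \code{\link{finalInitialRatio}}.
#' @return a \linkS4class{RelocalizationResult}.
#' @export
relocalizationAnalysis <- function(stack, poleA, poleB,
                                   initialFrame = 1L,
                                   finalFrame = nFrames(stack),
                                   roiHeightUm = 5, channel = "kif18a",
                                   ...) {
  stopifnot(is(stack, "SpindleStack"))
  pi_ <- percentLengthResample(spindleROIProfile(
    getFrame(stack, initialFrame), poleA, poleB, roiHeightUm, channel))
  pf <- percentLengthResample(spindleROIProfile(
    getFrame(stack, finalFrame), poleA, poleB, roiHeightUm, channel))
  finalInitialRatio(pi_, pf, channel = channel,
                    initialTime = stack@frameTimes[initialFrame],
                    finalTime = stack@frameTimes[finalFrame], ...)
}
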