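#' Distance from the pole to the maximum of a target channel
#'
#' For a line scan running from a spindle pole toward the spindle centre,
#' returns the distance (um) from the reference-channel peak
#' (gamma-tubulin, marking the pole) to the first maximum of the target
#' channel (KIF18A).  Ties break to the first, pole-proximal sample.  A
#' target maximum at or behind the reference peak -- the
#' pole-accumulated, inhibited-like pattern -- yields 0.
#'
#' @param p an \linkS4class{IntensityProfile} containing both channels.
#' @param referenceChannel pole marker channel (default
#'   \code{"gamma_tubulin"}).
#' @param targetChannel channel whose peak distance is measured (default
#'   \code{"kif18a"}).
#' @return distance in um (>= 0).
#' @export
distanceToMax <- function(p, referenceChannel = "gamma_tubulin",
                          targetChannel = "kif18a") {
  stopifnot(is(p, "IntensityProfile"))
  for (ch in c(referenceChannel, targetChannel))
    if (!ch %in% colnames(p@values))
      stop("channel '", ch, "' not present in the profile",
           call. = FALSE)
  tv <- p@values[, targetChannel]
  if (diff(range(tv)) <= 0)
    stop("flat target profile; no maximum to locate", call. = FALSE)
  iRef <- argmaxFirst(p@values[, referenceChannel])
  iTar <- argmaxFirst(tv)
  max(0, p@positions[iTar] - p@positions[iRef])
}

#' Align line scans on peak gamma-tubulin and average per distance
#'
#' Shifts each normalized scan by a whole number of samples so that its
#' gamma-tubulin maximum sits at distance 0, then averages the scans for
#' each sample distance over the scans that cover that distance.  The
#' per-scan distance from the pole to the target-channel maximum is also
#' retained: each line scan contributes one value to the per-condition
#' distribution.
#'
#' @param scans list of normalized \linkS4class{IntensityProfile}s with a
#'   common sample spacing (each channel maximum must be 1).
#' @param referenceChannel pole marker used for alignment.
#' @param targetChannel channel whose per-scan peak distance is recorded.
#' @return an \linkS4class{AlignedScanSet}.
#' @export
alignAndAverage <- function(scans, referenceChannel = "gamma_tubulin",
                            targetChannel = "kif18a") {
  if (length(scans) == 0) stop("no scans supplied", call. = FALSE)
  stopifnot(all(vapply(scans, is, logical(1), "IntensityProfile")))
  if (!all(vapply(scans, isNormalized, logical(1), tol = 1e-6)))
    stop("scans must be normalized (each channel maximum = 1)",
         call. = FALSE)
  sp <- vapply(scans, profileSpacing, numeric(1))
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("scans must share one sample spacing", call. = FALSE)
  spacing <- mean(sp)
  chans <- colnames(scans[[1]]@values)
  offsets <- vapply(scans, function(s)
    argmaxFirst(s@values[, referenceChannel]) - 1L, integer(1))
  # Sample i of scan k maps to distance (i - 1 - offset_k) * spacing.
  lens <- vapply(scans, function(s) length(s@positions), integer(1))
  lo <- min(-offsets)
  hi <- max(lens - 1L - offsets)
  grid <- lo:hi
  acc <- matrix(0, length(grid), length(chans),
                dimnames = list(NULL, chans))
  cnt <- integer(length(grid))
  for (k in seq_along(scans)) {
    idx <- (0:(lens[k] - 1L)) - offsets[k] - lo + 1L
    acc[idx, ] <- acc[idx, , drop = FALSE] + scans[[k]]@values
    cnt[idx] <- cnt[idx] + 1L
  }
  meanV <- acc / cnt
  d2m <- vapply(scans, distanceToMax, numeric(1),
                referenceChannel = referenceChannel,
                targetChannel = targetChannel)
  new("AlignedScanSet", distances = grid * spacing, meanValues = meanV,
      nScans = cnt, offsets = as.integer(offsets), distanceToMax = d2m,
      targetChannel = targetChannel)
}

#' Peak distance of the averaged profile
#'
#' Distance from 0 (the aligned gamma-tubulin peak) to the maximum of the
#' averaged target-channel profile.  Reported alongside the per-scan
#' distribution for comparison.
#'
#' @param x an \linkS4class{AlignedScanSet}.
#' @return distance in um (>= 0).
#' @export
averagedPeakDistance <- function(x) {
  stopifnot(is(x, "AlignedScanSet"))
  v <- x@meanValues[, x@targetChannel]
  max(0, x@distances[argmaxFirst(v)])
}
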