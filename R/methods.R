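#' @describeIn channelNames roles present in the image
#' @export
setMethod("channelNames", "SpindleImage", function(x) names(x@channels))

#' @describeIn channelNames raster for one role
#' @export
setMethod("getChannel", "SpindleImage", function(x, role) {
  if (!role %in% names(x@channels))
    stop("channel role '", role, "' not present (have: ",
         paste(names(x@channels), collapse = ", "), ")", call. = FALSE)
  x@channels[[role]]
})

#' @export
setMethod("pixelSize", "SpindleImage", function(x) x@pixelSize)

#' @export
setMethod("pixelSize", "SpindleScene", function(x) x@pixelSize)

#' @export
setMethod("dim", "SpindleImage", function(x) dim(x@channels[[1]]))

#' @export
setMethod("nFrames", "SpindleStack", function(x) length(x@frames))

#' @export
setMethod("getFrame", "SpindleStack", function(x, i) x@frames[[i]])

#' @export
setMethod("fwhm", "GaussianFit", function(x) x@fwhm)

#' @export
setMethod("fwhm", "AlignmentResult", function(x) x@fwhm)

setMethod("show", "SpindleImage", function(object) {
  d <- dim(object)
  cat("SpindleImage:", d[1], "x", d[2], "px,",
      format(object@pixelSize, digits = 4), "um/px\n")
  cat("  channels:", paste(channelNames(object), collapse = ", "), "\n")
  if (!is.na(object@frameTime))
    cat("  frame time:", object@frameTime, "s\n")
})

setMethod("show", "SpindleStack", function(object) {
  cat("SpindleStack:", nFrames(object), "frames,",
      "t =", paste(format(object@frameTimes, digits = 3), collapse = ", "),
      "min\n")
  show(object@frames[[1]])
})

setMethod("show", "IntensityProfile", function(object) {
  n <- length(object@positions)
  cat("IntensityProfile:", n, "samples over",
      format(object@positions[n] - object@positions[1], digits = 4),
      "um; channels:", paste(colnames(object@values), collapse = ", "),
      "\n")
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: center %.3f um, sigma %.3f um, FWHM %.3f um%s\n",
    object@center, object@sigma, object@fwhm,
    if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult [%s]: FWHM %.3f um, spindle %.3f um%s\n",
              object@cellId, object@fwhm, object@spindleLength,
              if (length(object@flags))
                paste0(" (", paste(object@flags, collapse = ", "), ")")
              else ""))
})

setMethod("show", "AlignedScanSet", function(object) {
  cat("AlignedScanSet:", length(object@offsets), "scans;",
      "mean distance-to-max",
      format(mean(object@distanceToMax), digits = 4), "um (",
      object@targetChannel, ")\n")
})

setMethod("show", "RelocalizationResult", function(object) {
  cat(sprintf(
    "RelocalizationResult: AUC %.2f, deviation AUC %.2f, %.0f%% masked\n",
    object@auc, object@deviationAuc, 100 * object@maskedFraction))
})

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf(
    "FourPLFit: IC50 %.3g nM (hill %.2f, bottom %.1f, top %.1f)%s\n",
    object@ic50, object@hill, object@bottom, object@top,
    if (object@converged) "" else " [FLAGGED]"))
})

setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@fields), "fields,",
      sum(object@fields$total_cells), "cells,",
      sum(object@fields$mitotic_cells), "mitotic\n")
})

#' @describeIn asResultTable one row per scan with its distance to max
#' @export
setMethod("asResultTable", "AlignedScanSet", function(x, ...) {
  data.frame(scan = seq_along(x@distanceToMax),
             offset_samples = x@offsets,
             distance_to_max_um = x@distanceToMax)
})

#' @describeIn asResultTable one-row summary of a 4PL fit
#' @export
setMethod("asResultTable", "FourPLFit", function(x, ...) {
  data.frame(bottom = x@bottom, top = x@top, ic50_nM = x@ic50,
             hill = x@hill, rss = x@rss, converged = x@converged)
})

#' @describeIn asResultTable one-row summary of an alignment result
#' @export
setMethod("asResultTable", "AlignmentResult", function(x, ...) {
  data.frame(cell_id = x@cellId, fwhm_um = x@fwhm,
             spindle_length_um = x@spindleLength,
             converged = x@fit@converged,
             flags = paste(x@flags, collapse = ";"))
})
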