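#' Channel accessors
#'
#' @param x a \linkS4class{SpindleImage}.
#' @param role channel role name.
#' @return \code{channelNames} returns the role names; \code{getChannel}
#'   the raster matrix for one role.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' Pixel size accessor
#'
#' @param x an object carrying a pixel size.
#' @return micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Number of frames in a stack
#'
#' @param x a \linkS4class{SpindleStack}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract a single frame
#'
#' @param x a \linkS4class{SpindleStack}.
#' @param i frame index (1-based).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' FWHM accessor
#'
#' @param x a \linkS4class{GaussianFit} or \linkS4class{AlignmentResult}.
#' @return full width at half maximum in micrometres.
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' Tidy data.frame view of a result object
#'
#' @param x a result object.
#' @param ... unused.
#' @return a flat \code{data.frame}, one row per cell/scan/well.
#' @export
setGeneric("asResultTable", function(x, ...) standardGeneric("asResultTable"))
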