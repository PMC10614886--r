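FWHM_FACTOR <- 2 * sqrt(2 * log(2))   # 2.3548...

#' Fit a Gaussian to a normalized intensity profile
#'
#' Least-squares fit of \code{offset + amplitude * exp(-(x - center)^2 /
#' (2 sigma^2))} by bounded Levenberg-Marquardt, initialized from the
#' profile's moments (centre = intensity-weighted mean above baseline,
#' sigma = weighted SD, offset = minimum, amplitude = max - min).  Sigma
#' is bounded to (0, axis length], the centre to the axis.  The FWHM of
#' the chromosome distribution is \code{2*sqrt(2*log(2)) * sigma}.
#' Non-convergence is flagged on the result, never silent.
#'
#' @param p an \linkS4class{IntensityProfile} with >= 8 samples (use
#'   \code{\link{normalizeProfile}} first; the fit itself is invariant to
#'   profile rescaling).
#' @param channel channel column to fit; defaults to the only column.
#' @return a \linkS4class{GaussianFit}.
#' @export
fitGaussianProfile <- function(p, channel = NULL) {
  stopifnot(is(p, "IntensityProfile"))
  if (is.null(channel)) {
    if (ncol(p@values) != 1L)
      stop("profile has several channels; name one", call. = FALSE)
    channel <- colnames(p@values)[1]
  }
  x <- p@positions
  y <- p@values[, channel]
  if (length(x) < 8L) stop("need >= 8 samples to fit", call. = FALSE)
  if (diff(range(y)) <= 0)
    stop("degenerate flat profile; nothing to fit", call. = FALSE)
  axisLen <- x[length(x)] - x[1]
  w <- y - min(y)
  c0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - c0)^2) / sum(w))
  s0 <- min(max(s0, profileSpacing(p)), axisLen)
  start <- list(offset = min(y), amplitude = max(y) - min(y),
                center = c0, sigma = s0)
  lower <- c(offset = -Inf, amplitude = 0, center = x[1], sigma = 1e-6)
  upper <- c(offset = Inf, amplitude = Inf, center = x[length(x)],
             sigma = axisLen)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-(x - center)^2 / (2 * sigma^2)),
      data = data.frame(x = x, y = y), start = start,
      lower = lower[names(start)], upper = upper[names(start)],
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("GaussianFit", amplitude = start$amplitude,
               center = start$center, sigma = start$sigma,
               offset = start$offset,
               fwhm = FWHM_FACTOR * start$sigma,
               rss = sum((y - mean(y))^2), converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv && cf[["sigma"]] > 1e-6 &&
    cf[["sigma"]] < axisLen
  new("GaussianFit", amplitude = cf[["amplitude"]],
      center = cf[["center"]], sigma = cf[["sigma"]],
      offset = cf[["offset"]], fwhm = FWHM_FACTOR * cf[["sigma"]],
      rss = sum(stats::resid(fit)^2), converged = conv)
}

#' Spindle length from a pole annotation
#'
#' Euclidean distance between the two pole centres, converted to
#' micrometres.
#'
#' @param poleA,poleB pole positions \code{c(x, y)} in 0-based pixels
#'   (sub-pixel allowed).
#' @param pixelSizeUm micrometres per pixel.
#' @return length in um.
#' @examples
#' spindleLength(c(0, 0), c(12, 0), 0.5)  # 6
#' @export
spindleLength <- function(poleA, poleB, pixelSizeUm) {
  stopIfNot2D(poleA, "poleA"); stopIfNot2D(poleB, "poleB")
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0", call. = FALSE)
  if (all(poleA == poleB)) stop("coincident poles", call. = FALSE)
  sqrt(sum((poleB - poleA)^2)) * pixelSizeUm
}

#' Chromosome-alignment metric for one cell
#'
#' Composes the full per-cell pipeline: boxed pole-to-pole profile of the
#' kinetochore (or DNA) channel, internal normalization to the profile
#' maximum, Gaussian fit, and the FWHM of that fit, together with the
#' spindle length.  A FWHM exceeding the spindle length is flagged, not
#' rejected.
#'
#' @param image a \linkS4class{SpindleImage}.
#' @param poleA,poleB pole positions \code{c(x, y)} in 0-based pixels.
#' @param channel profile channel (\code{"kinetochore"} for ACA-stained
#'   cancer lines; use the DNA/DAPI channel for rescue experiments).
#' @param boxHeightUm box height in um.
#' @param cellId cell identifier carried through errors and results.
#' @return an \linkS4class{AlignmentResult}.
#' @export
chromosomeAlignment <- function(image, poleA, poleB,
                                channel = "kinetochore",
                                boxHeightUm = 5, cellId = "cell") {
  res <- tryCatch({
    prof <- extractBoxProfile(image, poleA, poleB, boxHeightUm, channel,
                              cellId = cellId)
    fit <- fitGaussianProfile(normalizeProfile(prof), channel)
    len <- spindleLength(poleA, poleB, pixelSize(image))
    flags <- character()
    if (!fit@converged) flags <- c(flags, "fit_not_converged")
    if (fit@fwhm > len) flags <- c(flags, "fwhm_exceeds_spindle_length")
    new("AlignmentResult", cellId = cellId, fwhm = fit@fwhm,
        spindleLength = len, fit = fit, flags = flags)
  }, error = function(e)
    stop("cell '", cellId, "': ", conditionMessage(e), call. = FALSE))
  res
}

#' Locate candidate spindle poles from the gamma-tubulin channel
#'
#' Convenience helper only -- annotations always take precedence.  Returns
#' the two brightest local maxima separated by at least
#' \code{minSeparationUm}.
#'
#' @param image a \linkS4class{SpindleImage}.
#' @param minSeparationUm minimum pole separation in um.
#' @return list with \code{poleA}, \code{poleB} in 0-based pixels.
#' @export
findPoles <- function(image, minSeparationUm = 3) {
  m <- getChannel(image, "gamma_tubulin")
  ord <- order(m, decreasing = TRUE)
  sepPx <- minSeparationUm / pixelSize(image)
  first <- ord[1]
  p1 <- c((first - 1) %/% nrow(m), (first - 1) %% nrow(m))  # (x, y)
  for (idx in ord[-1]) {
    p2 <- c((idx - 1) %/% nrow(m), (idx - 1) %% nrow(m))
    if (sqrt(sum((p2 - p1)^2)) >= sepPx)
      return(list(poleA = p1, poleB = p2))
  }
  stop("no second pole found at the requested separation", call. = FALSE)
}
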