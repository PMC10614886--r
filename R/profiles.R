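# Shared sampler: mean of bilinearly interpolated intensities across
# `width` perpendicular offsets (1 px apart, symmetric about the line),
# at n_seg + 1 uniformly spaced samples from `start` to `end` (px).
sampleWideLine <- function(image, start, end, width, channels) {
  d <- dim(image)
  delta <- end - start
  lenPx <- sqrt(sum(delta^2))
  nSeg <- round(lenPx)
  if (nSeg < 1) stop("line must be at least one pixel long", call. = FALSE)
  u <- delta / lenPx
  v <- c(-u[2], u[1])                     # perpendicular unit vector
  f <- (0:nSeg) / nSeg
  cx <- start[1] + f * delta[1]
  cy <- start[2] + f * delta[2]
  offs <- (seq_len(width) - (width + 1) / 2)
  X <- outer(cx, offs * v[1], `+`)        # samples x offsets
  Y <- outer(cy, offs * v[2], `+`)
  if (any(X < 0) || any(X > d[2] - 1) || any(Y < 0) || any(Y > d[1] - 1))
    stop("scan (with its width) exits the raster", call. = FALSE)
  vals <- vapply(channels, function(role) {
    m <- getChannel(image, role)
    rowMeans(matrix(bilinear(m, as.vector(X), as.vector(Y)),
                    nrow = length(cx)))
  }, numeric(length(cx)))
  colnames(vals) <- channels
  list(values = vals, positions = f * lenPx * pixelSize(image),
       nSeg = nSeg)
}

#' Extract a wide line-scan intensity profile
#'
#' Reproduces a wide-line plot profile: samples are taken every pixel
#' along the line from \code{start} to \code{end} (both 0-based pixel
#' coordinates, sub-pixel allowed), and each sample is the mean of
#' bilinearly interpolated intensities at \code{widthPx} perpendicular
#' offsets spaced one pixel apart, symmetric about the line.  The number
#' of segments is the line length in pixels rounded to the nearest
#' integer, so a 6.5 um line at 0.1083 um/px yields 61 samples spanning
#' exactly 6.5 um.
#'
#' @param image a \linkS4class{SpindleImage}.
#' @param start,end line endpoints, \code{c(x, y)} in 0-based pixels.
#' @param widthPx perpendicular averaging width in pixels (>= 1); the
#'   fixed-cell localization protocol uses 10.
#' @param channels channel roles to sample (default: all).
#' @param cellId identifier stored on the profile.
#' @return an \linkS4class{IntensityProfile} with positions in um from
#'   the scan start.
#' @export
extractLineProfile <- function(image, start, end, widthPx = 10,
                               channels = channelNames(image),
                               cellId = NA_character_) {
  stopIfNot2D(start, "start"); stopIfNot2D(end, "end")
  if (all(start == end)) stop("start and end must differ", call. = FALSE)
  if (widthPx < 1) stop("widthPx must be >= 1", call. = FALSE)
  s <- sampleWideLine(image, start, end, widthPx, channels)
  new("IntensityProfile", positions = s$positions, values = s$values,
      widthPx = widthPx, cellId = cellId)
}

#' Extract a boxed pole-to-pole intensity profile
#'
#' Measures the intensity distribution along the pole-to-pole axis inside
#' a box of fixed height centred on the axis, as used for the
#' chromosome-alignment metric: each axial sample is the mean intensity
#' across the box height at that position, and the profile spans exactly
#' pole A to pole B.
#'
#' @param image a \linkS4class{SpindleImage}.
#' @param poleA,poleB pole positions, \code{c(x, y)} in 0-based pixels.
#' @param boxHeightUm box height in um (default 5).
#' @param channel channel role to profile (kinetochore marker or DNA).
#' @param cellId identifier stored on the profile.
#' @return an \linkS4class{IntensityProfile}; positions run 0 (pole A) to
#'   the spindle length (pole B) in um.
#' @export
extractBoxProfile <- function(image, poleA, poleB, boxHeightUm = 5,
                              channel = "kinetochore",
                              cellId = NA_character_) {
  stopIfNot2D(poleA, "poleA"); stopIfNot2D(poleB, "poleB")
  if (all(poleA == poleB)) stop("poles must differ", call. = FALSE)
  if (boxHeightUm <= 0) stop("boxHeightUm must be > 0", call. = FALSE)
  heightPx <- max(1L, round(boxHeightUm / pixelSize(image)))
  s <- sampleWideLine(image, poleA, poleB, heightPx, channel)
  new("IntensityProfile", positions = s$positions, values = s$values,
      widthPx = heightPx, cellId = cellId)
}

#' Normalize a profile internally to its highest value
#'
#' Each channel is divided by its own maximum, so every channel's maximum
#' becomes exactly 1 (the internal normalization applied to every line
#' scan and boxed profile before fitting or averaging).  Idempotent.
#'
#' @param p an \linkS4class{IntensityProfile}.
#' @return the normalized profile; positions unchanged.
#' @export
normalizeProfile <- function(p) {
  stopifnot(is(p, "IntensityProfile"))
  mx <- apply(p@values, 2, max)
  if (any(mx <= 0))
    stop("cannot normalize: channel(s) with non-positive maximum: ",
         paste(colnames(p@values)[mx <= 0], collapse = ", "),
         call. = FALSE)
  v <- sweep(p@values, 2, mx, `/`)
  initialize(p, values = v)
}

isNormalized <- function(p, tol = 1e-9) {
  all(abs(apply(p@values, 2, max) - 1) <= tol)
}

#' Serialize a profile to CSV
#'
#' Columns: \code{position_um} then one column per channel role.
#'
#' @param p an \linkS4class{IntensityProfile}.
#' @param path output CSV; when \code{NULL} the data.frame is returned.
#' @param configHash optional provenance hash for the CSV header.
#' @return the data.frame, invisibly when written.
#' @export
profileToCSV <- function(p, path = NULL, configHash = NULL) {
  df <- data.frame(position_um = p@positions, p@values,
                   check.names = FALSE)
  if (is.null(path)) return(df)
  writeResultTable(df, path, configHash)
  invisible(df)
}
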