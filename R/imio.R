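#' Write a spindle image (or stack) to multi-page TIFF + JSON sidecar
#'
#' One TIFF page per channel; for a stack, pages are ordered frame-major
#' (frame 1 channels, frame 2 channels, ...; TCYX).  The channel order,
#' pixel size, frame times and intensity scaling are recorded in a JSON
#' sidecar next to the TIFF (\code{<path>.json}).  Rasters whose values
#' are all integers below 2^16 are stored losslessly as 16-bit pages;
#' anything else is stored as 32-bit float scaled to [0, 1].
#'
#' @param x a \linkS4class{SpindleImage} or \linkS4class{SpindleStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeSpindleImage <- function(x, path) {
  if (is(x, "SpindleImage")) {
    images <- list(x); frameTimes <- NULL
  } else if (is(x, "SpindleStack")) {
    images <- x@frames; frameTimes <- x@frameTimes
  } else stop("x must be a SpindleImage or SpindleStack", call. = FALSE)
  roles <- channelNames(images[[1]])
  pages <- unlist(lapply(images, function(im)
    unname(im@channels[roles])), recursive = FALSE)
  allInt <- all(vapply(pages, function(m)
    all(m == round(m)) && max(m) < 65536, logical(1)))
  if (allInt) {
    scale <- 65535
    out <- lapply(pages, function(m) m / scale)
    tiff::writeTIFF(out, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    scale <- max(vapply(pages, max, numeric(1)), 1e-12)
    out <- lapply(pages, function(m) m / scale)
    tiff::writeTIFF(out, path, bits.per.sample = 32L,
                    compression = "none")
  }
  sidecar <- list(channels = roles,
                  pixel_size_um = pixelSize(images[[1]]),
                  n_frames = length(images),
                  frame_times_min = frameTimes,
                  dtype = if (allInt) "uint16" else "float32",
                  scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spindle image or stack from multi-page TIFF
#'
#' Reads the JSON sidecar written by \code{\link{writeSpindleImage}} when
#' present; otherwise the channel-role order and pixel size must be
#' supplied.  The write/read round trip is lossless for integer rasters.
#'
#' @param path TIFF path.
#' @param channels channel roles in page order (overrides the sidecar).
#' @param pixelSizeUm pixel size in um/px (overrides the sidecar).
#' @return a \linkS4class{SpindleImage}, or a \linkS4class{SpindleStack}
#'   when the sidecar records more than one frame.
#' @export
readSpindleImage <- function(path, channels = NULL, pixelSizeUm = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- NULL
  scPath <- paste0(path, ".json")
  if (file.exists(scPath)) sidecar <- jsonlite::read_json(scPath)
  if (is.null(channels))
    channels <- unlist(sidecar$channels)
  if (is.null(pixelSizeUm))
    pixelSizeUm <- sidecar$pixel_size_um
  if (is.null(channels) || is.null(pixelSizeUm))
    stop("no sidecar found; supply `channels` and `pixelSizeUm`",
         call. = FALSE)
  asIs <- is.null(sidecar$dtype) || identical(sidecar$dtype, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = asIs)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (is.null(sidecar$scale)) 65535 else sidecar$scale
  if (!asIs) pages <- lapply(pages, function(m) m * scale)
  pages <- lapply(pages, function(m) {
    storage.mode(m) <- "double"; m
  })
  nCh <- length(channels)
  have <- length(pages)
  nFrames <- if (!is.null(sidecar$n_frames)) sidecar$n_frames
             else max(1L, have %/% nCh)
  if (have != nCh * nFrames) {
    msg <- paste0("TIFF has ", have, " pages but the mapping requires ",
                  nCh * nFrames)
    if (have < nCh * nFrames) {
      missing <- channels[seq.int(have %% nCh + 1L, nCh)]
      msg <- paste0(msg, "; missing role(s): ",
                    paste(missing, collapse = ", "))
    }
    stop(msg, call. = FALSE)
  }
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes != shapes[, 1]))
    stop("page shapes differ across the TIFF", call. = FALSE)
  mkImage <- function(frame, frameTime = NA_real_) {
    ch <- pages[(frame - 1L) * nCh + seq_len(nCh)]
    names(ch) <- channels
    new("SpindleImage", channels = ch, pixelSize = pixelSizeUm,
        frameTime = frameTime)
  }
  if (nFrames == 1L) return(mkImage(1L))
  times <- unlist(sidecar$frame_times_min)
  if (is.null(times)) times <- seq_len(nFrames)
  frames <- lapply(seq_len(nFrames), function(i)
    mkImage(i, times[i] * 60))
  new("SpindleStack", frames = frames, frameTimes = times)
}

#' Read per-cell pole annotations
#'
#' Expects a CSV with columns \code{cell_id}, \code{pole_a_x},
#' \code{pole_a_y}, \code{pole_b_x}, \code{pole_b_y} (0-based pixel
#' coordinates, sub-pixel floats allowed) and optionally
#' \code{line_x0/line_y0/line_x1/line_y1} for manual scan endpoints.
#'
#' @param path annotation CSV.
#' @param image optional \linkS4class{SpindleImage}; when given, every
#'   pole is checked to lie inside the raster and offending
#'   \code{cell_id}s are reported.
#' @return a \code{data.frame} of annotations.
#' @export
readPoleAnnotations <- function(path, image = NULL) {
  ann <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("cell_id", "pole_a_x", "pole_a_y", "pole_b_x", "pole_b_y")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  same <- ann$pole_a_x == ann$pole_b_x & ann$pole_a_y == ann$pole_b_y
  if (any(same))
    stop("coincident poles for cell_id: ",
         paste(ann$cell_id[same], collapse = ", "), call. = FALSE)
  if (!is.null(image)) {
    d <- dim(image)
    bad <- ann$pole_a_x < 0 | ann$pole_a_x > d[2] - 1 |
           ann$pole_b_x < 0 | ann$pole_b_x > d[2] - 1 |
           ann$pole_a_y < 0 | ann$pole_a_y > d[1] - 1 |
           ann$pole_b_y < 0 | ann$pole_b_y > d[1] - 1
    if (any(bad))
      stop("pole outside raster bounds for cell_id: ",
           paste(ann$cell_id[bad], collapse = ", "), call. = FALSE)
  }
  ann
}

#' Write a result table as annotated CSV
#'
#' Flat CSV, one row per cell/scan/well, preceded by comment lines
#' (\code{#}) recording the package version and, when supplied, the
#' configuration hash, so every output is traceable to the run that
#' produced it.  Read back with \code{comment.char = "#"}.
#'
#' @param df a \code{data.frame}.
#' @param path output CSV path.
#' @param configHash optional hash string of the run configuration.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(df, path, configHash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("spindlemetrics"))
  writeLines(paste0("# spindlemetrics version ", ver), con)
  if (!is.null(configHash))
    writeLines(paste0("# config_hash ", configHash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{writeResultTable}}
#'
#' @param path CSV path.
#' @return a \code{data.frame}.
#' @export
readResultTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
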