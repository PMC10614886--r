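#' Mitotic index of a count table
#'
#' Percentage of cells in mitosis, pooled over fields
#' (\code{100 * sum(mitotic) / sum(total)}), with the per-field
#' percentages preserved for replicate-style plotting.
#'
#' @param ct a \linkS4class{CountTable}.
#' @return list with \code{percent} (pooled) and \code{perField}
#'   (data.frame of per-field percentages).
#' @export
mitoticIndex <- function(ct) {
  stopifnot(is(ct, "CountTable"))
  f <- ct@fields
  if (sum(f$total_cells) == 0)
    stop("zero total cells", call. = FALSE)
  list(percent = 100 * sum(f$mitotic_cells) / sum(f$total_cells),
       perField = data.frame(field = f$field,
                             percent = 100 * f$mitotic_cells /
                               f$total_cells))
}

#' Multipolar fraction of the mitotic population
#'
#' Percentage of mitotic cells scored with more than two spindle poles.
#' Monopolar cells (one pole) count toward the denominator but never the
#' numerator.
#'
#' @param ct a \linkS4class{CountTable}.
#' @return percent of mitotic cells with > 2 poles.
#' @export
multipolarFraction <- function(ct) {
  stopifnot(is(ct, "CountTable"))
  p <- ct@poles
  if (nrow(p) == 0) stop("no mitotic cells scored", call. = FALSE)
  100 * sum(p$n_poles > 2) / nrow(p)
}

#' Control-normalized proliferation fold change
#'
#' Per well, the fold change is the cell count at the final timepoint
#' divided by the count at the first timepoint; it is then normalized to
#' the mean fold change of the control condition within the same
#' experiment batch (so the batch mean of the control's normalized values
#' is exactly 1).
#'
#' @param series long-format \code{data.frame} with columns \code{batch},
#'   \code{well_id}, \code{condition}, \code{time_h}, \code{count} (rows
#'   from \code{\link{generateGrowthSeries}} may be \code{rbind}ed).
#' @param controlCondition condition used as the normalizer (e.g. DMSO,
#'   or the wild-type rescue line).
#' @return \code{data.frame} with one row per well: \code{batch},
#'   \code{well_id}, \code{condition}, \code{fold_change},
#'   \code{normalized_fold_change}.
#' @export
normalizedFoldChange <- function(series, controlCondition = "control") {
  need <- c("batch", "well_id", "condition", "time_h", "count")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  wells <- unique(series[c("batch", "well_id", "condition")])
  wells$fold_change <- mapply(function(b, w) {
    s <- series[series$batch == b & series$well_id == w, ]
    s <- s[order(s$time_h), ]
    if (s$count[1] <= 0)
      stop("well '", w, "' in batch '", b,
           "' has non-positive starting count", call. = FALSE)
    s$count[nrow(s)] / s$count[1]
  }, wells$batch, wells$well_id)
  wells$normalized_fold_change <- NA_real_
  for (b in unique(wells$batch)) {
    inB <- wells$batch == b
    ctrl <- inB & wells$condition == controlCondition
    if (!any(ctrl))
      stop("control condition '", controlCondition,
           "' missing in batch '", b, "'", call. = FALSE)
    wells$normalized_fold_change[inB] <-
      wells$fold_change[inB] / mean(wells$fold_change[ctrl])
  }
  rownames(wells) <- NULL
  wells
}

#' Background-subtracted expression level from ROI intensities
#'
#' Mean intensity inside a spindle ROI minus the mean inside a background
#' ROI of the same image.  A background mean at or above the spindle mean
#' is kept (negative corrected value) but flagged with a warning.
#'
#' @param image a \linkS4class{SpindleImage}.
#' @param spindleRoi,backgroundRoi rectangles \code{c(x0, y0, x1, y1)} in
#'   0-based pixel indices (inclusive); must lie inside the raster and
#'   not overlap.
#' @param channel intensity channel (default \code{"kif18a"}).
#' @param cellId identifier for the record.
#' @return one-row \code{data.frame}: \code{cell_id}, \code{spindle_mean},
#'   \code{background_mean}, \code{corrected}.
#' @export
expressionLevel <- function(image, spindleRoi, backgroundRoi,
                            channel = "kif18a", cellId = "cell") {
  d <- dim(image)
  checkRoi <- function(r, what) {
    if (length(r) != 4L || r[1] > r[3] || r[2] > r[4] ||
        any(r[c(1, 3)] < 0) || any(r[c(1, 3)] > d[2] - 1) ||
        any(r[c(2, 4)] < 0) || any(r[c(2, 4)] > d[1] - 1))
      stop(what, " ROI must be c(x0, y0, x1, y1) inside the raster",
           call. = FALSE)
  }
  checkRoi(spindleRoi, "spindle"); checkRoi(backgroundRoi, "background")
  overlap <- spindleRoi[1] <= backgroundRoi[3] &&
    backgroundRoi[1] <= spindleRoi[3] &&
    spindleRoi[2] <= backgroundRoi[4] &&
    backgroundRoi[2] <= spindleRoi[4]
  if (overlap) stop("ROIs must not overlap", call. = FALSE)
  m <- getChannel(image, channel)
  roiMean <- function(r)
    mean(m[(r[2]:r[4]) + 1, (r[1]:r[3]) + 1])
  sm <- roiMean(spindleRoi); bm <- roiMean(backgroundRoi)
  if (bm >= sm)
    warning("background mean >= spindle mean for cell '", cellId,
            "'; corrected value is <= 0", call. = FALSE)
  data.frame(cell_id = cellId, spindle_mean = sm, background_mean = bm,
             corrected = sm - bm)
}

#' Normalize expression records to the control mean
#'
#' Divides each background-corrected value by the mean corrected value of
#' the control cells, so the control mean maps to exactly 1.
#'
#' @param records \code{data.frame} of rows from
#'   \code{\link{expressionLevel}} with an added \code{condition} column.
#' @param controlCondition the normalizer condition.
#' @return the records with a \code{normalized} column added.
#' @export
normalizeExpression <- function(records, controlCondition = "control") {
  ctrl <- records$condition == controlCondition
  if (!any(ctrl))
    stop("no rows with control condition '", controlCondition, "'",
         call. = FALSE)
  records$normalized <- records$corrected / mean(records$corrected[ctrl])
  records
}
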