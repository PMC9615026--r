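# ROI-based organelle counting for neurons: peroxisomes per named ROI
# (soma, growth cone) and the growth-cone-to-soma ratio.

#' Count objects inside named ROIs
#'
#' An object is counted in an ROI iff its centroid lies inside the ROI
#' polygon (boundary-inclusive). Overlapping ROIs are permitted: an object
#' may count in several, with a notice.
#'
#' @param objects An \linkS4class{ObjectSet} (or centroid matrix/data.frame).
#' @param geometry A \linkS4class{CellGeometry} carrying the ROI polygons.
#' @param roiNames ROI names to count; all must exist in the geometry.
#' @param cellId Identifier carried into the result.
#' @return List of class \code{"RoiCountResult"}: \code{cellId},
#'   \code{counts} (named integer vector), and \code{gcSomaRatio} =
#'   growth-cone count / soma count when both ROIs are requested (\code{NA}
#'   with a warning when the soma count is zero).
#' @export
roiObjectCounts <- function(objects, geometry,
                            roiNames = c("soma", "growth_cone"),
                            cellId = "cell") {
  missing <- setdiff(roiNames, names(geometry@rois))
  if (length(missing))
    stop("ROI(s) not present in geometry: ", paste(missing, collapse = ", "))
  xy <- .objectXY(objects)
  counts <- integer(length(roiNames))
  names(counts) <- roiNames
  membership <- matrix(FALSE, nrow(xy), length(roiNames))
  for (j in seq_along(roiNames)) {
    poly <- geometry@rois[[roiNames[j]]]
    if (nrow(xy) > 0L)
      membership[, j] <- .pointInPolygon(xy[, 1L], xy[, 2L], poly,
                                         boundary = TRUE)
    counts[j] <- sum(membership[, j])
  }
  if (nrow(xy) > 0L && any(rowSums(membership) > 1L))
    message(sum(rowSums(membership) > 1L),
            " object(s) fall in more than one ROI (ROIs overlap)")
  ratio <- NA_real_
  if (all(c("soma", "growth_cone") %in% roiNames)) {
    if (counts[["soma"]] > 0L) {
      ratio <- counts[["growth_cone"]] / counts[["soma"]]
    } else {
      warning("soma count is zero; growth-cone/soma ratio not available")
    }
  }
  structure(list(cellId = cellId, counts = counts, gcSomaRatio = ratio),
            class = "RoiCountResult")
}

#' @export
print.RoiCountResult <- function(x, ...) {
  cat("RoiCountResult [", x$cellId, "]:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat("  growth-cone/soma ratio:",
      if (is.na(x$gcSomaRatio)) "not available" else
        format(x$gcSomaRatio, digits = 4), "\n")
  invisible(x)
}
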