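# Per-slice thresholding of the marker channel, construct-positive
# restriction, whole-cell region, and object labeling.
#
# Object identity (for counting and radial analysis) is defined on 8-connected
# components of the 2-D maximum projection of the per-slice masks, so a
# punctum spanning 2-3 adjacent slices counts as one object.

.parseMethod <- function(method) {
  if (is.list(method) && !is.null(method$thresholds))
    return(list(kind = "record", thresholds = method$thresholds))
  if (!is.character(method) || length(method) != 1L)
    stop("method must be 'otsu', 'fixed:<t>', 'quantile:<q>' or a methodRecord")
  if (method == "otsu") return(list(kind = "otsu"))
  if (startsWith(method, "fixed:"))
    return(list(kind = "fixed", value = as.numeric(sub("^fixed:", "", method))))
  if (startsWith(method, "quantile:"))
    return(list(kind = "quantile",
                value = as.numeric(sub("^quantile:", "", method))))
  stop("unknown thresholding method: ", method)
}

.otsuThreshold <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(Inf)  # flat slice: empty mask
  EBImage::otsu(matrix(x), range = rng, levels = 256L)
}

# Remove connected components smaller than minSize from a logical matrix.
.sizeFilter <- function(m, minSize) {
  if (minSize <= 1L || !any(m)) return(m)
  lab <- .labelComponents(m)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz >= minSize)
  m & matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Segment the marker channel into per-slice masks and labeled objects
#'
#' Each z-slice is thresholded independently; components smaller than
#' \code{minSizePx} are removed per slice; objects are then the 8-connected
#' components of the 2-D maximum projection of the cleaned mask.
#'
#' @param stack A \linkS4class{ChannelStack} with a declared marker channel.
#' @param method \code{"otsu"} (default; a flat slice yields an empty mask),
#'   \code{"fixed:<t>"}, \code{"quantile:<q>"} (per-slice quantile), or the
#'   \code{methodRecord} of a previous run to reproduce its mask bit-exactly.
#' @param minSizePx Minimum per-slice component size in pixels (>= 1).
#' @return List with \code{mask} (\linkS4class{MaskStack}) and \code{objects}
#'   (\linkS4class{ObjectSet}).
#' @export
segmentMarker <- function(stack, method = "otsu", minSizePx = 2L) {
  stopifnot(minSizePx >= 1L)
  spec <- .parseMethod(method)
  v <- channelData(stack, "marker")
  d <- dim(v)
  m <- array(FALSE, d)
  thr <- numeric(d[1L])
  for (z in seq_len(d[1L])) {
    sl <- matrix(v[z, , ], d[2L], d[3L])
    thr[z] <- switch(spec$kind,
      otsu = .otsuThreshold(sl),
      fixed = spec$value,
      quantile = stats::quantile(sl, spec$value, names = FALSE, type = 7L),
      record = spec$thresholds[z])
    msl <- sl > thr[z]
    m[z, , ] <- .sizeFilter(msl, minSizePx)
  }
  rec <- list(method = if (spec$kind == "record") "record" else
                if (is.character(method)) method else "record",
              thresholds = thr, minSizePx = as.integer(minSizePx))
  maskStack <- MaskStack(m, sourceRole = "marker", methodRecord = rec)
  list(mask = maskStack, objects = .labelObjects(maskStack))
}

# Build the ObjectSet from the 2-D max projection of a MaskStack.
.labelObjects <- function(maskStack) {
  m <- maskStack@masks
  d <- dim(m)
  proj <- matrix(FALSE, d[2L], d[3L])
  for (z in seq_len(d[1L])) proj <- proj | matrix(m[z, , ], d[2L], d[3L])
  lab <- .labelComponents(proj)
  n <- max(lab)
  if (n == 0L) {
    return(ObjectSet(data.frame(id = integer(0), x = numeric(0),
                                y = numeric(0), z = numeric(0),
                                area = integer(0), sliceMin = integer(0),
                                sliceMax = integer(0))))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  px <- idx[, 2L] - 1; py <- idx[, 1L] - 1
  cx <- tapply(px, ids, mean)
  cy <- tapply(py, ids, mean)
  area <- tabulate(ids, n)
  sliceMin <- rep(NA_integer_, n); sliceMax <- rep(NA_integer_, n)
  zSum <- numeric(n); zCnt <- numeric(n)
  for (z in seq_len(d[1L])) {
    msl <- matrix(m[z, , ], d[2L], d[3L])
    l <- lab[msl]
    if (!length(l)) next
    tab <- tabulate(l, n)
    present <- tab > 0L
    sliceMin[present & is.na(sliceMin)] <- z
    sliceMax[present] <- z
    zSum <- zSum + (z - 1) * tab
    zCnt <- zCnt + tab
  }
  zMean <- zSum / pmax(zCnt, 1)
  ObjectSet(data.frame(id = seq_len(n), x = as.numeric(cx), y = as.numeric(cy),
                       z = zMean, area = area, sliceMin = sliceMin,
                       sliceMax = sliceMax))
}

#' Restrict a marker mask to construct-positive pixels
#'
#' Implements the double-positive inclusion rule: only organelle pixels where
#' the construct is also present enter the enrichment analysis.
#'
#' @param markerMask A \linkS4class{MaskStack} from
#'   \code{\link{segmentMarker}}.
#' @param stack The parent \linkS4class{ChannelStack} (construct channel
#'   declared).
#' @param constructThreshold Intensity threshold; pixels with construct
#'   intensity >= this value are construct-positive. The default (NULL)
#'   computes a per-cell Otsu threshold of the construct channel inside the
#'   marker mask, a pixel-level analog of requiring visible construct signal
#'   on the organelles.
#' @return A \linkS4class{MaskStack}, always a subset of \code{markerMask}.
#' @export
doublePositiveMask <- function(markerMask, stack, constructThreshold = NULL) {
  v <- channelData(stack, "construct")
  if (!identical(dim(v), dim(markerMask@masks)))
    stop("markerMask shape does not match the stack")
  if (is.null(constructThreshold)) {
    vals <- v[markerMask@masks]
    constructThreshold <- if (length(vals) == 0L) Inf else {
      rng <- range(vals)
      if (rng[1L] == rng[2L]) rng[1L]
      else EBImage::otsu(matrix(vals), range = rng, levels = 256L)
    }
  }
  m <- markerMask@masks & (v >= constructThreshold)
  MaskStack(m, sourceRole = "construct",
            methodRecord = c(markerMask@methodRecord,
                             list(constructThreshold = constructThreshold)))
}

#' Whole-cell region mask
#'
#' The domain over which "whole-cell" cytosolic background is evaluated. With
#' a geometry, the outline polygon is rasterized (boundary-inclusive) and
#' replicated across z. Without one, the fallback is the union across
#' channels of global Otsu exceedances, recorded in the method record.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param geometry Optional \linkS4class{CellGeometry}.
#' @return A \linkS4class{MaskStack}.
#' @export
cellRegion <- function(stack, geometry = NULL) {
  d <- dim(stack@voxels)
  if (!is.null(geometry)) {
    r <- .rasterizePolygon(geometry@outline, d[2L], d[3L])
    m <- array(FALSE, d[1:3])
    for (z in seq_len(d[1L])) m[z, , ] <- r
    return(MaskStack(m, sourceRole = "other",
                     methodRecord = list(method = "outline")))
  }
  m <- array(FALSE, d[1:3])
  thr <- numeric(d[4L])
  for (ch in seq_len(d[4L])) {
    vc <- array(stack@voxels[, , , ch], d[1:3])
    thr[ch] <- .otsuThreshold(vc)
    m <- m | (vc > thr[ch])
  }
  MaskStack(m, sourceRole = "other",
            methodRecord = list(method = "union-otsu", thresholds = thr))
}
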