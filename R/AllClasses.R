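#' @import methods
NULL

.CHANNEL_ROLES <- c("marker", "construct", "cargo", "other")

#' ChannelStack: a multi-channel fluorescence z-stack
#'
#' The atomic input of every pipeline stage: a 4-D non-negative intensity
#' array indexed \code{(z, y, x, channel)} with per-channel biological roles
#' and voxel spacing. Roles name what each channel images: the organelle
#' \code{marker} (e.g. a peroxisome-lumen label), the membrane-anchored
#' \code{construct} whose expression is used for normalization, the
#' \code{cargo} protein whose recruitment is scored, or \code{other}.
#'
#' @slot voxels 4-D numeric array \code{(z, y, x, channel)}, all values >= 0.
#' @slot channelRoles Character vector, one role per channel, each one of
#'   \code{"marker"}, \code{"construct"}, \code{"cargo"}, \code{"other"};
#'   \code{"marker"} and \code{"construct"} may each be declared at most once.
#' @slot zStepUm Slice spacing in micrometers (e.g. 0.3 for COS-7 stacks,
#'   0.2 for neurons).
#' @slot pixelSizeUm Lateral pixel size in micrometers.
#' @export
setClass("ChannelStack",
  representation(voxels = "array", channelRoles = "character",
                 zStepUm = "numeric", pixelSizeUm = "numeric"))

setValidity("ChannelStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 4L) return("voxels must be a 4-D (z, y, x, channel) array")
  if (any(d < 1L)) return("all stack extents must be >= 1")
  if (any(object@voxels < 0)) return("intensities must be non-negative")
  if (length(object@channelRoles) != d[4L])
    return("channelRoles must have one entry per channel")
  if (!all(object@channelRoles %in% .CHANNEL_ROLES))
    return(paste("channel roles must be one of:",
                 paste(.CHANNEL_ROLES, collapse = ", ")))
  for (role in c("marker", "construct"))
    if (sum(object@channelRoles == role) > 1L)
      return(paste0("role '", role, "' declared for more than one channel"))
  if (length(object@zStepUm) != 1L || object@zStepUm <= 0)
    return("zStepUm must be a positive scalar")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  TRUE
})

#' Construct a ChannelStack
#'
#' @param voxels 4-D array \code{(z, y, x, channel)}; intensities of any
#'   non-negative numeric type are promoted to double.
#' @param channelRoles Character vector of per-channel roles.
#' @param zStepUm,pixelSizeUm Voxel spacing in micrometers.
#' @return A \linkS4class{ChannelStack}.
#' @examples
#' v <- array(0, c(2, 8, 8, 3))
#' cs <- ChannelStack(v, c("marker", "construct", "cargo"))
#' @export
ChannelStack <- function(voxels, channelRoles,
                         zStepUm = 0.3, pixelSizeUm = 0.25) {
  storage.mode(voxels) <- "double"
  new("ChannelStack", voxels = voxels, channelRoles = channelRoles,
      zStepUm = zStepUm, pixelSizeUm = pixelSizeUm)
}

#' CellGeometry: user-supplied cell outline, center and named ROIs
#'
#' @slot outline Matrix of >= 3 \code{(x, y)} vertices in 0-based pixel
#'   coordinates (y increases downward); must be a simple polygon.
#' @slot center \code{(x, y)} point strictly inside the outline, typically the
#'   user-chosen cell center from which radial shells are drawn.
#' @slot rois Named list of simple ROI polygons (e.g. \code{"soma"},
#'   \code{"growth_cone"}).
#' @export
setClass("CellGeometry",
  representation(outline = "matrix", center = "numeric", rois = "list"))

setValidity("CellGeometry", function(object) {
  if (nrow(object@outline) < 3L) return("degenerate polygon: outline needs >= 3 vertices")
  if (ncol(object@outline) != 2L) return("outline must be an (x, y) matrix")
  if (!.isSimplePolygon(object@outline)) return("outline polygon is self-intersecting")
  if (length(object@center) != 2L) return("center must be an (x, y) point")
  if (!.pointInPolygon(object@center[1L], object@center[2L], object@outline,
                       boundary = FALSE))
    return("center not inside outline")
  if (length(object@rois)) {
    if (is.null(names(object@rois)) || any(names(object@rois) == ""))
      return("all ROI polygons must be named")
    for (nm in names(object@rois)) {
      p <- object@rois[[nm]]
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
        return(paste0("ROI '", nm, "' is not a polygon matrix"))
      if (!.isSimplePolygon(p))
        return(paste0("ROI '", nm, "' is self-intersecting"))
    }
  }
  TRUE
})

#' Construct a CellGeometry
#'
#' @param outline Matrix of \code{(x, y)} vertices.
#' @param center \code{(x, y)} point strictly inside the outline.
#' @param rois Named list of ROI polygon matrices.
#' @return A \linkS4class{CellGeometry}.
#' @examples
#' g <- CellGeometry(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), c(5, 5))
#' @export
CellGeometry <- function(outline, center, rois = list()) {
  outline <- as.matrix(outline)
  new("CellGeometry", outline = outline, center = as.numeric(center),
      rois = rois)
}

#' MaskStack: per-slice binary masks
#'
#' @slot masks 3-D logical array \code{(z, y, x)} matching the parent stack.
#' @slot sourceRole The channel role the mask was derived from.
#' @slot methodRecord List fully determining the mask given the stack
#'   (method name, per-slice thresholds, size filter), so re-running
#'   reproduces it bit-exactly.
#' @export
setClass("MaskStack",
  representation(masks = "array", sourceRole = "character",
                 methodRecord = "list"))

setValidity("MaskStack", function(object) {
  if (length(dim(object@masks)) != 3L) return("masks must be a 3-D (z, y, x) array")
  if (!is.logical(object@masks)) return("masks must be logical")
  TRUE
})

#' Construct a MaskStack
#'
#' @param masks 3-D logical array \code{(z, y, x)}.
#' @param sourceRole Channel role the mask was derived from.
#' @param methodRecord Provenance list.
#' @return A \linkS4class{MaskStack}.
#' @export
MaskStack <- function(masks, sourceRole = "other", methodRecord = list()) {
  new("MaskStack", masks = masks, sourceRole = sourceRole,
      methodRecord = methodRecord)
}

#' ObjectSet: labeled organelle objects
#'
#' Objects are 8-connected components of the 2-D maximum projection of a
#' \linkS4class{MaskStack}, so a punctum spanning several z-slices counts once.
#'
#' @slot objects \code{data.frame} with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (centroid, 0-based pixel coordinates), \code{area} (projected
#'   pixel count), \code{sliceMin}, \code{sliceMax}.
#' @export
setClass("ObjectSet", representation(objects = "data.frame"))

setValidity("ObjectSet", function(object) {
  need <- c("id", "x", "y", "z", "area", "sliceMin", "sliceMax")
  if (!all(need %in% names(object@objects)))
    return(paste("objects table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@objects$id)) return("object ids must be unique")
  TRUE
})

#' Construct an ObjectSet
#'
#' @param objects \code{data.frame} with the columns listed above.
#' @return An \linkS4class{ObjectSet}.
#' @export
ObjectSet <- function(objects) new("ObjectSet", objects = objects)

#' EnrichmentResult: per-cell cargo enrichment scores
#'
#' @slot cellId Cell identifier.
#' @slot rawEnrichment Background-subtracted mean cargo intensity on the
#'   analysis mask, averaged over used z-slices (intensity units; may be
#'   negative when cargo is depleted on the organelles).
#' @slot constructIntensity Mean construct intensity on the analysis mask,
#'   averaged over used slices.
#' @slot normalizedEnrichment \code{rawEnrichment / constructIntensity}
#'   (dimensionless).
#' @slot background Mean cytosolic cargo intensity (cell region minus marker
#'   mask), averaged over used slices.
#' @slot nSlicesUsed Number of z-slices with a non-empty analysis mask.
#' @slot analysisMaskPx Total analysis-mask pixels over used slices.
#' @export
setClass("EnrichmentResult",
  representation(cellId = "character", rawEnrichment = "numeric",
                 constructIntensity = "numeric",
                 normalizedEnrichment = "numeric", background = "numeric",
                 nSlicesUsed = "integer", analysisMaskPx = "integer"))

setValidity("EnrichmentResult", function(object) {
  if (object@nSlicesUsed < 1L) return("nSlicesUsed must be >= 1")
  if (object@analysisMaskPx <= 0L) return("analysisMaskPx must be > 0")
  if (!is.finite(object@normalizedEnrichment))
    return("normalizedEnrichment must be finite")
  TRUE
})

#' ShellSet: shape-scaled concentric shells
#'
#' Shell boundaries are scaled copies of the cell outline about the center
#' with factors \code{k / nShells}; boundary \code{nShells} is the outline
#' itself, so the shells follow the shape of the cell.
#'
#' @slot nShells Number of shells.
#' @slot boundaries List of boundary polygons, innermost first.
#' @slot center \code{(x, y)} shell origin.
#' @slot outline The generating outline polygon.
#' @export
setClass("ShellSet",
  representation(nShells = "integer", boundaries = "list",
                 center = "numeric", outline = "matrix"))

#' ShellDistribution: percentage frequency of objects per shell
#'
#' @slot frequencies Numeric vector of per-shell percentages; sums to 100
#'   whenever any object was included.
#' @slot nIncluded,nExcluded Numbers of objects inside / outside the outline.
#' @export
setClass("ShellDistribution",
  representation(frequencies = "numeric", nIncluded = "integer",
                 nExcluded = "integer"))

setValidity("ShellDistribution", function(object) {
  if (any(object@frequencies < 0)) return("frequencies must be >= 0")
  if (object@nIncluded > 0L &&
      abs(sum(object@frequencies) - 100) > 1e-6)
    return("frequencies must sum to 100 when objects are included")
  TRUE
})
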