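#' @rdname accessors
#' @export
setMethod("voxels", "ChannelStack", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("channelRoles", "ChannelStack", function(object) object@channelRoles)

#' @rdname accessors
#' @export
setMethod("zStepUm", "ChannelStack", function(object) object@zStepUm)

#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "ChannelStack", function(object) object@pixelSizeUm)

.channelIndex <- function(stack, which) {
  if (is.character(which)) {
    idx <- match(which, stack@channelRoles)
    if (is.na(idx))
      stop("stack has no channel with role '", which, "'")
  } else {
    idx <- as.integer(which)
    if (idx < 1L || idx > dim(stack@voxels)[4L])
      stop("channel index out of range")
  }
  idx
}

#' @rdname channelData
#' @export
setMethod("channelData", "ChannelStack", function(object, which) {
  idx <- .channelIndex(object, which)
  d <- dim(object@voxels)
  array(object@voxels[, , , idx], d[1:3])
})

#' @rdname accessors
#' @export
setMethod("cellOutline", "CellGeometry", function(object) object@outline)

#' @rdname accessors
#' @export
setMethod("cellCenter", "CellGeometry", function(object) object@center)

#' @rdname accessors
#' @export
setMethod("cellRois", "CellGeometry", function(object) object@rois)

#' @rdname accessors
#' @export
setMethod("masks", "MaskStack", function(object) object@masks)

#' @rdname accessors
#' @export
setMethod("methodRecord", "MaskStack", function(object) object@methodRecord)

#' @rdname accessors
#' @export
setMethod("objectTable", "ObjectSet", function(object) object@objects)

#' @rdname accessors
#' @export
setMethod("nShells", "ShellSet", function(object) object@nShells)

#' @rdname accessors
#' @export
setMethod("shellBoundaries", "ShellSet", function(object) object@boundaries)

#' @rdname accessors
#' @export
setMethod("shellFrequencies", "ShellDistribution",
          function(object) object@frequencies)

#' @rdname accessors
#' @export
setMethod("nIncluded", "ShellDistribution", function(object) object@nIncluded)

#' @rdname accessors
#' @export
setMethod("nExcluded", "ShellDistribution", function(object) object@nExcluded)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@voxels)
  cat("ChannelStack:", d[1L], "slices x", d[2L], "x", d[3L], "px x",
      d[4L], "channels\n")
  cat("  roles:", paste(object@channelRoles, collapse = ", "), "\n")
  cat("  voxel spacing:", object@zStepUm, "um (z) x",
      object@pixelSizeUm, "um (xy)\n")
})

setMethod("show", "CellGeometry", function(object) {
  cat("CellGeometry: outline with", nrow(object@outline), "vertices,",
      "center (", object@center[1L], ",", object@center[2L], ")\n")
  if (length(object@rois))
    cat("  ROIs:", paste(names(object@rois), collapse = ", "), "\n")
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@masks)
  cat("MaskStack:", d[1L], "slices x", d[2L], "x", d[3L], "px;",
      sum(object@masks), "foreground voxels\n")
  if (length(object@methodRecord))
    cat("  method:", object@methodRecord$method %||% "?", "\n")
})

setMethod("show", "ObjectSet", function(object) {
  cat("ObjectSet:", nrow(object@objects), "objects\n")
  if (nrow(object@objects))
    print(utils::head(object@objects, 5L))
})

setMethod("show", "ShellSet", function(object) {
  cat("ShellSet:", object@nShells, "shape-scaled shells about (",
      object@center[1L], ",", object@center[2L], ")\n")
})

setMethod("show", "ShellDistribution", function(object) {
  cat("ShellDistribution (%):",
      paste(sprintf("%.1f", object@frequencies), collapse = " "), "\n")
  cat("  objects included:", object@nIncluded,
      "excluded:", object@nExcluded, "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult [", object@cellId, "]\n")
  cat(sprintf("  raw: %.4g  construct: %.4g  normalized: %.4g\n",
              object@rawEnrichment, object@constructIntensity,
              object@normalizedEnrichment))
  cat(sprintf("  background: %.4g  slices used: %d  mask px: %d\n",
              object@background, object@nSlicesUsed, object@analysisMaskPx))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert enrichment results to a tidy table
#'
#' @param results A single \linkS4class{EnrichmentResult} or a list of them.
#' @param condition Optional condition label(s) recycled across rows.
#' @return \code{data.frame} with one row per cell.
#' @export
enrichmentTable <- function(results, condition = NA_character_) {
  if (is(results, "EnrichmentResult")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(cellId = r@cellId, rawEnrichment = r@rawEnrichment,
               constructIntensity = r@constructIntensity,
               normalizedEnrichment = r@normalizedEnrichment,
               background = r@background, nSlicesUsed = r@nSlicesUsed,
               analysisMaskPx = r@analysisMaskPx,
               stringsAsFactors = FALSE)
  }))
  df$condition <- rep_len(condition, nrow(df))
  df
}
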