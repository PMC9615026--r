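#' @name accessors
#' @title Accessors for pexquant classes
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than \code{@} access.
#' @param object A pexquant S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("zStepUm", function(object) standardGeneric("zStepUm"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname accessors
#' @export
setGeneric("cellOutline", function(object) standardGeneric("cellOutline"))

#' @rdname accessors
#' @export
setGeneric("cellCenter", function(object) standardGeneric("cellCenter"))

#' @rdname accessors
#' @export
setGeneric("cellRois", function(object) standardGeneric("cellRois"))

#' @rdname accessors
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("methodRecord", function(object) standardGeneric("methodRecord"))

#' @rdname accessors
#' @export
setGeneric("objectTable", function(object) standardGeneric("objectTable"))

#' @rdname accessors
#' @export
setGeneric("nShells", function(object) standardGeneric("nShells"))

#' @rdname accessors
#' @export
setGeneric("shellBoundaries", function(object) standardGeneric("shellBoundaries"))

#' @rdname accessors
#' @export
setGeneric("shellFrequencies", function(object) standardGeneric("shellFrequencies"))

#' @rdname accessors
#' @export
setGeneric("nIncluded", function(object) standardGeneric("nIncluded"))

#' @rdname accessors
#' @export
setGeneric("nExcluded", function(object) standardGeneric("nExcluded"))

#' Extract a single channel of a stack as a 3-D (z, y, x) array
#'
#' @param object A \linkS4class{ChannelStack}.
#' @param which Channel role name (e.g. \code{"marker"}) or channel index.
#' @return 3-D numeric array.
#' @export
setGeneric("channelData", function(object, which) standardGeneric("channelData"))
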